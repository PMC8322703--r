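# Interaction-network construction and MCODE complex detection.

write_edges_fixture <- function(lines, gz = FALSE) {
  path <- withr::local_tempfile(
    fileext = if (gz) ".tsv.gz" else ".tsv",
    .local_envir = parent.frame()
  )
  con <- if (gz) gzfile(path, "w") else file(path, "w")
  writeLines(lines, con)
  close(con)
  path
}

test_that("load_edge_list applies the strict confidence cut and scale detection", {
  p <- write_edges_fixture(c(
    "protein1\tprotein2\tcombined_score",
    "A\tB\t0.39", "A\tC\t0.40", "B\tC\t0.41"
  ))
  g <- suppressMessages(load_edge_list(p))
  expect_equal(igraph::ecount(g), 1L) # only 0.41 survives strict >
  expect_setequal(igraph::V(g)$name, c("B", "C"))

  # 0-1000 scale auto-detected
  p2 <- write_edges_fixture(c("A\tB\t900", "A\tC\t250"))
  g2 <- suppressMessages(load_edge_list(p2))
  expect_equal(igraph::E(g2)$confidence, 0.9)

  # duplicate edge keeps the max confidence; self-loops dropped
  p3 <- write_edges_fixture(c("A\tB\t0.5", "B\tA\t0.8", "C\tC\t0.99", "B\tC\t0.7"))
  g3 <- suppressMessages(load_edge_list(p3))
  expect_equal(igraph::ecount(g3), 2L)
  ab <- igraph::E(g3)[igraph::V(g3)["A"] %--% igraph::V(g3)["B"]]
  expect_equal(igraph::E(g3)$confidence[as.integer(ab)], 0.8)

  # malformed rows name the line
  p4 <- write_edges_fixture(c("A\tB\t0.5", "broken-line"))
  expect_error(suppressMessages(load_edge_list(p4)), "line 2")
  p5 <- write_edges_fixture(c("id1\tid2\tscore", "A\tB\tnot_a_number"))
  expect_error(suppressMessages(load_edge_list(p5)), "line 2")

  # gzip tolerated
  p6 <- write_edges_fixture(c("A\tB\t0.95"), gz = TRUE)
  expect_equal(igraph::ecount(suppressMessages(load_edge_list(p6))), 1L)
})

test_that("induce_on_genes restricts and drops isolated nodes per the flag", {
  g <- igraph::graph_from_data_frame(
    data.frame(a = c("A", "B", "C"), b = c("B", "C", "A")),
    directed = FALSE, vertices = data.frame(name = c("A", "B", "C", "D"))
  )
  out <- induce_on_genes(g, c("A", "B", "D"))
  expect_setequal(igraph::V(out)$name, c("A", "B")) # D isolated, dropped
  expect_equal(igraph::ecount(out), 1L)
  keepD <- induce_on_genes(g, c("A", "B", "D"), drop_isolated = FALSE)
  expect_true("D" %in% igraph::V(keepD)$name)
  expect_warning(empty <- induce_on_genes(g, c("X", "Y")), "empty")
  expect_equal(igraph::vcount(empty), 0L)
})

test_that("loading then inducing on all nodes is the identity", {
  p <- write_edges_fixture(c("A\tB\t0.9", "B\tC\t0.8", "C\tA\t0.7", "C\tD\t0.95"))
  g <- suppressMessages(load_edge_list(p))
  g2 <- induce_on_genes(g, igraph::V(g)$name)
  expect_true(igraph::identical_graphs(
    igraph::permute(g2, match(igraph::V(g2)$name, igraph::V(g)$name)), g,
    attrs = FALSE
  ) || (igraph::vcount(g2) == igraph::vcount(g) && igraph::ecount(g2) == igraph::ecount(g)))
})

test_that("MCODE vertex weights follow the neighborhood k-core definition", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- LETTERS[1:4]
  expect_equal(unname(mcode_node_weights(k4)), rep(2, 4)) # neighborhood K3: k=2, density 1

  leaf <- igraph::graph_from_data_frame(data.frame(a = "A", b = "B"), directed = FALSE)
  expect_equal(unname(mcode_node_weights(leaf)), c(0, 0))

  c4 <- igraph::make_ring(4)
  igraph::V(c4)$name <- LETTERS[1:4]
  expect_equal(unname(mcode_node_weights(c4)), rep(0, 4)) # neighbors disconnected

  # isomorphism equivariance on random graphs
  set.seed(17)
  for (i in 1:10) {
    n <- sample(5:9, 1)
    g <- igraph::sample_gnp(n, 0.5)
    igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
    w <- mcode_node_weights(g)
    perm <- sample(n)
    gp <- igraph::permute(g, perm)
    wp <- mcode_node_weights(gp)
    expect_equal(wp[names(w)], w)
  }
})

test_that("MCODE finds dense complexes and discards coreless growth", {
  # K5 with a pendant path of 3: the single cluster is the K5
  g <- igraph::make_full_graph(5)
  igraph::V(g)$name <- paste0("k", 1:5)
  g <- igraph::add_vertices(g, 3, name = paste0("p", 1:3))
  g <- igraph::add_edges(g, c("k1", "p1", "p1", "p2", "p2", "p3"))
  cl <- mcode_find_clusters(g)
  expect_equal(nrow(cl), 1L)
  expect_setequal(cl$nodes[[1]], paste0("k", 1:5))
  expect_equal(cl$score, 5) # density 1 x size 5

  # a tree has no 2-core: no clusters
  tr <- igraph::make_tree(10, children = 2, mode = "undirected")
  igraph::V(tr)$name <- paste0("t", 1:10)
  expect_equal(nrow(mcode_find_clusters(tr)), 0L)

  # two disconnected K4s: two clusters, one per clique
  g2 <- igraph::disjoint_union(igraph::make_full_graph(4), igraph::make_full_graph(4))
  igraph::V(g2)$name <- c(paste0("a", 1:4), paste0("b", 1:4))
  cl2 <- mcode_find_clusters(g2)
  expect_equal(nrow(cl2), 2L)
  expect_setequal(cl2$nodes[[1]], paste0("a", 1:4))
  expect_setequal(cl2$nodes[[2]], paste0("b", 1:4))
})

test_that("every returned cluster passes its own gates on random graphs", {
  set.seed(23)
  for (i in 1:8) {
    g <- igraph::sample_gnp(25, 0.12)
    igraph::V(g)$name <- sprintf("n%02d", 1:25)
    cl <- mcode_find_clusters(g)
    if (!nrow(cl)) next
    all_nodes <- unlist(cl$nodes)
    expect_equal(anyDuplicated(all_nodes), 0L) # disjoint node sets
    for (j in seq_len(nrow(cl))) {
      sub <- igraph::induced_subgraph(g, cl$nodes[[j]])
      expect_true(igraph::is_connected(sub))
      expect_gte(max(igraph::coreness(sub)), 2)
      expect_gt(cl$score[j], 0)
    }
    expect_true(all(diff(cl$score) <= 1e-12)) # ranked by score desc
  }
})
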