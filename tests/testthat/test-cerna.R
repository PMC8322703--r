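# ceRNA assembly: intersection, direction validation, circRNA attachment,
# coverage filter, network invariants, MCC ranking.

toy_targets <- function() {
  # 5/4/3 pairs across the three sources, 2 pairs common to all three
  tibble::tibble(
    mirna = c(
      "m1", "m2", "m3", "m4", "m5", # targetscan
      "m1", "m2", "m3", "m6", # mirdb
      "m1", "m2", "m7" # mirwalk
    ),
    mrna = c(
      "gA", "gB", "gC", "gD", "gE",
      "gA", "gB", "gC2", "gF",
      "gA", "gB", "gG"
    ),
    source = rep(c("targetscan", "mirdb", "mirwalk"), c(5, 4, 3))
  )
}

test_that("intersect_three_dbs keeps pairs present in all three sources", {
  out <- intersect_three_dbs(toy_targets())
  expect_equal(nrow(out), 2L)
  expect_setequal(paste(out$mirna, out$mrna), c("m1 gA", "m2 gB"))
  two <- dplyr::filter(toy_targets(), source != "mirwalk")
  expect_error(intersect_three_dbs(two), "three")
})

test_that("validate_directions keeps only opposite-direction pairs", {
  pairs <- tibble::tibble(mirna = c("M", "M2", "M3"), mrna = c("G", "G", "G2"))
  demis <- tibble::tibble(
    mirna = c("M", "M2"),
    direction = c("down", "up")
  )
  dirs <- c(G = "up", G2 = "down")
  out <- validate_directions(pairs, demis, dirs)
  expect_equal(nrow(out), 1L)
  expect_equal(out$mirna, "M") # up-gene + down-miRNA kept
  # M2 same direction dropped; M3 absent from demis dropped
  expect_error(
    validate_directions(pairs, demis, c(G = "up")),
    "no direction given .*G2"
  )
  # property: never a same-direction pair in the output
  set.seed(41)
  for (i in 1:20) {
    p <- tibble::tibble(
      mirna = sample(paste0("mi", 1:6), 10, replace = TRUE),
      mrna = sample(paste0("g", 1:4), 10, replace = TRUE)
    )
    d <- tibble::tibble(
      mirna = paste0("mi", 1:5),
      direction = sample(c("up", "down"), 5, replace = TRUE)
    )
    gd <- setNames(sample(c("up", "down"), 4, replace = TRUE), paste0("g", 1:4))
    v <- validate_directions(p, d, gd)
    if (nrow(v)) expect_true(all(v$mirna_direction != v$mrna_direction))
  }
})

test_that("attach_circrnas drops mRNAs whose miRNAs all lack circRNA partners", {
  pairs <- tibble::tibble(
    mirna = c("m1", "m2", "m3", "m4"),
    mrna = c("g1", "g2", "g2", "g3")
  )
  circ <- tibble::tibble(circrna = c("c1", "c1", "c2"), mirna = c("m1", "m3", "m3"))
  out <- attach_circrnas(pairs, circ)
  expect_setequal(out$kept_mrnas, c("g1", "g2")) # g2 kept through m3
  expect_equal(out$dropped_mrnas, "g3") # m4 has no circ row
  expect_setequal(out$candidate_circs, c("c1", "c2"))
  # all-dropped case warns
  expect_warning(
    empty <- attach_circrnas(pairs, tibble::tibble(circrna = character(), mirna = character())),
    "all mRNAs dropped"
  )
  expect_equal(length(empty$kept_mrnas), 0L)
})

test_that("coverage_filter equals the exhaustive circ-by-mRNA oracle", {
  cover_oracle <- function(circs, mrnas, pairs, circ) {
    keep <- character()
    for (cc in circs) {
      ok <- TRUE
      for (g in mrnas) {
        mi_c <- circ$mirna[circ$circrna == cc]
        mi_g <- pairs$mirna[pairs$mrna == g]
        if (!length(intersect(mi_c, mi_g))) {
          ok <- FALSE
          break
        }
      }
      if (ok) keep <- c(keep, cc)
    }
    sort(keep)
  }
  # hand case: c covers all 3 mRNAs, c2 only 2 of 3
  pairs <- tibble::tibble(mirna = c("m1", "m2", "m3"), mrna = c("g1", "g2", "g3"))
  circ <- tibble::tibble(
    circrna = c("c", "c", "c", "c2", "c2"),
    mirna = c("m1", "m2", "m3", "m1", "m2")
  )
  expect_equal(coverage_filter(c("c", "c2"), paste0("g", 1:3), pairs, circ), "c")
  # single-mRNA network: any circ touching one of its miRNAs is retained
  expect_setequal(coverage_filter(c("c", "c2"), "g1", pairs, circ), c("c", "c2"))
  # empty circ table: nothing retained
  expect_equal(
    coverage_filter(character(), "g1", pairs, tibble::tibble(circrna = character(), mirna = character())),
    character()
  )
  # random instances against the double-loop oracle
  set.seed(53)
  for (i in 1:25) {
    pairs <- tibble::tibble(
      mirna = sample(paste0("m", 1:6), 12, replace = TRUE),
      mrna = sample(paste0("g", 1:4), 12, replace = TRUE)
    ) |> dplyr::distinct()
    circ <- tibble::tibble(
      circrna = sample(paste0("c", 1:5), 10, replace = TRUE),
      mirna = sample(paste0("m", 1:6), 10, replace = TRUE)
    ) |> dplyr::distinct()
    att <- suppressWarnings(attach_circrnas(pairs, circ))
    got <- coverage_filter(att$candidate_circs, att$kept_mrnas, pairs, circ)
    expect_equal(got, cover_oracle(att$candidate_circs, att$kept_mrnas, pairs, circ))
  }
})

test_that("build_cerna_network enforces the tripartite invariants", {
  pairs <- tibble::tibble(mirna = c("m1", "m2"), mrna = c("g1", "g2"))
  circ <- tibble::tibble(circrna = c("c1", "c1"), mirna = c("m1", "m2"))
  net <- build_cerna_network("c1", c("g1", "g2"), pairs, circ,
    dirs = c(g1 = "up", g2 = "down")
  )
  expect_equal(nrow(net$nodes), 5L)
  expect_equal(nrow(net$edges), 4L)
  expect_equal(glance(net)$n_circrna, 1L)
  # a validated miRNA not targeted by a retained circ is excluded
  pairs2 <- dplyr::bind_rows(pairs, tibble::tibble(mirna = "m9", mrna = "g1"))
  net2 <- build_cerna_network("c1", c("g1", "g2"), pairs2, circ,
    dirs = c(g1 = "up", g2 = "down")
  )
  expect_false("m9" %in% net2$nodes$node)
  # classes partition and no forbidden edges on random instances
  set.seed(61)
  for (i in 1:15) {
    p <- tibble::tibble(
      mirna = sample(paste0("m", 1:5), 8, replace = TRUE),
      mrna = sample(paste0("g", 1:3), 8, replace = TRUE)
    ) |> dplyr::distinct()
    cc <- tibble::tibble(
      circrna = sample(paste0("c", 1:3), 8, replace = TRUE),
      mirna = sample(paste0("m", 1:5), 8, replace = TRUE)
    ) |> dplyr::distinct()
    att <- suppressWarnings(attach_circrnas(p, cc))
    ret <- coverage_filter(att$candidate_circs, att$kept_mrnas, p, cc)
    if (!length(ret) || !length(att$kept_mrnas)) next
    nn <- build_cerna_network(ret, att$kept_mrnas, p, cc)
    expect_equal(anyDuplicated(nn$nodes$node), 0L)
    cls <- setNames(nn$nodes$class, nn$nodes$node)
    pairs_cls <- paste(cls[nn$edges$from], cls[nn$edges$to])
    expect_true(all(pairs_cls %in% c("circRNA miRNA", "miRNA mRNA")))
  }
})

test_that("MCC ranking of a tripartite tree reduces to degree", {
  pairs <- tibble::tibble(
    mirna = c("mHub", "mHub", "mHub", "mHub", "m2"),
    mrna = c("g1", "g2", "g3", "g4", "g5")
  )
  circ <- tibble::tibble(circrna = c("c1", "c1"), mirna = c("mHub", "m2"))
  net <- build_cerna_network("c1", paste0("g", 1:5), pairs, circ)
  mcc <- centrality(net$graph, "MCC")
  deg <- igraph::degree(net$graph)
  expect_equal(mcc[names(deg)], deg) # triangle-free: every maximal clique is an edge
  ranked <- rank_cerna_mcc(net, top = 3)
  expect_equal(ranked[1], "mHub") # degree-5 hub miRNA first
  expect_equal(length(rank_cerna_mcc(net, top = 50)), nrow(net$nodes))
})

test_that("the shipped validated-pair fixture drives the full worked example", {
  pairs <- read_validated_pairs(
    system.file("extdata", "asthma_hub_mirna_pairs.tsv", package = "cernaflow")
  )
  expect_equal(nrow(pairs), 45L)
  expect_equal(dplyr::n_distinct(pairs$mrna), 14L)
  # the two single-miRNA genes whose miRNAs lack circRNA partners drop out
  supported <- setdiff(unique(pairs$mirna), c("hsa-miR-1293", "hsa-miR-3664-5p"))
  circ <- tibble::tibble(circrna = "hsa_circ_synthetic_1", mirna = supported)
  att <- attach_circrnas(pairs, circ)
  expect_setequal(att$dropped_mrnas, c("CST4", "CTSG"))
  expect_equal(length(att$kept_mrnas), 12L)
})

test_that("end-to-end assembly keeps planted triplets and rejects every decoy class", {
  sim <- simulate_cerna_tables(seed = 7)
  net <- assemble_cerna(sim$targets, sim$demis, sim$truth$mrna_dirs, sim$circ)
  steps <- attr(net, "steps")
  circs <- net$nodes$node[net$nodes$class == "circRNA"]
  expect_setequal(circs, sim$truth$circs)
  expect_setequal(
    net$nodes$node[net$nodes$class == "mRNA"],
    sim$truth$pairs$mrna
  )
  # decoy A (missing source) fails intersection
  expect_false(any(sim$truth$decoys$missing_source$mrna %in% steps$intersected$mrna))
  # decoy B (same direction) fails validation
  expect_true(all(sim$truth$decoys$same_direction$mrna %in% steps$intersected$mrna))
  expect_false(any(sim$truth$decoys$same_direction$mrna %in% steps$validated$mrna))
  # decoy C (partial coverage) fails the coverage filter
  expect_true(all(sim$truth$decoys$partial_coverage %in% steps$candidate_circs))
  expect_false(any(sim$truth$decoys$partial_coverage %in% steps$retained_circs))
})
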