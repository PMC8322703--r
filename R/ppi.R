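# Protein-protein interaction network handling: confidence-filtered edge
# lists (STRING-dump layout), induced DEG subnetworks, and an MCODE
# implementation (k-core-based vertex weighting, seeded greedy growth,
# 2-core haircut).

as_named_graph <- function(net) {
  if (is.null(igraph::V(net)$name)) {
    igraph::V(net)$name <- as.character(seq_len(igraph::vcount(net)))
  }
  net
}

edge_table_to_network <- function(edges, min_conf = 0.4) {
  edges <- as_tibble(edges)
  names(edges)[1:3] <- c("a", "b", "confidence")
  edges$confidence <- as.numeric(edges$confidence)
  n_in <- nrow(edges)
  if (n_in && max(edges$confidence) > 1) edges$confidence <- edges$confidence / 1000
  loops <- edges$a == edges$b
  edges <- edges[!loops, , drop = FALSE]
  # canonical undirected pair; duplicates keep the maximum confidence
  lo <- pmin(edges$a, edges$b)
  hi <- pmax(edges$a, edges$b)
  edges$a <- lo
  edges$b <- hi
  edges <- edges |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::summarise(confidence = max(.data$confidence), .groups = "drop")
  n_dedup <- nrow(edges)
  edges <- edges[edges$confidence > min_conf, , drop = FALSE]
  inform(sprintf(
    "edge list: %d rows in, %d self-loops dropped, %d duplicates merged, %d edges kept at confidence > %g.",
    n_in, sum(loops), n_in - sum(loops) - n_dedup, nrow(edges), min_conf
  ))
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

#' Load a confidence-scored interaction edge list
#'
#' Reads a TSV with two identifier columns and a combined-score column
#' (STRING-dump layout; a header row is tolerated). Scores on a 0-1000 scale
#' are auto-detected (maximum > 1) and divided by 1000. Edges are kept when
#' confidence is strictly above `min_conf`; self-loops are dropped and
#' duplicate pairs are merged keeping the maximum confidence.
#'
#' @param path TSV path (optionally gzip-compressed).
#' @param min_conf Confidence cut (strict `>`; default 0.4).
#'
#' @return An undirected simple [igraph::graph] with edge attribute
#'   `confidence`.
#' @export
load_edge_list <- function(path, min_conf = 0.4) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("edge list file is empty.")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  if (length(fields[[1]]) >= 3 && is.na(suppressWarnings(as.numeric(fields[[1]][3])))) {
    start <- 2L # header row
  }
  if (start > length(fields)) abort("edge list has a header but no data rows.")
  rows <- fields[start:length(fields)]
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) < 3 || is.na(suppressWarnings(as.numeric(f[3])))) {
      abort(sprintf("malformed edge list row at line %d.", i + start - 1L))
    }
  }
  edges <- tibble(
    a = vapply(rows, `[`, character(1), 1),
    b = vapply(rows, `[`, character(1), 2),
    confidence = as.numeric(vapply(rows, `[`, character(1), 3))
  )
  edge_table_to_network(edges, min_conf = min_conf)
}

#' Induce a network on a gene set
#'
#' Subgraph on the intersection of `genes` with the network's nodes; nodes
#' left with degree zero are removed when `drop_isolated` is `TRUE`
#' (the "hide disconnected nodes" convention).
#'
#' @param net An [igraph::graph] with named vertices.
#' @param genes Character vector of gene symbols.
#' @param drop_isolated Drop degree-zero nodes from the induced graph
#'   (default `TRUE`).
#'
#' @return The induced [igraph::graph] (possibly empty, with a warning).
#' @export
induce_on_genes <- function(net, genes, drop_isolated = TRUE) {
  net <- as_named_graph(net)
  keep <- intersect(unique(genes), igraph::V(net)$name)
  g <- igraph::induced_subgraph(net, keep)
  if (drop_isolated && igraph::vcount(g)) {
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  }
  if (igraph::vcount(g) == 0) warn("induced network is empty.")
  g
}

#' MCODE vertex weights
#'
#' For each node `v`, take the subgraph induced on its neighbors (excluding
#' `v`), find its highest k-core `K`, and set
#' `weight(v) = k(K) * density(K)` with `density = 2|E| / (|V|(|V|-1))`
#' (a single node has density 0). Dense, clique-like neighborhoods score
#' high; leaves and sparse stars score 0.
#'
#' @param net An [igraph::graph].
#' @return Named numeric vector of node weights.
#' @export
mcode_node_weights <- function(net) {
  net <- as_named_graph(net)
  n <- igraph::vcount(net)
  w <- setNames(numeric(n), igraph::V(net)$name)
  if (!n) {
    return(w)
  }
  for (i in seq_len(n)) {
    nb <- setdiff(as.integer(igraph::neighbors(net, i)), i)
    if (length(nb) < 2) next
    g2 <- igraph::induced_subgraph(net, nb)
    core <- igraph::coreness(g2)
    k <- max(core)
    if (k == 0) next
    kk <- igraph::induced_subgraph(g2, which(core >= k))
    nv <- igraph::vcount(kk)
    dens <- if (nv < 2) 0 else 2 * igraph::ecount(kk) / (nv * (nv - 1))
    w[i] <- k * dens
  }
  w
}

#' Find dense clusters with the MCODE procedure
#'
#' Seeds are unvisited nodes in decreasing [mcode_node_weights()] order
#' (ties by node id); from each seed a cluster grows breadth-first through
#' neighbors whose weight is at least `(1 - node_score_cut)` times the seed
#' weight, up to `max_depth` hops. A 2-core haircut trims singly connected
#' periphery, clusters whose core number falls below `k_core` are discarded,
#' and each surviving cluster is the component containing its seed. Clusters
#' have disjoint node sets and are ranked by `score = density * size`.
#'
#' @param net An [igraph::graph].
#' @param node_score_cut Growth tolerance below the seed weight (default 0.2).
#' @param degree_cut Minimum degree for a node to seed a cluster (default 2).
#' @param k_core Minimum core number a cluster must retain (default 2).
#' @param haircut Apply the 2-core haircut (default `TRUE`).
#' @param max_depth Maximum growth depth from the seed (default 100).
#'
#' @return Tibble with one row per cluster: `cluster`, `seed`, `n_nodes`,
#'   `n_edges`, `density`, `score`, and a `nodes` list-column (sorted node
#'   ids), ordered by score descending.
#' @export
mcode_find_clusters <- function(net, node_score_cut = 0.2, degree_cut = 2,
                                k_core = 2, haircut = TRUE, max_depth = 100) {
  net <- as_named_graph(net)
  n <- igraph::vcount(net)
  empty <- tibble(
    cluster = integer(), seed = character(), n_nodes = integer(),
    n_edges = integer(), density = numeric(), score = numeric(),
    nodes = list()
  )
  if (!n) {
    return(empty)
  }
  w <- mcode_node_weights(net)
  nms <- igraph::V(net)$name
  deg <- igraph::degree(net)
  adj <- igraph::adjacent_vertices(net, igraph::V(net))
  visited <- rep(FALSE, n)
  out <- list()
  for (s in order(-w, nms)) {
    if (visited[s] || deg[s] < degree_cut) next
    thr <- (1 - node_score_cut) * w[s]
    visited[s] <- TRUE
    members <- s
    depth <- c(0L)
    queue <- 1L
    while (length(queue)) {
      v <- members[queue[1]]
      dv <- depth[queue[1]]
      queue <- queue[-1]
      if (dv >= max_depth) next
      for (u in as.integer(adj[[v]])) {
        if (!visited[u] && w[u] >= thr) {
          visited[u] <- TRUE
          members <- c(members, u)
          depth <- c(depth, dv + 1L)
          queue <- c(queue, length(members))
        }
      }
    }
    sub <- igraph::induced_subgraph(net, members)
    if (haircut && igraph::vcount(sub)) {
      sub <- igraph::induced_subgraph(sub, which(igraph::coreness(sub) >= 2))
    }
    if (!igraph::vcount(sub)) next
    if (max(igraph::coreness(sub)) < k_core) next
    comp <- igraph::components(sub)
    seed_name <- nms[s]
    cid <- if (seed_name %in% igraph::V(sub)$name) {
      comp$membership[[seed_name]]
    } else {
      candidates <- which(comp$csize == max(comp$csize))
      first_node <- vapply(candidates, function(cc) {
        min(igraph::V(sub)$name[comp$membership == cc])
      }, character(1))
      candidates[order(first_node)][1]
    }
    sub <- igraph::induced_subgraph(sub, which(comp$membership == cid))
    nv <- igraph::vcount(sub)
    ne <- igraph::ecount(sub)
    dens <- if (nv < 2) 0 else 2 * ne / (nv * (nv - 1))
    score <- dens * nv
    if (score <= 0) next
    out[[length(out) + 1]] <- tibble(
      seed = seed_name, n_nodes = nv, n_edges = ne,
      density = dens, score = score,
      nodes = list(sort(igraph::V(sub)$name))
    )
  }
  if (!length(out)) {
    return(empty)
  }
  res <- dplyr::bind_rows(out)
  res <- res[order(-res$score, -res$n_nodes, res$seed), ]
  res <- dplyr::mutate(res, cluster = dplyr::row_number(), .before = 1)
  res
}

#' Export a network as an edge TSV
#' @param net An [igraph::graph].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  net <- as_named_graph(net)
  el <- igraph::as_edgelist(net)
  tbl <- tibble(a = el[, 1], b = el[, 2])
  conf <- igraph::edge_attr(net, "confidence")
  if (!is.null(conf)) tbl$confidence <- conf
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Export a network as node-link JSON
#' @param net An [igraph::graph].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(net, path) {
  net <- as_named_graph(net)
  el <- igraph::as_edgelist(net)
  nodes <- lapply(seq_len(igraph::vcount(net)), function(i) {
    node <- list(id = igraph::V(net)$name[i])
    for (a in igraph::vertex_attr_names(net)) {
      if (a != "name") node[[a]] <- igraph::vertex_attr(net, a, i)
    }
    node
  })
  links <- lapply(seq_len(nrow(el)), function(i) list(source = el[i, 1], target = el[i, 2]))
  jsonlite::write_json(list(nodes = nodes, links = links), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
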