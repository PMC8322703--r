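# The ten topological centralities of the cytoHubba-style hub ensemble.
# All treat the graph as simple and undirected and ignore edge attributes.
# MCC, DMNC, MNC, EPC, BottleNeck and Radiality follow the definitions
# documented below; Degree, Betweenness and shortest-path distances come
# from igraph primitives. Closeness is the harmonic (reciprocal-distance)
# form, well-defined on disconnected graphs.

#' The ten hub-ensemble centrality methods
#' @export
CENTRALITY_METHODS <- c(
  "MCC", "DMNC", "MNC", "Degree", "EPC",
  "BottleNeck", "EcCentricity", "Closeness", "Radiality", "Betweenness"
)

graph_distances <- function(net) {
  igraph::distances(net, weights = NA)
}

mcc_scores <- function(net) {
  s <- setNames(numeric(igraph::vcount(net)), igraph::V(net)$name)
  if (igraph::ecount(net) == 0) {
    return(s)
  }
  cliques <- igraph::max_cliques(net, min = 2)
  for (cl in cliques) {
    idx <- as.integer(cl)
    s[idx] <- s[idx] + factorial(length(idx) - 1)
  }
  s
}

# Largest connected component of the neighbor-induced subgraph of v
# (v excluded). Ties among equally large components go to the one holding
# the lexicographically smallest node id.
neighborhood_component <- function(net, i) {
  nb <- setdiff(as.integer(igraph::neighbors(net, i)), i)
  if (!length(nb)) {
    return(NULL)
  }
  g2 <- igraph::induced_subgraph(net, nb)
  comp <- igraph::components(g2)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1) {
    first_node <- vapply(big, function(cc) {
      min(igraph::V(g2)$name[comp$membership == cc])
    }, character(1))
    big <- big[order(first_node)][1]
  }
  igraph::induced_subgraph(g2, which(comp$membership == big[1]))
}

mnc_scores <- function(net) {
  vapply(seq_len(igraph::vcount(net)), function(i) {
    g <- neighborhood_component(net, i)
    if (is.null(g)) 0 else igraph::vcount(g)
  }, numeric(1)) |> setNames(igraph::V(net)$name)
}

dmnc_scores <- function(net) {
  vapply(seq_len(igraph::vcount(net)), function(i) {
    g <- neighborhood_component(net, i)
    if (is.null(g)) 0 else igraph::ecount(g) / igraph::vcount(g)^1.7
  }, numeric(1)) |> setNames(igraph::V(net)$name)
}

closeness_scores <- function(net) {
  d <- graph_distances(net)
  diag(d) <- Inf # exclude self; 1/Inf = 0
  setNames(rowSums(1 / d), igraph::V(net)$name)
}

eccentricity_scores <- function(net) {
  d <- graph_distances(net)
  diag(d) <- 0
  vapply(seq_len(nrow(d)), function(i) {
    di <- d[i, ]
    ecc <- max(di[is.finite(di)])
    if (ecc == 0) 0 else 1 / ecc
  }, numeric(1)) |> setNames(igraph::V(net)$name)
}

radiality_scores <- function(net) {
  n <- igraph::vcount(net)
  d <- graph_distances(net)
  comp <- igraph::components(net)
  out <- setNames(numeric(n), igraph::V(net)$name)
  if (n < 2) {
    return(out)
  }
  for (cc in seq_len(comp$no)) {
    idx <- which(comp$membership == cc)
    if (length(idx) < 2) next
    dc <- d[idx, idx, drop = FALSE]
    diam <- max(dc)
    for (j in seq_along(idx)) {
      out[idx[j]] <- sum(diam + 1 - dc[j, -j]) / (n - 1)
    }
  }
  out
}

bottleneck_scores <- function(net) {
  nms <- igraph::V(net)$name
  n <- igraph::vcount(net)
  score <- setNames(numeric(n), nms)
  if (n < 2) {
    return(score)
  }
  d <- graph_distances(net)
  adj <- igraph::adjacent_vertices(net, igraph::V(net))
  for (s in seq_len(n)) {
    comp <- which(is.finite(d[s, ]))
    if (length(comp) < 2) next
    # one BFS shortest-path tree rooted at s: each node's parent is its
    # lexicographically smallest neighbor one step closer to the root
    ord <- comp[order(-d[s, comp])]
    desc <- setNames(numeric(length(comp)), nms[comp])
    for (v in ord) {
      if (v == s) next
      cand <- as.integer(adj[[v]])
      cand <- cand[d[s, cand] == d[s, v] - 1]
      parent <- cand[order(nms[cand])][1]
      desc[nms[parent]] <- desc[nms[parent]] + desc[nms[v]] + 1
    }
    score[comp] <- score[comp] + as.numeric(desc[nms[comp]] > n / 4)
  }
  score
}

epc_scores <- function(net, seed = NULL, iters = 1000, keep_p = 0.5) {
  run <- function() {
    n <- igraph::vcount(net)
    ne <- igraph::ecount(net)
    tot <- numeric(n)
    for (i in seq_len(iters)) {
      keep <- which(runif(ne) < keep_p)
      sg <- igraph::subgraph_from_edges(net, keep, delete.vertices = FALSE)
      comp <- igraph::components(sg)
      tot <- tot + (comp$csize[comp$membership] - 1)
    }
    setNames(tot / iters, igraph::V(net)$name)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Compute one topological centrality
#'
#' The ten methods, as used by the hub ensemble:
#' \describe{
#'   \item{Degree}{node degree.}
#'   \item{MCC}{Maximal Clique Centrality: sum of `(|C| - 1)!` over the
#'     maximal cliques containing the node (isolated nodes score 0).}
#'   \item{MNC}{size of the largest connected component of the subgraph
#'     induced on the node's neighbors (node excluded).}
#'   \item{DMNC}{`|E| / |V|^1.7` of that same component.}
#'   \item{Closeness}{harmonic closeness, `sum_w 1/d(v, w)` with
#'     `1/Inf = 0`.}
#'   \item{EcCentricity}{reciprocal eccentricity within the node's
#'     component; isolated nodes score 0.}
#'   \item{Radiality}{`sum_{w in comp(v)} (diam_c + 1 - d(v, w)) / (n - 1)`
#'     with `diam_c` the component diameter and `n` the graph order.}
#'   \item{Betweenness}{standard unnormalized shortest-path betweenness.}
#'   \item{BottleNeck}{per root, one BFS shortest-path tree (parent ties
#'     broken toward the lexicographically smaller node); a node gains 1 for
#'     every tree in which its proper descendant count exceeds `|V|/4` (the
#'     root's descendant count is its component size minus 1).}
#'   \item{EPC}{Edge Percolated Component: mean number of nodes reachable
#'     from the node over `epc_iters` random subgraphs, each edge kept
#'     independently with probability `epc_keep_p`.}
#' }
#'
#' @param net An [igraph::graph] (simple, undirected).
#' @param method One of [CENTRALITY_METHODS].
#' @param seed Optional integer seed for the EPC Monte-Carlo draws (the
#'   global RNG state is preserved).
#' @param epc_iters Number of EPC percolation iterations (default 1000).
#' @param epc_keep_p Per-edge keep probability for EPC (default 0.5).
#'
#' @return Named numeric vector, one finite non-negative score per node.
#' @export
#'
#' @examples
#' g <- igraph::make_full_graph(3)
#' igraph::V(g)$name <- c("a", "b", "c")
#' centrality(g, "MCC") # every triangle node scores (3 - 1)! = 2
centrality <- function(net, method, seed = NULL, epc_iters = 1000, epc_keep_p = 0.5) {
  if (length(method) != 1 || !method %in% CENTRALITY_METHODS) {
    abort(sprintf(
      "unknown centrality method %s; must be one of %s.",
      deparse(substitute(method)), paste(CENTRALITY_METHODS, collapse = ", ")
    ))
  }
  net <- as_named_graph(net)
  switch(method,
    Degree = igraph::degree(net),
    Betweenness = igraph::betweenness(net, directed = FALSE, weights = NA),
    Closeness = closeness_scores(net),
    EcCentricity = eccentricity_scores(net),
    Radiality = radiality_scores(net),
    MCC = mcc_scores(net),
    MNC = mnc_scores(net),
    DMNC = dmnc_scores(net),
    BottleNeck = bottleneck_scores(net),
    EPC = epc_scores(net, seed = seed, iters = epc_iters, keep_p = epc_keep_p)
  )
}

#' All ten centralities as a node-by-method table
#'
#' @inheritParams centrality
#' @param methods Methods to compute (default all ten).
#' @return Tibble with a `node` column plus one column per method.
#' @export
centrality_table <- function(net, methods = CENTRALITY_METHODS, seed = NULL,
                             epc_iters = 1000, epc_keep_p = 0.5) {
  net <- as_named_graph(net)
  out <- tibble(node = igraph::V(net)$name)
  for (m in methods) {
    sc <- centrality(net, m, seed = seed, epc_iters = epc_iters, epc_keep_p = epc_keep_p)
    out[[m]] <- unname(sc[out$node])
  }
  out
}

#' Top-k nodes of a score vector
#'
#' Nodes sorted by score descending, ties broken by node id ascending; the
#' first `min(k, n)` are returned.
#'
#' @param scores Named numeric vector (or two-column data frame
#'   `node`, `score`).
#' @param k List length (default 50).
#' @return Character vector of node ids.
#' @export
top_k_list <- function(scores, k = 50) {
  if (is.data.frame(scores)) scores <- setNames(scores[[2]], scores[[1]])
  if (!length(scores)) {
    return(character())
  }
  ord <- order(-scores, names(scores))
  head(names(scores)[ord], min(k, length(scores)))
}

#' Aggregate per-method top-k lists into hub genes
#'
#' Runs [rra_aggregate()] over the method lists with a common universe of
#' `N` ranked positions (nodes missing from a list take the worst rank) and
#' keeps nodes whose Bonferroni-corrected score is below `score_cut`.
#'
#' @param lists List of ordered node lists, one per centrality method.
#' @param N Total node count of the network (universe size; at least the
#'   longest list).
#' @param score_cut Corrected-score cut (strict; default 0.05).
#' @return Tibble with columns `node`, `rho`, `score`, sorted by score.
#' @export
aggregate_hubs <- function(lists, N, score_cut = 0.05) {
  if (N < max(c(0L, lengths(lists)))) {
    abort("`N` must be at least the longest list length.")
  }
  res <- rra_aggregate(lists, universes = N)
  res <- res[res$score < score_cut, c("item", "rho", "score")]
  names(res)[1] <- "node"
  as_tibble(res)
}

#' Identify hub genes by the ten-centrality RRA ensemble
#'
#' Computes all ten centralities, takes each method's top-`top_k` list, and
#' aggregates the lists with [aggregate_hubs()].
#'
#' @inheritParams centrality
#' @param top_k Per-method list length (default 50).
#' @param score_cut Corrected-score cut for hub calls (default 0.05).
#' @return List with `hubs` (tibble `node`, `rho`, `score`), `centralities`
#'   (the [centrality_table()]), and `lists` (the per-method top-k lists).
#' @export
identify_hubs <- function(net, top_k = 50, score_cut = 0.05, seed = NULL,
                          epc_iters = 1000, epc_keep_p = 0.5) {
  net <- as_named_graph(net)
  ct <- centrality_table(net, seed = seed, epc_iters = epc_iters, epc_keep_p = epc_keep_p)
  lists <- lapply(CENTRALITY_METHODS, function(m) {
    top_k_list(setNames(ct[[m]], ct$node), k = top_k)
  })
  names(lists) <- CENTRALITY_METHODS
  list(
    hubs = aggregate_hubs(lists, N = igraph::vcount(net), score_cut = score_cut),
    centralities = ct,
    lists = lists
  )
}
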