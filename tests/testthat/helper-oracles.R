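# Independent brute-force oracles used to pin the graph statistics, plus an
# enumerator of all connected graphs up to isomorphism. The oracles work on
# plain adjacency matrices with hand-rolled Floyd-Warshall distances and
# matrix-power shortest-path counts, independent of the code paths they
# check (which use igraph BFS/Brandes primitives or bespoke algorithms).

named_graph <- function(g) {
  igraph::V(g)$name <- sprintf("v%02d", seq_len(igraph::vcount(g)))
  g
}

graph_from_pairs <- function(n, pairs) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(pairs)) g <- igraph::add_edges(g, pairs)
  named_graph(g)
}

o_adj <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g, type = "both"))
  diag(A) <- 0
  A[A > 1] <- 1
  A
}

# all-pairs shortest-path lengths, Floyd-Warshall
o_dist <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  d[A == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, dk)
  }
  d
}

# shortest-path counts via adjacency-matrix powers: all walks of minimal
# length are simple shortest paths
o_sigma <- function(A, d) {
  n <- nrow(A)
  powers <- vector("list", n)
  powers[[1]] <- A
  for (k in seq_len(n - 1)[-1]) powers[[k]] <- powers[[k - 1]] %*% A
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s != t && is.finite(d[s, t])) sigma[s, t] <- powers[[d[s, t]]][s, t]
    }
  }
  sigma
}

o_betweenness <- function(A) {
  n <- nrow(A)
  d <- o_dist(A)
  sig <- o_sigma(A, d)
  out <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s < t && s != v && t != v && is.finite(d[s, t]) &&
          d[s, v] + d[v, t] == d[s, t]) {
          acc <- acc + sig[s, v] * sig[v, t] / sig[s, t]
        }
      }
    }
    out[v] <- acc
  }
  out
}

o_is_clique <- function(A, idx) {
  length(idx) < 2 || all(A[idx, idx][upper.tri(diag(length(idx)))] == 1)
}

o_mcc <- function(A) {
  n <- nrow(A)
  out <- numeric(n)
  for (k in 2:max(2, n)) {
    if (k > n) break
    for (idx in utils::combn(n, k, simplify = FALSE)) {
      if (!o_is_clique(A, idx)) next
      outside <- setdiff(seq_len(n), idx)
      maximal <- !length(outside) || !any(vapply(outside, function(u) {
        all(A[u, idx] == 1)
      }, logical(1)))
      if (maximal) out[idx] <- out[idx] + factorial(k - 1)
    }
  }
  out
}

# components of an induced subgraph, from reachability on the submatrix;
# returns list of index vectors (into the full graph)
o_components <- function(A, idx) {
  if (!length(idx)) return(list())
  d <- o_dist(A[idx, idx, drop = FALSE])
  left <- seq_along(idx)
  comps <- list()
  while (length(left)) {
    cc <- which(is.finite(d[left[1], ]))
    comps[[length(comps) + 1]] <- idx[cc]
    left <- setdiff(left, cc)
  }
  comps
}

# largest neighbor component; ties resolved toward the smallest vertex index
o_neighborhood_comp <- function(A, v) {
  nb <- which(A[v, ] == 1)
  if (!length(nb)) return(integer())
  comps <- o_components(A, nb)
  sizes <- lengths(comps)
  big <- which(sizes == max(sizes))
  firsts <- vapply(comps[big], min, numeric(1))
  comps[[big[which.min(firsts)]]]
}

o_mnc <- function(A) {
  vapply(seq_len(nrow(A)), function(v) length(o_neighborhood_comp(A, v)), numeric(1))
}

o_dmnc <- function(A) {
  vapply(seq_len(nrow(A)), function(v) {
    cc <- o_neighborhood_comp(A, v)
    if (!length(cc)) return(0)
    e <- sum(A[cc, cc]) / 2
    e / length(cc)^1.7
  }, numeric(1))
}

o_closeness <- function(A) {
  d <- o_dist(A)
  diag(d) <- Inf
  rowSums(1 / d)
}

o_eccentricity <- function(A) {
  d <- o_dist(A)
  vapply(seq_len(nrow(A)), function(v) {
    dv <- d[v, ]
    e <- max(dv[is.finite(dv)])
    if (e == 0) 0 else 1 / e
  }, numeric(1))
}

o_radiality <- function(A) {
  n <- nrow(A)
  d <- o_dist(A)
  out <- numeric(n)
  if (n < 2) return(out)
  for (cc in o_components(A, seq_len(n))) {
    if (length(cc) < 2) next
    diam <- max(d[cc, cc])
    for (v in cc) out[v] <- sum(diam + 1 - d[v, setdiff(cc, v)]) / (n - 1)
  }
  out
}

# direct restatement of the BottleNeck definition: one lexicographic BFS
# tree per root, count proper descendants
o_bottleneck <- function(A) {
  n <- nrow(A)
  d <- o_dist(A)
  out <- numeric(n)
  for (s in seq_len(n)) {
    comp <- which(is.finite(d[s, ]))
    if (length(comp) < 2) next
    parent <- rep(NA_integer_, n)
    for (v in setdiff(comp, s)) {
      cand <- which(A[v, ] == 1 & d[s, ] == d[s, v] - 1)
      parent[v] <- min(cand)
    }
    ndesc <- numeric(n)
    for (v in comp[order(-d[s, comp])]) {
      if (v == s) next
      ndesc[parent[v]] <- ndesc[parent[v]] + ndesc[v] + 1
    }
    out[comp] <- out[comp] + as.numeric(ndesc[comp] > n / 4)
  }
  out
}

# exact EPC: expectation (and variance) of per-node reachable counts over
# all edge subsets, weighted by the keep probability
o_epc_exact <- function(A, keep_p) {
  n <- nrow(A)
  eidx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  ne <- nrow(eidx)
  m1 <- numeric(n)
  m2 <- numeric(n)
  for (mask in 0:(2^ne - 1)) {
    kept <- if (ne) which(bitwAnd(mask, 2^(seq_len(ne) - 1)) > 0) else integer()
    B <- matrix(0, n, n)
    if (length(kept)) {
      for (e in kept) {
        B[eidx[e, 1], eidx[e, 2]] <- 1
        B[eidx[e, 2], eidx[e, 1]] <- 1
      }
    }
    pr <- keep_p^length(kept) * (1 - keep_p)^(ne - length(kept))
    d <- o_dist(B)
    reach <- rowSums(is.finite(d)) - 1
    m1 <- m1 + pr * reach
    m2 <- m2 + pr * reach^2
  }
  list(mean = m1, var = pmax(0, m2 - m1^2))
}

# ---- enumeration of connected graphs up to isomorphism ----

canon_key <- function(g) {
  lab <- igraph::canonical_permutation(g)$labeling
  gc <- igraph::permute(g, lab)
  el <- igraph::as_edgelist(gc, names = FALSE)
  if (nrow(el)) {
    el <- t(apply(el, 1, sort))
    el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  }
  paste(igraph::vcount(g), paste(el[, 1], el[, 2], sep = "-", collapse = ";"), sep = "|")
}

.atlas_cache <- new.env(parent = emptyenv())

# All connected graphs with 1..max_n vertices, one representative per
# isomorphism class, built by vertex augmentation (every connected graph
# has a non-cut vertex, so augmentation from n-1 reaches every class).
connected_graph_atlas <- function(max_n) {
  key <- as.character(max_n)
  if (!is.null(.atlas_cache[[key]])) {
    return(.atlas_cache[[key]])
  }
  levels <- list(list(igraph::make_empty_graph(1, directed = FALSE)))
  for (n in 2:max_n) {
    seen <- new.env(parent = emptyenv())
    nxt <- list()
    for (g in levels[[n - 1]]) {
      for (mask in 1:(2^(n - 1) - 1)) {
        nbrs <- which(bitwAnd(mask, 2^(seq_len(n - 1) - 1)) > 0)
        g2 <- igraph::add_vertices(g, 1)
        g2 <- igraph::add_edges(g2, rbind(nbrs, n))
        k <- canon_key(g2)
        if (is.null(seen[[k]])) {
          seen[[k]] <- TRUE
          nxt[[length(nxt) + 1]] <- g2
        }
      }
    }
    levels[[n]] <- nxt
  }
  atlas <- lapply(unlist(levels, recursive = FALSE), named_graph)
  .atlas_cache[[key]] <- atlas
  atlas
}
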