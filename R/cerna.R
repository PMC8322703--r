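# circRNA-miRNA-mRNA (ceRNA) network assembly. miRNA->mRNA predictions from
# three sources are intersected, validated against differentially expressed
# miRNAs under the sponge direction constraint (miRNA and target move in
# opposite directions), circRNAs are attached through their miRNA partners,
# and only circRNAs covering every remaining mRNA are retained.

check_direction <- function(x, what) {
  bad <- setdiff(unique(x), c("up", "down"))
  if (length(bad)) {
    abort(sprintf(
      "%s direction must be \"up\" or \"down\"; found: %s",
      what, paste(bad, collapse = ", ")
    ))
  }
  invisible(x)
}

as_direction_lookup <- function(dirs, what = "mRNA") {
  if (is.data.frame(dirs)) {
    dirs <- as_tibble(dirs)
    id_col <- intersect(c("mrna", "gene", "item", "node"), names(dirs))[1]
    if (is.na(id_col) || !"direction" %in% names(dirs)) {
      abort("direction table needs an id column (mrna/gene/item/node) and `direction`.")
    }
    dirs <- setNames(dirs$direction, dirs[[id_col]])
  }
  check_direction(dirs, what)
  dirs
}

#' Intersect miRNA target predictions from three sources
#'
#' Keeps the (miRNA, mRNA) pairs predicted by all three sources.
#'
#' @param targets Tibble with columns `mirna`, `mrna`, `source`; exactly
#'   three distinct sources must be present.
#' @return Tibble with columns `mirna`, `mrna` (distinct pairs).
#' @export
intersect_three_dbs <- function(targets) {
  targets <- as_tibble(targets)
  if (!all(c("mirna", "mrna", "source") %in% names(targets))) {
    abort("`targets` needs columns mirna, mrna, source.")
  }
  ns <- dplyr::n_distinct(targets$source)
  if (ns != 3) {
    abort(sprintf("exactly three target sources required; found %d.", ns))
  }
  targets |>
    dplyr::distinct(.data$mirna, .data$mrna, .data$source) |>
    dplyr::count(.data$mirna, .data$mrna) |>
    dplyr::filter(.data$n == 3) |>
    dplyr::select("mirna", "mrna")
}

#' Validate target pairs against differentially expressed miRNAs
#'
#' A sponge-regulated target moves opposite to its miRNA, so a pair is kept
#' only when the miRNA's differential-expression direction is opposite to
#' the mRNA's. miRNAs absent from the DE table are dropped.
#'
#' @param pairs Tibble with columns `mirna`, `mrna`.
#' @param demis Differentially expressed miRNA table with columns `mirna`
#'   and `direction` (`"up"`/`"down"`), e.g. from [moderated_t_test()] on a
#'   miRNA matrix followed by [filter_degs()].
#' @param mrna_dirs Direction of every mRNA in `pairs`: named character
#'   vector or a table with an id column and `direction`.
#'
#' @return Tibble with columns `mirna`, `mrna`, `mrna_direction`,
#'   `mirna_direction` (only opposite-direction pairs).
#' @export
validate_directions <- function(pairs, demis, mrna_dirs) {
  pairs <- as_tibble(pairs)
  dirs <- as_direction_lookup(mrna_dirs, "mRNA")
  missing <- setdiff(unique(pairs$mrna), names(dirs))
  if (length(missing)) {
    abort(sprintf(
      "no direction given for mRNA(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  demis <- as_tibble(demis)
  if (!all(c("mirna", "direction") %in% names(demis))) {
    abort("`demis` needs columns mirna and direction.")
  }
  check_direction(demis$direction, "miRNA")
  mi_dir <- setNames(demis$direction, demis$mirna)
  out <- pairs |>
    dplyr::mutate(
      mrna_direction = unname(dirs[.data$mrna]),
      mirna_direction = unname(mi_dir[.data$mirna])
    ) |>
    dplyr::filter(
      !is.na(.data$mirna_direction),
      .data$mirna_direction != .data$mrna_direction
    )
  dplyr::distinct(out)
}

#' Attach circRNAs: drop mRNAs without circRNA-supported miRNAs
#'
#' An mRNA is dropped when none of its (validated) miRNAs has a circRNA
#' partner; candidate circRNAs are those linked to at least one miRNA of a
#' surviving mRNA.
#'
#' @param pairs Validated pair table with columns `mirna`, `mrna`.
#' @param circ circRNA link table with columns `circrna`, `mirna`.
#'
#' @return List with `kept_mrnas`, `candidate_circs`, `dropped_mrnas`
#'   (sorted character vectors).
#' @export
attach_circrnas <- function(pairs, circ) {
  pairs <- as_tibble(pairs)
  circ <- as_tibble(circ)
  if (!all(c("circrna", "mirna") %in% names(circ))) {
    abort("`circ` needs columns circrna and mirna.")
  }
  circ_mirnas <- unique(circ$mirna)
  support <- pairs |>
    dplyr::group_by(.data$mrna) |>
    dplyr::summarise(ok = any(.data$mirna %in% circ_mirnas), .groups = "drop")
  kept <- sort(support$mrna[support$ok])
  dropped <- sort(support$mrna[!support$ok])
  if (!length(kept)) warn("all mRNAs dropped: no miRNA has a circRNA partner.")
  surviving_mirnas <- unique(pairs$mirna[pairs$mrna %in% kept & pairs$mirna %in% circ_mirnas])
  candidates <- sort(unique(circ$circrna[circ$mirna %in% surviving_mirnas]))
  list(kept_mrnas = kept, candidate_circs = candidates, dropped_mrnas = dropped)
}

#' Retain circRNAs covering every remaining mRNA
#'
#' A circRNA is retained only if, for every kept mRNA, it targets some
#' miRNA validated against that mRNA — i.e. it can regulate all remaining
#' mRNAs through its miRNA partners.
#'
#' @param candidate_circs Candidate circRNA ids (from [attach_circrnas()]).
#' @param kept_mrnas Kept mRNAs (from [attach_circrnas()]).
#' @param pairs Validated pair table (`mirna`, `mrna`).
#' @param circ circRNA link table (`circrna`, `mirna`).
#'
#' @return Sorted character vector of retained circRNA ids.
#' @export
coverage_filter <- function(candidate_circs, kept_mrnas, pairs, circ) {
  if (!length(candidate_circs) || !length(kept_mrnas)) {
    return(character())
  }
  pairs <- as_tibble(pairs)
  circ <- as_tibble(circ)
  covered <- circ |>
    dplyr::filter(.data$circrna %in% candidate_circs) |>
    dplyr::inner_join(pairs, by = "mirna", relationship = "many-to-many") |>
    dplyr::filter(.data$mrna %in% kept_mrnas) |>
    dplyr::distinct(.data$circrna, .data$mrna) |>
    dplyr::count(.data$circrna)
  sort(covered$circrna[covered$n == length(kept_mrnas)])
}

#' Build the tripartite ceRNA network
#'
#' Nodes are the retained circRNAs, the kept mRNAs, and the miRNAs linked to
#' both a retained circRNA and a kept mRNA; edges are the circRNA-miRNA and
#' miRNA-mRNA links restricted to those nodes. The result is validated:
#' node classes partition the node set, only circ-mi and mi-mRNA edges
#' occur, and every mRNA is reachable from at least one circRNA.
#'
#' @param retained_circs Retained circRNA ids (from [coverage_filter()]).
#' @param kept_mrnas Kept mRNA ids (from [attach_circrnas()]).
#' @param pairs Validated pair table (`mirna`, `mrna`).
#' @param circ circRNA link table (`circrna`, `mirna`).
#' @param dirs Optional direction lookup for nodes (named vector or table);
#'   nodes without an entry get `NA`.
#'
#' @return An object of class `cerna_network`: list with `graph` (igraph),
#'   `nodes` (tibble `node`, `class`, `direction`) and `edges` (tibble
#'   `from`, `to`, `type`).
#' @export
build_cerna_network <- function(retained_circs, kept_mrnas, pairs, circ, dirs = NULL) {
  pairs <- as_tibble(pairs)
  circ <- as_tibble(circ)
  pairs_k <- pairs[pairs$mrna %in% kept_mrnas, c("mirna", "mrna")]
  circ_r <- circ[circ$circrna %in% retained_circs, c("circrna", "mirna")]
  mirnas <- sort(intersect(unique(circ_r$mirna), unique(pairs_k$mirna)))
  circ_edges <- dplyr::distinct(circ_r[circ_r$mirna %in% mirnas, ])
  pair_edges <- dplyr::distinct(pairs_k[pairs_k$mirna %in% mirnas, ])
  mrnas <- sort(unique(pair_edges$mrna))
  circs <- sort(unique(circ_edges$circrna))
  nodes <- tibble(
    node = c(circs, mirnas, mrnas),
    class = rep(c("circRNA", "miRNA", "mRNA"), c(length(circs), length(mirnas), length(mrnas)))
  )
  if (anyDuplicated(nodes$node)) {
    abort("node classes do not partition the node set (shared identifiers across classes).")
  }
  nodes$direction <- NA_character_
  if (!is.null(dirs)) {
    dirs <- as_direction_lookup(dirs, "node")
    nodes$direction <- unname(dirs[nodes$node])
  }
  edges <- dplyr::bind_rows(
    tibble(from = circ_edges$circrna, to = circ_edges$mirna, type = "circ-mi"),
    tibble(from = pair_edges$mirna, to = pair_edges$mrna, type = "mi-mRNA")
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  # invariants
  if (length(mrnas)) {
    if (!length(circs)) abort("mRNAs present but no circRNA retained; network invalid.")
    d <- igraph::distances(g, v = mrnas, to = circs, weights = NA)
    if (!all(apply(d, 1, function(x) any(is.finite(x))))) {
      abort("internal error: an mRNA is unreachable from every circRNA.")
    }
  }
  structure(list(graph = g, nodes = nodes, edges = edges), class = "cerna_network")
}

#' Run the full ceRNA assembly chain
#'
#' [intersect_three_dbs()] -> [validate_directions()] -> [attach_circrnas()]
#' -> [coverage_filter()] -> [build_cerna_network()].
#'
#' @param targets Three-source target table (`mirna`, `mrna`, `source`).
#' @param demis miRNA DE table (`mirna`, `direction`).
#' @param mrna_dirs Direction lookup for the candidate mRNAs.
#' @param circ circRNA link table (`circrna`, `mirna`).
#'
#' @return A `cerna_network` whose `"steps"` attribute records the
#'   intermediate pair sets and kept/dropped/retained ids.
#' @export
assemble_cerna <- function(targets, demis, mrna_dirs, circ) {
  pairs3 <- intersect_three_dbs(targets)
  validated <- validate_directions(pairs3, demis, mrna_dirs)
  att <- attach_circrnas(validated, circ)
  retained <- coverage_filter(att$candidate_circs, att$kept_mrnas, validated, circ)
  net <- build_cerna_network(retained, att$kept_mrnas, validated, circ, dirs = mrna_dirs)
  attr(net, "steps") <- list(
    intersected = pairs3, validated = validated,
    kept_mrnas = att$kept_mrnas, dropped_mrnas = att$dropped_mrnas,
    candidate_circs = att$candidate_circs, retained_circs = retained
  )
  net
}

#' Rank ceRNA nodes by Maximal Clique Centrality
#'
#' MCC is computed on the tripartite graph viewed as a plain undirected
#' graph; on a triangle-free graph MCC reduces to node degree.
#'
#' @param net A `cerna_network` or [igraph::graph].
#' @param top Number of nodes to return (default 10; the full ordering when
#'   larger than the node count).
#' @return Character vector of node ids, best first.
#' @export
rank_cerna_mcc <- function(net, top = 10) {
  g <- if (inherits(net, "cerna_network")) net$graph else net
  top_k_list(centrality(g, "MCC"), k = top)
}

#' @export
print.cerna_network <- function(x, ...) {
  n <- table(factor(x$nodes$class, levels = c("circRNA", "miRNA", "mRNA")))
  cat(sprintf(
    "<cerna_network> %d circRNAs, %d miRNAs, %d mRNAs; %d edges\n",
    n[["circRNA"]], n[["miRNA"]], n[["mRNA"]], nrow(x$edges)
  ))
  invisible(x)
}

#' Edge table of a ceRNA network
#' @param x A `cerna_network`.
#' @param ... Unused.
#' @return Tibble with columns `from`, `to`, `type`.
#' @export
tidy.cerna_network <- function(x, ...) as_tibble(x$edges)

#' One-row composition summary of a ceRNA network
#' @param x A `cerna_network`.
#' @param ... Unused.
#' @return Tibble with `n_circrna`, `n_mirna`, `n_mrna`, `n_edges`.
#' @export
glance.cerna_network <- function(x, ...) {
  n <- table(factor(x$nodes$class, levels = c("circRNA", "miRNA", "mRNA")))
  tibble(
    n_circrna = as.integer(n[["circRNA"]]),
    n_mirna = as.integer(n[["miRNA"]]),
    n_mrna = as.integer(n[["mRNA"]]),
    n_edges = nrow(x$edges)
  )
}

# ---- table readers (TSV dialects used by the ceRNA stage) ----

#' Read a miRNA target table (mirna, mrna, source)
#' @param path TSV path.
#' @return Tibble with columns `mirna`, `mrna`, `source`.
#' @export
read_target_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("mirna", "mrna", "source") %in% names(out))) {
    abort("target table needs columns mirna, mrna, source.")
  }
  out
}

#' Read a differentially expressed miRNA table
#' @param path TSV path with at least columns `mirna` and `direction`.
#' @return Tibble.
#' @export
read_demi_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("mirna", "direction") %in% names(out))) {
    abort("DEMi table needs columns mirna and direction.")
  }
  check_direction(out$direction, "miRNA")
  if ("log2fc" %in% names(out)) {
    bad <- (out$log2fc >= 0) != (out$direction == "up")
    if (any(bad)) abort("DEMi direction inconsistent with log2fc sign.")
  }
  out
}

#' Read a circRNA link table (circrna, mirna)
#' @param path TSV path.
#' @return Tibble with distinct `circrna`, `mirna` pairs.
#' @export
read_circ_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("circrna", "mirna") %in% names(out))) {
    abort("circRNA table needs columns circrna and mirna.")
  }
  dplyr::distinct(out)
}

#' Read a validated miRNA-mRNA pair table with slash-separated miRNA lists
#'
#' Parses the curated-pair dialect: one row per mRNA with its direction and
#' a `/`-separated list of validated miRNAs, expanded to one row per pair.
#' The shipped asthma bronchial-epithelium fixture uses this layout:
#' `system.file("extdata", "asthma_hub_mirna_pairs.tsv", package = "cernaflow")`.
#'
#' @param path TSV path with columns `mrna`, `direction`, `mirnas`.
#' @return Tibble with columns `mirna`, `mrna`, `mrna_direction`.
#' @export
read_validated_pairs <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("mrna", "direction", "mirnas") %in% names(raw))) {
    abort("validated pair table needs columns mrna, direction, mirnas.")
  }
  check_direction(raw$direction, "mRNA")
  out <- raw |>
    dplyr::mutate(mirna = strsplit(.data$mirnas, "/", fixed = TRUE)) |>
    tidyr::unnest("mirna") |>
    dplyr::transmute(
      mirna = trimws(.data$mirna),
      mrna = .data$mrna,
      mrna_direction = .data$direction
    )
  dplyr::distinct(out)
}

#' Export a ceRNA network: nodes/edges TSV and node-link JSON
#' @param net A `cerna_network`.
#' @param nodes_path,edges_path,json_path Output paths (`NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_cerna_network <- function(net, nodes_path = NULL, edges_path = NULL, json_path = NULL) {
  stopifnot(inherits(net, "cerna_network"))
  if (!is.null(nodes_path)) readr::write_tsv(net$nodes, nodes_path)
  if (!is.null(edges_path)) readr::write_tsv(net$edges, edges_path)
  if (!is.null(json_path)) write_network_json(net$graph, json_path)
  invisible(c(nodes_path, edges_path, json_path))
}
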