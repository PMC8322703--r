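# Robust Rank Aggregation: each item's normalized ranks across m ordered
# lists are compared with the order statistics of m independent uniforms.
# beta_k = P(U_(k) <= r_k) is a binomial tail; rho is the minimum over k and
# the reported score is the Bonferroni-corrected min(1, m * rho). Small
# scores flag items ranked consistently near the top of all lists.

#' Normalized rank matrix over the union of ordered lists
#'
#' The item at 1-based position `i` in a list with universe size `N` gets
#' normalized rank `r = i / N`; items absent from a list are `NA` (treated as
#' worst rank, `r = 1`, by [rra_aggregate()]).
#'
#' @param lists List of character vectors, each an ordered item list with no
#'   duplicates (best first).
#' @param universes Universe size per list (scalar recycled, or one value per
#'   list); must be at least the list length.
#'
#' @return Numeric matrix, union items x lists, with `NA` for missing
#'   entries; universe sizes in the `"universes"` attribute.
#' @export
#'
#' @examples
#' normalized_ranks(list(c("a", "b"), c("b", "c")), universes = 10)
normalized_ranks <- function(lists, universes) {
  if (!length(lists)) abort("need at least one list.")
  m <- length(lists)
  universes <- rep_len(as.numeric(universes), m)
  for (i in seq_len(m)) {
    if (anyDuplicated(lists[[i]])) {
      abort(sprintf("duplicate item within list %d.", i))
    }
    if (universes[i] < length(lists[[i]])) {
      abort(sprintf(
        "universe size (%g) smaller than list %d length (%d).",
        universes[i], i, length(lists[[i]])
      ))
    }
  }
  items <- sort(unique(unlist(lists, use.names = FALSE)))
  if (!length(items)) abort("the union of the input lists is empty.")
  r <- matrix(NA_real_,
    nrow = length(items), ncol = m,
    dimnames = list(items, names(lists) %||% paste0("list", seq_len(m)))
  )
  for (i in seq_len(m)) {
    li <- lists[[i]]
    if (length(li)) r[match(li, items), i] <- seq_along(li) / universes[i]
  }
  attr(r, "universes") <- universes
  r
}

#' Order-statistic beta scores for one item's sorted rank vector
#'
#' For `r` ascending with entries in (0, 1], `beta_k = P(U_(k) <= r_k)` where
#' `U_(k)` is the k-th order statistic of `m` independent uniforms, i.e. the
#' upper binomial tail `sum_{j >= k} C(m, j) r_k^j (1 - r_k)^(m - j)`.
#'
#' @param r Sorted (ascending) normalized rank vector of length `m`, missing
#'   entries already substituted by 1.
#' @param m Number of lists; must equal `length(r)`.
#'
#' @return Numeric vector of `m` beta scores.
#' @export
#'
#' @examples
#' beta_scores(c(0.1, 0.2), m = 2) # 1 - 0.9^2 and 0.2^2
beta_scores <- function(r, m = length(r)) {
  r <- as.numeric(r)
  if (length(r) != m) abort("`r` must have length `m` (substitute missing entries with 1).")
  if (is.unsorted(r)) abort("`r` must be sorted ascending.")
  if (any(r <= 0 | r > 1)) abort("normalized ranks must lie in (0, 1].")
  k <- seq_len(m)
  pbinom(k - 1, size = m, prob = r, lower.tail = FALSE)
}

#' Rho and Bonferroni-corrected RRA score for one rank vector
#'
#' `rho` is the minimum beta score over the `m` order statistics; the
#' corrected score is `min(1, m * rho)`.
#'
#' @inheritParams beta_scores
#' @return List with elements `rho` and `score`.
#' @export
rho_score <- function(r, m = length(r)) {
  b <- beta_scores(r, m)
  rho <- min(b)
  list(rho = rho, score = min(1, m * rho))
}

#' Aggregate ordered lists with the Robust Rank Aggregation score
#'
#' Builds the normalized rank matrix over the union of items, substitutes
#' missing entries with the worst rank `r = 1`, and computes `rho` and the
#' Bonferroni-corrected score per item. When a fold-change table is supplied,
#' `mean_lfc` is the arithmetic mean of per-dataset log2 fold changes over
#' the datasets measuring the item.
#'
#' @inheritParams normalized_ranks
#' @param lfc_table Optional data frame with columns `item` and `log2fc`
#'   (one row per item per dataset measuring it).
#'
#' @return A tibble of class `rra_result` with columns `item`, `rho`,
#'   `score`, `mean_lfc`, sorted by score ascending (ties by item).
#' @export
rra_aggregate <- function(lists, universes, lfc_table = NULL) {
  rmat <- normalized_ranks(lists, universes)
  m <- ncol(rmat)
  rmat[is.na(rmat)] <- 1
  rho <- apply(rmat, 1, function(r) min(beta_scores(sort(r), m)))
  out <- tibble(
    item = rownames(rmat),
    rho = unname(rho),
    score = pmin(1, m * unname(rho)),
    mean_lfc = NA_real_
  )
  if (!is.null(lfc_table)) {
    lfc_table <- as_tibble(lfc_table)
    if (!all(c("item", "log2fc") %in% names(lfc_table))) {
      abort("`lfc_table` needs columns item and log2fc.")
    }
    means <- lfc_table |>
      dplyr::group_by(.data$item) |>
      dplyr::summarise(mean_lfc = mean(.data$log2fc), .groups = "drop")
    out$mean_lfc <- means$mean_lfc[match(out$item, means$item)]
  }
  out <- out[order(out$score, out$item), ]
  class(out) <- c("rra_result", class(out))
  out
}

#' Select robust items from up/down aggregations
#'
#' Keeps items with `score < score_cut` and `|mean_lfc| > lfc_cut` from each
#' directional aggregation, labelling each with the direction it came from.
#' An item passing in both directions indicates inconsistent input and is an
#' error.
#'
#' @param rra_up,rra_down [rra_aggregate()] results for the up- and
#'   down-ranked lists.
#' @param score_cut Corrected-score cut (strict; default 0.05).
#' @param lfc_cut Absolute mean log2 fold-change cut (strict; default 0.5).
#'
#' @return Tibble with columns `item`, `rho`, `score`, `mean_lfc`,
#'   `direction`, sorted by score.
#' @export
select_robust <- function(rra_up, rra_down, score_cut = 0.05, lfc_cut = 0.5) {
  keep <- function(x, dir) {
    x <- as_tibble(x)
    x <- x[x$score < score_cut & !is.na(x$mean_lfc) & abs(x$mean_lfc) > lfc_cut, ]
    x$direction <- dir
    x
  }
  up <- keep(rra_up, "up")
  down <- keep(rra_down, "down")
  both <- intersect(up$item, down$item)
  if (length(both)) {
    abort(sprintf(
      "item(s) pass in both directions (inconsistent input): %s",
      paste(both, collapse = ", ")
    ))
  }
  out <- dplyr::bind_rows(up, down)
  out[order(out$score, out$item), ]
}

#' Write ranked per-dataset lists or aggregated results as TSV
#' @param x An `rra_result` (or any data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rra_table <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}

#' Read a ranked-list TSV (item, log2fc, p)
#' @param path Input path.
#' @return Tibble with columns `item`, `log2fc`, `p`.
#' @export
read_ranked_list <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("item", "log2fc") %in% names(out))) {
    abort("ranked list needs at least columns item and log2fc.")
  }
  out
}
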