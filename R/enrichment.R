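# Over-representation analysis: hypergeometric upper tail against a
# caller-supplied measured-gene universe, Benjamini-Hochberg corrected.

#' Read a GMT gene-set collection
#'
#' Tab-separated: set name, description, then member genes.
#'
#' @param path GMT path (optionally gzip-compressed).
#' @return Tibble with columns `set`, `description`, and list-column
#'   `genes`; set names are unique and sets non-empty.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("GMT file is empty.")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) {
    abort(sprintf("GMT line %d has no member genes.", bad[1]))
  }
  out <- tibble(
    set = vapply(fields, `[`, character(1), 1),
    description = vapply(fields, `[`, character(1), 2),
    genes = lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  )
  if (anyDuplicated(out$set)) abort("duplicate set names in GMT.")
  if (any(lengths(out$genes) == 0)) abort("empty gene set in GMT.")
  out
}

#' Write a gene-set collection as GMT
#' @param sets Tibble as returned by [read_gmt()] (or a named list of gene
#'   vectors).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (!is.data.frame(sets)) {
    sets <- tibble(
      set = names(sets), description = names(sets),
      genes = unname(sets)
    )
  }
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$set[i], sets$description[i], sets$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set with `K` members in the universe of size `N`, the
#' enrichment p-value of a query of size `n` overlapping `k` members is the
#' hypergeometric upper tail `P(X >= k)`; q-values are Benjamini-Hochberg
#' over all tested sets. Query genes outside the universe are dropped with a
#' warning.
#'
#' @param query Character vector of query genes.
#' @param sets Gene-set collection: tibble from [read_gmt()] or a named list
#'   of gene vectors.
#' @param universe Character vector of all measured genes.
#' @param alpha Significance cut reported in the `significant` column
#'   (raw `p < alpha`; default 0.05).
#'
#' @return Tibble sorted by p: `set`, `description`, `overlap` (k),
#'   `set_size` (K in universe), `query_size`, `universe_size`, `p`, `q`,
#'   `significant`, plus a `hits` list-column of overlapping genes.
#' @export
#'
#' @examples
#' ora("g1", list(s = c("g1", "g2")), universe = paste0("g", 1:10))
ora <- function(query, sets, universe, alpha = 0.05) {
  if (is.data.frame(sets)) {
    desc <- setNames(sets$description, sets$set)
    sets <- setNames(sets$genes, sets$set)
  } else {
    desc <- setNames(names(sets), names(sets))
  }
  if (!length(sets)) abort("no gene sets supplied.")
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warn(sprintf(
      "dropping %d query gene(s) outside the universe: %s",
      length(outside), paste(head(outside, 5), collapse = ", ")
    ))
    query <- intersect(query, universe)
  }
  if (!length(query)) abort("query is empty after universe filtering.")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    hits <- intersect(query, members)
    K <- length(members)
    k <- length(hits)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(
      set = nm, description = unname(desc[nm]), overlap = k, set_size = K,
      query_size = n, universe_size = N, p = p, hits = list(sort(hits))
    )
  })
  out <- dplyr::bind_rows(rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha
  out <- out[order(out$p, out$set), ]
  dplyr::relocate(out, "hits", .after = "significant")
}
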