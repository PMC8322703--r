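# Expression matrix container and readers.
#
# Values are log2 intensities, features (probes or gene symbols) in rows,
# samples in columns; every sample carries a case/control label.

#' Construct an expression matrix with group labels
#'
#' @param values Numeric matrix of log2 intensities, features x samples, with
#'   unique row names (feature ids) and column names (sample ids).
#' @param groups Named character vector mapping every sample id to `"case"`
#'   or `"control"`.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `groups` (the label vector, ordered as the columns).
#' @export
#'
#' @examples
#' v <- matrix(rnorm(12), 3, 4,
#'   dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' m <- expr_matrix(v, setNames(c("case", "case", "control", "control"),
#'   colnames(v)))
#' dim(m$values)
expr_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have feature row names and sample column names.")
  }
  if (anyDuplicated(rownames(values))) {
    abort("duplicate feature ids in expression matrix.")
  }
  if (anyDuplicated(colnames(values))) {
    abort("duplicate sample ids in expression matrix.")
  }
  if (!all(is.finite(values))) {
    abort("all expression values must be finite.")
  }
  groups <- groups[colnames(values)]
  if (anyNA(groups) || anyNA(names(groups))) {
    abort("every sample id must have a group label.")
  }
  if (!all(groups %in% c("case", "control"))) {
    abort("group labels must be \"case\" or \"control\".")
  }
  structure(list(values = values, groups = groups), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d features x %d samples (%d case, %d control)\n",
    nrow(x$values), ncol(x$values),
    sum(x$groups == "case"), sum(x$groups == "control")
  ))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Long tidy view of an expression matrix
#'
#' @param x An [expr_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `feature`, `sample`, `group`, `value`.
#' @export
tidy.expr_matrix <- function(x, ...) {
  tibble(
    feature = rep(rownames(x$values), times = ncol(x$values)),
    sample = rep(colnames(x$values), each = nrow(x$values)),
    group = rep(unname(x$groups), each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

read_group_map <- function(path) {
  gm <- read.delim(path,
    header = FALSE, sep = "", colClasses = "character",
    stringsAsFactors = FALSE, comment.char = "", quote = ""
  )
  if (ncol(gm) < 2) abort("group map must have two columns: sample id, group.")
  gm <- gm[, 1:2]
  # tolerate a header row
  if (!tolower(gm[1, 2]) %in% c("case", "control")) gm <- gm[-1, , drop = FALSE]
  grp <- tolower(gm[[2]])
  bad <- setdiff(unique(grp), c("case", "control"))
  if (length(bad)) {
    abort(sprintf(
      "group labels must be \"case\" or \"control\"; found: %s",
      paste(bad, collapse = ", ")
    ))
  }
  setNames(grp, gm[[1]])
}

#' Read an expression table and attach case/control labels
#'
#' Reads a tab- or comma-separated numeric table whose first column holds
#' feature (probe or gene) ids and whose header row holds sample ids, plus a
#' two-column sample -> group map. Both files may be gzip-compressed.
#' Samples absent from the group map are dropped with a warning.
#'
#' @param path Path to the expression table (TSV or CSV, optionally `.gz`).
#' @param group_map Path to a two-column table (`sample_id`, `group`), where
#'   group is `case` or `control` (a header row is tolerated).
#'
#' @return An [expr_matrix()].
#' @export
read_expression_table <- function(path, group_map) {
  sep <- detect_sep(path)
  raw <- read.delim(path,
    sep = sep, header = TRUE, check.names = FALSE,
    colClasses = "character", stringsAsFactors = FALSE,
    comment.char = "", quote = ""
  )
  if (ncol(raw) < 2) abort("expression table needs an id column plus samples.")
  feature_ids <- raw[[1]]
  if (anyDuplicated(feature_ids)) abort("duplicate feature ids in expression table.")
  cells <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells),
    dim = dim(cells),
    dimnames = list(feature_ids, colnames(cells))
  ))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "non-numeric value \"%s\" at row %d, column %d of the expression table",
      cells[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2]
    ))
  }
  gm <- read_group_map(group_map)
  unknown <- setdiff(colnames(num), names(gm))
  if (length(unknown)) {
    warn(sprintf(
      "dropping %d sample(s) absent from the group map: %s",
      length(unknown), paste(unknown, collapse = ", ")
    ))
    num <- num[, setdiff(colnames(num), unknown), drop = FALSE]
  }
  groups <- gm[colnames(num)]
  n_case <- sum(groups == "case")
  n_control <- sum(groups == "control")
  if (n_case < 2 || n_control < 2) {
    abort(sprintf(
      "each group needs at least 2 samples (got %d case, %d control); group variance is undefined otherwise.",
      n_case, n_control
    ))
  }
  expr_matrix(num, groups)
}

#' Read a two-column probe annotation table
#'
#' @param path Path to a TSV with probe id and gene symbol columns (a header
#'   row is tolerated; may be gzip-compressed). Multi-symbol entries use
#'   `///`, `;` or `,` separators.
#' @return A tibble with columns `probe_id`, `symbol`.
#' @export
read_probe_annotation <- function(path) {
  ann <- read.delim(path,
    header = FALSE, sep = "\t", colClasses = "character",
    stringsAsFactors = FALSE, comment.char = "", quote = ""
  )
  if (ncol(ann) < 2) abort("probe annotation must have two columns.")
  out <- tibble(probe_id = ann[[1]], symbol = ann[[2]])
  if (nrow(out) > 1 && tolower(out$probe_id[1]) %in% c("probe_id", "probe", "id")) {
    out <- out[-1, ]
  }
  if (anyDuplicated(out$probe_id)) abort("probe ids must be unique in the annotation.")
  out
}

# Split a platform symbol field on the GEO dialect separators.
split_symbols <- function(x) {
  parts <- strsplit(trimws(x), "\\s*(///|;|,)\\s*")
  lapply(parts, function(s) unique(s[nzchar(s)]))
}

#' Collapse probe-level rows to unique gene symbols
#'
#' Probes annotated to zero or to multiple gene symbols are eliminated; when
#' several probes map to the same symbol their per-sample arithmetic mean is
#' taken, so the result has one row per gene symbol.
#'
#' @param m An [expr_matrix()] whose rows are probe ids.
#' @param ann Probe annotation: a data frame with columns `probe_id` and
#'   `symbol` (multi-symbol entries separated by `///`, `;` or `,`), as
#'   returned by [read_probe_annotation()].
#'
#' @return An [expr_matrix()] with gene symbols as row names.
#' @export
collapse_probes <- function(m, ann) {
  stopifnot(inherits(m, "expr_matrix"))
  ann <- as_tibble(ann)
  if (!all(c("probe_id", "symbol") %in% names(ann))) {
    abort("`ann` needs columns probe_id and symbol.")
  }
  if (anyDuplicated(ann$probe_id)) abort("probe ids must be unique in the annotation.")
  syms <- split_symbols(ann$symbol)
  single <- lengths(syms) == 1L
  map <- setNames(vapply(syms[single], identity, character(1)), ann$probe_id[single])
  keep <- rownames(m$values)[rownames(m$values) %in% names(map)]
  if (!length(keep)) abort("no probe maps to exactly one gene symbol.")
  v <- m$values[keep, , drop = FALSE]
  gene <- unname(map[keep])
  summed <- rowsum(v, group = gene)
  counts <- as.vector(table(gene)[rownames(summed)])
  expr_matrix(summed / counts, m$groups)
}

#' Enforce log2 scale on an expression matrix
#'
#' A maximum value above `threshold` is taken as evidence of an unlogged
#' intensity matrix, in which case `log2(x + 1)` is applied; otherwise the
#' matrix is returned unchanged. The decision is reported via a message and
#' recorded in the `"log2_transformed"` attribute, and a second application
#' never re-transforms.
#'
#' @param m An [expr_matrix()].
#' @param threshold Heuristic cut on the maximum value (default 30) above
#'   which the data are considered unlogged.
#'
#' @return An [expr_matrix()] on the log2 scale.
#' @export
ensure_log2 <- function(m, threshold = 30) {
  stopifnot(inherits(m, "expr_matrix"))
  mx <- max(m$values)
  if (mx > threshold) {
    if (min(m$values) < 0) {
      abort(sprintf(
        "matrix looks unlogged (max %.3g > %g) but contains negative values; cannot log2-transform.",
        mx, threshold
      ))
    }
    m$values <- log2(m$values + 1)
    inform(sprintf(
      "max value %.3g > %g: applied log2(x + 1) transform.", mx, threshold
    ))
    attr(m, "log2_transformed") <- TRUE
  } else {
    inform(sprintf("max value %.3g <= %g: matrix kept as is.", mx, threshold))
    attr(m, "log2_transformed") <- attr(m, "log2_transformed") %||% FALSE
  }
  m
}

#' Flag heterogeneous samples by mean inter-sample correlation
#'
#' Computes all pairwise Pearson correlations between samples; a sample is
#' flagged when its mean correlation to the other samples falls more than
#' `k_mads` median absolute deviations (scaled, [stats::mad()]) below the
#' median of those means. Constant (zero-variance) samples are flagged
#' unconditionally with a warning. The caller decides whether to drop the
#' flagged samples.
#'
#' @param m An [expr_matrix()] with at least 4 samples.
#' @param k_mads Flagging threshold in MAD units (default 3).
#'
#' @return Character vector of flagged sample ids (possibly empty), in
#'   column order.
#' @export
detect_outlier_samples <- function(m, k_mads = 3) {
  stopifnot(inherits(m, "expr_matrix"))
  v <- m$values
  n <- ncol(v)
  if (n < 4) abort("need at least 4 samples to assess heterogeneity.")
  sds <- apply(v, 2, sd)
  constant <- !is.finite(sds) | sds == 0
  if (any(constant)) {
    warn(sprintf(
      "constant sample(s) flagged unconditionally: %s",
      paste(colnames(v)[constant], collapse = ", ")
    ))
  }
  cc <- suppressWarnings(cor(v))
  mean_cor <- vapply(
    seq_len(n),
    function(i) mean(cc[-i, i], na.rm = TRUE),
    numeric(1)
  )
  ok <- !constant & is.finite(mean_cor)
  flagged <- constant
  if (sum(ok) >= 2) {
    med <- median(mean_cor[ok])
    dev <- mad(mean_cor[ok])
    if (dev > 0) {
      flagged <- flagged | (is.finite(mean_cor) & mean_cor < med - k_mads * dev)
    }
  }
  colnames(v)[flagged]
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_table()]: writes the value table (first
#' column `feature`) and, if `group_map` is given, the sample -> group map.
#'
#' @param m An [expr_matrix()].
#' @param path Output TSV path for the values.
#' @param group_map Optional output TSV path for the group map.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(m, path, group_map = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  tbl <- as.data.frame(m$values)
  tbl <- cbind(feature = rownames(m$values), tbl)
  readr::write_tsv(tbl, path)
  if (!is.null(group_map)) {
    readr::write_tsv(
      tibble(sample_id = names(m$groups), group = unname(m$groups)),
      group_map
    )
  }
  invisible(path)
}
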