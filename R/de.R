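# Two-group differential expression with an empirical-Bayes moderated
# t-statistic: per-gene pooled variances are shrunk toward a common prior
# variance s0^2 with prior degrees of freedom d0, both estimated by the
# method of moments on log variances (Smyth-style), and the t reference
# distribution gains the prior degrees of freedom.

#' Invert the trigamma function
#'
#' Solves `trigamma(x) = y` for `x > 0` by a monotone Newton iteration on
#' `1/trigamma` (globally convergent because `1/trigamma` is almost linear).
#'
#' @param y Positive target value (vectorised).
#' @return `x` such that `trigamma(x) = y`.
#' @export
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy) || yy <= 0) abort("`y` must be positive and finite.")
    if (yy > 1e7) return(1 / sqrt(yy))
    if (yy < 1e-6) return(1 / yy)
    x <- 0.5 + 1 / yy
    for (i in 1:100) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif) / x < 1e-12) break
    }
    x
  }, numeric(1))
}

#' Estimate the variance-shrinkage prior from per-gene variances
#'
#' Method-of-moments estimator on log variances: with
#' `e_g = log(s2_g) - digamma(df/2) + log(df/2)`, the excess variance of `e`
#' over `trigamma(df/2)` identifies the prior degrees of freedom `d0` through
#' `trigamma(d0/2) = var(e) - trigamma(df/2)`, solved by [trigamma_inverse()];
#' the prior variance follows from the mean of `e`. When the excess is
#' non-positive the prior is degenerate (`d0 = Inf`, complete shrinkage) and
#' `s0_2` is the geometric mean of the observed variances, so that genes with
#' identical variances keep their ordinary pooled t exactly.
#'
#' @param s2 Per-gene residual variances (at least 10 positive values).
#' @param df Residual degrees of freedom shared by all genes.
#'
#' @return An object of class `variance_prior`: list with `d0` (prior df,
#'   possibly `Inf`) and `s0_2` (prior variance).
#' @export
estimate_variance_prior <- function(s2, df) {
  s2 <- s2[is.finite(s2)]
  if (!length(s2) || all(s2 <= 0)) abort("all variances are zero; cannot estimate a prior.")
  pos <- s2[s2 > 0]
  if (length(pos) < 10) abort("need at least 10 genes with positive variance.")
  if (df <= 0) abort("`df` must be positive.")
  e <- log(pos) - digamma(df / 2) + log(df / 2)
  ve <- var(e)
  target <- ve - trigamma(df / 2)
  if (!is.finite(target) || target <= 0) {
    d0 <- Inf
    # literally identical variances need no log-scale bias correction: the
    # common variance is the prior, keeping the pooled t exact; otherwise
    # the non-positive moment target is sampling noise and the corrected
    # mean of e estimates log(s0^2) unbiasedly
    s0_2 <- if (ve < 1e-12) exp(mean(log(pos))) else exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(target)
    s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0_2 = s0_2), class = "variance_prior")
}

#' @export
print.variance_prior <- function(x, ...) {
  cat(sprintf("<variance_prior> d0 = %s, s0^2 = %.5g\n", format(x$d0), x$s0_2))
  invisible(x)
}

#' Moderated t-test for a two-group expression matrix
#'
#' Per gene, the pooled residual variance `s2` on `n1 + n2 - 2` df is shrunk
#' to `s2_post = (d0 * s0_2 + df * s2) / (d0 + df)`; the moderated t is
#' `log2fc / sqrt(s2_post * (1/n1 + 1/n2))` with a two-sided p-value from a
#' Student t on `d0 + df` degrees of freedom (standard normal when
#' `d0 = Inf`). `log2fc` is mean(case) - mean(control).
#'
#' @param m An [expr_matrix()] with at least 2 samples per group.
#' @param prior Optional pre-computed [estimate_variance_prior()] result;
#'   estimated from the data when `NULL`.
#'
#' @return An object of class `de_fit`. Use [tidy()] for the per-gene table
#'   (`gene`, `log2fc`, `t`, `p`, `s2`, `df_resid`, `direction`) and
#'   [glance()] for the prior and design summary.
#' @export
moderated_t_test <- function(m, prior = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  case <- names(m$groups)[m$groups == "case"]
  control <- names(m$groups)[m$groups == "control"]
  n1 <- length(case)
  n2 <- length(control)
  if (n1 < 2 || n2 < 2) abort("each group needs at least 2 samples.")
  v <- m$values
  mu1 <- rowMeans(v[, case, drop = FALSE])
  mu0 <- rowMeans(v[, control, drop = FALSE])
  ss1 <- rowSums((v[, case, drop = FALSE] - mu1)^2)
  ss0 <- rowSums((v[, control, drop = FALSE] - mu0)^2)
  df <- n1 + n2 - 2
  s2 <- (ss1 + ss0) / df
  log2fc <- mu1 - mu0
  if (is.null(prior)) prior <- estimate_variance_prior(s2, df)
  d0 <- prior$d0
  s2_post <- if (is.infinite(d0)) {
    rep(prior$s0_2, length(s2))
  } else {
    (d0 * prior$s0_2 + df * s2) / (d0 + df)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  untestable <- se == 0
  if (any(untestable)) {
    warn(sprintf(
      "%d gene(s) with zero posterior variance cannot be tested; p set to 1.",
      sum(untestable)
    ))
  }
  t_mod <- ifelse(untestable, 0, log2fc / se)
  p <- if (is.infinite(d0)) 2 * pnorm(-abs(t_mod)) else 2 * pt(-abs(t_mod), df = d0 + df)
  p[untestable] <- 1
  p <- pmax(p, .Machine$double.xmin) # keep p in (0, 1]
  table <- tibble(
    gene = rownames(v),
    log2fc = unname(log2fc),
    t = unname(t_mod),
    p = unname(p),
    s2 = unname(s2),
    df_resid = df,
    direction = ifelse(log2fc >= 0, "up", "down")
  )
  structure(
    list(table = table, prior = prior, n_case = n1, n_control = n2, df_resid = df),
    class = "de_fit"
  )
}

#' @export
print.de_fit <- function(x, ...) {
  cat(sprintf(
    "<de_fit> %d genes, %d case vs %d control; prior d0 = %s, s0^2 = %.4g\n",
    nrow(x$table), x$n_case, x$n_control, format(x$prior$d0), x$prior$s0_2
  ))
  print(head(x$table, 5))
  invisible(x)
}

#' Per-gene results of a moderated t fit
#' @param x A `de_fit`.
#' @param ... Unused.
#' @return Tibble with one row per gene.
#' @export
tidy.de_fit <- function(x, ...) x$table

#' One-row summary of a moderated t fit
#' @param x A `de_fit`.
#' @param ... Unused.
#' @return Tibble with columns `d0`, `s0_2`, `n_genes`, `n_case`,
#'   `n_control`, `df_resid`.
#' @export
glance.de_fit <- function(x, ...) {
  tibble(
    d0 = x$prior$d0, s0_2 = x$prior$s0_2, n_genes = nrow(x$table),
    n_case = x$n_case, n_control = x$n_control, df_resid = x$df_resid
  )
}

de_table <- function(x) {
  if (inherits(x, "de_fit")) {
    return(x$table)
  }
  x <- as_tibble(x)
  if (!all(c("gene", "log2fc", "p") %in% names(x))) {
    abort("expected a de_fit or a table with columns gene, log2fc, p.")
  }
  x
}

#' Threshold a differential-expression table into up/down gene lists
#'
#' Keeps genes with `p < alpha` and `log2fc` strictly beyond `+lfc` (up) or
#' `-lfc` (down). Each list is ordered by absolute fold change descending,
#' ties broken by gene symbol ascending — the ranking consumed by
#' [rra_aggregate()].
#'
#' @param x A `de_fit` or a data frame with columns `gene`, `log2fc`, `p`.
#' @param lfc Absolute log2 fold-change cut (strict; default 0.5).
#' @param alpha p-value cut (strict; default 0.05).
#'
#' @return List with character vectors `up` and `down`.
#' @export
filter_degs <- function(x, lfc = 0.5, alpha = 0.05) {
  tbl <- de_table(x)
  pick <- function(rows) {
    rows <- rows[order(-abs(rows$log2fc), rows$gene), ]
    rows$gene
  }
  list(
    up = pick(tbl[tbl$p < alpha & tbl$log2fc > lfc, ]),
    down = pick(tbl[tbl$p < alpha & tbl$log2fc < -lfc, ])
  )
}

#' Write a differential-expression table as TSV
#' @param x A `de_fit` or tidy DE table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(x, path) {
  readr::write_tsv(de_table(x), path)
  invisible(path)
}
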