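# Expression IO: reading, probe collapsing, log2 enforcement, outlier flags.

write_expr_fixture <- function(values, groups, sep = "\t", gz = FALSE) {
  path <- withr::local_tempfile(fileext = if (gz) ".tsv.gz" else ".tsv", .local_envir = parent.frame())
  gmap <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  tbl <- cbind(feature = rownames(values), as.data.frame(values))
  con <- if (gz) gzfile(path, "w") else file(path, "w")
  write.table(tbl, con, sep = sep, quote = FALSE, row.names = FALSE)
  close(con)
  write.table(data.frame(s = names(groups), g = unname(groups)), gmap,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  list(values = path, groups = gmap)
}

toy_values <- function(nr = 3, nc = 4, seed = 1) {
  set.seed(seed)
  matrix(round(rnorm(nr * nc, 8), 3), nr, nc,
    dimnames = list(paste0("P", seq_len(nr)), paste0("S", seq_len(nc)))
  )
}

test_that("read_expression_table reads TSV/CSV, attaches groups, drops unmapped samples", {
  v <- toy_values()
  grp <- setNames(c("case", "case", "control", "control"), colnames(v))
  fx <- write_expr_fixture(v, grp)
  m <- read_expression_table(fx$values, fx$groups)
  expect_s3_class(m, "expr_matrix")
  expect_equal(dim(m), c(3L, 4L))
  expect_equal(m$values, v)
  expect_equal(unname(m$groups), c("case", "case", "control", "control"))

  # comma-separated dialect
  fx_csv <- write_expr_fixture(v, grp, sep = ",")
  expect_equal(read_expression_table(fx_csv$values, fx_csv$groups)$values, v)

  # gzip tolerated
  fx_gz <- write_expr_fixture(v, grp, gz = TRUE)
  expect_equal(read_expression_table(fx_gz$values, fx_gz$groups)$values, v)

  # a sample absent from the group map is dropped with a warning
  v5 <- cbind(v, S5 = c(1, 2, 3))
  fx5 <- write_expr_fixture(v5, grp)
  expect_warning(m5 <- read_expression_table(fx5$values, fx5$groups), "S5")
  expect_equal(colnames(m5$values), colnames(v))
})

test_that("read_expression_table rejects non-numeric cells naming row and column", {
  v <- toy_values()
  grp <- setNames(c("case", "case", "control", "control"), colnames(v))
  vc <- v
  storage.mode(vc) <- "character"
  vc[2, 3] <- "NA"
  fx <- write_expr_fixture(vc, grp)
  expect_error(read_expression_table(fx$values, fx$groups), "row 2, column 3")
})

test_that("read_expression_table requires two samples per group", {
  v <- toy_values()
  grp <- setNames(c("case", "control", "control", "control"), colnames(v))
  fx <- write_expr_fixture(v, grp)
  expect_error(read_expression_table(fx$values, fx$groups), "at least 2 samples")
})

test_that("collapse_probes averages same-symbol probes and drops 0/multi-symbol probes", {
  v <- matrix(
    c(
      2, 4, # P1 -> A
      4, 6, # P2 -> A
      9, 9, # P3 -> A///B (eliminated)
      7, 7, # P4 -> "" (eliminated)
      1, 2 # P5 -> C
    ),
    ncol = 2, byrow = TRUE,
    dimnames = list(paste0("P", 1:5), c("S1", "S2"))
  )
  m <- expr_matrix(v, setNames(c("case", "control"), c("S1", "S2")))
  ann <- data.frame(
    probe_id = paste0("P", 1:5),
    symbol = c("A", "A", "A///B", "", "C")
  )
  out <- collapse_probes(m, ann)
  expect_equal(sort(rownames(out$values)), c("A", "C"))
  expect_equal(unname(out$values["A", ]), c(3, 5))
  expect_equal(unname(out$values["C", ]), c(1, 2))

  # alternative separators also mark multi-symbol probes
  ann2 <- data.frame(probe_id = paste0("P", 1:5), symbol = c("A", "A", "A;B", "X,Y", "C"))
  expect_equal(sort(rownames(collapse_probes(m, ann2)$values)), c("A", "C"))

  # re-collapsing with an identity annotation is idempotent
  idann <- data.frame(probe_id = rownames(out$values), symbol = rownames(out$values))
  expect_equal(collapse_probes(out, idann)$values, out$values)

  # nothing mappable is an error
  ann3 <- data.frame(probe_id = paste0("P", 1:5), symbol = rep("A///B", 5))
  expect_error(collapse_probes(m, ann3), "exactly one")
})

test_that("ensure_log2 transforms only unlogged data, idempotently, and rejects negatives", {
  mk <- function(v) {
    expr_matrix(
      matrix(v, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2"))),
      setNames(c("case", "control"), c("s1", "s2"))
    )
  }
  logged <- mk(c(3.2, 8, 14.2, 5))
  expect_message(out <- ensure_log2(logged), "kept as is")
  expect_equal(out$values, logged$values)

  raw <- mk(c(1023, 100, 3, 7))
  expect_message(tr <- ensure_log2(raw), "log2")
  expect_equal(tr$values["g1", "s1"], 10) # log2(1024)
  expect_true(attr(tr, "log2_transformed"))
  # second application never re-transforms
  expect_message(tr2 <- ensure_log2(tr), "kept as is")
  expect_equal(tr2$values, tr$values)

  neg <- mk(c(-5, 5000, 3, 7))
  expect_error(ensure_log2(neg), "negative")
})

test_that("detect_outlier_samples flags the planted noise sample and constant samples", {
  set.seed(11)
  profile <- rnorm(300, 8, 1.5)
  good <- sapply(1:5, function(i) profile + rnorm(300, sd = 0.3))
  noise <- rnorm(300, 8, 1.5)
  v <- cbind(good, noise)
  colnames(v) <- paste0("S", 1:6)
  rownames(v) <- paste0("g", 1:300)
  grp <- setNames(rep(c("case", "control"), 3), colnames(v))
  m <- expr_matrix(v, grp)
  flagged <- detect_outlier_samples(m)
  # oracle: inspect the correlation matrix directly
  cc <- cor(v)
  mean_cor <- sapply(1:6, function(i) mean(cc[-i, i]))
  expect_equal(which.min(mean_cor), 6L)
  expect_lt(mean_cor[6], median(mean_cor) - 3 * mad(mean_cor))
  expect_identical(flagged, "S6")

  # homogeneous samples: nothing flagged
  homog <- v[, 1:5]
  mh <- expr_matrix(homog, grp[1:5])
  expect_identical(detect_outlier_samples(mh), character(0))

  # constant sample flagged unconditionally
  v2 <- v
  v2[, 3] <- 5
  m2 <- expr_matrix(v2, grp)
  expect_warning(f2 <- detect_outlier_samples(m2), "constant")
  expect_true("S3" %in% f2)

  # permutation equivariance in sample order
  perm <- c(4, 6, 1, 3, 2, 5)
  mp <- expr_matrix(v[, perm], grp[perm])
  expect_setequal(detect_outlier_samples(mp), flagged)
})

test_that("expression matrices round-trip through write/read", {
  v <- toy_values(5, 4, seed = 7)
  grp <- setNames(c("case", "case", "control", "control"), colnames(v))
  m <- expr_matrix(v, grp)
  vpath <- withr::local_tempfile(fileext = ".tsv")
  gpath <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(m, vpath, group_map = gpath)
  back <- read_expression_table(vpath, gpath)
  expect_equal(back$values, m$values)
  expect_equal(back$groups, m$groups)
})
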