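test_that("summary_stats matches hand computation and the complete-matrix identity", {
  s <- summary_stats(agg_matrix(matrix(c(1, 0, 1, 0), 2)))
  expect_equal(s$C, 0.5)
  expect_equal(s$R, 0.5)
  expect_equal(s$M, 0.5)
  # complete mask: C = R = M to machine precision
  set.seed(2)
  for (i in 1:20) {
    x <- agg_matrix(matrix(runif(30), 5, 6))
    s <- summary_stats(x)
    expect_equal(s$C, s$M, tolerance = 1e-15)
    expect_equal(s$R, s$M, tolerance = 1e-15)
  }
  expect_error(summary_stats(agg_matrix(matrix(NA_real_, 2, 2))), "no observed data")
})

test_that("summary_stats agrees with a brute-force loop on random masked matrices", {
  set.seed(13)
  for (i in 1:200) {
    x <- random_masked_matrix(sample(2:10, 1), sample(2:10, 1), runif(1, 0, 0.8))
    s <- summary_stats(x)
    o <- brute_stats(x$values)
    expect_equal(s$C, o$C, tolerance = 1e-12)
    expect_equal(s$R, o$R, tolerance = 1e-12)
    expect_equal(s$M, o$M, tolerance = 1e-12)
    if (!is.na(o$r)) expect_equal(s$r, o$r, tolerance = 1e-12)
  }
})

test_that("statistics respect permutation invariances", {
  set.seed(17)
  x <- random_masked_matrix(8, 6, 0.4)
  s0 <- summary_stats(x)
  # row permutation: all three means invariant
  xp <- agg_matrix(x$values[sample(8), ])
  sp <- summary_stats(xp)
  expect_equal(sp$C, s0$C)
  expect_equal(sp$R, s0$R)
  expect_equal(sp$M, s0$M)
  # column permutation: C and M invariant (R too: row means unchanged)
  xc <- agg_matrix(x$values[, sample(6)])
  sc <- summary_stats(xc)
  expect_equal(sc$C, s0$C)
  expect_equal(sc$M, s0$M)
  # within-row value permutation on a fixed mask: R invariant
  v <- x$values
  for (i in 1:8) {
    idx <- which(!is.na(v[i, ]))
    if (length(idx) > 1) v[i, idx] <- v[i, sample(idx)]
  }
  expect_equal(summary_stats(agg_matrix(v))$R, s0$R)
})

test_that("column_profile reports averages, counts and undefined columns", {
  x <- agg_matrix(matrix(c(1, 0, NA, 1, NA, NA), 3, 2))
  prof <- column_profile(x)
  expect_equal(prof$average[1], 0.5)
  expect_equal(prof$count[1], 2L)
  expect_equal(prof$count[2], 1L)
  # a column with fewer observations than min_obs is undefined
  prof10 <- column_profile(x, min_obs = 10)
  expect_true(all(is.na(prof10$average)))
  # consistency: mean over defined columns equals C at min_obs = 1
  set.seed(23)
  y <- random_masked_matrix(12, 7, 0.5)
  p <- column_profile(y, min_obs = 1)
  expect_equal(mean(p$average, na.rm = TRUE), summary_stats(y)$C)
  # binning pools adjacent columns
  pb <- column_profile(y, bin = 3)
  expect_equal(nrow(pb), 3L)
  expect_equal(pb$count[1], sum(!is.na(y$values[, 1:3])))
  expect_equal(pb$average[1], mean(y$values[, 1:3], na.rm = TRUE))
})

test_that("build_matrix_pair places calls at their boundary distances", {
  calls <- data.frame(chrom = "chr1", pos = c(1000, 1003), strand = "+",
                      rate = c(1, 0), coverage = 5)
  bounds <- data.frame(chrom = "chr1", boundary_pos = 1000, strand = "+",
                       upstream_span = 5, downstream_span = 5, label = "j1")
  pair <- build_matrix_pair(calls, bounds)
  expect_equal(pair$right$values[1, ], c(1, NA, NA, 0, NA))
  expect_true(all(is.na(pair$left$values)))
  # same calls on a minus-strand boundary appear mirrored on the left matrix
  bounds$strand <- "-"
  pairm <- build_matrix_pair(calls, bounds)
  expect_equal(pairm$left$values[1, ], c(1, NA, NA, 0, NA))
  expect_true(all(is.na(pairm$right$values)))
})

test_that("build_matrix_pair matches a naive per-boundary linear scan", {
  set.seed(29)
  n_calls <- 400
  calls <- data.frame(chrom = sample(c("chr1", "chr2"), n_calls, TRUE),
                      pos = sample(0:2000, n_calls), strand = "+",
                      rate = round(runif(n_calls), 3), coverage = 5)
  calls <- calls[!duplicated(calls[c("chrom", "pos")]), ]
  bounds <- data.frame(chrom = sample(c("chr1", "chr2"), 50, TRUE),
                       boundary_pos = sample(100:1900, 50),
                       strand = sample(c("+", "-"), 50, TRUE),
                       upstream_span = 30, downstream_span = 30,
                       label = paste0("j", 1:50))
  pair <- build_matrix_pair(calls, bounds)
  # oracle: scan calls one by one for each boundary
  left <- matrix(NA_real_, 50, 30); right <- matrix(NA_real_, 50, 30)
  for (i in 1:50) {
    for (k in seq_len(nrow(calls))) {
      if (calls$chrom[k] != bounds$chrom[i]) next
      d <- calls$pos[k] - bounds$boundary_pos[i]
      if (bounds$strand[i] == "+") {
        if (d >= 0 && d < 30) right[i, d + 1] <- calls$rate[k]
        if (d < 0 && d >= -30) left[i, -d] <- calls$rate[k]
      } else {
        if (d < 0 && d >= -30) right[i, -d] <- calls$rate[k]
        if (d >= 0 && d < 30) left[i, d + 1] <- calls$rate[k]
      }
    }
  }
  expect_identical(pair$left$values, left)
  expect_identical(pair$right$values, right)
})

test_that("witness_matrix realises requested statistics", {
  w <- witness_matrix(c(2, 3), c(1, 3), c(1, 3))
  s <- summary_stats(w)
  expect_equal(s$R, 2 / 3, tolerance = 1e-9)
  expect_equal(s$C, 1 / 3, tolerance = 1e-9)
  expect_equal(s$M, 1 / 3, tolerance = 1e-9)
  # any complete constant matrix realises an equal triple
  w5 <- witness_matrix(0.5, 0.5, 0.5)
  expect_true(all(!is.na(w5$values)))
  expect_equal(summary_stats(w5)$M, 0.5)
  expect_error(witness_matrix(1.2, 0.5, 0.5), "inside \\(0, 1\\)")
})

test_that("witness_matrix covers random rational triples to 1e-9", {
  set.seed(31)
  for (i in 1:30) {
    tr <- runif(3, 0.05, 0.95)
    s <- summary_stats(witness_matrix(tr[1], tr[2], tr[3]))
    expect_lt(max(abs(c(s$R - tr[1], s$C - tr[2], s$M - tr[3]))), 1e-9)
  }
})
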