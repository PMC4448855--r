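test_that("leave-one-out features match their definitions", {
  x <- agg_matrix(rbind(c(1, NA, 0)))
  f <- compute_features(x)
  expect_equal(f$X[1, 1], 0)      # only observed other cell is 0
  expect_equal(f$Y[1, 1], 1 / 2)  # one of the two other cells is missing
  expect_equal(f$B[1, 1], 0)
  # all-missing rest of row
  y <- agg_matrix(rbind(c(0.4, NA, NA)))
  fy <- compute_features(y)
  expect_equal(fy$B[1, 1], 1)
  expect_equal(fy$X[1, 1], 0)
  expect_equal(fy$Y[1, 1], 1)
})

test_that("features agree with a naive per-cell loop, whole-row and block mode", {
  set.seed(79)
  for (i in 1:15) {
    x <- random_masked_matrix(sample(2:8, 1), sample(2:9, 1), runif(1, 0.1, 0.7))
    for (block in list(NULL, 3, 5)) {
      got <- compute_features(x, block = block)
      want <- brute_features(x$values, block = block)
      expect_equal(got$B, want$B)
      expect_equal(got$X, want$X)
      expect_equal(got$Y, want$Y)
    }
  }
})

test_that("an intercept-only column fits its mean and min_obs gates fitting", {
  v <- matrix(NA_real_, 20, 2)
  v[, 1] <- 0.5
  v[1:20, 2] <- 0.5
  x <- agg_matrix(v)
  f <- compute_features(x)
  cm <- fit_column(1, f, x)
  expect_true(cm$fitted)
  pred <- predict_cell(cm, list(B = f$B[1, 1], X = f$X[1, 1], Y = f$Y[1, 1]))
  expect_equal(unname(pred), 0.5, tolerance = 1e-6)
  # nine observations against a ten-observation gate
  v9 <- matrix(runif(18), 9, 2)
  x9 <- agg_matrix(rbind(v9, matrix(c(NA, 0.5), 1)))
  cm9 <- fit_column(1, compute_features(x9), x9)
  expect_false(cm9$fitted)
  expect_equal(cm9$n_obs, 9L)
  expect_error(predict_cell(cm9, list(B = 0, X = 0.5, Y = 0)), "no fitted model")
})

test_that("the fractional-logit fitter agrees with quasibinomial glm", {
  set.seed(83)
  n <- 300
  X <- runif(n); Y <- runif(n); B <- rep(0, n)
  eta <- 1.5 * X - 0.8 * Y + 0.2
  rate <- rbinom(n, 20, plogis(eta)) / 20
  v <- matrix(NA_real_, n, 2)
  v[, 2] <- rate
  x <- agg_matrix(v)
  feats <- list(B = cbind(B, B), X = cbind(X, X), Y = cbind(Y, Y))
  cm <- fit_column(2, feats, x, ridge = 0)
  g <- suppressWarnings(glm(rate ~ X + Y, family = quasibinomial()))
  expect_equal(unname(cm$coef[c("x", "y", "z")]),
               unname(coef(g)[c("X", "Y", "(Intercept)")]), tolerance = 1e-5)
})

test_that("predict_cell evaluates the logistic formula exactly", {
  zero <- structure(list(column = 1L, coef = c(b = 0, x = 0, y = 0, z = 0),
                         n_obs = 50L, fitted = TRUE), class = "column_model")
  expect_equal(unname(predict_cell(zero, list(B = 1, X = 0.3, Y = 0.9))), 0.5)
  cancel <- structure(list(column = 1L, coef = c(b = 0, x = 2, y = 0, z = -1),
                           n_obs = 50L, fitted = TRUE), class = "column_model")
  expect_equal(unname(predict_cell(cancel, list(B = 0, X = 0.5, Y = 0.77))), 0.5)
  set.seed(89)
  for (i in 1:1000) {
    co <- rnorm(4, 0, 2)
    f <- list(B = rbinom(1, 1, 0.2), X = runif(1), Y = runif(1))
    model <- structure(list(column = 1L,
                            coef = c(b = co[1], x = co[2], y = co[3], z = co[4]),
                            n_obs = 50L, fitted = TRUE), class = "column_model")
    eta <- co[1] * f$B + co[2] * f$X + co[3] * f$Y + co[4]
    expect_equal(unname(predict_cell(model, f)), 1 / (1 + exp(-eta)), tolerance = 1e-12)
  }
})

test_that("complete_matrix recovers separable row types and gates sparse columns", {
  set.seed(97)
  n <- 60
  type <- rep(c(1, 0), each = n / 2)
  v <- matrix(rep(type, 8), n, 8)
  v[matrix(runif(n * 8), n, 8) < 0.3] <- NA
  v[rowSums(!is.na(v)) == 0, 1] <- type[rowSums(!is.na(v)) == 0]
  v <- cbind(v, NA_real_)  # a column with no data stays unfitted
  v[1:5, 9] <- type[1:5]   # 5 < min_obs
  fit <- complete_matrix(agg_matrix(v), cv = FALSE)
  expect_false(9L %in% fit$fitted_columns)
  expect_true(all(is.na(fit$completed$values[, 9])))
  comp <- fit$completed$values[, fit$fitted_columns]
  expect_true(all(comp > 0 & comp < 1))
  expect_lt(max(abs(comp - matrix(rep(type, length(fit$fitted_columns)),
                                  n))), 0.05)
  expect_error(complete_matrix(agg_matrix(matrix(c(runif(5), rep(NA, 7)), 6, 2))),
               "no column")
})

test_that("predictions are monotone in X when only x is positive", {
  model <- structure(list(column = 1L, coef = c(b = 0, x = 1.7, y = 0, z = -0.4),
                          n_obs = 50L, fitted = TRUE), class = "column_model")
  xs <- seq(0, 1, 0.05)
  preds <- sapply(xs, function(xx) predict_cell(model, list(B = 0, X = xx, Y = runif(1))))
  expect_true(all(diff(preds) > 0))
})

test_that("the TLS line is exact in the perfect-prediction limit and known cases", {
  o <- runif(50)
  tl <- methagg:::tls_line(o, o)
  expect_equal(tl$slope, 1)
  expect_equal(tl$variance_explained, 1)
  # exact anti-diagonal
  tl2 <- methagg:::tls_line(o, 1 - o)
  expect_equal(tl2$slope, -1)
  expect_equal(tl2$variance_explained, 1)
})

test_that("cross-validation is deterministic in the seed and covers observed cells", {
  set.seed(101)
  n <- 80
  tend <- runif(n)
  v <- matrix(rep(tend, 6), n, 6) + matrix(rnorm(n * 6, 0, 0.05), n, 6)
  v <- pmin(pmax(v, 0), 1)
  v[matrix(runif(n * 6), n, 6) < 0.3] <- NA
  x <- agg_matrix(v)
  cv1 <- cross_validate(x, seed = 7)
  cv2 <- cross_validate(x, seed = 7)
  expect_identical(cv1$pooled_pairs, cv2$pooled_pairs)
  expect_identical(cv1$tls_slope, cv2$tls_slope)
  # every observed cell of a fitted column appears exactly once
  fitted_cols <- sort(unique(cv1$pooled_pairs$column))
  expect_equal(nrow(cv1$pooled_pairs),
               sum(colSums(!is.na(v))[fitted_cols]))
  expect_equal(cv1$fold_count, 10L)
  # near-noiseless signal: slope close to 1
  expect_lt(abs(cv1$tls_slope - 1), 0.15)
})
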