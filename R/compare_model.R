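#' Leave-one-out row features for COMPARE
#'
#' For each cell `(i, j)` of an aggregation matrix, three features summarise
#' the rest of row `i` (or, in block mode, the part of row `i` inside a
#' column window centred on `j`), always excluding the target cell itself:
#'
#' * `B`: 1 if the rest of the row has no observed value, else 0;
#' * `X`: the mean observed methylation rate of the rest of the row
#'   (0 when `B = 1`);
#' * `Y`: the proportion of missing cells in the rest of the row.
#'
#' `X` carries the region's methylation tendency, `Y` its conservation /
#' CpG-depletion state; their interplay is what lets the model separate
#' methylation from missingness.
#'
#' @param x An `agg_matrix`.
#' @param block Window width in columns for block mode (`NULL` = whole
#'   row). The window is centred on the target column and truncated at the
#'   matrix edges.
#' @return A list of three n-by-m numeric matrices `B`, `X`, `Y`.
#' @export
compute_features <- function(x, block = NULL) {
  stopifnot(inherits(x, "agg_matrix"))
  v <- x$values
  n <- nrow(v); m <- ncol(v)
  obs <- !is.na(v)
  v0 <- ifelse(obs, v, 0)
  B <- X <- Y <- matrix(0, n, m)
  half_lo <- half_hi <- NULL
  if (!is.null(block)) {
    stopifnot(block >= 1)
    half_lo <- floor((block - 1) / 2)
    half_hi <- ceiling((block - 1) / 2)
  }
  for (j in seq_len(m)) {
    cols <- if (is.null(block)) seq_len(m) else max(1L, j - half_lo):min(m, j + half_hi)
    width <- length(cols)
    cnt <- rowSums(obs[, cols, drop = FALSE]) - obs[, j]
    sm <- rowSums(v0[, cols, drop = FALSE]) - v0[, j]
    B[, j] <- as.numeric(cnt == 0)
    X[, j] <- ifelse(cnt > 0, sm / cnt, 0)
    Y[, j] <- if (width > 1L) (width - 1L - cnt) / (width - 1L) else 1
  }
  list(B = B, X = X, Y = Y)
}

#' Fit the per-column logistic model of COMPARE
#'
#' Fits, for one column `j`, the logistic regression
#' `E[rate] = 1 / (1 + exp(-(b B + x X + y Y + z)))` on the column's
#' observed cells, treating the bisulfite rates in `[0, 1]` as fractional
#' responses under a cross-entropy (quasi-binomial) objective. Columns with
#' fewer than `min_obs` observations are not fitted (too little training
#' data at that relative location). A small L2 penalty on the slope
#' coefficients keeps estimates finite on separable or collinear columns.
#'
#' @param j Column index.
#' @param features Feature list from [compute_features()] on the same
#'   matrix (and block).
#' @param x The `agg_matrix`.
#' @param min_obs Minimum observed cells required to fit (default 10).
#' @param ridge L2 penalty on `(b, x, y)` (the intercept is unpenalized).
#' @param weights Optional per-row observation weights for column `j`
#'   (e.g. read coverage); default unweighted.
#' @return An object of class `column_model`: list with `column`, `coef`
#'   (named `b`, `x`, `y`, `z`), `n_obs`, `fitted`, `converged`,
#'   `iterations`.
#' @export
fit_column <- function(j, features, x, min_obs = 10L, ridge = 1e-6, weights = NULL) {
  v <- x$values[, j]
  rows <- which(!is.na(v))
  n_obs <- length(rows)
  if (n_obs < min_obs) {
    return(structure(list(column = j, coef = c(b = NA_real_, x = NA_real_,
                                               y = NA_real_, z = NA_real_),
                          n_obs = n_obs, fitted = FALSE, converged = NA,
                          iterations = 0L),
                     class = "column_model"))
  }
  Z <- cbind(b = features$B[rows, j], x = features$X[rows, j],
             y = features$Y[rows, j], z = 1)
  fit <- irls_fractional_logit(Z, v[rows], ridge = ridge,
                               penalized = c(TRUE, TRUE, TRUE, FALSE),
                               w = if (is.null(weights)) NULL else weights[rows])
  if (!fit$converged) {
    stop(sprintf("logistic fit did not converge for column %d", j))
  }
  structure(list(column = j,
                 coef = stats::setNames(as.numeric(fit$beta), c("b", "x", "y", "z")),
                 n_obs = n_obs, fitted = TRUE, converged = fit$converged,
                 iterations = fit$iterations),
            class = "column_model")
}

# Penalized IRLS for fractional-response logistic regression
# (cross-entropy objective, L2 penalty on selected coefficients), with a
# BFGS fallback when the Newton path stalls.
irls_fractional_logit <- function(Z, yv, ridge = 1e-6, penalized = NULL,
                                  w = NULL, tol = 1e-8, max_iter = 100L) {
  p <- ncol(Z)
  if (is.null(penalized)) penalized <- rep(TRUE, p)
  if (is.null(w)) w <- rep(1, length(yv))
  P <- diag(as.numeric(penalized), p)
  objective <- function(beta) {
    eta <- drop(Z %*% beta)
    # numerically stable cross-entropy: log(1 + e^eta) - y * eta
    ce <- sum(w * (log1p(exp(-abs(eta))) + pmax(eta, 0) - yv * eta))
    ce + 0.5 * ridge * sum(beta^2 * penalized)
  }
  beta <- rep(0, p)
  obj <- objective(beta)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(Z %*% beta)
    mu <- stats::plogis(eta)
    wt <- pmax(w * mu * (1 - mu), 1e-10)
    zz <- eta + w * (yv - mu) / wt
    H <- crossprod(Z, Z * wt) + ridge * P
    beta_new <- tryCatch(solve(H, crossprod(Z, wt * zz)),
                         error = function(e) NULL)
    if (is.null(beta_new)) break
    beta_new <- drop(beta_new)
    obj_new <- objective(beta_new)
    # step-halving keeps the Newton update monotone
    step <- 1
    while (!is.finite(obj_new) || obj_new > obj + 1e-12) {
      step <- step / 2
      if (step < 1e-8) break
      beta_new <- beta + step * (beta_new - beta)
      obj_new <- objective(beta_new)
    }
    if (!is.finite(obj_new)) break
    done <- abs(obj - obj_new) < tol * (abs(obj) + 1)
    beta <- beta_new
    obj <- obj_new
    if (done) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    op <- stats::optim(beta, objective, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-12))
    if (op$convergence == 0) {
      beta <- op$par
      converged <- TRUE
    }
  }
  list(beta = beta, converged = converged, iterations = iter)
}

#' Inferred methylation tendency for one cell
#'
#' Evaluates the fitted logistic model at a feature triple: the probability
#' that the position would be methylated if it carried a CpG site.
#'
#' @param model A fitted `column_model`.
#' @param f List or vector with elements/fields `B`, `X`, `Y`.
#' @return Tendency strictly inside (0, 1).
#' @export
predict_cell <- function(model, f) {
  if (!isTRUE(model$fitted)) stop(sprintf("column %d has no fitted model", model$column))
  co <- model$coef
  eta <- co[["b"]] * f[["B"]] + co[["x"]] * f[["X"]] + co[["y"]] * f[["Y"]] + co[["z"]]
  pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
}

#' COMPARE: logistic-regression completion of an aggregation matrix
#'
#' Fits the per-column logistic model at every column with at least
#' `min_obs` observed values and infers a methylation tendency at every
#' cell of the fitted columns (observed cells included: the model predicts
#' everywhere, and the completed matrix is what unbiased `C`/`R`/`M`
#' statistics should be computed on). A 10-fold cross-validation of the
#' observed cells is run alongside and scored with a total-least-squares
#' line through the (observed, inferred) pairs.
#'
#' @param x An `agg_matrix`.
#' @param block Optional block width in columns (see [compute_features()]).
#' @param min_obs Minimum observations per column to fit (default 10).
#' @param ridge L2 penalty on slope coefficients.
#' @param seed Seed controlling the cross-validation folds.
#' @param keep_observed If `TRUE`, observed cells retain their measured
#'   values in the completed matrix instead of the model inference.
#' @param cv If `FALSE`, skip cross-validation.
#' @param folds Number of CV folds.
#' @return An object of class `compare_fit`: `column_models` (list),
#'   `completed` (`agg_matrix`, `NA` in unfitted columns), `block`,
#'   `fitted_columns`, `cv` (a `compare_cv` or `NULL`).
#' @export
complete_matrix <- function(x, block = NULL, min_obs = 10L, ridge = 1e-6,
                            seed = 1L, keep_observed = FALSE, cv = TRUE,
                            folds = 10L) {
  stopifnot(inherits(x, "agg_matrix"))
  feats <- compute_features(x, block = block)
  m <- ncol(x$values)
  models <- lapply(seq_len(m), fit_column, features = feats, x = x,
                   min_obs = min_obs, ridge = ridge)
  fitted_cols <- which(vapply(models, function(mo) mo$fitted, TRUE))
  if (!length(fitted_cols)) {
    stop(sprintf("no column has the %d observations required for fitting", min_obs))
  }
  completed <- matrix(NA_real_, nrow(x$values), m)
  for (j in fitted_cols) {
    completed[, j] <- predict_cell(models[[j]],
                                   list(B = feats$B[, j], X = feats$X[, j], Y = feats$Y[, j]))
  }
  if (keep_observed) {
    obs <- !is.na(x$values)
    sel <- obs & col(obs) %in% fitted_cols
    completed[sel] <- x$values[sel]
  }
  cv_rep <- if (cv) {
    cross_validate(x, block = block, k = folds, min_obs = min_obs,
                   ridge = ridge, seed = seed, features = feats)
  } else NULL
  structure(list(column_models = models,
                 completed = agg_matrix(completed, x$orientation),
                 block = if (is.null(block)) "whole-row" else block,
                 fitted_columns = fitted_cols, min_obs = min_obs,
                 cv = cv_rep),
            class = "compare_fit")
}

#' @export
print.compare_fit <- function(x, ...) {
  cat(sprintf("COMPARE fit: %d/%d columns fitted (block: %s, min_obs %d)\n",
              length(x$fitted_columns), length(x$column_models),
              as.character(x$block), x$min_obs))
  if (!is.null(x$cv)) print(x$cv)
  invisible(x)
}

#' Cross-validation of the COMPARE model
#'
#' The observed cells of each fittable column are split at random into `k`
#' folds; each fold is predicted from a model trained on the remaining
#' folds, and the (observed rate, inferred tendency) pairs are pooled over
#' all columns. Because both coordinates carry error (model misfit on one
#' side, finite bisulfite coverage on the other), accuracy is summarised by
#' the first-principal-component (total-least-squares) line through the
#' centred pairs: its slope, and the fraction of pair variance it explains
#' (1 minus the perpendicular sum of squares over the total sum of
#' squares).
#'
#' @param x An `agg_matrix`.
#' @param block Optional block width (must match the fit).
#' @param k Number of folds (default 10).
#' @param min_obs Minimum training observations per fold fit; columns where
#'   a fold would leave fewer are skipped with a warning.
#' @param ridge L2 penalty on slope coefficients.
#' @param seed Seed; fold assignment is derived per column so the whole
#'   report is reproducible from this integer.
#' @param features Optional precomputed [compute_features()] result.
#' @return An object of class `compare_cv`: `fold_count`, `pooled_pairs`
#'   (data frame `observed`, `inferred`, `column`), `tls_slope`,
#'   `variance_explained`, `seed`, `skipped_columns`.
#' @export
cross_validate <- function(x, block = NULL, k = 10L, min_obs = 10L,
                           ridge = 1e-6, seed = 1L, features = NULL) {
  stopifnot(inherits(x, "agg_matrix"), k >= 2L)
  if (is.null(features)) features <- compute_features(x, block = block)
  v <- x$values
  m <- ncol(v)
  obs_list <- inf_list <- col_list <- list()
  skipped <- integer(0)
  for (j in seq_len(m)) {
    rows <- which(!is.na(v[, j]))
    if (length(rows) < min_obs) next
    set.seed(derive_seed(seed, j))
    fold <- sample(rep_len(seq_len(k), length(rows)))
    if (min(table(factor(fold, levels = seq_len(k)))) < 1 ||
        length(rows) - max(table(fold)) < min_obs) {
      warning(sprintf("column %d skipped in CV: a fold leaves fewer than %d training points",
                      j, min_obs))
      skipped <- c(skipped, j)
      next
    }
    pred <- rep(NA_real_, length(rows))
    ok <- TRUE
    for (f in seq_len(k)) {
      train <- rows[fold != f]
      test <- rows[fold == f]
      Z <- cbind(features$B[train, j], features$X[train, j], features$Y[train, j], 1)
      fit <- irls_fractional_logit(Z, v[train, j], ridge = ridge,
                                   penalized = c(TRUE, TRUE, TRUE, FALSE))
      if (!fit$converged) {
        ok <- FALSE
        break
      }
      eta <- fit$beta[1] * features$B[test, j] + fit$beta[2] * features$X[test, j] +
        fit$beta[3] * features$Y[test, j] + fit$beta[4]
      pred[fold == f] <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
    }
    if (!ok) {
      warning(sprintf("column %d skipped in CV: fold model did not converge", j))
      skipped <- c(skipped, j)
      next
    }
    obs_list[[length(obs_list) + 1L]] <- v[rows, j]
    inf_list[[length(inf_list) + 1L]] <- pred
    col_list[[length(col_list) + 1L]] <- rep(j, length(rows))
  }
  if (!length(obs_list)) stop("no column could be cross-validated")
  pairs <- data.frame(observed = unlist(obs_list), inferred = unlist(inf_list),
                      column = unlist(col_list))
  tls <- tls_line(pairs$observed, pairs$inferred)
  structure(list(fold_count = k, pooled_pairs = pairs,
                 tls_slope = tls$slope, variance_explained = tls$variance_explained,
                 seed = seed, skipped_columns = skipped),
            class = "compare_cv")
}

# First-principal-component (total least squares) line through centred but
# unstandardised pairs: slope of the principal eigenvector, and the share
# of total variance it captures (1 - perpendicular SS / total SS).
tls_line <- function(xs, ys) {
  cx <- xs - mean(xs)
  cy <- ys - mean(ys)
  S <- matrix(c(sum(cx * cx), sum(cx * cy), sum(cx * cy), sum(cy * cy)), 2)
  if (sum(diag(S)) <= 0) return(list(slope = 1, variance_explained = 1))
  eig <- eigen(S, symmetric = TRUE)
  v1 <- eig$vectors[, 1]
  slope <- if (abs(v1[1]) < 1e-300) Inf else v1[2] / v1[1]
  list(slope = slope,
       variance_explained = eig$values[1] / sum(eig$values))
}

#' @export
print.compare_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV: %d pooled (observed, inferred) pairs\n",
              x$fold_count, nrow(x$pooled_pairs)))
  cat(sprintf("  TLS slope %.4f, variance explained %.4f",
              x$tls_slope, x$variance_explained))
  cat(" (perpendicular-SS formalization)\n")
  if (length(x$skipped_columns)) {
    cat("  skipped columns:", paste(x$skipped_columns, collapse = ", "), "\n")
  }
  invisible(x)
}
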