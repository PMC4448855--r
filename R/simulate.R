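#' Canonical 12-region worked example of Yule-Simpson bias
#'
#' A deterministic junction pair in which every region has identical
#' methylation tendency on both sides of the boundary (8 fully methylated
#' regions, 4 fully unmethylated ones over 4 columns per side), yet the
#' metaplot statistic steps across the boundary: on the left side each
#' methylated region carries a single CpG (two per column), while
#' unmethylated regions are fully observed; the right side is fully
#' observed. The resulting statistics are `C = 1/3, R = 2/3, M = 1/3` on
#' the left and `C = R = M = 2/3` on the right: a pure missingness artifact,
#' since regional tendencies are equal throughout.
#'
#' @return A `junction_pair` with 12 coupled rows and 4 columns per side.
#' @export
fig1_pair <- function() {
  left <- matrix(NA_real_, 12L, 4L)
  # methylated regions: one observed CpG each, two regions per column
  for (i in 1:8) left[i, ((i - 1L) %% 4L) + 1L] <- 1
  left[9:12, ] <- 0
  right <- matrix(0, 12L, 4L)
  right[1:8, ] <- 1
  junction_pair(agg_matrix(left, "toward_boundary"),
                agg_matrix(right, "away_from_boundary"))
}

#' Equal-methylation-tendency null for a junction pair
#'
#' Named generator for the null used throughout: values are shuffled within
#' each coupled row while the missingness mask stays fixed, so both sides
#' of every boundary share one methylation tendency by construction (see
#' [shuffle_pair()], to which this delegates). With `joint = TRUE` the
#' mask is shuffled along with the values (each row's cells, observed and
#' missing alike, are permuted), simulating equal selective pressure as
#' well as equal methylation.
#'
#' @param pair A `junction_pair`.
#' @param seed Integer seed.
#' @param joint Shuffle mask and values jointly (default `FALSE`).
#' @return A `junction_pair`.
#' @export
equal_tendency_null <- function(pair, seed = NULL, joint = FALSE) {
  if (!joint) return(shuffle_pair(pair, seed = seed))
  stopifnot(inherits(pair, "junction_pair"))
  if (!is.null(seed)) set.seed(seed)
  ml <- ncol(pair$left$values)
  joined <- cbind(pair$left$values, pair$right$values)
  for (i in seq_len(nrow(joined))) {
    joined[i, ] <- joined[i, sample(ncol(joined))]
  }
  junction_pair(agg_matrix(joined[, seq_len(ml), drop = FALSE], pair$left$orientation),
                agg_matrix(joined[, -seq_len(ml), drop = FALSE], pair$right$orientation),
                row_labels = pair$row_labels)
}

#' Differential-methylation simulation on an existing mask
#'
#' Reproduces a known-truth differential dataset from a real (or simulated)
#' junction pair while keeping its CpG-site structure: each coupled row is
#' binarized by its joined mean (mean >= `threshold` makes all its observed
#' cells 1, otherwise 0), then a fraction `diff_fraction` of the methylated
#' rows is selected uniformly at random to be differentially methylated and
#' their left-side observed cells are set to 0. Optionally, the three
#' boundary-adjacent columns of each side are substituted by the adjacent
#' three columns (a workaround for sparse data next to splice junctions).
#'
#' @param pair A `junction_pair` in which every coupled row has at least
#'   one observed value.
#' @param diff_fraction Fraction of methylated rows made differential
#'   (default 0.05; at least one row is selected whenever positive).
#' @param threshold Binarization threshold on the joined row mean
#'   (default 0.5, with ties going to methylated).
#' @param boundary_column_substitution Replace each side's three
#'   boundary-adjacent columns by their neighbours (default `FALSE`).
#' @param seed Integer seed.
#' @return A `junction_pair` with attribute `labels`: per-row ground truth
#'   in `{unmethylated, methylated, differential}`.
#' @export
differential_simulation <- function(pair, diff_fraction = 0.05, threshold = 0.5,
                                    boundary_column_substitution = FALSE,
                                    seed = NULL) {
  stopifnot(inherits(pair, "junction_pair"))
  if (!is.null(seed)) set.seed(seed)
  lv <- pair$left$values
  rv <- pair$right$values
  joined <- cbind(lv, rv)
  rmean <- rowMeans(joined, na.rm = TRUE)
  if (any(is.nan(rmean))) stop("every coupled row needs at least one observed value")
  meth <- rmean >= threshold
  if (!any(meth)) stop("zero methylated rows: nothing can be made differential")
  lv[!is.na(lv)] <- 0
  rv[!is.na(rv)] <- 0
  lv[meth, ][!is.na(lv[meth, , drop = FALSE])] <- 1
  rv[meth, ][!is.na(rv[meth, , drop = FALSE])] <- 1
  n_diff <- if (diff_fraction > 0) max(1L, round(sum(meth) * diff_fraction)) else 0L
  labels <- ifelse(meth, "methylated", "unmethylated")
  if (n_diff > 0L) {
    diff_rows <- sample(which(meth), n_diff)
    lv[diff_rows, ][!is.na(lv[diff_rows, , drop = FALSE])] <- 0
    labels[diff_rows] <- "differential"
  }
  if (boundary_column_substitution) {
    if (ncol(lv) < 6L || ncol(rv) < 6L) {
      stop("boundary column substitution needs at least 6 columns per side")
    }
    lv[, 1:3] <- lv[, 4:6]
    rv[, 1:3] <- rv[, 4:6]
  }
  out <- junction_pair(agg_matrix(lv, pair$left$orientation),
                       agg_matrix(rv, pair$right$orientation),
                       row_labels = pair$row_labels)
  attr(out, "labels") <- labels
  out
}

#' Parameters of the deamination-coupled generator
#'
#' Bundles the knobs of [deamination_pair()]: region and column counts, the
#' fraction of constitutively methylated regions, the per-cell CpG
#' observation probabilities by methylation class and boundary side (the
#' deamination mechanism: methylated regions under weak selection lose CpG
#' sites, so their observation density is lower), measurement jitter and a
#' true cross-boundary tendency step.
#'
#' @param n Number of regions (default 500).
#' @param m Columns per side (default 20).
#' @param p_methylated Fraction of methylated regions (default 0.64, the
#'   share under which selecting 5 percent of methylated regions makes
#'   3.2 percent of all regions differential).
#' @param cg_density_meth_left,cg_density_unmeth_left,cg_density_meth_right,cg_density_unmeth_right
#'   Per-site observation probabilities (defaults 0.8 everywhere; lower
#'   `cg_density_meth_left` to induce deamination coupling).
#' @param noise_sd SD of the truncated Gaussian jitter on observed rates
#'   (default 0.05).
#' @param true_step Signed tendency shift added on the right side
#'   (default 0).
#' @return A list of class `deamination_params`.
#' @export
deamination_params <- function(n = 500L, m = 20L, p_methylated = 0.64,
                               cg_density_meth_left = 0.8,
                               cg_density_unmeth_left = 0.8,
                               cg_density_meth_right = 0.8,
                               cg_density_unmeth_right = 0.8,
                               noise_sd = 0.05, true_step = 0) {
  stopifnot(n >= 1, m >= 1,
            p_methylated >= 0, p_methylated <= 1,
            cg_density_meth_left >= 0, cg_density_meth_left <= 1,
            cg_density_unmeth_left >= 0, cg_density_unmeth_left <= 1,
            cg_density_meth_right >= 0, cg_density_meth_right <= 1,
            cg_density_unmeth_right >= 0, cg_density_unmeth_right <= 1,
            noise_sd >= 0)
  structure(list(n = as.integer(n), m = as.integer(m), p_methylated = p_methylated,
                 cg_density_meth_left = cg_density_meth_left,
                 cg_density_unmeth_left = cg_density_unmeth_left,
                 cg_density_meth_right = cg_density_meth_right,
                 cg_density_unmeth_right = cg_density_unmeth_right,
                 noise_sd = noise_sd, true_step = true_step),
            class = "deamination_params")
}

#' Deamination-coupled junction pair with known ground truth
#'
#' Generates a junction pair in which missingness may be coupled to
#' methylation, the mechanism by which deamination biases metaplot
#' comparisons. Each region is methylated with probability `p_methylated`
#' (true tendency 1, else 0; the right-side tendency is shifted by
#' `true_step` and clipped to `[0, 1]`); each cell is observed with the
#' class- and side-specific density; observed values are the true tendency
#' plus truncated Gaussian jitter.
#'
#' @param params A `deamination_params` object (or the default).
#' @param seed Integer seed.
#' @return A `junction_pair` with attributes `methylated` (logical per
#'   row), `truth_left` and `truth_right` (per-cell true tendencies).
#' @export
deamination_pair <- function(params = deamination_params(), seed = 1L) {
  stopifnot(inherits(params, "deamination_params"))
  set.seed(seed)
  n <- params$n; m <- params$m
  meth <- stats::runif(n) < params$p_methylated
  t_left <- ifelse(meth, 1, 0)
  t_right <- pmin(pmax(t_left + params$true_step, 0), 1)
  dens_left <- ifelse(meth, params$cg_density_meth_left, params$cg_density_unmeth_left)
  dens_right <- ifelse(meth, params$cg_density_meth_right, params$cg_density_unmeth_right)
  draw_side <- function(tend, dens) {
    obs <- matrix(stats::runif(n * m), n, m) < dens
    vals <- matrix(rep(tend, m), n, m)
    if (params$noise_sd > 0) {
      vals <- vals + matrix(stats::rnorm(n * m, 0, params$noise_sd), n, m)
      vals <- pmin(pmax(vals, 0), 1)
    }
    vals[!obs] <- NA_real_
    vals
  }
  lv <- draw_side(t_left, dens_left)
  rv <- draw_side(t_right, dens_right)
  if (all(is.na(lv)) || all(is.na(rv))) {
    stop("degenerate parameters: one side of the simulated pair is entirely missing")
  }
  out <- junction_pair(agg_matrix(lv, "toward_boundary"),
                       agg_matrix(rv, "away_from_boundary"))
  attr(out, "methylated") <- meth
  attr(out, "truth_left") <- matrix(rep(t_left, m), n, m)
  attr(out, "truth_right") <- matrix(rep(t_right, m), n, m)
  out
}
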