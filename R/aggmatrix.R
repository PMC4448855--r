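#' Aggregation matrix of per-site methylation rates
#'
#' An aggregation matrix holds one genomic region per row and one relative
#' position (distance from a functional boundary) per column. Cell `(i, j)`
#' is the methylation rate observed at distance `j - 1` from boundary `i`;
#' positions without a CpG site carry `NA` ("missing data"). Column 1 is
#' always the position adjacent to the boundary after strand normalisation.
#'
#' @param values Numeric matrix with entries in `[0, 1]` or `NA` for
#'   positions that cannot carry signal (no CpG site).
#' @param orientation Either `"toward_boundary"` (column index increases
#'   toward the boundary when plotted genomically, i.e. the upstream side)
#'   or `"away_from_boundary"` (the downstream side). Purely descriptive:
#'   column 1 is the boundary-adjacent position in both cases.
#' @return An object of class `agg_matrix`.
#' @export
agg_matrix <- function(values, orientation = c("away_from_boundary", "toward_boundary")) {
  orientation <- match.arg(orientation)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("aggregation matrix values must be numeric")
  if (nrow(values) < 1L || ncol(values) < 1L) stop("aggregation matrix needs n >= 1 and m >= 1")
  obs <- values[!is.na(values)]
  if (length(obs) && (min(obs) < -1e-12 || max(obs) > 1 + 1e-12)) {
    stop("observed aggregation matrix values must lie in [0, 1]")
  }
  structure(list(values = unname(values), orientation = orientation),
            class = "agg_matrix")
}

#' @export
dim.agg_matrix <- function(x) dim(x$values)

#' @export
print.agg_matrix <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("agg_matrix: %d regions x %d positions (%s), %.1f%% observed\n",
              d[1], d[2], x$orientation, 100 * mean(!is.na(x$values))))
  invisible(x)
}

#' Observation mask of an aggregation matrix
#'
#' @param x An `agg_matrix`.
#' @return Logical matrix, `TRUE` where a methylation value is observed.
#' @export
obs_mask <- function(x) {
  stopifnot(inherits(x, "agg_matrix"))
  !is.na(x$values)
}

#' Row-coupled pair of aggregation matrices flanking one boundary type
#'
#' Row `i` of `left` and row `i` of `right` derive from the same boundary
#' instance (e.g. the intron and exon side of one intron-exon junction).
#'
#' @param left,right `agg_matrix` objects with equal row counts.
#' @param row_labels Optional character vector of shared region identifiers.
#' @return An object of class `junction_pair`.
#' @export
junction_pair <- function(left, right, row_labels = NULL) {
  stopifnot(inherits(left, "agg_matrix"), inherits(right, "agg_matrix"))
  if (nrow(left$values) != nrow(right$values)) {
    stop("left and right matrices must have the same number of rows")
  }
  if (is.null(row_labels)) {
    row_labels <- paste0("region_", seq_len(nrow(left$values)))
  }
  if (length(row_labels) != nrow(left$values)) stop("row_labels length mismatch")
  structure(list(left = left, right = right, row_labels = as.character(row_labels)),
            class = "junction_pair")
}

#' @export
print.junction_pair <- function(x, ...) {
  cat(sprintf("junction_pair: %d coupled regions; left %d cols, right %d cols\n",
              nrow(x$left$values), ncol(x$left$values), ncol(x$right$values)))
  invisible(x)
}

#' Averaging statistics of an aggregation matrix
#'
#' Computes the three averaging statistics whose divergence signals
#' missingness structure: `C`, the mean of per-column averages (the
#' metaplot "%mCG" value); `R`, the mean of per-row (regional) averages;
#' and `M`, the mean over all observed cells. Also returns `r`, the Pearson
#' correlation between each row's observed-site count and its mean, a
#' diagnostic for deamination coupling (methylated regions carrying fewer
#' CpGs give r < 0).
#'
#' Rows (columns) with no observed cell have no mean and are excluded from
#' `R` (`C`) and from `r`; on a fully observed matrix `C == R == M` exactly.
#'
#' @param x An `agg_matrix`.
#' @return A list of class `agg_summary` with fields `C`, `R`, `M`, `r`,
#'   `n_rows_used`, `n_cols_used`, `n_obs`.
#' @export
summary_stats <- function(x) {
  stopifnot(inherits(x, "agg_matrix"))
  v <- x$values
  obs <- !is.na(v)
  n_obs <- sum(obs)
  if (n_obs == 0L) stop("no observed data: all cells of the aggregation matrix are missing")
  row_n <- rowSums(obs)
  col_n <- colSums(obs)
  row_mean <- rowSums(v, na.rm = TRUE)[row_n > 0] / row_n[row_n > 0]
  col_mean <- colSums(v, na.rm = TRUE)[col_n > 0] / col_n[col_n > 0]
  counts <- row_n[row_n > 0]
  r <- if (length(counts) >= 2L && stats::sd(counts) > 0 && stats::sd(row_mean) > 0) {
    stats::cor(counts, row_mean)
  } else {
    NA_real_
  }
  structure(list(C = mean(col_mean), R = mean(row_mean),
                 M = sum(v[obs]) / n_obs, r = r,
                 n_rows_used = length(row_mean), n_cols_used = length(col_mean),
                 n_obs = n_obs),
            class = "agg_summary")
}

#' @export
print.agg_summary <- function(x, ...) {
  cat(sprintf("C = %.4f  R = %.4f  M = %.4f  r(count, mean) = %s\n",
              x$C, x$R, x$M,
              if (is.na(x$r)) "NA" else sprintf("%.3f", x$r)))
  cat(sprintf("  (%d rows, %d columns with data; %d observed cells)\n",
              x$n_rows_used, x$n_cols_used, x$n_obs))
  invisible(x)
}

#' Per-column methylation profile
#'
#' The standard metaplot profile: the average observed methylation rate at
#' each distance from the boundary, with the number of observations backing
#' it. Columns with fewer than `min_obs` observations are reported as `NA`
#' (undefined), mirroring the minimum-observation gate used for inference.
#' Columns may optionally be pooled into fixed-width bins before averaging.
#'
#' @param x An `agg_matrix`.
#' @param min_obs Minimum observed values a column (or bin) needs for its
#'   average to be defined. Default 1.
#' @param bin Bin width in columns; 1 (default) keeps site-specific
#'   resolution.
#' @return A data frame with `column` (or bin start), `average`, `count`.
#' @export
column_profile <- function(x, min_obs = 1L, bin = 1L) {
  stopifnot(inherits(x, "agg_matrix"), min_obs >= 0, bin >= 1)
  v <- x$values
  if (bin > 1L) {
    grp <- (seq_len(ncol(v)) - 1L) %/% as.integer(bin)
    starts <- tapply(seq_len(ncol(v)), grp, min)
    sums <- sapply(split(seq_len(ncol(v)), grp), function(j) sum(v[, j, drop = FALSE], na.rm = TRUE))
    cnts <- sapply(split(seq_len(ncol(v)), grp), function(j) sum(!is.na(v[, j, drop = FALSE])))
    avg <- ifelse(cnts >= min_obs & cnts > 0, sums / cnts, NA_real_)
    return(data.frame(column = as.integer(starts), average = as.numeric(avg),
                      count = as.integer(cnts), row.names = NULL))
  }
  cnts <- colSums(!is.na(v))
  sums <- colSums(v, na.rm = TRUE)
  avg <- ifelse(cnts >= min_obs & cnts > 0, sums / cnts, NA_real_)
  data.frame(column = seq_len(ncol(v)), average = as.numeric(avg),
             count = as.integer(cnts), row.names = NULL)
}

#' Build a junction matrix pair from methylation calls and boundaries
#'
#' Places each call at its distance from each boundary: the right matrix
#' holds positions `boundary_pos .. boundary_pos + downstream_span - 1`
#' (column 1 adjacent to the boundary) and the left matrix positions
#' `boundary_pos - 1 .. boundary_pos - upstream_span` (column 1 adjacent).
#' Minus-strand boundaries are orientation-flipped so that column index
#' always measures distance from the boundary in the 5'->3' sense of the
#' region: their genomic downstream becomes the left matrix.
#'
#' @param calls Data frame of methylation calls as returned by
#'   [read_calls()]: columns `chrom`, `pos`, `strand`, `rate`, `coverage`.
#'   Call strand is ignored here (collapse dyads first if desired).
#' @param boundaries Data frame of boundary instances as returned by
#'   [read_boundaries()].
#' @param upstream_span,downstream_span Number of columns (bp at site
#'   resolution) on each side; defaults taken from the boundary table.
#' @return A `junction_pair`. Rows with no call on either side are kept
#'   (all-missing rows are legitimate and counted by downstream steps);
#'   an attribute `n_empty_rows` reports how many had no data at all.
#' @export
build_matrix_pair <- function(calls, boundaries,
                              upstream_span = NULL, downstream_span = NULL) {
  up <- if (is.null(upstream_span)) boundaries$upstream_span[1] else upstream_span
  dn <- if (is.null(downstream_span)) boundaries$downstream_span[1] else downstream_span
  stopifnot(up >= 1, dn >= 1)
  nb <- nrow(boundaries)
  left <- matrix(NA_real_, nb, up)
  right <- matrix(NA_real_, nb, dn)
  by_chrom <- split(calls[c("pos", "rate")], calls$chrom)
  for (i in seq_len(nb)) {
    b <- boundaries$boundary_pos[i]
    cc <- by_chrom[[as.character(boundaries$chrom[i])]]
    if (is.null(cc)) next
    minus <- identical(boundaries$strand[i], "-")
    if (!minus) {
      # plus strand: upstream = genomic left of b, downstream = genomic right
      sel <- cc$pos >= b & cc$pos <= b + dn - 1
      right[i, cc$pos[sel] - b + 1L] <- cc$rate[sel]
      sel <- cc$pos <= b - 1 & cc$pos >= b - up
      left[i, b - cc$pos[sel]] <- cc$rate[sel]
    } else {
      # minus strand: transcription runs right-to-left; flip sides
      sel <- cc$pos <= b - 1 & cc$pos >= b - dn
      right[i, b - cc$pos[sel]] <- cc$rate[sel]
      sel <- cc$pos >= b & cc$pos <= b + up - 1
      left[i, cc$pos[sel] - b + 1L] <- cc$rate[sel]
    }
  }
  pair <- junction_pair(agg_matrix(left, "toward_boundary"),
                        agg_matrix(right, "away_from_boundary"),
                        row_labels = boundaries$label)
  attr(pair, "n_empty_rows") <- sum(rowSums(!is.na(left)) + rowSums(!is.na(right)) == 0)
  pair
}
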