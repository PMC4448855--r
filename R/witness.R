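#' Construct an aggregation matrix with prescribed C, R and M
#'
#' For any rational targets `0 < r, c, m < 1` there exists an aggregation
#' matrix whose row-average mean equals `r`, column-average mean equals `c`
#' and grand observed mean equals `m`; the three statistics are mutually
#' unconstrained once missing data is allowed. This function realises such
#' a witness explicitly, which is useful for building worked examples and
#' for property-testing the averaging statistics.
#'
#' Two parametric families are searched, each solved in closed form for its
#' cell values once integer shape parameters are fixed, so the achieved
#' statistics are exact up to floating-point rounding (far below `tol`):
#'
#' * *singles + mixed row*: `k` rows carrying a single cell in column 1
#'   plus one fully observed row. Covers targets with `m` between `r` and
#'   `c` (the balancing cell argument needs the row- and column-side
#'   discrepancies to have opposite signs).
#' * *diagonal + stack + block*: a diagonal of single cells (lifting row
#'   and column means together), a one-column stack (breaking the row /
#'   column symmetry) and a dense constant block (dominating the cell
#'   count, hence `M`). Covers `m` outside `[min(r, c), max(r, c)]`.
#'
#' Transpose (swapping `r` and `c`) and value-complement (mapping targets
#' to `1 - r, 1 - c, 1 - m`) symmetries reduce every regime to one of the
#' above.
#'
#' @param r,c,m Target mean of row averages, mean of column averages and
#'   grand mean. Each is a single numeric in (0, 1) or a length-2 vector
#'   `c(numerator, denominator)`.
#' @param tol Acceptance tolerance on each statistic (default 1e-9).
#' @param max_dim Cap on the witness's row and column counts; extreme
#'   targets (e.g. `r`, `c` near 1 with `m` near 0) need large witnesses
#'   and fail with an error suggesting a larger cap if it is exceeded.
#' @return An `agg_matrix` whose [summary_stats()] match the targets.
#' @export
witness_matrix <- function(r, c, m, tol = 1e-9, max_dim = 10000L) {
  r <- .as_fraction(r, "r"); c <- .as_fraction(c, "c"); m <- .as_fraction(m, "m")
  check <- function(v) {
    s <- summary_stats(v)
    if (abs(s$R - r) <= tol && abs(s$C - c) <= tol && abs(s$M - m) <= tol) v else NULL
  }
  # degenerate target: a complete constant matrix
  if (abs(r - c) < 1e-13 && abs(r - m) < 1e-13) {
    return(agg_matrix(matrix(m, 2L, 2L)))
  }
  # mixed regime: m between r and c
  for (transpose in c(FALSE, TRUE)) {
    t3 <- if (transpose) c(c, r, m) else c(r, c, m)
    w <- .witness_singles_row(t3[1], t3[2], t3[3], max_dim)
    if (!is.null(w)) {
      if (transpose) w <- agg_matrix(t(w$values))
      out <- check(w)
      if (!is.null(out)) return(out)
    }
  }
  # outside regime: diagonal + stack + block, under all symmetry frames
  for (complement in c(FALSE, TRUE)) {
    for (transpose in c(FALSE, TRUE)) {
      t3 <- c(r, c, m)
      if (complement) t3 <- 1 - t3
      if (transpose) t3 <- t3[c(2, 1, 3)]
      w <- .witness_diag_block(t3[1], t3[2], t3[3], max_dim)
      if (!is.null(w)) {
        v <- w$values
        if (transpose) v <- t(v)
        if (complement) v <- 1 - v
        out <- check(agg_matrix(v))
        if (!is.null(out)) return(out)
      }
    }
  }
  stop(sprintf(paste("no witness found for (r, c, m) = (%.6g, %.6g, %.6g)",
                     "within the %d x %d size cap; retry with a larger max_dim"),
               r, c, m, max_dim, max_dim))
}

.as_fraction <- function(x, name) {
  if (length(x) == 2L) x <- x[1] / x[2]
  if (length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1) {
    stop(sprintf("target %s must be a single value (or num/den pair) strictly inside (0, 1)", name))
  }
  as.numeric(x)
}

# Family: k single-cell rows (value x, column 1) + one complete row
# (y, z, ..., z) over mc columns. Closed form for (x, y, z) given (k, mc);
# the single balancing cell y has an O(1) feasibility window in k, so for
# each mc the window is root-found and nearby integers are tested.
.witness_singles_row <- function(r, c, m, max_dim) {
  solve_kmc <- function(k, mc) {
    S <- m * (k + mc)
    A <- (r * mc * (k + 1) - S) / (mc - 1)
    D <- ((k + 1) * c * mc - S) / k
    B <- S - A - D
    list(x = A / k, y = B, z = D / (mc - 1), k = k, mc = mc)
  }
  feasible <- function(s) {
    all(is.finite(c(s$x, s$y, s$z))) &&
      s$x >= 0 && s$x <= 1 && s$y >= 0 && s$y <= 1 && s$z >= 0 && s$z <= 1
  }
  build <- function(s) {
    v <- matrix(NA_real_, s$k + 1L, s$mc)
    v[seq_len(s$k), 1L] <- s$x
    v[s$k + 1L, ] <- c(s$y, rep(s$z, s$mc - 1L))
    agg_matrix(v)
  }
  kcap <- max_dim - 1L
  mcs <- unique(c(2:64, round(exp(seq(log(65), log(max_dim), length.out = 40)))))
  mcs <- mcs[mcs <= max_dim]
  for (mc in mcs) {
    g <- function(k) solve_kmc(k, mc)$y - 0.5
    lo <- g(1); hi <- g(kcap)
    ks <- integer(0)
    if (is.finite(lo) && is.finite(hi) && lo * hi <= 0) {
      k0 <- tryCatch(stats::uniroot(g, c(1, kcap), tol = 0.25)$root,
                     error = function(e) NA_real_)
      if (is.finite(k0)) ks <- unique(pmax(1L, pmin(kcap, floor(k0) + (-2:3))))
    } else {
      ks <- unique(pmin(kcap, c(1:8)))  # small-k corner cases
    }
    for (k in ks) {
      s <- solve_kmc(k, mc)
      if (feasible(s)) return(build(s))
    }
  }
  NULL
}

# Family: diagonal of d single cells (value h) + stack of d_r cells in one
# column (value a) + dense t x kap block (value l). Linear solve for
# (h, a, l) given integer shapes; shapes come from a first-order sizing
# heuristic plus a coarse log-grid fallback.
.witness_diag_block <- function(r, c, m, max_dim) {
  try_shape <- function(d, d_r, t, kap) {
    if (d < 1 || d_r < 2 || t < 1 || kap < 2) return(NULL)
    n <- d + d_r + t
    mm <- d + 1 + kap
    if (n > max_dim || mm > max_dim) return(NULL)
    K <- d + d_r + t * kap
    l <- (m * K - r * n) / (t * (kap - 1))
    E <- r * n - t * l          # = d h + d_r a
    FF <- c * mm - kap * l      # = d h + a
    a <- (E - FF) / (d_r - 1)
    h <- (FF - a) / d
    if (!all(is.finite(c(h, a, l)))) return(NULL)
    if (h < 0 || h > 1 || a < 0 || a > 1 || l < 0 || l > 1) return(NULL)
    v <- matrix(NA_real_, n, mm)
    v[cbind(seq_len(d), seq_len(d))] <- h
    v[d + seq_len(d_r), d + 1L] <- a
    v[d + d_r + seq_len(t), d + 1L + seq_len(kap)] <- l
    agg_matrix(v)
  }
  shapes <- list()
  push <- function(d, d_r, t, kap) shapes[[length(shapes) + 1L]] <<- c(d, d_r, t, kap)

  # first-order sizing for the frame m < c <= r (harmless to try elsewhere)
  if (m < 1 && m > 0 && r < 1 && c < 1) {
    kap0 <- r * (1 - m) / (m * (1 - r))
    d0 <- kap0 * c / (1 - c)
    for (sk in c(1, 1.04, 1.1, 1.25, 1.5, 2)) {
      for (sd in c(1, 1.05, 1.15, 1.35, 1.7)) {
        kap <- max(2L, ceiling(kap0 * sk) + 1L)
        d <- max(1L, ceiling(d0 * sd) + 2L)
        H0 <- d * 1.08 + 4
        for (st in c(1, 1.08, 1.2, 1.45)) {
          t <- max(1L, ceiling(H0 * (1 - r) / r * st) + 1L)
          for (d_r in unique(c(2L, 4L, max(2L, round(0.04 * d)), max(2L, round(0.12 * d))))) {
            push(d, d_r, t, kap)
          }
        }
      }
    }
  }
  # coarse log-grid fallback
  gg <- function(top, np) unique(pmax(1, round(exp(seq(0, log(top), length.out = np)))))
  for (d in gg(max_dim / 2, 14)) {
    for (d_r in c(2L, 6L, 24L, 96L)) {
      for (t in gg(max_dim / 4, 10)) {
        for (kap in gg(max_dim / 2, 10)) push(d, d_r, t, kap)
      }
    }
  }
  # prefer small witnesses
  sizes <- vapply(shapes, function(s) (s[1] + s[2] + s[3]) + (s[1] + 1 + s[4]), 0)
  for (i in order(sizes)) {
    s <- shapes[[i]]
    w <- try_shape(s[1], s[2], s[3], s[4])
    if (!is.null(w)) return(w)
  }
  NULL
}
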