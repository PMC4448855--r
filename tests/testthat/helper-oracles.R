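# Brute-force oracles and fixture generators shared across tests.

# Direct loop computation of C, R, M and the count-mean correlation,
# independent of the vectorised implementation.
brute_stats <- function(values) {
  row_means <- c()
  row_counts <- c()
  for (i in seq_len(nrow(values))) {
    obs <- values[i, !is.na(values[i, ])]
    if (length(obs)) {
      row_means <- c(row_means, mean(obs))
      row_counts <- c(row_counts, length(obs))
    }
  }
  col_means <- c()
  for (j in seq_len(ncol(values))) {
    obs <- values[!is.na(values[, j]), j]
    if (length(obs)) col_means <- c(col_means, mean(obs))
  }
  list(C = mean(col_means), R = mean(row_means),
       M = mean(values[!is.na(values)]),
       r = if (length(row_counts) >= 2 && sd(row_counts) > 0 && sd(row_means) > 0) {
         cor(row_counts, row_means)
       } else NA_real_)
}

# Naive per-cell loop over the leave-one-out feature definitions.
brute_features <- function(values, block = NULL) {
  n <- nrow(values); m <- ncol(values)
  B <- X <- Y <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cols <- if (is.null(block)) {
        seq_len(m)
      } else {
        max(1, j - floor((block - 1) / 2)):min(m, j + ceiling((block - 1) / 2))
      }
      rest <- setdiff(cols, j)
      vals <- values[i, rest]
      obs <- vals[!is.na(vals)]
      B[i, j] <- as.numeric(length(obs) == 0)
      X[i, j] <- if (length(obs)) mean(obs) else 0
      Y[i, j] <- if (length(rest)) sum(is.na(vals)) / length(rest) else 1
    }
  }
  list(B = B, X = X, Y = Y)
}

# Random aggregation matrix with iid uniform values and Bernoulli mask;
# guarantees at least one observed cell.
random_masked_matrix <- function(n, m, miss_prob = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- matrix(runif(n * m), n, m)
  v[matrix(runif(n * m), n, m) < miss_prob] <- NA
  if (all(is.na(v))) v[1, 1] <- runif(1)
  agg_matrix(v)
}

random_pair <- function(n, m, miss_prob = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  junction_pair(random_masked_matrix(n, m, miss_prob),
                random_masked_matrix(n, m, miss_prob))
}

# Write a call file with given columns; returns the path.
write_call_file <- function(chrom, pos, strand, rate, coverage,
                            path = tempfile(fileext = ".tsv")) {
  writeLines(paste(chrom, pos, strand, rate, coverage, sep = "\t"), path)
  path
}
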