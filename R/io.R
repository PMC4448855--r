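#' Read per-CpG methylation calls
#'
#' Reads a tab-delimited bedGraph-like call file with five columns:
#' chromosome, 0-based position, strand (`+`/`-`), methylation rate in
#' `[0, 1]` and read coverage. Records with coverage below `min_coverage`
#' are dropped (bisulfite rates from fewer than three reads are commonly
#' considered unreliable, hence the default).
#'
#' @param path Path to the call file. No header.
#' @param min_coverage Minimum read coverage for a call to be retained.
#' @return A data frame with columns `chrom`, `pos`, `strand`, `rate`,
#'   `coverage`, in file order within chromosome.
#' @export
read_calls <- function(path, min_coverage = 3L) {
  if (!file.exists(path)) stop("call file not found: ", path)
  stopifnot(min_coverage >= 0)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 5L)) {
    stop(sprintf("malformed call record at line %d: expected 5 tab-delimited fields, got %d",
                 which(nf != 5L)[1], nf[nf != 5L][1]))
  }
  m <- matrix(unlist(parts), ncol = 5L, byrow = TRUE)
  pos <- suppressWarnings(as.numeric(m[, 2]))
  rate <- suppressWarnings(as.numeric(m[, 4]))
  cov <- suppressWarnings(as.numeric(m[, 5]))
  bad <- which(is.na(pos) | is.na(rate) | is.na(cov) | !(m[, 3] %in% c("+", "-")))
  if (length(bad)) stop(sprintf("malformed call record at line %d", bad[1]))
  oob <- which(rate < 0 | rate > 1)
  if (length(oob)) {
    stop(sprintf("methylation rate outside [0, 1] at line %d: %g", oob[1], rate[oob[1]]))
  }
  if (any(pos < 0)) stop(sprintf("negative position at line %d", which(pos < 0)[1]))
  if (any(cov < 0)) stop(sprintf("negative coverage at line %d", which(cov < 0)[1]))
  keep <- cov >= min_coverage
  data.frame(chrom = m[keep, 1], pos = pos[keep], strand = m[keep, 3],
             rate = rate[keep], coverage = cov[keep], row.names = NULL)
}

#' Write methylation calls
#'
#' Inverse of [read_calls()] (modulo the coverage filter).
#'
#' @param calls Data frame with columns `chrom`, `pos`, `strand`, `rate`,
#'   `coverage`.
#' @param path Output path.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls[c("chrom", "pos", "strand", "rate", "coverage")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Collapse opposite-strand CG dyad calls into single site records
#'
#' A CG dyad yields one cytosine call per strand (plus-strand at position
#' `p`, minus-strand at `p + 1`). When both are present they are merged
#' into one plus-strand record at `p` with coverage-weighted rate and
#' summed coverage, treating the dyad as a single methylatable unit.
#' Unpaired calls are kept as-is (minus-strand singletons are shifted to
#' the plus-strand dyad coordinate `p`).
#'
#' @param calls Data frame as returned by [read_calls()].
#' @return A data frame of collapsed site records, strand `+` throughout.
#' @export
collapse_cg_dyads <- function(calls) {
  site_pos <- ifelse(calls$strand == "-", calls$pos - 1, calls$pos)
  key <- paste(calls$chrom, site_pos, sep = ":")
  wsum <- tapply(calls$rate * calls$coverage, key, sum)
  csum <- tapply(calls$coverage, key, sum)
  rsum <- tapply(calls$rate, key, mean)  # fallback when total coverage is 0
  first <- !duplicated(key)
  out <- data.frame(chrom = calls$chrom[first], pos = site_pos[first],
                    strand = "+", rate = NA_real_, coverage = NA_real_,
                    row.names = NULL)
  k <- key[first]
  out$rate <- ifelse(csum[k] > 0, wsum[k] / csum[k], rsum[k])
  out$coverage <- as.numeric(csum[k])
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Read boundary instances from a BED file
#'
#' Each BED interval yields one boundary instance anchored at the interval
#' start or end. Minus-strand instances are flagged so matrix construction
#' can orientation-flip them; for them the anchor is mirrored (`start`
#' anchors at the interval end), keeping the anchor's meaning in
#' transcription coordinates.
#'
#' @param path BED file with at least 6 columns (strand required).
#' @param upstream_span,downstream_span Side spans in bp.
#' @param anchor `"start"` or `"end"` of the interval in transcription
#'   orientation.
#' @return Data frame with columns `chrom`, `boundary_pos`, `strand`,
#'   `upstream_span`, `downstream_span`, `label`.
#' @export
read_boundaries <- function(path, upstream_span, downstream_span,
                            anchor = c("start", "end")) {
  anchor <- match.arg(anchor)
  if (!file.exists(path)) stop("BED file not found: ", path)
  stopifnot(upstream_span >= 1, downstream_span >= 1)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[ \t]+")
  nf <- lengths(parts)
  if (any(nf < 6L)) {
    stop(sprintf("malformed BED record at line %d: need 6 fields incl. strand, got %d",
                 which(nf < 6L)[1], nf[nf < 6L][1]))
  }
  m <- do.call(rbind, lapply(parts, function(p) p[1:6]))
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(start) | is.na(end) | !(m[, 6] %in% c("+", "-")))
  if (length(bad)) stop(sprintf("malformed BED record at line %d", bad[1]))
  minus <- m[, 6] == "-"
  pos <- if (anchor == "start") ifelse(minus, end, start) else ifelse(minus, start, end)
  data.frame(chrom = m[, 1], boundary_pos = pos, strand = m[, 6],
             upstream_span = upstream_span, downstream_span = downstream_span,
             label = m[, 4], row.names = NULL)
}

#' Filter boundary instances by flank-length and exclusion predicates
#'
#' @param boundaries Data frame from [read_boundaries()].
#' @param min_flank Minimum span that must fit on each side (e.g. both the
#'   intron and the exon at least 200 bp): instances whose declared spans
#'   are shorter are dropped.
#' @param exclude Optional data frame of half-open intervals (`chrom`,
#'   `start`, `end`); instances whose analysed window overlaps any interval
#'   are dropped.
#' @return The retained subset, with attribute `discarded` reporting the
#'   count removed by each predicate.
#' @export
filter_boundaries <- function(boundaries, min_flank = 0, exclude = NULL) {
  keep_len <- boundaries$upstream_span >= min_flank & boundaries$downstream_span >= min_flank
  keep_ex <- rep(TRUE, nrow(boundaries))
  if (!is.null(exclude) && nrow(exclude) > 0) {
    ws <- boundaries$boundary_pos - boundaries$upstream_span
    we <- boundaries$boundary_pos + boundaries$downstream_span
    for (i in seq_len(nrow(boundaries))) {
      ex <- exclude[exclude$chrom == boundaries$chrom[i], , drop = FALSE]
      if (nrow(ex) && any(ex$start < we[i] & ex$end > ws[i])) keep_ex[i] <- FALSE
    }
  }
  out <- boundaries[keep_len & keep_ex, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "discarded") <- c(flank_length = sum(!keep_len),
                              exclusion_overlap = sum(keep_len & !keep_ex))
  out
}

#' Write / read an aggregation matrix as TSV
#'
#' Plain tab-separated dialect: a first comment line recording the
#' orientation, a header of column indices, one row per region with the
#' region label in the first field, and the literal token `NA` for missing
#' cells. The round trip is lossless including the missingness mask.
#'
#' @param x An `agg_matrix`.
#' @param path Output path.
#' @param labels Optional row labels (defaults to `region_i`).
#' @export
write_matrix <- function(x, path, labels = NULL) {
  stopifnot(inherits(x, "agg_matrix"))
  v <- x$values
  if (is.null(labels)) labels <- paste0("region_", seq_len(nrow(v)))
  if (any(grepl("\t", labels))) stop("row labels must not contain tabs")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#orientation=", x$orientation), con)
  writeLines(paste(c("region", paste0("pos_", seq_len(ncol(v)))), collapse = "\t"), con)
  body <- apply(v, 1L, function(row) {
    paste(ifelse(is.na(row), "NA", formatC(row, digits = 17, format = "g")), collapse = "\t")
  })
  writeLines(paste(labels, body, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_matrix
#' @return `read_matrix` returns the `agg_matrix`; row labels are attached
#'   as attribute `labels`.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path)
  orientation <- "away_from_boundary"
  if (length(lines) && startsWith(lines[1], "#orientation=")) {
    orientation <- sub("^#orientation=", "", lines[1])
    lines <- lines[-1]
  }
  if (length(lines) < 2L) stop("matrix file has no data rows: ", path)
  lines <- lines[-1]  # header
  parts <- strsplit(lines, "\t", fixed = TRUE)
  labels <- vapply(parts, `[`, "", 1L)
  vals <- lapply(parts, function(p) suppressWarnings(as.numeric(p[-1])))
  ncols <- unique(lengths(vals))
  if (length(ncols) != 1L) stop("ragged matrix rows in ", path)
  v <- do.call(rbind, vals)
  out <- agg_matrix(v, orientation)
  attr(out, "labels") <- labels
  out
}

#' Write / read a junction pair as two matrix TSV files
#'
#' @param pair A `junction_pair`.
#' @param left_path,right_path Output paths.
#' @export
write_pair <- function(pair, left_path, right_path) {
  stopifnot(inherits(pair, "junction_pair"))
  write_matrix(pair$left, left_path, labels = pair$row_labels)
  write_matrix(pair$right, right_path, labels = pair$row_labels)
  invisible(c(left_path, right_path))
}

#' @rdname write_pair
#' @export
read_pair <- function(left_path, right_path) {
  l <- read_matrix(left_path)
  r <- read_matrix(right_path)
  labs <- attr(l, "labels")
  if (!identical(labs, attr(r, "labels"))) {
    stop("left and right matrices have different region labels; not a coupled pair")
  }
  junction_pair(l, r, row_labels = labs)
}
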