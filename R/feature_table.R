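#' Feature-table conventions
#'
#' reefnet represents an ASV feature table as a plain numeric matrix with
#' samples in rows and ASVs in columns, both with unique dimnames — the same
#' convention vegan uses for community matrices. `validate_feature_table()`
#' enforces it and is called by every consumer.
#'
#' @param counts sample x ASV matrix of non-negative integers.
#' @return the validated matrix, invisibly for `validate_feature_table()`.
#' @name feature_table
NULL

#' @rdname feature_table
#' @export
validate_feature_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("feature table must be a numeric matrix (samples x ASVs)")
  }
  if (nrow(counts) == 0 || ncol(counts) == 0) stop("feature table is empty")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("feature table needs sample and ASV dimnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate ASV ids")
  if (anyNA(counts) || any(counts < 0)) stop("feature table has negative or missing entries")
  invisible(counts)
}

#' Read or write a tab-separated feature table
#'
#' The on-disk format is a TSV whose first column holds row ids and whose
#' header names the remaining columns. `orientation` declares what the rows
#' are; the returned matrix is always canonical samples-as-rows.
#'
#' @param path file path.
#' @param orientation `"samples_rows"` (default) or `"asvs_rows"`.
#' @return `read_feature_table()`: a validated sample x ASV matrix.
#' @export
read_feature_table <- function(path, orientation = c("samples_rows", "asvs_rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("feature table needs an id column plus counts")
  if (anyDuplicated(names(df)[-1])) {
    stop("duplicate column ids in ", path)
  }
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate ids in first column of ", path)
  body <- df[, -1, drop = FALSE]
  if (!all(vapply(body, is.numeric, logical(1)))) {
    stop("non-numeric cell in feature table ", path)
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (orientation == "asvs_rows") m <- t(m)
  validate_feature_table(m)
  m
}

#' @rdname read_feature_table
#' @param counts sample x ASV matrix.
#' @export
write_feature_table <- function(counts, path) {
  validate_feature_table(counts)
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop globally rare ASVs
#'
#' Removes ASVs whose total count across all samples is less than `threshold`
#' of the table's grand total (default 0.005%, i.e. 5e-5 — the conventional
#' QIIME 2 abundance filter). The comparison is strict: an ASV sitting
#' exactly at the threshold is retained. The sample set is unchanged.
#'
#' @param counts sample x ASV matrix.
#' @param threshold minimum relative abundance as a fraction.
#' @return filtered matrix.
#' @export
filter_min_relative_abundance <- function(counts, threshold = 0.00005) {
  validate_feature_table(counts)
  total <- sum(counts)
  if (total == 0) stop("feature table grand total is zero")
  keep <- colSums(counts) / total >= threshold
  message(sprintf("abundance filter (%.4g): %d -> %d ASVs",
                  threshold, ncol(counts), sum(keep)))
  counts[, keep, drop = FALSE]
}

#' Keep ASVs observed in a minimum fraction of samples
#'
#' Prevalence filter for network construction: an ASV is retained when it has
#' a nonzero count in at least `min_fraction` of the samples (inclusive:
#' present in exactly 30% of samples passes the default).
#'
#' @param counts sample x ASV matrix.
#' @param min_fraction minimum fraction of samples, default 0.30.
#' @return filtered matrix.
#' @export
filter_prevalence <- function(counts, min_fraction = 0.30) {
  validate_feature_table(counts)
  prevalence <- colMeans(counts > 0)
  keep <- prevalence >= min_fraction
  message(sprintf("prevalence filter (>= %.0f%% of samples): %d -> %d ASVs",
                  100 * min_fraction, ncol(counts), sum(keep)))
  counts[, keep, drop = FALSE]
}

#' Rarefy (subsample) every sample to a common depth
#'
#' Each retained sample is subsampled without replacement to exactly `depth`
#' reads; samples whose total is below `depth` are dropped with a message.
#' Deterministic under `seed`.
#'
#' @param counts sample x ASV matrix.
#' @param depth target reads per sample; default: minimum sample total.
#' @param seed integer seed.
#' @return rarefied matrix (possibly fewer samples).
#' @export
rarefy <- function(counts, depth = NULL, seed = 1L) {
  validate_feature_table(counts)
  totals <- rowSums(counts)
  if (is.null(depth)) depth <- min(totals)
  depth <- as.integer(depth)
  if (depth <= 0) stop("rarefaction depth must be positive")
  drop <- totals < depth
  if (any(drop)) {
    message("rarefy: dropping ", sum(drop), " sample(s) below depth ", depth,
            ": ", paste(rownames(counts)[drop], collapse = ", "))
  }
  counts <- counts[!drop, , drop = FALSE]
  if (nrow(counts) == 0) stop("no samples at or above rarefaction depth")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  out <- counts
  for (i in seq_len(nrow(counts))) {
    reads <- rep.int(seq_len(ncol(counts)), counts[i, ])
    kept <- sample(reads, depth, replace = FALSE)
    out[i, ] <- tabulate(kept, nbins = ncol(counts))
  }
  out
}
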