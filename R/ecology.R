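#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum|x_i - y_i| / sum(x_i + y_i), computed between all sample
#' pairs of a feature table.
#'
#' @param counts sample x ASV matrix.
#' @return symmetric sample x sample matrix with zero diagonal, entries in
#'   `[0, 1]`.
#' @export
bray_curtis <- function(counts) {
  validate_feature_table(counts)
  if (nrow(counts) < 2) stop("need at least 2 samples")
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    stop("all-zero sample(s): ",
         paste(rownames(counts)[totals == 0], collapse = ", "))
  }
  num <- as.matrix(stats::dist(counts, method = "manhattan"))
  den <- outer(totals, totals, "+")
  d <- num / den
  diag(d) <- 0
  dimnames(d) <- list(rownames(counts), rownames(counts))
  d
}

.validate_distance_matrix <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) stop("distance matrix must be square")
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(diag(dm) != 0)) stop("distance matrix diagonal must be zero")
  if (any(dm < 0)) stop("distances must be non-negative")
  invisible(dm)
}

#' Principal coordinates analysis (classical MDS)
#'
#' Eigendecomposition of the double-centered matrix -D^2/2. Coordinates are
#' returned only for positive eigenvalues (sorted descending); negative
#' eigenvalues, which arise for semi-metric distances like Bray-Curtis, are
#' reported but not embedded.
#'
#' @param dm symmetric distance matrix.
#' @return list with `points` (samples x positive axes), `eigenvalues` (all,
#'   descending) and `negative_fraction` (sum of |negative| / sum of |all|).
#' @export
pcoa <- function(dm) {
  .validate_distance_matrix(dm)
  n <- nrow(dm)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (dm^2) %*% J
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  values <- eig$values
  pos <- which(values > max(values[1], 0) * 1e-12 & values > 0)
  points <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(values[pos]), length(pos))
  rownames(points) <- rownames(dm)
  colnames(points) <- paste0("PCo", seq_along(pos))
  list(points = points,
       eigenvalues = values,
       negative_fraction = sum(abs(values[values < 0])) / sum(abs(values)))
}

#' One-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: partitions the total sum
#' of squared distances by a single grouping factor and assesses the
#' pseudo-F statistic by permuting group labels.
#'
#' With n samples in k groups, `SS_total = sum_{i<j} d_ij^2 / n`,
#' `SS_within = sum_g (sum_{i<j in g} d_ij^2 / n_g)`,
#' `SS_between = SS_total - SS_within`,
#' `F = (SS_between / (k - 1)) / (SS_within / (n - k))`,
#' `R2 = SS_between / SS_total`, and
#' `p = (1 + #{F_perm >= F_obs}) / (n_perm + 1)` so the observed labeling
#' counts as one permutation.
#'
#' @param dm symmetric distance matrix.
#' @param labels group label per sample (recycled against `dm` rows).
#' @param n_perm number of label permutations, default 999.
#' @param seed integer seed for the permutation stream.
#' @return object of class `permanova_result`: list(F, R2, p, n_perm, seed,
#'   df_between, df_within).
#' @export
permanova <- function(dm, labels, n_perm = 999, seed = 1L) {
  .validate_distance_matrix(dm)
  n <- nrow(dm)
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels must match distance matrix rows")
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("degenerate grouping: need >= 2 groups with >= 2 samples each")
  }
  d2 <- dm^2
  k <- length(tab)

  ss_within_for <- function(lab) {
    ss <- 0
    for (g in names(tab)) {
      idx <- which(lab == g)
      ss <- ss + sum(d2[idx, idx]) / (2 * length(idx))
    }
    ss
  }
  ss_total <- sum(d2) / (2 * n)
  f_for <- function(lab) {
    ss_w <- ss_within_for(lab)
    ((ss_total - ss_w) / (k - 1)) / (ss_w / (n - k))
  }

  f_obs <- f_for(labels)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (f_for(sample(labels)) >= f_obs) exceed <- exceed + 1L
  }
  structure(list(
    F = f_obs,
    R2 = (ss_total - ss_within_for(labels)) / ss_total,
    p = (1 + exceed) / (n_perm + 1),
    n_perm = as.integer(n_perm),
    seed = as.integer(seed),
    df_between = k - 1L,
    df_within = n - k
  ), class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: F = %.3f, R2 = %.3f, P = %.4g (%d permutations)\n",
              x$F, x$R2, x$p, x$n_perm))
  invisible(x)
}

#' Pairwise PERMANOVA over all group pairs
#'
#' Runs [permanova()] on every pair of groups, mirroring pairwise community
#' comparisons reported without multiplicity correction.
#'
#' @inheritParams permanova
#' @return data.frame with columns pair, F, R2, p, n_perm, seed.
#' @export
pairwise_permanova <- function(dm, labels, n_perm = 999, seed = 1L) {
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  rows <- lapply(seq_along(pairs), function(i) {
    g <- pairs[[i]]
    idx <- which(labels %in% g)
    res <- permanova(dm[idx, idx, drop = FALSE], labels[idx],
                     n_perm = n_perm, seed = seed + i - 1L)
    data.frame(pair = paste(g, collapse = "_vs_"),
               F = res$F, R2 = res$R2, p = res$p,
               n_perm = res$n_perm, seed = res$seed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Percent change relative to a baseline
#'
#' `100 * (1 - value / baseline)`, rounded to the nearest integer percent for
#' reporting (positive = decrease).
#'
#' @param baseline positive reference value.
#' @param value observed value.
#' @return integer percent change.
#' @export
percent_change <- function(baseline, value) {
  if (!is.numeric(baseline) || baseline <= 0) stop("baseline must be positive")
  round(100 * (1 - value / baseline))
}
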