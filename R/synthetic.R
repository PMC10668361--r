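#' Specify a synthetic microbial community with planted network structure
#'
#' Builds the parameter object consumed by [sample_counts()]. The generator
#' draws grouped ASV count tables from a Gaussian copula with log-normal
#' marginals and multinomial read sampling, so that rank correlations between
#' taxa are controlled while counts remain compositional integers.
#'
#' The first `sum(module_sizes)` ASVs are partitioned into correlation
#' modules in order; remaining ASVs are independent "background" taxa.
#' Connector taxa gain additional latent correlation `rho_cross` to every
#' member of their designated foreign modules, planting the cross-module
#' links that the Zi-Pi role analysis should later flag as connectors.
#'
#' @param n_samples_per_group samples drawn per group.
#' @param group_names character vector of group labels.
#' @param n_asvs total number of ASVs.
#' @param module_sizes integer vector; sizes of planted correlation modules.
#'   Must sum to at most `n_asvs`.
#' @param rho_within latent correlation inside each module, in `[0, 1)`.
#' @param connectors named list mapping a connector ASV id (e.g. `"ASV_001"`)
#'   to the integer ids of its foreign modules. May be empty.
#' @param rho_cross latent correlation between a connector and members of its
#'   foreign modules, in `[0, 1)`.
#' @param effect_asvs ASV ids whose mean abundance is multiplied by
#'   `effect_size` in group `effect_group`.
#' @param effect_group group label receiving the abundance shift.
#' @param effect_size positive fold factor (1 = no effect).
#' @param base_logmean,base_logsd log-normal abundance parameters shared by
#'   all ASVs.
#' @param depth_mean expected library size; each sample's depth is
#'   Poisson(`depth_mean`).
#' @param seed integer seed making the draw reproducible.
#' @return An object of class `synthetic_spec`.
#' @seealso [build_latent_correlation()], [sample_counts()], [ground_truth()]
#' @export
synthetic_spec <- function(n_samples_per_group = 10,
                           group_names = c("LT", "LTB", "HT", "HTB"),
                           n_asvs = 300,
                           module_sizes = c(15, 12, 10),
                           rho_within = 0.85,
                           connectors = list(),
                           rho_cross = 0.75,
                           effect_asvs = character(),
                           effect_group = NULL,
                           effect_size = 1,
                           base_logmean = 0,
                           base_logsd = 1,
                           depth_mean = 10000,
                           seed = 1L) {
  stopifnot(n_samples_per_group >= 1, n_asvs >= 1, length(group_names) >= 1)
  if (anyDuplicated(group_names)) stop("duplicate group names")
  if (sum(module_sizes) > n_asvs) {
    stop("module sizes sum to more than n_asvs")
  }
  if (rho_within >= 1 || rho_within < 0 || rho_cross >= 1 || rho_cross < 0) {
    stop("invalid spec: latent correlations must lie in [0, 1)")
  }
  if (effect_size <= 0) stop("effect_size must be positive")
  if (depth_mean <= 0) stop("depth_mean must be positive")
  if (length(effect_asvs) && is.null(effect_group)) {
    stop("effect_asvs given without effect_group")
  }
  if (!is.null(effect_group) && !effect_group %in% group_names) {
    stop("effect_group not among group_names")
  }

  asv_ids <- sprintf("ASV_%03d", seq_len(n_asvs))
  module_of <- rep("none", n_asvs)
  names(module_of) <- asv_ids
  idx <- 1L
  for (m in seq_along(module_sizes)) {
    module_of[idx:(idx + module_sizes[m] - 1L)] <- as.character(m)
    idx <- idx + module_sizes[m]
  }
  if (length(connectors)) {
    bad <- setdiff(names(connectors), asv_ids)
    if (length(bad)) stop("unknown connector ASVs: ", paste(bad, collapse = ", "))
    for (a in names(connectors)) {
      fm <- connectors[[a]]
      if (!all(fm %in% seq_along(module_sizes))) {
        stop("connector ", a, " points to a nonexistent module")
      }
      if (any(as.character(fm) == module_of[[a]])) {
        stop("connector ", a, " lists its own module as foreign")
      }
    }
  }
  if (length(effect_asvs) && !all(effect_asvs %in% asv_ids)) {
    stop("unknown effect ASVs")
  }

  structure(list(
    n_samples_per_group = as.integer(n_samples_per_group),
    group_names = group_names,
    n_asvs = as.integer(n_asvs),
    asv_ids = asv_ids,
    module_sizes = as.integer(module_sizes),
    module_of = module_of,
    rho_within = rho_within,
    connectors = connectors,
    rho_cross = rho_cross,
    effect_asvs = effect_asvs,
    effect_group = effect_group,
    effect_size = effect_size,
    base_logmean = base_logmean,
    base_logsd = base_logsd,
    depth_mean = depth_mean,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic community spec:",
      length(x$group_names), "groups x", x$n_samples_per_group, "samples,",
      x$n_asvs, "ASVs\n")
  cat("  modules:", paste(x$module_sizes, collapse = "+"),
      sprintf("(rho_within = %.2f), %d connectors (rho_cross = %.2f)\n",
              x$rho_within, length(x$connectors), x$rho_cross))
  if (length(x$effect_asvs)) {
    cat(sprintf("  effect: %d ASVs x%.2g in group %s\n",
                length(x$effect_asvs), x$effect_size, x$effect_group))
  }
  invisible(x)
}

#' Latent correlation matrix implied by a synthetic spec
#'
#' Block matrix with `rho_within` inside every module block, `rho_cross`
#' between each connector and all members of its foreign modules, zero
#' elsewhere and unit diagonal. If the assembled matrix has an eigenvalue
#' below `-1e-10` it is projected to the nearest positive semi-definite
#' correlation matrix (negative eigenvalues clipped to zero, diagonal
#' rescaled to one).
#'
#' @param spec a [synthetic_spec()].
#' @return symmetric correlation matrix with ASV ids as dimnames.
#' @export
build_latent_correlation <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  p <- spec$n_asvs
  R <- diag(p)
  dimnames(R) <- list(spec$asv_ids, spec$asv_ids)
  for (m in unique(spec$module_of[spec$module_of != "none"])) {
    members <- which(spec$module_of == m)
    R[members, members] <- spec$rho_within
  }
  for (a in names(spec$connectors)) {
    i <- match(a, spec$asv_ids)
    for (fm in spec$connectors[[a]]) {
      members <- setdiff(which(spec$module_of == as.character(fm)), i)
      R[i, members] <- spec$rho_cross
      R[members, i] <- spec$rho_cross
    }
  }
  diag(R) <- 1
  eig <- eigen(R, symmetric = TRUE)
  if (min(eig$values) < -1e-10) {
    lam <- pmax(eig$values, 0)
    R <- eig$vectors %*% (lam * t(eig$vectors))
    d <- sqrt(diag(R))
    R <- R / tcrossprod(d)
    dimnames(R) <- list(spec$asv_ids, spec$asv_ids)
    eig2 <- eigen(R, symmetric = TRUE, only.values = TRUE)
    if (min(eig2$values) < -1e-8) stop("latent correlation not PSD after repair")
  }
  (R + t(R)) / 2
}

#' Ground truth bundle for a synthetic spec
#'
#' @param spec a [synthetic_spec()].
#' @return object of class `ground_truth` with the module map, connector set,
#'   differential (group-effect) set and latent correlation matrix.
#' @export
ground_truth <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  structure(list(
    module_of = spec$module_of,
    connector_set = as.character(names(spec$connectors)),
    differential_set = if (spec$effect_size != 1) spec$effect_asvs else character(),
    latent_correlation = build_latent_correlation(spec)
  ), class = "ground_truth")
}

# symmetric square root via eigendecomposition; tolerates the semi-definite
# matrices produced by PSD clipping (chol() would not)
.mat_sqrt <- function(R) {
  eig <- eigen(R, symmetric = TRUE)
  eig$vectors %*% (sqrt(pmax(eig$values, 0)) * t(eig$vectors))
}

#' Draw a grouped ASV count table from a synthetic spec
#'
#' For every sample a multivariate standard normal vector with the spec's
#' latent correlation is mapped ASV-wise through the log-normal quantile
#' function (mean shifted by `log(effect_size)` for effect ASVs in the effect
#' group), closed to relative abundances, and converted to counts by a
#' multinomial draw at a Poisson(`depth_mean`) library size. The call is
#' deterministic under `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param truth optional [ground_truth()]; rebuilt from `spec` when missing.
#' @return list with `counts` (sample x ASV integer matrix) and `metadata`
#'   (data.frame: sample_id, group, timepoint, temperature, treatment).
#' @export
sample_counts <- function(spec, truth = ground_truth(spec)) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(truth, "ground_truth"))
  R <- truth$latent_correlation
  n_groups <- length(spec$group_names)
  n <- n_groups * spec$n_samples_per_group
  p <- spec$n_asvs

  group <- rep(spec$group_names, each = spec$n_samples_per_group)
  sample_ids <- sprintf("%s_S%02d", group,
                        unlist(lapply(seq_len(n_groups),
                                      function(i) seq_len(spec$n_samples_per_group))))

  A <- .mat_sqrt(R)
  counts <- matrix(0L, n, p, dimnames = list(sample_ids, spec$asv_ids))
  meanlog <- matrix(spec$base_logmean, n, p)
  if (length(spec$effect_asvs) && spec$effect_size != 1) {
    rows <- which(group == spec$effect_group)
    cols <- match(spec$effect_asvs, spec$asv_ids)
    meanlog[rows, cols] <- meanlog[rows, cols] + log(spec$effect_size)
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  Z <- matrix(stats::rnorm(n * p), n, p) %*% A
  U <- stats::pnorm(Z)
  abundance <- stats::qlnorm(U, meanlog = meanlog, sdlog = spec$base_logsd)
  rel <- abundance / rowSums(abundance)
  depths <- pmax(stats::rpois(n, spec$depth_mean), 1L)
  for (i in seq_len(n)) {
    counts[i, ] <- stats::rmultinom(1, size = depths[i], prob = rel[i, ])[, 1]
  }

  timepoint <- rep(c("T2", "T3"), length.out = spec$n_samples_per_group)
  metadata <- data.frame(
    sample_id = sample_ids,
    group = group,
    timepoint = rep(timepoint, times = n_groups),
    temperature = ifelse(startsWith(group, "H"), 31, 27),
    treatment = ifelse(endsWith(group, "B"), "probiotic", "control"),
    stringsAsFactors = FALSE
  )
  list(counts = counts, metadata = metadata)
}

# save/restore the global RNG state so seeded generators do not perturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write / read ground truth as tab-separated files
#'
#' `export_truth()` writes three TSVs into `dir`: `modules.tsv`
#' (asv, module; background taxa labeled "none"), `connectors.tsv` (asv) and
#' `differential.tsv` (asv). `read_truth()` reads them back; the round trip
#' is lossless apart from the latent correlation matrix, which is not
#' serialized.
#'
#' @param truth a [ground_truth()].
#' @param dir output directory (created if needed).
#' @return `export_truth()` the directory path, invisibly; `read_truth()` a
#'   list with `module_of`, `connector_set`, `differential_set`.
#' @export
export_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir)
  utils::write.table(
    data.frame(asv = names(truth$module_of), module = unname(truth$module_of)),
    file.path(dir, "modules.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(asv = truth$connector_set),
    file.path(dir, "connectors.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(asv = truth$differential_set),
    file.path(dir, "differential.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname export_truth
#' @export
read_truth <- function(dir) {
  modules <- utils::read.delim(file.path(dir, "modules.tsv"),
                               colClasses = "character")
  connectors <- utils::read.delim(file.path(dir, "connectors.tsv"),
                                  colClasses = "character")
  differential <- utils::read.delim(file.path(dir, "differential.tsv"),
                                    colClasses = "character")
  module_of <- modules$module
  names(module_of) <- modules$asv
  list(module_of = module_of,
       connector_set = connectors$asv,
       differential_set = differential$asv)
}
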