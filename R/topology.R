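#' Per-node centrality attributes
#'
#' Degree, unnormalized shortest-path betweenness, closeness (computed within
#' each node's connected component: 1 / sum of distances to the other nodes
#' of its component), and local clustering coefficient (triangles divided by
#' possible triangles; 0 for nodes of degree < 2). All values are
#' deterministic functions of the graph.
#'
#' @param net igraph network (non-empty).
#' @return data.frame with columns node, degree, betweenness, closeness,
#'   local_clustering.
#' @export
node_attributes <- function(net) {
  if (igraph::vcount(net) == 0) stop("empty network")
  nodes <- igraph::V(net)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(net)))
  deg <- igraph::degree(net)
  btw <- igraph::betweenness(net, directed = FALSE, normalized = FALSE)
  lc <- igraph::transitivity(net, type = "local", isolates = "zero")
  lc[deg < 2] <- 0

  comp <- igraph::components(net)$membership
  clo <- numeric(length(nodes))
  d <- igraph::distances(net)
  for (c_id in unique(comp)) {
    idx <- which(comp == c_id)
    if (length(idx) == 1) {
      clo[idx] <- 0  # singleton component: closeness undefined, reported as 0
    } else {
      clo[idx] <- 1 / rowSums(d[idx, idx, drop = FALSE])
    }
  }
  data.frame(node = nodes, degree = as.integer(deg), betweenness = unname(btw),
             closeness = clo, local_clustering = lc,
             stringsAsFactors = FALSE, row.names = NULL)
}

# mean local clustering with the degree<2 -> 0 convention
.mean_clustering <- function(g) {
  if (igraph::vcount(g) == 0) return(NA_real_)
  lc <- igraph::transitivity(g, type = "local", isolates = "zero")
  lc[igraph::degree(g) < 2] <- 0
  mean(lc)
}

# average shortest path over unordered pairs of the largest component
.largest_component_path_length <- function(g) {
  if (igraph::ecount(g) == 0) return(NA_real_)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  igraph::mean_distance(sub, directed = FALSE)
}

#' Empirical topology metrics for a network
#'
#' @param net igraph network (non-empty, with edges).
#' @param membership module membership used for modularity Q; default from
#'   [detect_modules()].
#' @return list: n_nodes, n_edges, average_degree, clustering (mean local),
#'   path_length (largest component), density, Q.
#' @export
network_metrics <- function(net, membership = NULL) {
  if (igraph::vcount(net) == 0) stop("empty network")
  if (is.null(membership)) membership <- detect_modules(net)$membership
  nodes <- igraph::V(net)$name
  n <- igraph::vcount(net)
  m <- igraph::ecount(net)
  list(
    n_nodes = n,
    n_edges = m,
    average_degree = 2 * m / n,
    clustering = .mean_clustering(net),
    path_length = .largest_component_path_length(net),
    density = if (n > 1) m / (n * (n - 1) / 2) else 0,
    Q = igraph::modularity(net, membership[nodes])
  )
}

#' Erdos-Renyi G(n, m) null ensemble
#'
#' Draws `n_random` uniform random simple graphs with exactly the empirical
#' node and edge counts and records per replicate the mean local clustering,
#' the average path length of the largest component, and the modularity found
#' by the same greedy detector used on the empirical network.
#'
#' @param n_nodes,n_edges size of each random graph.
#' @param n_random ensemble size, default 1000.
#' @param seed integer seed.
#' @return list of class `er_ensemble` with per-metric mean/sd and the raw
#'   replicate vectors.
#' @export
er_ensemble <- function(n_nodes, n_edges, n_random = 1000, seed = 1L) {
  if (n_edges > n_nodes * (n_nodes - 1) / 2) {
    stop("infeasible edge count for a simple graph")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  clustering <- path_length <- modularity <- numeric(n_random)
  for (b in seq_len(n_random)) {
    g <- igraph::sample_gnm(n_nodes, n_edges)
    clustering[b] <- .mean_clustering(g)
    path_length[b] <- .largest_component_path_length(g)
    modularity[b] <- if (n_edges > 0) {
      igraph::modularity(g, igraph::membership(
        igraph::cluster_fast_greedy(g, weights = NULL)))
    } else NA_real_
  }
  structure(list(
    n_nodes = n_nodes, n_edges = n_edges,
    n_random = as.integer(n_random), seed = as.integer(seed),
    clustering_mean = mean(clustering), clustering_sd = stats::sd(clustering),
    path_length_mean = mean(path_length, na.rm = TRUE),
    path_length_sd = stats::sd(path_length, na.rm = TRUE),
    modularity_mean = mean(modularity), modularity_sd = stats::sd(modularity),
    clustering = clustering, path_length = path_length, modularity = modularity
  ), class = "er_ensemble")
}

#' Small-world coefficient sigma
#'
#' Humphries-Gurney sigma: `(C / C_rand) / (L / L_rand)` with the random
#' baselines taken from a size-matched G(n, m) ensemble. Values above 1
#' indicate small-world structure (more clustered than random at comparable
#' path length).
#'
#' @param clustering,path_length empirical values.
#' @param er_clustering_mean,er_path_length_mean ensemble means.
#' @return sigma, or NA with a warning when the ensemble clustering mean is 0.
#' @export
small_world_sigma <- function(clustering, path_length,
                              er_clustering_mean, er_path_length_mean) {
  if (is.na(er_clustering_mean) || er_clustering_mean <= 0) {
    warning("E-R ensemble clustering mean is zero; sigma undefined")
    return(NA_real_)
  }
  if (is.na(er_path_length_mean) || er_path_length_mean <= 0) {
    warning("E-R ensemble path length mean is zero; sigma undefined")
    return(NA_real_)
  }
  (clustering / er_clustering_mean) / (path_length / er_path_length_mean)
}

#' Full topology summary with Erdos-Renyi baselines
#'
#' Combines [network_metrics()], [er_ensemble()] and [small_world_sigma()]
#' into one record.
#'
#' @param net igraph network.
#' @param membership optional module membership (default: detected).
#' @param n_random E-R ensemble size.
#' @param seed integer seed for the ensemble.
#' @return list of class `topology_summary`.
#' @export
topology_summary <- function(net, membership = NULL, n_random = 1000, seed = 1L) {
  emp <- network_metrics(net, membership)
  ens <- er_ensemble(emp$n_nodes, emp$n_edges, n_random = n_random, seed = seed)
  sigma <- small_world_sigma(emp$clustering, emp$path_length,
                             ens$clustering_mean, ens$path_length_mean)
  structure(c(emp, list(
    small_world_sigma = sigma,
    er_clustering_mean = ens$clustering_mean,
    er_clustering_sd = ens$clustering_sd,
    er_path_length_mean = ens$path_length_mean,
    er_path_length_sd = ens$path_length_sd,
    er_modularity_mean = ens$modularity_mean,
    er_modularity_sd = ens$modularity_sd,
    n_random = ens$n_random, seed = ens$seed
  )), class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "Network: %d nodes, %d edges (density %.3f)\n",
    "  clustering %.3f (E-R %.3f +- %.3f)\n",
    "  path length %.3f (E-R %.3f +- %.3f)\n",
    "  modularity Q %.3f (E-R %.3f +- %.3f)\n",
    "  small-world sigma %.3f\n"),
    x$n_nodes, x$n_edges, x$density,
    x$clustering, x$er_clustering_mean, x$er_clustering_sd,
    x$path_length, x$er_path_length_mean, x$er_path_length_sd,
    x$Q, x$er_modularity_mean, x$er_modularity_sd,
    x$small_world_sigma))
  invisible(x)
}

# two-sample KS statistic D = sup |F_a - F_b|, tie-safe
.ks_statistic <- function(a, b) {
  m <- length(a)
  n <- length(b)
  z <- c(a, b)
  ord <- order(z)
  steps <- cumsum(ifelse(ord <= m, 1 / m, -1 / n))
  zs <- z[ord]
  if (anyDuplicated(zs)) {
    # evaluate the ECDF difference only after the last element of a tie group
    last_of_run <- c(diff(zs) != 0, TRUE)
    steps <- steps[last_of_run]
  }
  max(abs(steps))
}

# asymptotic two-sided p-value for the two-sample KS statistic
.ks_asymptotic_p <- function(d, m, n) {
  lambda <- sqrt(m * n / (m + n)) * d
  if (lambda < 1e-12) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, .Machine$double.xmin), 1)
}

#' Bootstrap two-sample Kolmogorov-Smirnov comparison of node attributes
#'
#' Computes the observed two-sample KS statistic D and its asymptotic
#' two-sided p-value on the raw attribute vectors (e.g. the degree
#' distributions of two networks), then resamples both vectors with
#' replacement (at their original sizes) `n_boot` times, recording D each
#' iteration, and summarizes the bootstrap distribution with a percentile
#' interval. Deterministic under `seed`.
#'
#' @param attr_a,attr_b non-empty numeric vectors.
#' @param n_boot bootstrap iterations, default 10000.
#' @param seed integer seed.
#' @param attribute optional label (e.g. "degree") carried into the result.
#' @return list of class `ks_comparison`: D, p, n_boot, seed, boot_mean,
#'   boot_ci (2.5/50/97.5 percentiles), attribute.
#' @export
ks_bootstrap_compare <- function(attr_a, attr_b, n_boot = 10000, seed = 1L,
                                 attribute = NA_character_) {
  if (length(attr_a) == 0 || length(attr_b) == 0) {
    stop("attribute vectors must be non-empty")
  }
  m <- length(attr_a)
  n <- length(attr_b)
  d_obs <- .ks_statistic(attr_a, attr_b)
  p <- .ks_asymptotic_p(d_obs, m, n)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  boot_d <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    boot_d[b] <- .ks_statistic(attr_a[sample.int(m, m, replace = TRUE)],
                               attr_b[sample.int(n, n, replace = TRUE)])
  }
  structure(list(
    attribute = attribute,
    D = d_obs,
    p = p,
    n_boot = as.integer(n_boot),
    seed = as.integer(seed),
    boot_mean = mean(boot_d),
    boot_ci = stats::quantile(boot_d, c(0.025, 0.5, 0.975))
  ), class = "ks_comparison")
}

#' @export
print.ks_comparison <- function(x, ...) {
  cat(sprintf("KS comparison%s: D = %.3f, p = %.3g (bootstrap %d: D in [%.3f, %.3f])\n",
              if (is.na(x$attribute)) "" else paste0(" (", x$attribute, ")"),
              x$D, x$p, x$n_boot, x$boot_ci[1], x$boot_ci[3]))
  invisible(x)
}
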