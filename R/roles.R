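#' Detect modules by greedy modularity maximization
#'
#' Clauset-Newman-Moore greedy agglomeration (igraph's `cluster_fast_greedy`)
#' on the unweighted graph. The algorithm is deterministic for a given vertex
#' ordering; reefnet networks are built with lexicographically sorted vertex
#' names, so repeated runs give identical partitions. Each connected
#' component is partitioned; isolated vertices would be their own modules but
#' never occur because isolated ASVs are excluded from networks.
#'
#' @param net igraph network (non-empty).
#' @return list of class `module_partition`: `membership` (named integer
#'   vector) and `Q` (modularity of the partition).
#' @export
detect_modules <- function(net) {
  if (igraph::vcount(net) == 0) stop("empty network")
  comm <- igraph::cluster_fast_greedy(net, weights = NULL)
  membership <- igraph::membership(comm)
  Q <- igraph::modularity(net, membership)
  # deterministic fallback: igraph occasionally cuts the CNM dendrogram below
  # its modularity optimum on dense graphs (e.g. complete graphs); the
  # one-module-per-component partition is the correct answer there
  comp <- igraph::components(net)$membership
  Q_comp <- igraph::modularity(net, comp)
  if (Q_comp > Q + 1e-12) {
    membership <- comp
    Q <- Q_comp
  }
  names(membership) <- igraph::V(net)$name
  structure(list(
    membership = membership,
    Q = Q
  ), class = "module_partition")
}

#' Per-node module link statistics
#'
#' For every node: its degree `k`, the vector of link counts into each module
#' (`k_to_module`), the count into its own module (`k_is`), and its module's
#' mean and population standard deviation of within-module degree — the
#' ingredients of the Zi and Pi connectivity scores.
#'
#' @param net igraph network.
#' @param membership named module membership vector (from [detect_modules()]
#'   or ground truth) covering every vertex.
#' @return list of class `node_module_stats`.
#' @export
node_module_stats <- function(net, membership) {
  nodes <- igraph::V(net)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(net)))
  if (!all(nodes %in% names(membership))) {
    stop("membership does not cover all network nodes")
  }
  membership <- membership[nodes]
  modules <- sort(unique(membership))
  adj <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  dimnames(adj) <- list(nodes, nodes)

  # k_to_module[i, s] = links of node i into module s
  mod_indicator <- vapply(modules, function(s) as.numeric(membership == s),
                          numeric(length(nodes)))
  k_to_module <- adj %*% mod_indicator
  colnames(k_to_module) <- as.character(modules)
  k <- rowSums(adj)
  k_is <- k_to_module[cbind(seq_along(nodes),
                            match(membership, modules))]
  names(k_is) <- nodes

  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  mean_ks <- as.numeric(tapply(k_is, membership, mean)[as.character(membership)])
  sd_ks <- as.numeric(tapply(k_is, membership, pop_sd)[as.character(membership)])
  names(mean_ks) <- names(sd_ks) <- nodes

  structure(list(
    nodes = nodes,
    membership = membership,
    k = k,
    k_is = k_is,
    k_to_module = k_to_module,
    mean_ks = mean_ks,
    sd_ks = sd_ks
  ), class = "node_module_stats")
}

#' Within-module connectivity (Zi)
#'
#' Z-score of a node's within-module degree against the mean and population
#' standard deviation of within-module degree over its module:
#' `Zi = (k_is - mean_ks) / sd_ks`. Modules whose members all have equal
#' within-module degree have `sd_ks = 0`; Zi is defined as 0 there.
#'
#' @param stats a [node_module_stats()] object.
#' @return named numeric vector of Zi values.
#' @export
within_module_z <- function(stats) {
  stopifnot(inherits(stats, "node_module_stats"))
  zi <- as.numeric(ifelse(stats$sd_ks > 0,
                          (stats$k_is - stats$mean_ks) / stats$sd_ks, 0))
  names(zi) <- stats$nodes
  zi
}

#' Among-module connectivity / participation coefficient (Pi)
#'
#' `Pi = 1 - sum_s (k_s / k)^2` over the node's link counts `k_s` into each
#' module. Pi is 0 exactly when all of a node's links stay inside one module
#' and approaches 1 as links spread evenly over many modules.
#'
#' @param stats a [node_module_stats()] object.
#' @return named numeric vector of Pi values in `[0, 1)`.
#' @export
participation <- function(stats) {
  stopifnot(inherits(stats, "node_module_stats"))
  pi <- 1 - rowSums((stats$k_to_module / stats$k)^2)
  names(pi) <- stats$nodes
  pi
}

#' Classify nodes into the four Zi-Pi topological roles
#'
#' Network hubs (`Zi > 2.5` and `Pi > 0.62`), module hubs (`Zi > 2.5`,
#' `Pi <= 0.62`), connectors (`Zi <= 2.5`, `Pi > 0.62`) and peripherals
#' (otherwise). Thresholds are strict on the "high" side, so a node sitting
#' exactly on a threshold falls into the lower category; such boundary nodes
#' are reported with a message.
#'
#' @param zi,pi numeric vectors of equal length.
#' @param zi_threshold,pi_threshold role thresholds, defaults 2.5 and 0.62.
#' @return character vector of roles.
#' @export
classify_roles <- function(zi, pi, zi_threshold = 2.5, pi_threshold = 0.62) {
  stopifnot(length(zi) == length(pi))
  boundary <- which(zi == zi_threshold | pi == pi_threshold)
  if (length(boundary)) {
    message("classify_roles: ", length(boundary),
            " node(s) exactly at a threshold assigned to the lower category")
  }
  hi_z <- zi > zi_threshold
  hi_p <- pi > pi_threshold
  ifelse(hi_z & hi_p, "network hub",
         ifelse(hi_z, "module hub",
                ifelse(hi_p, "connector", "peripheral")))
}

#' Full node-role table for a network
#'
#' Convenience wrapper: detects modules (unless a membership is supplied),
#' computes Zi and Pi, and classifies every node.
#'
#' @param net igraph network.
#' @param membership optional named membership vector; default
#'   [detect_modules()] on `net`.
#' @inheritParams classify_roles
#' @return data.frame (class `node_role_table`) with columns asv, module,
#'   degree, k_within, zi, pi, role; attribute `Q` holds the partition
#'   modularity.
#' @export
node_roles <- function(net, membership = NULL,
                       zi_threshold = 2.5, pi_threshold = 0.62) {
  if (is.null(membership)) {
    part <- detect_modules(net)
    membership <- part$membership
    Q <- part$Q
  } else {
    Q <- igraph::modularity(net, membership[igraph::V(net)$name])
  }
  stats <- node_module_stats(net, membership)
  zi <- within_module_z(stats)
  pi <- participation(stats)
  out <- data.frame(
    asv = stats$nodes,
    module = as.integer(stats$membership),
    degree = as.integer(stats$k),
    k_within = as.integer(stats$k_is),
    zi = zi,
    pi = pi,
    role = classify_roles(zi, pi, zi_threshold, pi_threshold),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "Q") <- Q
  class(out) <- c("node_role_table", "data.frame")
  out
}
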