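# shared fixtures and independent oracles

# small feature table with dimnames
toy_table <- function(values, n_samples, n_asvs,
                      sample_ids = paste0("S", seq_len(n_samples)),
                      asv_ids = paste0("A", seq_len(n_asvs))) {
  matrix(values, n_samples, n_asvs, dimnames = list(sample_ids, asv_ids))
}

# igraph from an edge matrix of vertex names
graph_from_pairs <- function(...) {
  pairs <- matrix(c(...), ncol = 2, byrow = TRUE)
  igraph::graph_from_data_frame(
    data.frame(from = pairs[, 1], to = pairs[, 2]), directed = FALSE)
}

# two disconnected K4 cliques on vertices a1..a4 / b1..b4
two_cliques <- function() {
  g <- igraph::make_full_graph(4) + igraph::make_full_graph(4)
  igraph::V(g)$name <- c(paste0("a", 1:4), paste0("b", 1:4))
  g
}

# naive per-definition Zi/Pi oracle: explicit loops over neighbors
oracle_zi_pi <- function(g, membership) {
  nodes <- igraph::V(g)$name
  membership <- membership[nodes]
  k_to <- lapply(nodes, function(v) {
    nb <- igraph::neighbors(g, v)$name
    table(factor(membership[nb], levels = sort(unique(membership))))
  })
  k_is <- mapply(function(v, kt) kt[[as.character(membership[[v]])]],
                 nodes, k_to)
  zi <- numeric(length(nodes))
  for (m in unique(membership)) {
    idx <- which(membership == m)
    mu <- mean(k_is[idx])
    sdv <- sqrt(mean((k_is[idx] - mu)^2))
    zi[idx] <- if (sdv > 0) (k_is[idx] - mu) / sdv else 0
  }
  k <- vapply(k_to, sum, numeric(1))
  pi <- 1 - vapply(seq_along(nodes), function(i) sum((k_to[[i]] / k[i])^2),
                   numeric(1))
  list(zi = unname(zi), pi = unname(pi), k = unname(k), k_is = unname(k_is))
}

# closed-form Spearman for tie-free vectors
spearman_d2 <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# planted 3-module recovery scenario (frozen; see methods vignette)
recovery_spec <- function(seed) {
  synthetic_spec(
    n_samples_per_group = 20, group_names = "G", n_asvs = 60,
    module_sizes = c(10, 10, 10), rho_within = 0.85,
    connectors = list(ASV_001 = 2L, ASV_011 = 3L), rho_cross = 0.75,
    seed = seed)
}

# run one planted replicate through the network stages
recover_replicate <- function(seed) {
  spec <- recovery_spec(seed)
  truth <- ground_truth(spec)
  sim <- suppressMessages(sample_counts(spec, truth))
  tab <- suppressMessages(filter_prevalence(sim$counts, 0.30))
  sp <- suppressMessages(spearman_matrix(tab))
  net <- build_network(threshold_edges(sp$rho, sp$p))
  if (igraph::ecount(net) == 0) {
    return(list(ari = NA_real_, pi_rank = NA, truth = truth, net = net))
  }
  rt <- suppressMessages(node_roles(net))
  planted <- rt$asv[truth$module_of[rt$asv] != "none"]
  ari <- if (length(planted) >= 2) {
    adjusted_rand_index(truth$module_of[planted],
                        rt$module[match(planted, rt$asv)])
  } else NA_real_
  is_conn <- rt$asv %in% truth$connector_set
  pi_rank <- if (any(is_conn) && any(!is_conn)) {
    mean(rt$pi[is_conn]) > mean(rt$pi[!is_conn])
  } else NA
  list(ari = ari, pi_rank = pi_rank, truth = truth, net = net, roles = rt)
}
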