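#' Pipeline configuration
#'
#' Bundles every input path, threshold and seed of the end-to-end analysis.
#' Defaults are the standard printed thresholds of the coral-microbiome
#' network workflow: 0.005% relative abundance, 30% prevalence, |rho| > 0.7,
#' p < 0.05, Zi 2.5, Pi 0.62, 999 permutations, 1000 random graphs, 10000
#' bootstrap iterations.
#'
#' @param counts sample x ASV matrix, or a path to a feature-table TSV.
#' @param metadata data.frame with a `sample_id` column, or a path to a
#'   metadata TSV.
#' @param group_column metadata column defining groups, default `"group"`.
#' @param networks character vector of group labels to build one network
#'   each; default: all groups.
#' @param abundance_threshold,prevalence_min,rho_threshold,p_threshold
#'   filter and edge thresholds.
#' @param zi_threshold,pi_threshold node-role thresholds.
#' @param n_perm PERMANOVA permutations.
#' @param n_random E-R ensemble size.
#' @param n_boot KS bootstrap iterations.
#' @param rarefy_depth subsampling depth; `NULL` = minimum sample total.
#' @param seed master seed; stage seeds are derived from it by a stable hash
#'   of the stage name.
#' @param out_dir output directory.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, metadata, group_column = "group",
                            networks = NULL,
                            abundance_threshold = 0.00005,
                            prevalence_min = 0.30,
                            rho_threshold = 0.7,
                            p_threshold = 0.05,
                            zi_threshold = 2.5,
                            pi_threshold = 0.62,
                            n_perm = 999,
                            n_random = 1000,
                            n_boot = 10000,
                            rarefy_depth = NULL,
                            seed = 1L,
                            out_dir = "reefnet_out") {
  stopifnot(abundance_threshold >= 0, prevalence_min >= 0, prevalence_min <= 1,
            rho_threshold >= 0, rho_threshold <= 1,
            p_threshold > 0, p_threshold <= 1,
            n_perm >= 1, n_random >= 1, n_boot >= 1)
  structure(list(
    counts = counts, metadata = metadata, group_column = group_column,
    networks = networks,
    abundance_threshold = abundance_threshold,
    prevalence_min = prevalence_min,
    rho_threshold = rho_threshold, p_threshold = p_threshold,
    zi_threshold = zi_threshold, pi_threshold = pi_threshold,
    n_perm = as.integer(n_perm), n_random = as.integer(n_random),
    n_boot = as.integer(n_boot),
    rarefy_depth = rarefy_depth, seed = as.integer(seed),
    out_dir = out_dir
  ), class = "pipeline_config")
}

# derive a stage seed from the master seed by a stable polynomial hash of
# the stage name; kept below 2^31 - 1
.stage_seed <- function(master, stage) {
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 2147483647
  as.integer((master + h) %% 2147483647)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full co-occurrence network pipeline
#'
#' Filters the feature table, computes Bray-Curtis distances, PCoA
#' coordinates and pairwise PERMANOVA, builds one Spearman co-occurrence
#' network per configured group (prevalence filter applied within the
#' group's samples), summarizes each network's topology against an E-R
#' ensemble, classifies Zi-Pi node roles, and compares every network pair by
#' bootstrap KS tests on degree, betweenness and closeness. All outputs are
#' written under `config$out_dir` as TSV/CSV/GraphML plus a `run_log.txt`
#' recording every derived seed and filter tally. Re-running with the same
#' config and seed reproduces every output byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with the in-memory results bundle.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  counts <- if (is.character(config$counts)) {
    read_feature_table(config$counts)
  } else config$counts
  validate_feature_table(counts)
  metadata <- if (is.character(config$metadata)) {
    utils::read.delim(config$metadata, stringsAsFactors = FALSE)
  } else config$metadata
  if (!"sample_id" %in% names(metadata)) stop("metadata needs a sample_id column")
  if (!config$group_column %in% names(metadata)) {
    stop("metadata lacks group column '", config$group_column, "'")
  }
  if (!all(rownames(counts) %in% metadata$sample_id)) {
    stop("metadata does not cover all samples")
  }
  metadata <- metadata[match(rownames(counts), metadata$sample_id), ]
  groups <- metadata[[config$group_column]]
  net_groups <- if (is.null(config$networks)) sort(unique(groups)) else config$networks
  missing_groups <- setdiff(net_groups, groups)
  if (length(missing_groups)) {
    stop("configured network group(s) not in metadata: ",
         paste(missing_groups, collapse = ", "))
  }

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c("reefnet pipeline log", sprintf("master seed: %d", config$seed))
  log_note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  capture_msgs <- function(expr) {
    withCallingHandlers(expr, message = function(m) {
      log_note("%s", sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  }

  # --- filtering -----------------------------------------------------------
  log_note("input: %d samples x %d ASVs", nrow(counts), ncol(counts))
  filtered <- capture_msgs(
    filter_min_relative_abundance(counts, config$abundance_threshold))
  rarefy_seed <- .stage_seed(config$seed, "rarefy")
  log_note("stage seed rarefy: %d", rarefy_seed)
  filtered <- capture_msgs(
    rarefy(filtered, depth = config$rarefy_depth, seed = rarefy_seed))
  metadata <- metadata[match(rownames(filtered), metadata$sample_id), ]
  groups <- metadata[[config$group_column]]
  log_note("after filtering: %d samples x %d ASVs", nrow(filtered), ncol(filtered))
  write_feature_table(filtered, file.path(config$out_dir, "filtered_table.tsv"))

  # --- community ecology ---------------------------------------------------
  dm <- bray_curtis(filtered)
  .write_tsv(data.frame(sample_id = rownames(dm), dm, check.names = FALSE),
             file.path(config$out_dir, "bray_curtis.tsv"))
  ord <- pcoa(dm)
  .write_tsv(data.frame(sample_id = rownames(ord$points),
                        ord$points[, seq_len(min(3, ncol(ord$points))), drop = FALSE],
                        check.names = FALSE),
             file.path(config$out_dir, "pcoa.tsv"))
  perm_seed <- .stage_seed(config$seed, "permanova")
  log_note("stage seed permanova: %d", perm_seed)
  perm <- pairwise_permanova(dm, groups, n_perm = config$n_perm, seed = perm_seed)
  .write_tsv(perm, file.path(config$out_dir, "permanova.tsv"))

  # --- per-group networks --------------------------------------------------
  networks <- list()
  roles <- list()
  attrs <- list()
  topo_rows <- list()
  for (g in net_groups) {
    sub <- filtered[groups == g, , drop = FALSE]
    sub <- capture_msgs(filter_prevalence(sub, config$prevalence_min))
    log_note("network %s: %d samples, %d ASVs after prevalence filter",
             g, nrow(sub), ncol(sub))
    sp <- capture_msgs(spearman_matrix(sub))
    edges <- threshold_edges(sp$rho, sp$p,
                             rho_threshold = config$rho_threshold,
                             p_threshold = config$p_threshold)
    net <- build_network(edges)
    networks[[g]] <- net
    export_network(net, file.path(config$out_dir, paste0("network_", g, ".graphml")))
    export_network(net, file.path(config$out_dir, paste0("edges_", g, ".csv")),
                   format = "csv")
    log_note("network %s: %d nodes, %d edges", g,
             igraph::vcount(net), igraph::ecount(net))
    if (igraph::ecount(net) == 0) {
      log_note("network %s empty; topology and roles skipped", g)
      next
    }
    part <- detect_modules(net)
    rt <- node_roles(net, membership = part$membership,
                     zi_threshold = config$zi_threshold,
                     pi_threshold = config$pi_threshold)
    roles[[g]] <- rt
    utils::write.csv(rt, file.path(config$out_dir, paste0("roles_", g, ".csv")),
                     row.names = FALSE, quote = FALSE)
    na <- node_attributes(net)
    attrs[[g]] <- na
    utils::write.csv(na, file.path(config$out_dir, paste0("node_attributes_", g, ".csv")),
                     row.names = FALSE, quote = FALSE)
    er_seed <- .stage_seed(config$seed, paste0("er_", g))
    log_note("stage seed er_%s: %d", g, er_seed)
    ts <- topology_summary(net, membership = part$membership,
                           n_random = config$n_random, seed = er_seed)
    topo_rows[[g]] <- data.frame(
      network = g, n_nodes = ts$n_nodes, n_edges = ts$n_edges,
      average_degree = ts$average_degree, clustering = ts$clustering,
      path_length = ts$path_length, density = ts$density, Q = ts$Q,
      small_world_sigma = ts$small_world_sigma,
      er_clustering_mean = ts$er_clustering_mean,
      er_clustering_sd = ts$er_clustering_sd,
      er_path_length_mean = ts$er_path_length_mean,
      er_path_length_sd = ts$er_path_length_sd,
      er_modularity_mean = ts$er_modularity_mean,
      er_modularity_sd = ts$er_modularity_sd,
      n_random = ts$n_random, seed = ts$seed,
      stringsAsFactors = FALSE)
  }
  if (length(topo_rows)) {
    .write_tsv(do.call(rbind, topo_rows), file.path(config$out_dir, "topology.tsv"))
  }

  # --- connector counts ----------------------------------------------------
  if (length(roles)) {
    conn <- do.call(rbind, lapply(names(roles), function(g) {
      data.frame(network = g,
                 n_nodes = nrow(roles[[g]]),
                 n_connectors = sum(roles[[g]]$role == "connector"),
                 n_module_hubs = sum(roles[[g]]$role == "module hub"),
                 n_network_hubs = sum(roles[[g]]$role == "network hub"),
                 n_peripherals = sum(roles[[g]]$role == "peripheral"),
                 stringsAsFactors = FALSE)
    }))
    .write_tsv(conn, file.path(config$out_dir, "connector_counts.tsv"))
  } else conn <- NULL

  # --- cross-network KS comparisons ---------------------------------------
  ks_rows <- list()
  attr_names <- c("degree", "betweenness", "closeness")
  gs <- names(attrs)
  if (length(gs) >= 2) {
    for (pair in utils::combn(gs, 2, simplify = FALSE)) {
      for (a in attr_names) {
        ks_seed <- .stage_seed(config$seed,
                               paste("ks", pair[1], pair[2], a, sep = "_"))
        res <- ks_bootstrap_compare(attrs[[pair[1]]][[a]], attrs[[pair[2]]][[a]],
                                    n_boot = config$n_boot, seed = ks_seed,
                                    attribute = a)
        ks_rows[[length(ks_rows) + 1]] <- data.frame(
          network_a = pair[1], network_b = pair[2], attribute = a,
          D = res$D, p = res$p, n_boot = res$n_boot, seed = res$seed,
          boot_lo = unname(res$boot_ci[1]), boot_hi = unname(res$boot_ci[3]),
          stringsAsFactors = FALSE)
      }
    }
    .write_tsv(do.call(rbind, ks_rows), file.path(config$out_dir, "ks_comparisons.tsv"))
  }

  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(list(
    filtered = filtered, metadata = metadata, distance = dm, pcoa = ord,
    permanova = perm, networks = networks, roles = roles,
    node_attributes = attrs,
    topology = if (length(topo_rows)) do.call(rbind, topo_rows) else NULL,
    connector_counts = conn,
    ks = if (length(ks_rows)) do.call(rbind, ks_rows) else NULL,
    log = log_lines
  ))
}

#' Generate the packaged demo fixture
#'
#' Builds a synthetic study emulating the mesocosm design: 4 groups (LT, LTB,
#' HT, HTB) x 10 samples, 300 ASVs with 3 planted correlation modules
#' (15 + 12 + 10 taxa, rho_within 0.85), 2 planted connectors (rho_cross
#' 0.75) and a 3-fold abundance shift of 30 background taxa in the HT group.
#' Writes `feature_table.tsv`, `metadata.tsv` and a `truth/` directory.
#'
#' @param seed integer seed.
#' @param dir output directory.
#' @return invisible list with spec, truth, counts and metadata.
#' @export
make_demo <- function(seed = 1L, dir = "reefnet_demo") {
  spec <- synthetic_spec(
    n_samples_per_group = 10,
    group_names = c("LT", "LTB", "HT", "HTB"),
    n_asvs = 300,
    module_sizes = c(15, 12, 10),
    rho_within = 0.85,
    connectors = list(ASV_001 = 2L, ASV_016 = 3L),
    rho_cross = 0.75,
    effect_asvs = sprintf("ASV_%03d", 41:70),
    effect_group = "HT",
    effect_size = 3,
    seed = seed
  )
  truth <- ground_truth(spec)
  sim <- sample_counts(spec, truth)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(sim$counts, file.path(dir, "feature_table.tsv"))
  .write_tsv(sim$metadata, file.path(dir, "metadata.tsv"))
  export_truth(truth, file.path(dir, "truth"))
  invisible(list(spec = spec, truth = truth,
                 counts = sim$counts, metadata = sim$metadata))
}
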