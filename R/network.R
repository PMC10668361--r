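#' Pairwise Spearman correlations with t-approximation p-values
#'
#' Ranks each ASV's counts with average ranks on ties, computes the Pearson
#' correlation of the ranks (= Spearman's rho), and two-sided p-values from
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with n - 2 degrees of freedom.
#' `rho = +-1` gets the smallest positive double as p. ASVs with constant
#' counts have undefined rank correlation; their rows/columns are set to NA
#' and reported with a message so the pairs are skipped downstream.
#'
#' @param counts sample x ASV matrix, prevalence-filtered.
#' @return list with `rho` and `p` (ASV x ASV matrices, NA diagonal) and `n`
#'   (number of samples).
#' @export
spearman_matrix <- function(counts) {
  validate_feature_table(counts)
  n <- nrow(counts)
  if (n < 5) stop("need at least 5 samples for correlation p-values")
  ranks <- apply(counts, 2, rank)       # average ranks on ties
  constant <- apply(counts, 2, function(x) length(unique(x)) == 1)
  if (any(constant)) {
    message("spearman_matrix: skipping ", sum(constant),
            " constant ASV(s): ",
            paste(colnames(counts)[constant], collapse = ", "))
  }
  rho <- suppressWarnings(stats::cor(ranks))
  rho[constant, ] <- NA
  rho[, constant] <- NA
  rho_c <- pmin(pmax(rho, -1), 1)
  tstat <- rho_c * sqrt((n - 2) / (1 - rho_c^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho_c) >= 1 - 1e-15] <- .Machine$double.xmin
  p[is.na(rho)] <- NA
  diag(rho) <- NA
  diag(p) <- NA
  list(rho = rho, p = p, n = n)
}

#' Threshold a correlation matrix into a co-occurrence edge list
#'
#' Keeps pairs with `|rho| > rho_threshold` and `p < p_threshold` (both
#' strict, so rho exactly at the threshold is excluded). Optionally applies a
#' Benjamini-Hochberg correction to the p-values first; this is off by
#' default, matching the common raw-p convention for |rho| > 0.7 networks.
#'
#' @param rho,p square matrices from [spearman_matrix()].
#' @param rho_threshold minimum |rho|, default 0.7.
#' @param p_threshold maximum p, default 0.05.
#' @param adjust_p apply Benjamini-Hochberg FDR before thresholding.
#' @return data.frame (class `edge_list`) with columns asv_a, asv_b (a < b),
#'   rho, p, sign.
#' @export
threshold_edges <- function(rho, p, rho_threshold = 0.7, p_threshold = 0.05,
                            adjust_p = FALSE) {
  stopifnot(is.matrix(rho), is.matrix(p), all(dim(rho) == dim(p)))
  ids <- colnames(rho)
  ut <- upper.tri(rho)
  pv <- p[ut]
  if (adjust_p) pv <- stats::p.adjust(pv, method = "BH")
  keep <- which(!is.na(rho[ut]) & !is.na(pv) &
                  abs(rho[ut]) > rho_threshold & pv < p_threshold)
  idx <- which(ut, arr.ind = TRUE)[keep, , drop = FALSE]
  edges <- data.frame(
    asv_a = ids[idx[, 1]],
    asv_b = ids[idx[, 2]],
    rho = rho[ut][keep],
    p = pv[keep],
    sign = ifelse(rho[ut][keep] > 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  # canonical order asv_a < asv_b, stable row order
  swap <- edges$asv_a > edges$asv_b
  tmp <- edges$asv_a[swap]
  edges$asv_a[swap] <- edges$asv_b[swap]
  edges$asv_b[swap] <- tmp
  edges <- edges[order(edges$asv_a, edges$asv_b), , drop = FALSE]
  rownames(edges) <- NULL
  class(edges) <- c("edge_list", "data.frame")
  edges
}

#' Build an igraph co-occurrence network from an edge list
#'
#' Returns a simple undirected igraph graph whose vertices are the ASVs
#' incident to at least one edge (isolated ASVs never enter the network).
#' Edge attributes `rho`, `p` and `sign` are carried over; the graph itself
#' is treated as unweighted by all topology code.
#'
#' @param edges an edge list from [threshold_edges()].
#' @param node_attrs optional data.frame with an `asv` column plus attribute
#'   columns (e.g. taxonomy) to attach to vertices.
#' @return an igraph object (possibly with 0 vertices for an empty edge list).
#' @export
build_network <- function(edges, node_attrs = NULL) {
  if (nrow(edges) == 0) {
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  }
  nodes <- sort(unique(c(edges$asv_a, edges$asv_b)))
  vdf <- data.frame(name = nodes, stringsAsFactors = FALSE)
  if (!is.null(node_attrs)) {
    stopifnot("asv" %in% names(node_attrs))
    m <- match(nodes, node_attrs$asv)
    for (col in setdiff(names(node_attrs), "asv")) {
      vdf[[col]] <- node_attrs[[col]][m]
    }
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("asv_a", "asv_b", "rho", "p", "sign")],
    directed = FALSE, vertices = vdf)
  if (igraph::any_multiple(g) || any(igraph::which_loop(g))) {
    stop("edge list is not simple (loops or duplicate pairs)")
  }
  g
}

#' Export a network as GraphML or an edge-list CSV
#'
#' GraphML output is Gephi-ingestible; the CSV has columns
#' source,target,rho,p,sign.
#'
#' @param net igraph network.
#' @param path output file.
#' @param format `"graphml"` or `"csv"`.
#' @export
export_network <- function(net, path, format = c("graphml", "csv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    df <- igraph::as_data_frame(net, what = "edges")
    names(df)[1:2] <- c("source", "target")
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
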