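#' Build a genus co-occurrence network for one tissue group
#'
#' Nodes are genera passing within-group prevalence and mean relative
#' abundance filters; edges connect genus pairs whose Spearman correlation
#' satisfies `|rho| >= rho_min` and `p < p_max` (two-sided t-approximation).
#' Correlations are computed on within-group relative abundances; being
#' rank-based, they are unchanged by any per-sample rescaling. Edge p-values
#' are used raw (no multiplicity correction), matching the conventional
#' thresholded co-occurrence construction.
#'
#' @param table counts-scale (or relative) genus [feature_table()] containing
#'   the group's samples.
#' @param group_samples sample ids of the group (>= 5).
#' @param rho_min minimum absolute Spearman correlation for an edge.
#' @param p_max maximum two-sided p-value for an edge.
#' @param min_prevalence within-group presence fraction a node must reach.
#' @param min_mean_abund minimum within-group mean relative abundance.
#' @param group group label stored on the network (e.g. `"LUAD"`).
#' @return list of class `co_network`: `nodes` (data.frame `node`,
#'   `prevalence`, `mean_abundance`), `edges` (data.frame `node1`, `node2`,
#'   `rho`, `p`, `sign`), `group`, `params`.
#' @export
build_network <- function(table, group_samples, rho_min = 0.7, p_max = 0.05,
                          min_prevalence = 0.2, min_mean_abund = 0,
                          group = NA_character_) {
  stopifnot(inherits(table, "feature_table"))
  if (length(group_samples) < 5L)
    stop("need at least 5 samples in the group", call. = FALSE)
  sub <- ft_subset(table, samples = group_samples)
  m <- ft_matrix(sub)
  tot <- rowSums(m)
  if (any(tot <= 0))
    stop("zero-total sample: ", rownames(m)[which(tot <= 0)[1L]], call. = FALSE)
  rel <- m / tot
  prev <- colMeans(m > 0)
  mean_ab <- colMeans(rel)
  keep <- prev >= min_prevalence & mean_ab >= min_mean_abund
  rel <- rel[, keep, drop = FALSE]
  nodes <- data.frame(node = colnames(rel), prevalence = unname(prev[keep]),
                      mean_abundance = unname(mean_ab[keep]),
                      stringsAsFactors = FALSE)
  edges <- data.frame(node1 = character(0), node2 = character(0),
                      rho = numeric(0), p = numeric(0), sign = character(0),
                      stringsAsFactors = FALSE)
  if (ncol(rel) >= 2L) {
    sm <- spearman_matrix(rel)
    idx <- which(upper.tri(sm$rho), arr.ind = TRUE)
    rho <- sm$rho[idx]; p <- sm$p[idx]
    pass <- !is.na(rho) & abs(rho) >= rho_min & p < p_max
    if (any(pass)) {
      edges <- data.frame(node1 = colnames(rel)[idx[pass, 1L]],
                          node2 = colnames(rel)[idx[pass, 2L]],
                          rho = rho[pass], p = p[pass],
                          sign = ifelse(rho[pass] >= 0, "positive", "negative"),
                          stringsAsFactors = FALSE)
    }
  }
  structure(list(nodes = nodes, edges = edges, group = group,
                 params = list(rho_min = rho_min, p_max = p_max,
                               min_prevalence = min_prevalence,
                               min_mean_abund = min_mean_abund)),
            class = "co_network")
}

#' @export
print.co_network <- function(x, ...) {
  cat(sprintf("<co_network> group=%s: %d nodes, %d edges\n",
              x$group, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

# igraph view of a co_network (isolated nodes kept).
as_network_graph <- function(net) {
  stopifnot(inherits(net, "co_network"))
  igraph::graph_from_data_frame(net$edges[, c("node1", "node2"), drop = FALSE],
                                directed = FALSE, vertices = net$nodes$node)
}

#' Global topology metrics of a co-occurrence network
#'
#' `density = 2E / (N (N - 1))`, `mean_degree = 2E / N`, and the clustering
#' coefficient as the mean local clustering over nodes, where nodes of degree
#' < 2 contribute 0. A single-node (or empty) network has density 0.
#'
#' @param net a `co_network`.
#' @return list with `density`, `mean_degree`, `clustering_coefficient`,
#'   `n_nodes`, `n_edges`.
#' @export
topology_metrics <- function(net) {
  stopifnot(inherits(net, "co_network"))
  n <- nrow(net$nodes); e <- nrow(net$edges)
  if (n < 1L) stop("network has no nodes", call. = FALSE)
  dens <- if (n < 2L) 0 else 2 * e / (n * (n - 1))
  mean_deg <- if (n < 1L) 0 else 2 * e / n
  clust <- 0
  if (e > 0) {
    g <- as_network_graph(net)
    local <- igraph::transitivity(g, type = "local", isolates = "zero")
    local[!is.finite(local)] <- 0
    clust <- mean(local)
  }
  list(density = dens, mean_degree = mean_deg, clustering_coefficient = clust,
       n_nodes = n, n_edges = e)
}

#' Node centralities of a co-occurrence network
#'
#' Degree centrality `deg / (N - 1)`, harmonic closeness centrality
#' normalized by `N - 1` (finite on disconnected graphs), and normalized
#' shortest-path betweenness with unit edge weights.
#'
#' @param net a `co_network`.
#' @return data.frame `node`, `degree_centrality`, `closeness_centrality`,
#'   `betweenness_centrality`.
#' @export
centralities <- function(net) {
  stopifnot(inherits(net, "co_network"))
  g <- as_network_graph(net)
  n <- igraph::vcount(g)
  if (n == 0L)
    return(data.frame(node = character(0), degree_centrality = numeric(0),
                      closeness_centrality = numeric(0),
                      betweenness_centrality = numeric(0)))
  dc <- if (n > 1L) igraph::degree(g) / (n - 1) else rep(0, n)
  cc <- if (n > 1L) igraph::harmonic_centrality(g, normalized = TRUE)
        else rep(0, n)
  bc <- if (n > 2L) igraph::betweenness(g, directed = FALSE, normalized = TRUE)
        else rep(0, n)
  data.frame(node = igraph::V(g)$name,
             degree_centrality = unname(dc),
             closeness_centrality = unname(cc),
             betweenness_centrality = unname(bc),
             stringsAsFactors = FALSE)
}

#' Bootstrap-stable core nodes of a group's network
#'
#' Per iteration: cluster-bootstrap the group's patients, rebuild the network
#' from the resampled samples with identical filters and thresholds, and rank
#' nodes by a composite centrality (mean of the degree- and closeness-
#' centrality ranks). A node's stability is the fraction of iterations in
#' which it ranks in the top `top_k`; the stable set is every node with
#' stability at least `stability_min`. Iterations producing an empty network
#' contribute no top-k nodes (counted and reported).
#'
#' @param table counts-scale genus [feature_table()].
#' @param metadata cohort metadata.
#' @param group tissue group (`"LUAD"` or `"NC"`).
#' @param n_bootstrap,top_k,stability_min bootstrap iterations, rank cutoff
#'   and stability threshold.
#' @param seed RNG seed.
#' @param ... filters passed to [build_network()] (`rho_min`, `p_max`,
#'   `min_prevalence`, `min_mean_abund`).
#' @return list with `stable_nodes`, `stability` (named per-node fraction),
#'   `n_empty` (iterations with an empty network), and the parameters used.
#' @export
bootstrap_stable_nodes <- function(table, metadata, group, n_bootstrap = 500,
                                   top_k = 10, stability_min = 0.6, seed = 1,
                                   ...) {
  stopifnot(inherits(table, "feature_table"))
  metadata <- align_metadata(table, metadata)
  gs <- metadata$sample_id[metadata$tissue == group]
  gp <- metadata$patient_id[metadata$tissue == group]
  if (length(unique(gp)) < 5L)
    stop("group has fewer than 5 patients", call. = FALSE)
  draws <- cluster_bootstrap(gp, n_bootstrap, seed = seed)
  feats <- ft_features(table)
  in_top <- stats::setNames(numeric(length(feats)), feats)
  n_empty <- 0L
  for (draw in draws) {
    idx <- unlist(lapply(draw, function(p) which(gp == p)), use.names = FALSE)
    sub <- ft_matrix(table)[gs[idx], , drop = FALSE]
    rownames(sub) <- sprintf("bs%04d", seq_len(nrow(sub))) # duplicates kept
    net <- tryCatch(
      build_network(feature_table(sub, scale = table$scale),
                    group_samples = rownames(sub), group = group, ...),
      error = function(e) NULL)
    if (is.null(net) || nrow(net$edges) == 0L) { n_empty <- n_empty + 1L; next }
    ct <- centralities(net)
    # larger centrality = better rank; composite = mean of the two rank lists
    comp <- (rank(-ct$degree_centrality, ties.method = "average") +
             rank(-ct$closeness_centrality, ties.method = "average")) / 2
    top <- ct$node[order(comp)][seq_len(min(top_k, nrow(ct)))]
    in_top[top] <- in_top[top] + 1
  }
  if (n_empty > 0)
    p16_log("bootstrap_stable_nodes: %d iteration(s) yielded an empty network",
            n_empty)
  stability <- in_top / n_bootstrap
  list(stable_nodes = names(stability)[stability >= stability_min],
       stability = stability, n_empty = n_empty,
       params = list(n_bootstrap = n_bootstrap, top_k = top_k,
                     stability_min = stability_min, group = group))
}
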