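# Graph-theoretic comparison of the node set defined by the
# group-difference clusters: per-subject bivariate-correlation networks,
# cost thresholding (the cost fixes the edge count, hence the average
# degree), six unweighted graph metrics, and one-sided group tests across
# costs. Shortest-path machinery comes from igraph; the metric
# conventions layered on top are: efficiency uses 1/Inf = 0, average path
# length is taken over connected pairs only, betweenness is normalised by
# (n-1)(n-2)/2 per node, and nodes with fewer than 2 neighbours
# contribute 0 to local efficiency and clustering.

#' Correlation network over a set of node masks
#'
#' Node time series are the conditioned mean series over each cluster mask
#' (connectivity-pathway conditioning); the network is their pairwise
#' Pearson correlation matrix.
#'
#' @param bold a [bold_image()]
#' @param nodes list of >= 3 nonempty masks
#' @param motion,wm_mask,csf_mask,spec,c_mult conditioning controls, as in
#'   [extract_seed_series()]
#' @param condition set `FALSE` to use raw mean series
#' @param subject_id optional identifier carried into metric rows
#' @return object of class `corr_network`: `C` (n x n correlation matrix),
#'   `n_nodes`, `subject_id`
#' @export
build_network <- function(bold, nodes, motion = NULL, wm_mask = NULL,
                          csf_mask = NULL, spec = NULL, c_mult = 3,
                          condition = TRUE, subject_id = NA_character_) {
  if (length(nodes) < 3) stop_acf("build_network: need at least 3 nodes")
  series <- vapply(seq_along(nodes), function(i) {
    s <- extract_seed_series(bold, nodes[[i]], motion = motion,
                             wm_mask = wm_mask, csf_mask = csf_mask,
                             spec = spec, c_mult = c_mult,
                             condition = condition)
    if (sd(s) == 0) stop_acf("build_network: node ", i, " has a constant series")
    s
  }, numeric(bold$n_volumes))
  C <- cor(series)
  diag(C) <- 1
  structure(list(C = C, n_nodes = length(nodes), subject_id = subject_id),
            class = "corr_network")
}

#' Threshold a correlation network at a connection cost
#'
#' Keeps the `K = round(cost * n(n-1)/2)` largest off-diagonal
#' correlations as unweighted edges. Ranking is by signed correlation
#' value (the strongest positive couplings survive, the usual
#' resting-state convention; set `absolute = TRUE` to rank by magnitude);
#' ties are broken by lexicographic node-pair order so the edge set is
#' deterministic.
#'
#' @param net a [build_network()] result (or a bare correlation matrix)
#' @param cost fraction of possible edges kept, in (0, 1)
#' @param absolute rank by `|r|` instead of signed `r`
#' @return object of class `cost_graph`: binary symmetric `adjacency`,
#'   `cost`, `edge_count`
#' @export
threshold_by_cost <- function(net, cost, absolute = FALSE) {
  C <- if (inherits(net, "corr_network")) net$C else as.matrix(net)
  n <- nrow(C)
  if (!(cost > 0 && cost <= 1)) stop_acf("threshold_by_cost: cost must be in (0, 1]")
  npairs <- n * (n - 1) / 2
  K <- round(cost * npairs)
  if (K < 1) stop_acf("threshold_by_cost: cost too small, no edges retained")
  ut <- which(upper.tri(C), arr.ind = TRUE)
  vals <- C[ut]
  rank_vals <- if (absolute) abs(vals) else vals
  ord <- order(-rank_vals, ut[, 1], ut[, 2])
  keep <- ord[seq_len(min(K, npairs))]
  A <- matrix(0L, n, n)
  A[ut[keep, , drop = FALSE]] <- 1L
  A <- A + t(A)
  structure(list(adjacency = A, cost = cost, edge_count = length(keep)),
            class = "cost_graph")
}

#' Six graph metrics of a binarised network
#'
#' Unweighted, undirected metrics: global efficiency (mean inverse
#' shortest-path length over ordered pairs, `1/Inf = 0`), local
#' efficiency (mean over nodes of the global efficiency of the node's
#' neighbour-induced subgraph; 0 for < 2 neighbours), mean betweenness
#' centrality (normalised by `(n-1)(n-2)/2`), average path length over
#' connected pairs, mean clustering coefficient (triangle ratio, 0 for
#' degree < 2), and mean degree.
#'
#' @param g a [threshold_by_cost()] result (or a binary adjacency matrix)
#' @param subject_id,cost optional identifiers carried into the row
#' @return one-row data.frame with the six metrics
#' @export
graph_metrics <- function(g, subject_id = NULL, cost = NULL) {
  A <- if (inherits(g, "cost_graph")) g$adjacency else as.matrix(g)
  if (inherits(g, "cost_graph") && is.null(cost)) cost <- g$cost
  n <- nrow(A)
  ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  D <- igraph::distances(ig)
  off <- upper.tri(D)
  dvals <- D[off]
  inv <- ifelse(is.finite(dvals), 1 / dvals, 0)
  global_eff <- mean(inv)
  path_length <- if (any(is.finite(dvals))) mean(dvals[is.finite(dvals)]) else NA_real_
  betw <- mean(igraph::betweenness(ig, normalized = TRUE))
  clust <- mean(igraph::transitivity(ig, type = "localundirected",
                                     isolates = "zero"))
  deg <- igraph::degree(ig)
  local_eff <- mean(vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) return(0)
    Dn <- igraph::distances(igraph::induced_subgraph(ig, nb))
    offn <- upper.tri(Dn)
    mean(ifelse(is.finite(Dn[offn]), 1 / Dn[offn], 0))
  }, numeric(1)))
  out <- data.frame(global_efficiency = global_eff,
                    local_efficiency = local_eff,
                    betweenness = betw,
                    path_length = path_length,
                    clustering = clust,
                    degree = mean(deg))
  if (!is.null(cost)) out <- cbind(data.frame(cost = cost), out)
  if (!is.null(subject_id)) out <- cbind(data.frame(subject_id = subject_id), out)
  out
}

#' Per-subject metric table across a cost grid
#'
#' @param net a [build_network()] result
#' @param costs cost grid (default 0.10-0.30 in steps of 0.05)
#' @return data.frame, one row per cost
#' @export
metrics_across_costs <- function(net, costs = c(0.10, 0.15, 0.20, 0.25, 0.30)) {
  do.call(rbind, lapply(costs, function(cst)
    graph_metrics(threshold_by_cost(net, cst),
                  subject_id = net$subject_id, cost = cst)))
}

#' Group comparison of a graph metric across costs
#'
#' One-sided two-sample t-test of the network-level metric at each cost.
#' The default alternative is patients < controls (the direction of a less
#' efficient patient network).
#'
#' @param rows_patients,rows_controls metric tables from
#'   [metrics_across_costs()] (stacked over subjects)
#' @param metric column name, e.g. `"global_efficiency"`
#' @param costs costs to test; every requested cost must be present in
#'   both tables
#' @param direction `"g1_lt_g2"` (patients lower, default) or
#'   `"g1_gt_g2"`
#' @return data.frame of (cost, t, df, p)
#' @export
compare_groups_metric <- function(rows_patients, rows_controls, metric,
                                  costs = c(0.10, 0.15, 0.20, 0.25, 0.30),
                                  direction = c("g1_lt_g2", "g1_gt_g2")) {
  direction <- match.arg(direction)
  if (!metric %in% names(rows_patients))
    stop_acf("compare_groups_metric: unknown metric '", metric, "'")
  out <- lapply(costs, function(cst) {
    xp <- rows_patients[[metric]][abs(rows_patients$cost - cst) < 1e-9]
    xc <- rows_controls[[metric]][abs(rows_controls$cost - cst) < 1e-9]
    if (length(xp) < 2 || length(xc) < 2)
      stop_acf("compare_groups_metric: cost ", cst, " missing from the metric rows")
    tt <- t.test(xp, xc, var.equal = TRUE,
                 alternative = if (direction == "g1_lt_g2") "less" else "greater")
    data.frame(cost = cst, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
  })
  do.call(rbind, out)
}
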