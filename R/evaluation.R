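#' Induced four-graphlet counts
#'
#' Counts induced occurrences of the four undirected graphlets used to probe
#' higher-order structure: triangle, square (chordless 4-cycle), diamond
#' (4-cycle with one diagonal) and K4 (complete 4-clique).
#'
#' Counting is per-edge common-neighbour counting with algebraic corrections:
#' with codegrees `c_uv = |N(u) \cap N(v)|`,
#' triangles `= sum_edges c_uv / 3`; non-induced 4-cycles
#' `= sum_pairs choose(c_uv, 2) / 2`; non-induced diamonds
#' `= sum_edges choose(c_uv, 2)`; K4 `= sum_edges e(N(u) \cap N(v)) / 6`.
#' Every K4 contains 6 non-induced diamonds and 3 non-induced 4-cycles, and
#' every diamond contains 1 non-induced 4-cycle, giving the induced counts.
#'
#' @param net a [spatial_network()] (or 0/1 adjacency matrix).
#' @return named integer vector: `triangle`, `square`, `diamond`, `k4`.
#' @examples
#' # K4 contains 4 triangles and no induced square/diamond
#' A <- matrix(1, 4, 4); diag(A) <- 0
#' graphlet_counts(A)
#' @export
graphlet_counts <- function(net) {
  A <- if (inherits(net, "spatial_network")) adjacency_matrix(net)
       else as.matrix(net)
  n <- nrow(A)
  if (n < 3L || sum(A) == 0)
    return(c(triangle = 0L, square = 0L, diamond = 0L, k4 = 0L))
  C <- A %*% A                      # codegree matrix
  up <- upper.tri(A)
  tri <- sum((A * C)[up]) / 3
  cyc4_non <- sum(choose(C[up], 2)) / 2
  dia_non <- sum(choose((A * C)[up], 2))
  eidx <- which(A == 1 & up, arr.ind = TRUE)
  k4 <- 0
  if (nrow(eidx)) {
    nbr <- lapply(seq_len(n), function(i) which(A[i, ] == 1))
    for (r in seq_len(nrow(eidx))) {
      common <- intersect(nbr[[eidx[r, 1L]]], nbr[[eidx[r, 2L]]])
      if (length(common) >= 2L)
        k4 <- k4 + sum(A[common, common]) / 2
    }
    k4 <- k4 / 6
  }
  dia <- dia_non - 6 * k4
  sq <- cyc4_non - dia - 3 * k4
  c(triangle = as.integer(round(tri)), square = as.integer(round(sq)),
    diamond = as.integer(round(dia)), k4 = as.integer(round(k4)))
}

#' Standard network measures
#'
#' The battery of local and global measures used to compare models with
#' data: size of the largest connected component (LCC), diameter and average
#' shortest path on the LCC, global efficiency (mean of `1/delta_ij` over
#' all ordered pairs, 0 for disconnected pairs), local efficiency (mean over
#' nodes of the global efficiency of the neighbour-induced subgraph),
#' transitivity (3 x triangles / triplets) and average clustering
#' coefficient (nodes with degree < 2 contribute 0).
#'
#' @param net a [spatial_network()] or an `igraph` graph.
#' @return named list of measures.
#' @export
network_measures <- function(net) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  if (n == 0L) stop("empty graph")
  comp <- igraph::components(g)
  lcc_id <- which.max(comp$csize)
  lcc <- igraph::induced_subgraph(g, which(comp$membership == lcc_id))
  Dl <- igraph::distances(lcc)
  nl <- nrow(Dl)
  avg_sp <- if (nl > 1L) mean(Dl[upper.tri(Dl)]) else 0
  diam <- if (nl > 1L) max(Dl) else 0
  Dg <- igraph::distances(g)
  inv <- 1 / Dg
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  e_glob <- if (n > 1L) sum(inv) / (n * (n - 1)) else 0
  e_loc <- mean(vapply(seq_len(n), function(i) {
    nb <- as.integer(igraph::neighbors(g, i))
    if (length(nb) < 2L) return(0)
    sub <- igraph::induced_subgraph(g, nb)
    Ds <- igraph::distances(sub)
    iv <- 1 / Ds; iv[!is.finite(iv)] <- 0; diag(iv) <- 0
    sum(iv) / (length(nb) * (length(nb) - 1))
  }, numeric(1)))
  trans <- igraph::transitivity(g, type = "global")
  if (is.nan(trans)) trans <- 0
  ci <- igraph::transitivity(g, type = "local", isolates = "zero")
  list(lcc_size = max(comp$csize), diameter = diam,
       avg_shortest_path = avg_sp, E_global = e_glob, E_local = e_loc,
       transitivity = trans, avg_clustering = mean(ci))
}

as_igraph <- function(net) {
  if (inherits(net, "igraph")) return(net)
  stopifnot(inherits(net, "spatial_network"))
  igraph::graph_from_edgelist(net$edge_idx, directed = FALSE) |>
    (\(g) igraph::add_vertices(g, max(0L, n_nodes(net) -
                                        igraph::vcount(g))))()
}

#' Degree-distribution summary statistics
#'
#' Mean, median, mean-to-median ratio and interquartile range of a degree
#' sequence over all nodes (including isolated ones, so the mean equals
#' `2E/N`). Quartiles use linear interpolation (type 7).
#'
#' @param degrees integer degree vector.
#' @return named list: `mean`, `median`, `mean_over_median`, `iqr`.
#' @export
degree_stats <- function(degrees) {
  stopifnot(length(degrees) >= 1L)
  m <- mean(degrees); md <- stats::median(degrees)
  list(mean = m, median = md,
       mean_over_median = if (md != 0) m / md else NA_real_,
       iqr = unname(diff(stats::quantile(degrees, c(0.25, 0.75), type = 7))))
}

#' Wiring-length optimality via node-position shuffling
#'
#' Permutes the position-to-node assignment uniformly while keeping the
#' topology intact and compares the resulting wiring lengths with the
#' observed one. Optimally placed nodes give an observed length far below
#' the shuffled distribution. The one-sided permutation p-value (observed
#' shorter than shuffled) uses add-one smoothing:
#' `p = (#\{L_perm <= L_obs\} + 1) / (n_perm + 1)`.
#'
#' @param net a [spatial_network()] with positions.
#' @param n_perm number of shuffles.
#' @param seed integer RNG seed.
#' @return list: `L_obs`, `ratio_mean` (mean shuffled L over observed L),
#'   `p_value`, `L_perm` (vector of shuffled lengths).
#' @export
wiring_shuffle_test <- function(net, n_perm = 1000L, seed = 1L) {
  stopifnot(n_perm >= 1L)
  L_obs <- wiring_length(net)
  pos <- node_positions(net)
  n <- nrow(pos)
  ei <- net$edge_idx
  set.seed(seed)
  L_perm <- vapply(seq_len(n_perm), function(r) {
    perm <- sample.int(n)
    dd <- pos[perm[ei[, 1L]], , drop = FALSE] -
      pos[perm[ei[, 2L]], , drop = FALSE]
    sum(sqrt(rowSums(dd * dd)))
  }, numeric(1))
  list(L_obs = L_obs, ratio_mean = mean(L_perm) / L_obs,
       p_value = (sum(L_perm <= L_obs) + 1) / (n_perm + 1),
       L_perm = L_perm)
}

#' ROC and precision-recall curves for edge classification
#'
#' Scores candidate pairs (e.g. model edge probabilities) against 0/1 labels
#' (e.g. presence of a synapse or a contact). The ROC curve sweeps the
#' threshold over tied score groups; its AUC is the trapezoidal area. The
#' precision-recall AUC is step-interpolated average precision,
#' `sum (R_k - R_{k-1}) P_k`, the robust summary under severe class
#' imbalance.
#'
#' @param scores numeric score per candidate pair (higher = more likely
#'   positive).
#' @param labels 0/1 (or logical) truth per pair; both classes must occur.
#' @return list: `roc` (data frame `fpr`, `tpr`), `auc_roc`, `pr` (data
#'   frame `recall`, `precision`), `auc_pr`.
#' @export
edge_classification_curves <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0L || N == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp_last <- which(!duplicated(s, fromLast = TRUE))  # end of each tie group
  tp <- cumsum(y)[grp_last]
  fp <- cumsum(1L - y)[grp_last]
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  auc_roc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  prec <- tp / (tp + fp)
  rec <- tp / P
  auc_pr <- sum(diff(c(0, rec)) * prec)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc_roc = auc_roc,
       pr = data.frame(recall = rec, precision = prec), auc_pr = auc_pr)
}

#' Spearman correlation between edge probabilities and synaptic weights
#'
#' Rank correlation (average ranks on ties, two-sided large-sample p-value)
#' between model edge probabilities and synapse counts, either over all
#' scored pairs or restricted to connectome edges.
#'
#' @param p numeric edge probabilities.
#' @param w numeric weights (same length).
#' @return list `r_s`, `p_value`, `n`; both `NA` (with a note) when either
#'   vector is constant.
#' @export
weight_correlation <- function(p, w) {
  stopifnot(length(p) == length(w))
  if (length(p) < 3L) stop("need at least 3 pairs")
  if (stats::sd(p) == 0 || stats::sd(w) == 0)
    return(list(r_s = NA_real_, p_value = NA_real_, n = length(p),
                note = "undefined: constant input"))
  ct <- suppressWarnings(
    stats::cor.test(p, w, method = "spearman", exact = FALSE))
  list(r_s = unname(ct$estimate), p_value = ct$p.value, n = length(p))
}

#' Compare a data statistic against an ensemble of model realizations
#'
#' Summarises how a statistic computed on data sits within its model
#' ensemble distribution: inverse fold change (model mean / data value),
#' z-score and two-sided normal p-value with conventional significance
#' stars.
#'
#' @param data_value statistic on the observed network.
#' @param model_values statistic per model realization (>= 2 values).
#' @param stat_name label.
#' @return object of class `ensemble_comparison`.
#' @export
ensemble_compare <- function(data_value, model_values, stat_name = "stat") {
  stopifnot(length(model_values) >= 2L)
  mu <- mean(model_values); sdv <- stats::sd(model_values)
  if (sdv == 0) {
    z <- if (data_value == mu) 0 else NA_real_
    p <- if (data_value == mu) 1 else NA_real_
  } else {
    z <- (data_value - mu) / sdv
    p <- 2 * (1 - stats::pnorm(abs(z)))
  }
  stars <- if (is.na(p)) "undefined"
           else if (p < 0.001) "***" else if (p < 0.01) "**"
           else if (p < 0.05) "*" else "n.s."
  structure(list(stat_name = stat_name, data_value = data_value,
                 model_mean = mu, model_sd = sdv,
                 inverse_fold_change = mu / data_value,
                 z = z, p_two_sided = p, significance = stars),
            class = "ensemble_comparison")
}

#' @export
print.ensemble_comparison <- function(x, ...) {
  cat(x$stat_name, ": data ", signif(x$data_value, 5), ", model ",
      signif(x$model_mean, 5), " +/- ", signif(x$model_sd, 4),
      " (inv. fold change ", signif(x$inverse_fold_change, 4), ", z = ",
      signif(x$z, 3), ", p = ", signif(x$p_two_sided, 3), " ",
      x$significance, ")\n", sep = "")
  invisible(x)
}
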