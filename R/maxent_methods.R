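#' Edge probabilities of a fitted ensemble
#'
#' Returns the independent Bernoulli edge probabilities `p_ij` implied by a
#' fitted ensemble, either for specific node pairs or for every allowed pair.
#' Probabilities are symmetric in the pair, zero on the diagonal, and exactly
#' zero outside the contactome for hard-constrained models. For the binned
#' distance models, a pair whose distance falls beyond the last fitted bin is
#' scored with the last bin's probability (with a warning).
#'
#' @param object a fitted [fit_maxent()] ensemble.
#' @param pairs either `NULL` (all allowed pairs) or a 2-column matrix/data
#'   frame of node ids (or integer node indices).
#' @param ... unused.
#' @return When `pairs` is `NULL`: a data frame `i`, `j` (node indices,
#'   `i < j`), `p`, covering all pairs (hard-constrained models list only
#'   contact pairs; probabilities elsewhere are identically zero). Otherwise
#'   a numeric vector of probabilities aligned with the rows of `pairs`.
#' @export
predict.maxent_ensemble <- function(object, pairs = NULL, ...) {
  net <- object$network
  n <- n_nodes(net)
  if (is.null(pairs)) {
    idx <- if (!is.null(object$mask)) object$mask else all_pairs_index(n)
    return(data.frame(i = idx[, 1L], j = idx[, 2L],
                      p = pair_probability(object, idx)))
  }
  pairs <- as.data.frame(pairs)
  i <- resolve_node(pairs[[1L]], net)
  j <- resolve_node(pairs[[2L]], net)
  if (any(i == j)) stop("self pairs have no edge probability (p_ii = 0)")
  idx <- cbind(pmin(i, j), pmax(i, j))
  pair_probability(object, idx)
}

resolve_node <- function(v, net) {
  if (is.numeric(v) && all(v == round(v)) && all(v >= 1) &&
      all(v <= n_nodes(net)) && !any(as.character(v) %in% node_ids(net)))
    return(as.integer(v))
  i <- match(as.character(v), node_ids(net))
  if (anyNA(i))
    stop("unknown node id(s): ",
         paste(unique(as.character(v)[is.na(i)]), collapse = ", "))
  i
}

all_pairs_index <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2L:n)
  cbind(i, j)
}

pair_probability <- function(object, idx) {
  model <- object$model
  net <- object$network
  p <- numeric(nrow(idx))
  in_mask <- if (is.null(object$mask)) rep(TRUE, nrow(idx))
             else edge_keys(idx) %in% edge_keys(object$mask)
  use <- in_mask
  if (model %in% c("k", "k+c")) {
    m <- object$y[idx[, 1L]] * object$y[idx[, 2L]]
    p[use] <- (m / (1 + m))[use]
  } else if (model == "k+L") {
    pos <- node_positions(net)
    dd <- pos[idx[, 1L], , drop = FALSE] - pos[idx[, 2L], , drop = FALSE]
    d <- sqrt(rowSums(dd * dd))
    m <- object$y[idx[, 1L]] * object$y[idx[, 2L]] * exp(-d / object$d0)
    p <- m / (1 + m)
  } else if (model %in% c("d", "d+c")) {
    pos <- node_positions(net)
    dd <- pos[idx[, 1L], , drop = FALSE] - pos[idx[, 2L], , drop = FALSE]
    d <- sqrt(rowSums(dd * dd))
    bt <- object$bin_table
    if (any(d[use] > bt$bin_hi[nrow(bt)] * (1 + 1e-9) + 1e-12))
      warning("pair distance(s) beyond the last fitted bin; ",
              "scored with the last bin's probability")
    b <- bin_assign(d, c(bt$bin_lo, bt$bin_hi[nrow(bt)]))
    p[use] <- bt$p[b][use]
  } else if (model == "c") {
    p[use] <- object$p_uniform
  }
  p[idx[, 1L] == idx[, 2L]] <- 0
  p
}

#' Sample network realizations from a fitted ensemble
#'
#' Edge probabilities are independent, so a realization is drawn by flipping
#' one Bernoulli coin per allowed pair. Realization `r` uses RNG seed
#' `seed + r`, so any prefix of a longer run is reproducible.
#'
#' @param object a fitted [fit_maxent()] ensemble.
#' @param nsim number of realizations (default 100).
#' @param seed integer base seed (required for reproducibility).
#' @param ... unused.
#' @return list of `nsim` two-column integer matrices of edge node indices
#'   (`i < j`), each with attribute `ids` giving the node-id vector.
#' @export
simulate.maxent_ensemble <- function(object, nsim = 100L, seed = 1L, ...) {
  pr <- predict(object)
  ids <- node_ids(object$network)
  lapply(seq_len(nsim), function(r) {
    set.seed(seed + r)
    keep <- stats::runif(nrow(pr)) < pr$p
    out <- cbind(i = pr$i[keep], j = pr$j[keep])
    attr(out, "ids") <- ids
    out
  })
}

#' Realization as a spatial_network on the fitted node table
#' @param object fitted ensemble
#' @param realization one element of [simulate.maxent_ensemble()]'s output
#' @export
realization_network <- function(object, realization) {
  net <- object$network
  out <- net
  out$edge_idx <- realization[, 1:2, drop = FALSE]
  storage.mode(out$edge_idx) <- "integer"
  dimnames(out$edge_idx) <- NULL
  out$weight <- NULL
  out
}

#' Log-likelihood of an observed network under a fitted ensemble
#'
#' `sum(log p_ij)` over observed edges plus `sum(log(1 - p_ij))` over allowed
#' non-edges. An observed edge with `p_ij = 0` (e.g. outside the hard contact
#' mask) gives `-Inf`; the offending pairs are attached as attribute
#' `"offending_pairs"`.
#'
#' @param object fitted [fit_maxent()] ensemble.
#' @param observed `spatial_network` on the same node set; defaults to the
#'   network the ensemble was fitted to.
#' @param ... unused.
#' @return a `logLik` object (`df` = number of fitted parameters).
#' @export
logLik.maxent_ensemble <- function(object, observed = object$network, ...) {
  if (!identical(node_ids(observed), node_ids(object$network)))
    stop("observed network must share the fitted node set")
  pr <- predict(object)
  obs_keys <- edge_keys(observed$edge_idx)
  pr_keys <- paste(pr$i, pr$j, sep = "-")
  is_edge <- pr_keys %in% obs_keys
  # edges outside the allowed pair set (hard mask) have p = 0
  off <- character(0)
  ll_edges <- sum(log(pr$p[is_edge]))
  bad <- is_edge & pr$p == 0
  if (!is.null(object$mask)) {
    missing_edge <- !(obs_keys %in% pr_keys)
    if (any(missing_edge)) {
      off <- c(off, obs_keys[missing_edge])
      ll_edges <- -Inf
    }
  }
  if (any(bad)) {
    off <- c(off, pr_keys[bad])
    ll_edges <- -Inf
  }
  ll_non <- sum(log1p(-pr$p[!is_edge]))
  df <- switch(object$model,
               "k" = , "k+c" = sum(object$k_star > 0),
               "k+L" = sum(object$k_star > 0) + 1L,
               "d" = , "d+c" = nrow(object$bin_table),
               "c" = 1L)
  structure(ll_edges + ll_non, df = df, nobs = nrow(pr),
            offending_pairs = off, class = "logLik")
}

#' @export
coef.maxent_ensemble <- function(object, ...) {
  ids <- node_ids(object$network)
  switch(object$model,
    "k" = , "k+c" = stats::setNames(-log(object$y), ids),
    "k+L" = c(stats::setNames(-log(object$y), ids), d0 = object$d0),
    "d" = , "d+c" = stats::setNames(object$bin_table$p,
                      sprintf("p[%.3g,%.3g)", object$bin_table$bin_lo,
                              object$bin_table$bin_hi)),
    "c" = c(p_uniform = object$p_uniform))
}

#' Expected degrees of a fitted ensemble
#' @param object fitted ensemble
#' @return numeric vector, `<k_i> = sum_j p_ij`, in node order.
#' @export
expected_degree <- function(object) {
  pr <- predict(object)
  n <- n_nodes(object$network)
  ke <- numeric(n)
  acc <- rowsum(c(pr$p, pr$p), c(pr$i, pr$j))
  ke[as.integer(rownames(acc))] <- acc[, 1L]
  ke
}

#' Expected total number of edges and expected wiring length
#' @param object fitted ensemble
#' @export
expected_edge_count <- function(object) sum(predict(object)$p)

#' @rdname expected_edge_count
#' @export
expected_wiring_length <- function(object) {
  pr <- predict(object)
  pos <- node_positions(object$network)
  dd <- pos[pr$i, , drop = FALSE] - pos[pr$j, , drop = FALSE]
  sum(pr$p * sqrt(rowSums(dd * dd)))
}

#' @export
residuals.maxent_ensemble <- function(object, ...) {
  degree_sequence(object$network) - expected_degree(object)
}

#' @export
print.maxent_ensemble <- function(x, ...) {
  cat("<maxent_ensemble> model '", x$model, "', ",
      n_nodes(x$network), " nodes\n", sep = "")
  if (!is.null(x$y))
    cat("  degree residual: ", signif(x$residual, 3),
        " (", x$iterations, " iterations)\n", sep = "")
  if (!is.null(x$d0)) cat("  d0: ", signif(x$d0, 6), " soma sizes\n", sep = "")
  if (!is.null(x$p_uniform))
    cat("  uniform contact p: ", signif(x$p_uniform, 6), "\n", sep = "")
  if (!is.null(x$bin_table))
    cat("  distance bins: ", nrow(x$bin_table), "\n", sep = "")
  if (!is.null(x$mask)) cat("  hard contact mask: ", nrow(x$mask),
                            " allowed pairs\n", sep = "")
  invisible(x)
}

#' @export
summary.maxent_ensemble <- function(object, ...) {
  out <- list(
    model = object$model,
    n_nodes = n_nodes(object$network),
    observed_edges = n_edges(object$network),
    expected_edges = expected_edge_count(object),
    expected_L = expected_wiring_length(object),
    observed_L = wiring_length(object$network),
    d0 = object$d0,
    boundary_nodes = if (!is.null(object$boundary)) sum(object$boundary)
                     else 0L,
    max_abs_degree_residual = max(abs(residuals(object))))
  class(out) <- "summary.maxent_ensemble"
  out
}

#' @export
print.summary.maxent_ensemble <- function(x, ...) {
  cat("Maximum-entropy ensemble, model '", x$model, "'\n", sep = "")
  cat("  nodes: ", x$n_nodes, "\n", sep = "")
  cat("  edges: observed ", x$observed_edges, ", expected ",
      signif(x$expected_edges, 8), "\n", sep = "")
  cat("  wiring length: observed ", signif(x$observed_L, 6), ", expected ",
      signif(x$expected_L, 6), " soma sizes\n", sep = "")
  if (!is.null(x$d0)) cat("  d0: ", signif(x$d0, 6), " soma sizes\n", sep = "")
  if (x$boundary_nodes > 0)
    cat("  boundary nodes (p -> 1 pairs): ", x$boundary_nodes, "\n", sep = "")
  cat("  max |k_obs - <k>|: ", signif(x$max_abs_degree_residual, 3), "\n",
      sep = "")
  invisible(x)
}

#' Plot observed vs model distance dependence
#'
#' Binned connection probability against pair distance for the observed
#' network (points) and the ensemble expectation (line), on a log-linear
#' scale where exponential decay is a straight line.
#'
#' @param x fitted ensemble
#' @param n_bins number of linear distance bins
#' @param ... passed to [graphics::plot()]
#' @export
plot.maxent_ensemble <- function(x, n_bins = 50L, ...) {
  obs <- binned_connection_probability(x$network, n_bins = n_bins)
  pr <- predict(x)
  pos <- node_positions(x$network)
  dd <- pos[pr$i, , drop = FALSE] - pos[pr$j, , drop = FALSE]
  d <- sqrt(rowSums(dd * dd))
  b <- bin_assign(d, c(obs$bin_lo, obs$bin_hi[nrow(obs)]))
  pm <- vapply(seq_len(nrow(obs)), function(k) {
    if (any(b == k)) mean(pr$p[b == k]) else NA_real_
  }, numeric(1))
  keep <- obs$p > 0 & !is.na(pm) & pm > 0
  graphics::plot(obs$center[keep], obs$p[keep], log = "y",
                 xlab = "distance (soma sizes)",
                 ylab = "connection probability", pch = 16, ...)
  graphics::lines(obs$center[keep], pm[keep], col = "red3", lwd = 2)
  graphics::legend("topright", legend = c("observed", paste0("model ", x$model)),
                   pch = c(16, NA), lty = c(NA, 1), col = c("black", "red3"),
                   bty = "n")
  invisible(x)
}
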