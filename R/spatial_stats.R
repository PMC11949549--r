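#' Binned connection probability versus distance
#'
#' Splits pair distances into linear bins and, per bin, reports the fraction
#' of pairs connected by an edge: `p_b = n_edges_b / n_pairs_b`. Bins are
#' half-open `[lo, hi)` with the last bin closed, spanning `[0, max d]`.
#' With `restrict_to`, the denominator is restricted to the given pair set
#' (e.g. contactome edges), yielding the conditional connection probability
#' given contact.
#'
#' @param net a [spatial_network()] whose edges define connections.
#' @param n_bins number of linear bins (default 50).
#' @param restrict_to optional 2-column matrix of node-index pairs (or a
#'   `spatial_network` whose edges give the pair set) to condition on.
#' @param bin_edges optional explicit bin-edge vector (overrides `n_bins`),
#'   useful to align conditional and unconditional curves on common bins.
#' @return data frame `bin_lo`, `bin_hi`, `center`, `n_pairs`, `n_edges`,
#'   `p`.
#' @export
binned_connection_probability <- function(net, n_bins = 50L,
                                          restrict_to = NULL,
                                          bin_edges = NULL) {
  if (inherits(restrict_to, "spatial_network"))
    restrict_to <- restrict_to$edge_idx
  fit_distance_core(net, restrict_to, n_bins, bin_edges)$bin_table
}

#' Distance dependence of a spatial network
#'
#' Couples the binned connection-probability curve with the finite-size
#' cutoff `d_fs` of the sampled volume: beyond the mode of the all-pairs
#' distance histogram, the bounded experimental volume distorts the
#' empirical p(d), so decay fits should not use those bins.
#'
#' @inheritParams binned_connection_probability
#' @param source label recording what the curve conditions on.
#' @return object of class `distance_dependence`: list with `bin_table`,
#'   `d_fs`, `source`.
#' @export
distance_dependence <- function(net, n_bins = 50L, restrict_to = NULL,
                                source = c("connectome", "contactome",
                                           "conditional-on-contact")) {
  source <- match.arg(source)
  structure(list(bin_table = binned_connection_probability(net, n_bins,
                                                           restrict_to),
                 d_fs = finite_size_threshold(net, n_bins),
                 source = source),
            class = "distance_dependence")
}

#' @export
print.distance_dependence <- function(x, ...) {
  cat("<distance_dependence> (", x$source, "), ", nrow(x$bin_table),
      " bins, d_fs = ", signif(x$d_fs, 4), " soma sizes\n", sep = "")
  invisible(x)
}

#' Fit an exponential decay scale to a distance-dependence curve
#'
#' Assumes `p(d) = alpha * exp(-d / d0)` and estimates `d0` by
#' count-weighted least squares of `log p_b` against bin centers. Only bins
#' with at least `min_edges_per_bin` edges and centers within `fit_range`
#' are used; by default the upper end of the range is the finite-size cutoff
#' `d_fs` (for a `distance_dependence` input) so that volume-truncation
#' artefacts are excluded.
#'
#' @param dd a `distance_dependence` object or a bin-table data frame.
#' @param fit_range optional `c(lo, hi)` in soma-size units.
#' @param min_edges_per_bin minimum edge count for a bin to enter the fit
#'   (default 10).
#' @return object of class `exponential_fit`: list with `d0`, `alpha`,
#'   `fit_range`, `n_bins_used`, `min_edges_per_bin`.
#' @examples
#' bt <- data.frame(center = 1:20, p = exp(-(1:20) / 5), n_edges = 100,
#'                  n_pairs = 1000)
#' fit_exponential(bt)$d0  # 5
#' @export
fit_exponential <- function(dd, fit_range = NULL, min_edges_per_bin = 10L) {
  if (inherits(dd, "distance_dependence")) {
    if (is.null(fit_range)) fit_range <- c(0, dd$d_fs)
    bt <- dd$bin_table
  } else bt <- as.data.frame(dd)
  if (is.null(fit_range)) fit_range <- c(0, Inf)
  use <- bt$n_edges >= min_edges_per_bin & bt$p > 0 &
    bt$center >= fit_range[1] & bt$center <= fit_range[2]
  if (sum(use) < 2L)
    stop("fewer than 2 eligible bins for the exponential fit")
  fit <- stats::lm(log(p) ~ center, data = bt[use, ],
                   weights = bt$n_edges[use])
  slope <- unname(stats::coef(fit)[2L])
  if (slope >= 0)
    warning("non-decaying connection probability; d0 is negative/infinite")
  structure(list(d0 = -1 / slope, alpha = exp(unname(stats::coef(fit)[1L])),
                 fit_range = fit_range, n_bins_used = sum(use),
                 min_edges_per_bin = min_edges_per_bin),
            class = "exponential_fit")
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat("<exponential_fit> d0 = ", signif(x$d0, 4), " soma sizes (alpha = ",
      signif(x$alpha, 4), ", ", x$n_bins_used, " bins)\n", sep = "")
  invisible(x)
}

#' Finite-size cutoff of a sampled volume
#'
#' The mode of the all-pairs distance histogram: beyond this distance the
#' bounded experimental volume depletes the pair counts, so the empirical
#' connection probability is no longer representative. Ties pick the
#' smaller distance.
#'
#' @param net a [spatial_network()] (>= 3 nodes).
#' @param n_bins histogram bins (default 50, matching the distance models).
#' @return bin-center of the maximal-count bin, in soma-size units.
#' @export
finite_size_threshold <- function(net, n_bins = 50L) {
  if (n_nodes(net) < 3L) stop("need at least 3 nodes")
  d <- pairwise_distances(net)
  edges <- make_bin_edges(d, n_bins)
  cnt <- tabulate(bin_assign(d, edges), nbins = n_bins)
  b <- which.max(cnt)  # which.max takes the first (smaller-distance) tie
  (edges[b] + edges[b + 1L]) / 2
}

#' Soma radius from center-to-contact distance samples
#'
#' Kernel density estimation with a linear (triangular) kernel on the
#' distances from soma centers to physical contact locations; the typical
#' soma radius is the location of the density peak. The density is evaluated
#' on a grid with resolution at most `bandwidth / 10`; tied maxima take the
#' smaller location (with a message).
#'
#' @param contact_distances numeric vector of distances, micrometres
#'   (>= 50 samples).
#' @param bandwidth triangular-kernel half-width, micrometres.
#' @return estimated soma radius in micrometres.
#' @export
soma_size_estimate <- function(contact_distances, bandwidth) {
  x <- contact_distances[is.finite(contact_distances)]
  if (length(x) < 50L) stop("need at least 50 distance samples")
  stopifnot(bandwidth > 0)
  grid <- seq(max(min(x) - bandwidth, 0), max(x) + bandwidth,
              by = bandwidth / 10)
  dens <- vapply(grid, function(g) sum(pmax(0, 1 - abs(g - x) / bandwidth)),
                 numeric(1))
  peaks <- which(dens == max(dens))
  if (length(peaks) > 1L)
    message("tied density maxima; taking the smaller location")
  grid[peaks[1L]]
}

#' Directional (principal-axis) distance dependence
#'
#' Finds the principal axes of the node-position cloud (ordered by
#' positional variance) and, for each axis, bins the connection probability
#' against the absolute projected pair separation `|delta_pos . axis|`,
#' fitting an exponential decay scale per axis. In layered cortical tissue
#' the decay scale along the neuron-alignment axis exceeds the across-layer
#' scales.
#'
#' @param net a [spatial_network()] with >= 4 non-coplanar nodes.
#' @param n_bins linear bins per axis (default 50).
#' @param min_edges_per_bin passed to [fit_exponential()].
#' @return object of class `directional_fit`: `axes` (3x3 orthonormal
#'   matrix, columns ordered by variance), `variance` (per axis), `d_axis`
#'   (decay scale per axis), `bin_tables` (list of 3 bin tables).
#' @export
directional_dependence <- function(net, n_bins = 50L,
                                   min_edges_per_bin = 10L) {
  pos <- node_positions(net)
  if (nrow(pos) < 4L) stop("need at least 4 nodes")
  pc <- stats::prcomp(pos, center = TRUE, scale. = FALSE)
  if (pc$sdev[3L] < 1e-12 * pc$sdev[1L])
    stop("degenerate (coplanar) position cloud")
  n <- nrow(pos)
  ekey <- pair_linear_index(net$edge_idx[, 1L], net$edge_idx[, 2L], n)
  is_edge <- logical(n * (n - 1) / 2)
  is_edge[ekey] <- TRUE
  tables <- vector("list", 3L)
  d_axis <- numeric(3L)
  for (a in 1:3) {
    proj <- drop(pos %*% pc$rotation[, a])
    d <- abs(proj[rep.int(seq_len(n - 1L), (n - 1L):1L)] -
             proj[sequence((n - 1L):1L, from = 2L:n)])
    edges <- make_bin_edges(d, n_bins)
    b <- bin_assign(d, edges)
    n_pairs <- tabulate(b, nbins = n_bins)
    n_edge <- tabulate(b[is_edge], nbins = n_bins)
    tables[[a]] <- data.frame(
      bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
      center = (edges[-1L] + edges[-length(edges)]) / 2,
      n_pairs = n_pairs, n_edges = n_edge,
      p = ifelse(n_pairs > 0, n_edge / n_pairs, 0))
    d_axis[a] <- fit_exponential(tables[[a]],
                                 min_edges_per_bin = min_edges_per_bin)$d0
  }
  structure(list(axes = pc$rotation, variance = pc$sdev^2,
                 d_axis = d_axis, bin_tables = tables),
            class = "directional_fit")
}

#' @export
print.directional_fit <- function(x, ...) {
  cat("<directional_fit> decay scales d_1, d_2, d_3 = ",
      paste(signif(x$d_axis, 4), collapse = ", "), " soma sizes\n", sep = "")
  invisible(x)
}
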