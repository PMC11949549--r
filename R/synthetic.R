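#' Seeded generators of planted connectome/contactome scenarios
#'
#' These generators produce multilayer scenarios with known ground truth,
#' emulating the structure of volumetric connectome reconstructions: 3D node
#' positions (optionally anisotropic), a contactome whose connection
#' probability decays exponentially with distance, a connectome that is a
#' strict subset of the contactome with heterogeneous (broad, non-power-law)
#' degrees, heavy-tailed positive integer edge weights correlated with edge
#' probability, and per-node surface point clouds. All randomness is
#' reproducible from an integer seed.
#'
#' @name synthetic
NULL

#' @describeIn synthetic uniform node positions in an (anisotropically
#'   scaled) box. `box` gives the three edge lengths in soma-size units;
#'   `anisotropy` multiplies them per axis.
#' @param n number of nodes (>= 2).
#' @param box numeric 3-vector of box extents.
#' @param anisotropy numeric 3-vector of per-axis scales.
#' @param seed integer seed.
#' @return `generate_positions`: a node data frame `id`, `x`, `y`, `z`.
#' @export
generate_positions <- function(n, box = c(100, 100, 100),
                               anisotropy = c(1, 1, 1), seed = 1L) {
  stopifnot(n >= 2L, length(box) == 3L, length(anisotropy) == 3L)
  set.seed(seed)
  ext <- box * anisotropy
  data.frame(id = sprintf("n%05d", seq_len(n)),
             x = stats::runif(n, 0, ext[1L]),
             y = stats::runif(n, 0, ext[2L]),
             z = stats::runif(n, 0, ext[3L]))
}

#' @describeIn synthetic contact network with planted exponential distance
#'   dependence: each pair is an edge independently with probability
#'   `min(1, density_scale * exp(-d / d0_c))`.
#' @param nodes node data frame from `generate_positions`.
#' @param d0_c planted contact decay scale, soma-size units.
#' @param density_scale prefactor (connection probability at distance 0).
#' @return `plant_contactome`: a [spatial_network()].
#' @export
plant_contactome <- function(nodes, d0_c = 12, density_scale = 1,
                             seed = 1L) {
  stopifnot(d0_c > 0, density_scale >= 0)
  net0 <- spatial_network(nodes)
  set.seed(seed)
  keep <- pairwise_distances(net0, fun = function(i, j, d) {
    p <- pmin(1, density_scale * exp(-d / d0_c))
    sel <- stats::runif(length(d)) < p
    cbind(i[sel], j[sel])
  })
  net0$edge_idx <- do.call(rbind, keep)
  storage.mode(net0$edge_idx) <- "integer"
  net0
}

#' @describeIn synthetic connectome as a heterogeneous subnetwork of the
#'   contactome: contact edge (i,j) is kept with probability
#'   `y_i y_j / (1 + y_i y_j)` where `y = exp(-theta)` is log-normal with
#'   spread `heterogeneity`; the scale of `y` is calibrated by a 1-D root
#'   solve so the expected kept fraction equals `fraction`. With
#'   `heterogeneity = 0` this reduces to a uniform random subnetwork.
#' @param contactome a [spatial_network()].
#' @param heterogeneity log-normal sigma of the planted node propensities.
#' @param fraction target expected `E_syn / E_cont` in (0, 1].
#' @return `plant_connectome`: list with `connectome`
#'   ([spatial_network()]), `y_true` (planted propensities) and `p_edge`
#'   (per-contact-edge keep probabilities).
#' @export
plant_connectome <- function(contactome, heterogeneity = 1, fraction = 0.1,
                             seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- n_nodes(contactome)
  set.seed(seed)
  z <- stats::rnorm(n, 0, heterogeneity)
  ei <- contactome$edge_idx
  keep_prob <- function(logscale) {
    y <- exp(z + logscale)
    m <- y[ei[, 1L]] * y[ei[, 2L]]
    m / (1 + m)
  }
  f <- function(logscale) mean(keep_prob(logscale)) - fraction
  root <- stats::uniroot(f, lower = -40, upper = 40, tol = 1e-12)
  y_true <- exp(z + root$root)
  p_edge <- keep_prob(root$root)
  keep <- stats::runif(nrow(ei)) < p_edge
  conn <- contactome
  conn$edge_idx <- ei[keep, , drop = FALSE]
  conn$weight <- NULL
  list(connectome = conn, y_true = y_true, p_edge = p_edge)
}

#' @describeIn synthetic heavy-tailed positive integer edge weights whose
#'   mean increases with the planted edge probability, guaranteeing a
#'   positive rank correlation between weight and probability:
#'   `w = 1 + NegBinom(size, mu = weight_scale * p_true / mean(p_true))`.
#' @param p_true planted per-edge probabilities in (0, 1].
#' @param weight_scale mean excess synapse count on a typical edge.
#' @param size negative-binomial dispersion (small = heavier tail).
#' @return `generate_weights`: integer vector of weights (>= 1).
#' @export
generate_weights <- function(p_true, weight_scale = 3, size = 0.5,
                             seed = 1L) {
  stopifnot(all(p_true > 0), all(p_true <= 1))
  set.seed(seed)
  mu <- weight_scale * p_true / mean(p_true)
  1L + stats::rnbinom(length(p_true), size = size, mu = mu)
}

#' @describeIn synthetic per-node surface point clouds: a dense spherical
#'   shell of radius `soma_radius` around the node position plus sparse
#'   points out to `neurite_extent` (straight neurite rays), so that
#'   center-to-contact distance samples peak near `soma_radius`.
#' @param soma_radius soma shell radius, micrometres.
#' @param neurite_extent maximal neurite reach, micrometres.
#' @param points_per_node samples per cloud.
#' @param soma_fraction fraction of points on the soma shell.
#' @return `generate_point_clouds`: named list of [point_cloud()]s.
#' @export
generate_point_clouds <- function(nodes, soma_radius = 2.5,
                                  neurite_extent = 25,
                                  points_per_node = 120L,
                                  soma_fraction = 0.7, seed = 1L) {
  stopifnot(soma_radius > 0, neurite_extent > soma_radius)
  set.seed(seed)
  n_soma <- round(points_per_node * soma_fraction)
  n_neur <- points_per_node - n_soma
  out <- lapply(seq_len(nrow(nodes)), function(i) {
    ctr <- as.numeric(nodes[i, c("x", "y", "z")])
    u <- matrix(stats::rnorm(3L * n_soma), ncol = 3L)
    u <- u / sqrt(rowSums(u^2))
    shell <- sweep(u * soma_radius, 2L, ctr, "+")
    nd <- matrix(stats::rnorm(3L * n_neur), ncol = 3L)
    nd <- nd / sqrt(rowSums(nd^2))
    reach <- stats::runif(n_neur, soma_radius, neurite_extent)
    neur <- sweep(nd * reach, 2L, ctr, "+")
    point_cloud(rbind(shell, neur), node_id = as.character(nodes$id[i]))
  })
  names(out) <- as.character(nodes$id)
  out
}

#' Generate a complete planted multilayer scenario
#'
#' Composes the planted generators into one seeded scenario: positions,
#' contactome with exponential distance dependence, heterogeneous-degree
#' connectome (a strict subset of the contactome), heavy-tailed synaptic
#' weights and, optionally, per-node point clouds. Defaults emulate a
#' mouse-cortex-like patch scaled to desk size: a 100-soma-size box,
#' contact decay scale 12 soma sizes, connectome/contactome edge fraction
#' 0.08 and log-normal degree heterogeneity 1.
#'
#' @param n number of nodes.
#' @param box,anisotropy passed to [generate_positions()].
#' @param d0_c,density_scale passed to [plant_contactome()].
#' @param heterogeneity,fraction passed to [plant_connectome()].
#' @param clouds also generate point clouds (slower)?
#' @param soma_radius,neurite_extent,points_per_node passed to
#'   [generate_point_clouds()].
#' @param seed integer seed; sub-generators use fixed offsets of it.
#' @return list of class `synthetic_scenario`: `nodes`, `contactome`,
#'   `connectome` (weighted), `y_true`, `p_edge`, `weights`, `clouds`
#'   (or `NULL`), `params`, `seed`.
#' @examples
#' sc <- synthetic_scenario(n = 100, seed = 42)
#' validate_multilayer(sc$connectome, sc$contactome)$valid
#' @export
synthetic_scenario <- function(n = 500L, box = c(100, 100, 100),
                               anisotropy = c(1, 1, 1), d0_c = 12,
                               density_scale = 1, heterogeneity = 1,
                               fraction = 0.08, clouds = FALSE,
                               soma_radius = 1, neurite_extent = 10,
                               points_per_node = 120L, seed = 1L) {
  nodes <- generate_positions(n, box, anisotropy, seed = seed)
  contactome <- plant_contactome(nodes, d0_c, density_scale,
                                 seed = seed + 1000L)
  pc <- plant_connectome(contactome, heterogeneity, fraction,
                         seed = seed + 2000L)
  conn <- pc$connectome
  w <- if (n_edges(conn) > 0) {
    p_kept <- pc$p_edge[edge_keys(contactome$edge_idx) %in%
                          edge_keys(conn$edge_idx)]
    generate_weights(p_kept, seed = seed + 3000L)
  } else integer(0)
  conn$weight <- as.integer(w)
  cl <- if (clouds)
    generate_point_clouds(nodes, soma_radius, neurite_extent,
                          points_per_node, seed = seed + 4000L)
  else NULL
  structure(list(nodes = nodes, contactome = contactome, connectome = conn,
                 y_true = pc$y_true, p_edge = pc$p_edge,
                 weights = conn$weight, clouds = cl,
                 params = list(box = box, anisotropy = anisotropy,
                               d0_c = d0_c, density_scale = density_scale,
                               heterogeneity = heterogeneity,
                               fraction = fraction,
                               soma_radius = soma_radius,
                               neurite_extent = neurite_extent),
                 seed = seed),
            class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("<synthetic_scenario> n = ", nrow(x$nodes), ", E_cont = ",
      n_edges(x$contactome), ", E_syn = ", n_edges(x$connectome),
      ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}
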