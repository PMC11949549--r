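#' Fit a canonical maximum-entropy connectome ensemble
#'
#' Fits one of six maximum-entropy network ensembles to an observed
#' connectome. Each ensemble is a product of independent Bernoulli edge
#' variables with probabilities `p_ij` chosen to maximise ensemble entropy
#' subject to constraints taken from the observed network; all six preserve
#' the expected total number of edges.
#'
#' \describe{
#'   \item{`"k"`}{soft configuration model: expected degrees equal observed
#'     degrees, `p_ij = y_i y_j / (1 + y_i y_j)` with one multiplier per node
#'     (`y_i = e^{-theta_i}`).}
#'   \item{`"k+L"`}{degrees plus expected total wiring length `L`:
#'     `p_ij = y_i y_j e^{-d_ij/d0} / (1 + y_i y_j e^{-d_ij/d0})`; the decay
#'     scale `d0` (soma-size units) is calibrated by bisection so the
#'     ensemble-expected wiring length matches the observed one.}
#'   \item{`"d"`}{binned distance dependence: pair distances are split into
#'     `n_bins` linear bins and `p_b` = (observed edges in bin)/(pairs in
#'     bin); the expected edge total then equals the observed count exactly.}
#'   \item{`"c"`}{uniform random subnetwork of the contactome:
#'     `p = E_syn / E_cont` on contact pairs, 0 elsewhere.}
#'   \item{`"d+c"`}{distance dependence conditional on contact: per-bin
#'     probability (synaptic edges in bin)/(contact pairs in bin), applied to
#'     contact pairs only.}
#'   \item{`"k+c"`}{soft configuration model under the hard contact
#'     constraint: `p_ij` forced to zero off the contactome; multipliers
#'     solved over contact pairs only.}
#' }
#'
#' Degree multipliers are solved by the multiplicative fixed-point update
#' `y_i <- k_i* y_i / <k_i>(y)` (the standard iterative scheme for the soft
#' configuration model), with 0.5 damping when the residual oscillates.
#' Nodes with `k_i* = 0` get `p_ij = 0` exactly. Nodes whose target degree
#' equals their number of allowed partners sit on the boundary of the model
#' (`p -> 1` on all their pairs); their multipliers are clamped at a large
#' ceiling and reported in `$boundary`.
#'
#' @param network observed [spatial_network()] (the connectome).
#' @param model one of `"k"`, `"d"`, `"k+L"`, `"c"`, `"d+c"`, `"k+c"`.
#' @param contactome contact-layer `spatial_network` on the same nodes;
#'   required for `"c"`, `"d+c"`, `"k+c"`.
#' @param n_bins number of linear distance bins for models `"d"`/`"d+c"`.
#' @param tol convergence tolerance on the maximum relative degree error
#'   `max_i |<k_i> - k_i*| / max(k_i*, 1)`.
#' @param max_iter maximum fixed-point iterations per solve.
#' @param tol_L relative tolerance on the expected wiring length for
#'   `"k+L"` (default 1e-4, i.e. 0.01 percent of the total edge length).
#' @param d0_bracket length-2 numeric bracket for the `"k+L"` decay scale in
#'   soma-size units; default spans 1e-3 to 1e3 times the mean pair distance.
#' @return an object of class `maxent_ensemble`; see
#'   [predict.maxent_ensemble()], [simulate.maxent_ensemble()],
#'   [logLik.maxent_ensemble()].
#' @examples
#' sc <- synthetic_scenario(n = 80, seed = 1)
#' fit <- fit_maxent(sc$connectome, "k")
#' max(abs(residuals(fit)))        # degrees reproduced
#' fit_c <- fit_maxent(sc$connectome, "c", contactome = sc$contactome)
#' @export
fit_maxent <- function(network, model = c("k", "d", "k+L", "c", "d+c", "k+c"),
                       contactome = NULL, n_bins = 50L, tol = 1e-8,
                       max_iter = 10000L, tol_L = 1e-4, d0_bracket = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(network, "spatial_network"))
  needs_contact <- model %in% c("c", "d+c", "k+c")
  if (needs_contact) {
    if (is.null(contactome))
      stop("model '", model, "' needs a contactome")
    rep <- validate_multilayer(network, contactome)
    if (!rep$valid)
      stop("observed connectome has ", nrow(rep$violations),
           " edge(s) outside the contactome; cannot apply a hard contact ",
           "constraint")
  }
  k_star <- degree_sequence(network)
  fit <- switch(model,
    "k"   = fit_degree_core(k_star, mask = NULL, net = network,
                            tol = tol, max_iter = max_iter),
    "k+c" = fit_degree_core(k_star, mask = contactome$edge_idx,
                            net = network, tol = tol, max_iter = max_iter),
    "k+L" = fit_degree_wiring_core(network, tol, max_iter, tol_L, d0_bracket),
    "d"   = fit_distance_core(network, NULL, n_bins),
    "d+c" = fit_distance_core(network, contactome$edge_idx, n_bins),
    "c"   = fit_uniform_core(network, contactome$edge_idx))
  fit$model <- model
  fit$network <- network
  fit$mask <- if (needs_contact) contactome$edge_idx else NULL
  fit$k_star <- k_star
  fit$call <- match.call()
  class(fit) <- "maxent_ensemble"
  fit
}

Y_CEILING <- 1e12

# expected degrees <k_i> = sum_j p_ij given propensities y (and optional
# distance kernel W or contact mask edge index)
expected_degrees <- function(y, mask = NULL, W = NULL) {
  n <- length(y)
  if (is.null(mask)) {
    M <- outer(y, y)
    if (!is.null(W)) M <- M * W
    P <- M / (1 + M)
    diag(P) <- 0
    rowSums(P)
  } else {
    m <- y[mask[, 1L]] * y[mask[, 2L]]
    p <- m / (1 + m)
    ke <- numeric(n)
    acc <- rowsum(c(p, p), c(mask[, 1L], mask[, 2L]))
    ke[as.integer(rownames(acc))] <- acc[, 1L]
    ke
  }
}

# fixed-point solve of the degree constraints; returns list(y, boundary, ...)
# Boundary nodes -- target degree equal to the number of allowed partners
# that themselves have positive targets -- have p -> 1 on all their pairs;
# they are pinned at a large multiplier ceiling and excluded from the
# residual (their constraint is met only in the limit).
solve_degrees <- function(k_star, mask = NULL, W = NULL,
                          tol = 1e-8, max_iter = 10000L, y0 = NULL) {
  n <- length(k_star)
  active <- k_star > 0
  allowed <- if (is.null(mask)) {
    rep.int(sum(active), n) - as.integer(active)
  } else {
    ok <- active[mask[, 1L]] & active[mask[, 2L]]
    a <- numeric(n)
    if (any(ok)) {
      mm <- mask[ok, , drop = FALSE]
      tab <- rowsum(rep.int(1L, 2L * nrow(mm)), c(mm[, 1L], mm[, 2L]))
      a[as.integer(rownames(tab))] <- tab[, 1L]
    }
    a
  }
  infeas <- k_star > allowed
  if (any(infeas))
    stop("infeasible degree constraint: target degree exceeds number of ",
         "allowed partners for node index ",
         paste(utils::head(which(infeas), 5L), collapse = ", "))
  pinned <- active & k_star == allowed & is.null(W)
  y <- if (is.null(y0)) k_star / sqrt(max(sum(k_star), 1)) else y0
  y[!active] <- 0
  y[active & y <= 0] <- 1e-8
  y[pinned] <- Y_CEILING
  free <- active & !pinned
  res_prev <- Inf
  res <- 0
  res_check <- Inf
  for (it in seq_len(max_iter)) {
    ke <- expected_degrees(y, mask, W)
    res <- if (any(free))
      max(abs(ke - k_star)[free] / pmax(k_star[free], 1)) else 0
    if (res <= tol)
      return(list(y = y, boundary = y >= Y_CEILING, iterations = it,
                  residual = res, converged = TRUE))
    # near-degenerate components (p -> 0 or 1 on some pairs) make the
    # multiplicative update crawl; polish with damped Newton on log y when
    # progress per 100 iterations is poor
    if (it %% 100L == 0L) {
      if (res > 0.2 * res_check && length(y) <= 3000L) {
        y <- newton_polish(y, k_star, free, mask, W)
        ke <- expected_degrees(y, mask, W)
        res <- if (any(free))
          max(abs(ke - k_star)[free] / pmax(k_star[free], 1)) else 0
        if (res <= tol)
          return(list(y = y, boundary = y >= Y_CEILING, iterations = it,
                      residual = res, converged = TRUE))
      }
      res_check <- res
    }
    y_new <- y
    y_new[free] <- y[free] * k_star[free] / pmax(ke[free], 1e-300)
    if (res > res_prev) y_new <- 0.5 * (y + y_new)  # damp oscillation
    y_new[free] <- pmin(y_new[free], Y_CEILING)
    y_new[pinned] <- Y_CEILING
    y <- y_new
    res_prev <- res
  }
  stop("degree fixed point did not converge after ", max_iter,
       " iterations (residual ", signif(res, 3), ")")
}

# one damped Newton step on log y for the free nodes; the Jacobian
# d<k_i>/d log y_j = p_ij (1 - p_ij) (j != i), diagonal = row sums, is the
# (symmetric, PSD) Fisher information of the independent-edge model
newton_polish <- function(y, k_star, free, mask, W) {
  n <- length(y)
  if (!any(free)) return(y)
  if (is.null(mask)) {
    M <- outer(y, y)
    if (!is.null(W)) M <- M * W
    P <- M / (1 + M)
    diag(P) <- 0
  } else {
    P <- matrix(0, n, n)
    m <- y[mask[, 1L]] * y[mask[, 2L]]
    p <- m / (1 + m)
    P[mask] <- p
    P[mask[, 2:1, drop = FALSE]] <- p
  }
  ke <- rowSums(P)
  Q <- P * (1 - P)
  f <- which(free)
  J <- Q[f, f, drop = FALSE]
  diag(J) <- rowSums(Q[f, , drop = FALSE])
  diag(J) <- diag(J) + 1e-12 * max(diag(J), 1)
  delta <- tryCatch(solve(J, (k_star - ke)[f]), error = function(e) NULL)
  if (is.null(delta)) return(y)
  delta <- pmin(pmax(delta, -5), 5)
  y2 <- y
  y2[f] <- pmin(y[f] * exp(delta), Y_CEILING)
  # accept only if the residual improves
  ke2 <- expected_degrees(y2, mask, W)
  r1 <- max(abs(ke - k_star)[free] / pmax(k_star[free], 1))
  r2 <- max(abs(ke2 - k_star)[free] / pmax(k_star[free], 1))
  if (r2 < r1) y2 else y
}

fit_degree_core <- function(k_star, mask, net, tol, max_iter) {
  sol <- solve_degrees(k_star, mask = mask, tol = tol, max_iter = max_iter)
  list(y = sol$y, boundary = sol$boundary, residual = sol$residual,
       iterations = sol$iterations)
}

fit_degree_wiring_core <- function(network, tol, max_iter, tol_L,
                                   d0_bracket, L_star = NULL) {
  k_star <- degree_sequence(network)
  if (is.null(L_star)) L_star <- wiring_length(network)
  if (L_star <= 0) stop("observed wiring length is zero; cannot fit 'k+L'")
  D <- distance_matrix(network)
  dbar <- mean(D[upper.tri(D)])
  if (is.null(d0_bracket)) d0_bracket <- c(1e-3, 1e3) * dbar
  stopifnot(length(d0_bracket) == 2L, all(d0_bracket > 0),
            d0_bracket[1] < d0_bracket[2])

  y0 <- NULL
  # a probe can legitimately fail at very small d0: the distance kernel
  # underflows and the degree constraints become unrepresentable there
  probe <- function(d0) {
    W <- exp(-D / d0)
    sol <- tryCatch(
      solve_degrees(k_star, W = W, tol = tol, max_iter = max_iter, y0 = y0),
      error = function(e) NULL)
    if (is.null(sol)) return(NULL)
    y0 <<- sol$y
    M <- outer(sol$y, sol$y) * W
    P <- M / (1 + M)
    diag(P) <- 0
    list(L = sum(P * D) / 2, sol = sol, d0 = d0)
  }
  wrap <- function(f) list(y = f$sol$y, boundary = f$sol$boundary,
                           d0 = f$d0, L_star = L_star, L_expected = f$L,
                           residual = f$sol$residual,
                           iterations = f$sol$iterations)
  hit <- function(f) !is.null(f) && abs(f$L - L_star) / L_star <= tol_L

  # locate a working starting scale, then expand geometrically until
  # <L>(d0) -- monotone increasing in d0 at the converged multipliers --
  # brackets the target
  start <- dbar
  f <- probe(start)
  tries <- 0L
  while (is.null(f) && tries < 60L) {
    start <- start * 2
    f <- probe(start)
    tries <- tries + 1L
  }
  if (is.null(f)) stop("could not solve the degree constraints at any d0")
  if (hit(f)) return(wrap(f))
  lo_f <- hi_f <- NULL
  if (f$L < L_star) lo_f <- f else hi_f <- f
  d0 <- start
  for (step in seq_len(60L)) {
    if (is.null(hi_f)) {
      d0 <- min(d0 * 2, d0_bracket[2])
      g <- probe(d0)
      if (is.null(g)) stop("degree solve failed while expanding d0 upward")
      if (hit(g)) return(wrap(g))
      if (g$L >= L_star) hi_f <- g else {
        if (d0 >= d0_bracket[2] ||
            (g$L - lo_f$L) < 1e-12 * max(L_star, 1))
          stop("target wiring length ", signif(L_star, 6),
               " not attainable: expected length saturates at ",
               signif(g$L, 6), " (degree-only limit); widen d0_bracket ",
               "or lower the target")
        lo_f <- g
      }
    } else if (is.null(lo_f)) {
      d0 <- max(d0 / 2, d0_bracket[1])
      g <- probe(d0)
      if (hit(g)) return(wrap(g))
      if (is.null(g) || d0 <= d0_bracket[1]) {
        if (!is.null(g) && g$L <= L_star) { lo_f <- g; next }
        stop("target wiring length ", signif(L_star, 6),
             " below what the model attains on the searchable d0 range (",
             "smallest expected length ", signif(hi_f$L, 6),
             "); widen d0_bracket")
      }
      if (g$L <= L_star) lo_f <- g else hi_f <- g
    } else break
  }
  if (is.null(lo_f) || is.null(hi_f))
    stop("could not bracket the target wiring length in d0")
  # geometric bisection on d0
  best <- if (abs(lo_f$L - L_star) < abs(hi_f$L - L_star)) lo_f else hi_f
  for (it in seq_len(200L)) {
    mid <- sqrt(lo_f$d0 * hi_f$d0)
    g <- probe(mid)
    if (is.null(g)) stop("degree solve failed during d0 bisection")
    if (abs(g$L - L_star) < abs(best$L - L_star)) best <- g
    if (hit(g)) return(wrap(g))
    if (g$L < L_star) lo_f <- g else hi_f <- g
    if (hi_f$d0 / lo_f$d0 < 1 + 1e-14) break
  }
  stop("wiring-length calibration did not reach tol_L; best residual ",
       signif(abs(best$L - L_star) / L_star, 3))
}

# shared binning for the distance models: linear bins [0, max d], last closed
make_bin_edges <- function(d, n_bins) {
  hi <- max(d)
  if (hi <= 0) hi <- 1
  seq(0, hi, length.out = n_bins + 1L)
}

bin_assign <- function(d, edges) {
  b <- findInterval(d, edges, rightmost.closed = TRUE, all.inside = TRUE)
  pmin(b, length(edges) - 1L)
}

fit_distance_core <- function(network, mask, n_bins, bin_edges = NULL) {
  stopifnot(n_bins >= 1L)
  n <- n_nodes(network)
  pos <- node_positions(network)
  if (is.null(mask)) {
    d_all <- pairwise_distances(network)
    ekey <- pair_linear_index(network$edge_idx[, 1L],
                              network$edge_idx[, 2L], n)
    is_edge <- logical(length(d_all))
    is_edge[ekey] <- TRUE
  } else {
    dd <- pos[mask[, 1L], , drop = FALSE] - pos[mask[, 2L], , drop = FALSE]
    d_all <- sqrt(rowSums(dd * dd))
    is_edge <- edge_keys(mask) %in% edge_keys(network$edge_idx)
  }
  edges <- if (is.null(bin_edges)) make_bin_edges(d_all, n_bins)
           else bin_edges
  n_bins <- length(edges) - 1L
  b <- bin_assign(d_all, edges)
  n_pairs <- tabulate(b, nbins = n_bins)
  n_edge <- tabulate(b[is_edge], nbins = n_bins)
  p <- ifelse(n_pairs > 0, n_edge / n_pairs, 0)
  list(bin_table = data.frame(
         bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
         center = (edges[-1L] + edges[-length(edges)]) / 2,
         n_pairs = n_pairs, n_edges = n_edge, p = p))
}

fit_uniform_core <- function(network, mask) {
  E_syn <- n_edges(network)
  E_cont <- nrow(mask)
  if (E_syn > E_cont)
    stop("infeasible: connectome has more edges than the contactome")
  list(p_uniform = if (E_cont > 0) E_syn / E_cont else 0)
}
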