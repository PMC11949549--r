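# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (double loops, exhaustive enumeration,
# generic root finding) so they share no code with the implementation.

# plain double-loop pairwise distances, lexicographic (i < j) order
brute_pair_distances <- function(pos) {
  n <- nrow(pos)
  out <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      out <- c(out, sqrt(sum((pos[i, ] - pos[j, ])^2)))
    }
  }
  out
}

# exhaustive induced graphlet enumeration over all 3- and 4-subsets
enumerate_graphlets <- function(A) {
  n <- nrow(A)
  tri <- 0L
  if (n >= 3) {
    for (s in utils::combn(n, 3, simplify = FALSE)) {
      if (sum(A[s, s]) / 2 == 3) tri <- tri + 1L
    }
  }
  sq <- dia <- k4 <- 0L
  if (n >= 4) {
    for (s in utils::combn(n, 4, simplify = FALSE)) {
      sub <- A[s, s]
      e <- sum(sub) / 2
      if (e == 6) k4 <- k4 + 1L
      else if (e == 5) dia <- dia + 1L
      else if (e == 4 && all(rowSums(sub) == 2)) sq <- sq + 1L
    }
  }
  c(triangle = tri, square = sq, diamond = dia, k4 = k4)
}

# a spatial_network from an explicit adjacency or edge matrix
make_net <- function(pos, edges = NULL, soma_size_unit = 1, ids = NULL) {
  n <- nrow(pos)
  if (is.null(ids)) ids <- sprintf("v%03d", seq_len(n))
  nodes <- data.frame(id = ids, x = pos[, 1], y = pos[, 2], z = pos[, 3])
  ed <- if (is.null(edges) || NROW(edges) == 0) NULL
        else data.frame(from = ids[edges[, 1]], to = ids[edges[, 2]])
  spatial_network(nodes, ed, soma_size_unit = soma_size_unit)
}

random_positions <- function(n, scale = 10, seed = 1) {
  set.seed(seed)
  matrix(runif(3 * n, 0, scale), ncol = 3)
}

# Erdos-Renyi edge matrix (i < j rows)
random_edges <- function(n, p, seed = 1) {
  set.seed(seed)
  pairs <- t(utils::combn(n, 2))
  pairs[runif(nrow(pairs)) < p, , drop = FALSE]
}

adjacency_from_edges <- function(n, edges) {
  A <- matrix(0, n, n)
  if (NROW(edges)) {
    A[edges] <- 1
    A[edges[, 2:1, drop = FALSE]] <- 1
  }
  A
}

# generic nonlinear solve of the soft-configuration degree equations
# k_i = sum_{j != i, allowed} y_i y_j / (1 + y_i y_j), unknowns log y_i
# (only nodes with k_i > 0; allowed = all pairs or a mask adjacency)
oracle_degree_probabilities <- function(k_star, mask_adj = NULL) {
  n <- length(k_star)
  act <- which(k_star > 0)
  allowed <- if (is.null(mask_adj)) 1 - diag(n) else mask_adj
  fn <- function(ly) {
    y <- numeric(n)
    y[act] <- exp(ly)
    M <- outer(y, y) * allowed
    P <- M / (1 + M)
    diag(P) <- 0
    rowSums(P)[act] - k_star[act]
  }
  sol <- pracma::fsolve(fn, x0 = rep(0, length(act)), tol = 1e-12)
  y <- numeric(n)
  y[act] <- exp(sol$x)
  M <- outer(y, y) * allowed
  P <- M / (1 + M)
  diag(P) <- 0
  P
}

# degree sequence has a node forced to the model boundary (target equal to
# its number of positive-degree partners) -- skipped in solver comparisons
has_boundary_node <- function(k_star, mask_adj = NULL) {
  n <- length(k_star)
  act <- k_star > 0
  allowed <- if (is.null(mask_adj)) {
    ifelse(act, sum(act) - 1, 0)
  } else {
    as.numeric(mask_adj %*% as.numeric(act))
  }
  any(act & k_star >= allowed)
}

# hand-built fitted ensemble (for closed-form probability checks and
# planted-truth simulation)
manual_ensemble <- function(model, network, y = NULL, d0 = NULL,
                            p_uniform = NULL, bin_table = NULL,
                            mask = NULL) {
  structure(list(model = model, network = network, y = y, d0 = d0,
                 p_uniform = p_uniform, bin_table = bin_table, mask = mask,
                 k_star = degree_sequence(network)),
            class = "maxent_ensemble")
}
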