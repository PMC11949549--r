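test_that("degree model reproduces regular and degenerate sequences", {
  # 4 nodes, all degrees 2: symmetry forces p = 2/3 on every pair
  pos <- random_positions(4, seed = 1)
  net <- make_net(pos, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
  fit <- fit_maxent(net, "k")
  expect_equal(predict(fit)$p, rep(2 / 3, 6), tolerance = 1e-7)

  # degrees (0,2,2,2): the zero-degree node gets p = 0 exactly; the others
  # sit on the model boundary (p -> 1) and are reported as such
  net2 <- make_net(pos, rbind(c(2, 3), c(3, 4), c(4, 2)))
  fit2 <- fit_maxent(net2, "k")
  pr <- predict(fit2)
  p1 <- pr$p[pr$i == 1 | pr$j == 1]
  expect_equal(p1, rep(0, 3))
  expect_true(all(pr$p[pr$i != 1 & pr$j != 1] > 1 - 1e-6))
  expect_true(any(fit2$boundary))
})

test_that("degree fixed point agrees with a generic nonlinear solver", {
  skip_if_not_installed("pracma")
  # spec'd case: n = 5, degrees (1,1,2,2,2)
  pos <- random_positions(5, seed = 2)
  net <- make_net(pos, rbind(c(1, 3), c(2, 4), c(3, 5), c(4, 5)))
  expect_equal(degree_sequence(net), c(1L, 1L, 2L, 2L, 2L))
  fit <- fit_maxent(net, "k")
  P_oracle <- oracle_degree_probabilities(degree_sequence(net))
  pr <- predict(fit)
  expect_equal(pr$p, P_oracle[cbind(pr$i, pr$j)], tolerance = 1e-6)

  # battery of random graphs with n <= 8 (boundary-free sequences)
  tested <- 0
  for (s in 1:60) {
    n <- sample(4:8, 1)
    edges <- random_edges(n, 0.5, seed = 100 + s)
    if (nrow(edges) < 2) next
    k <- tabulate(c(edges), nbins = n)
    if (has_boundary_node(k)) next
    net_s <- make_net(random_positions(n, seed = s), edges)
    fit_s <- fit_maxent(net_s, "k")
    # fixed point reproduces the targets within 1e-6 relative error
    ke <- expected_degree(fit_s)
    act <- k > 0
    expect_lt(max(abs(ke - k)[act] / pmax(k[act], 1)), 1e-6)
    P_o <- oracle_degree_probabilities(k)
    pr_s <- predict(fit_s)
    expect_equal(pr_s$p, P_o[cbind(pr_s$i, pr_s$j)], tolerance = 1e-5)
    tested <- tested + 1
  }
  expect_gte(tested, 20)
})

test_that("hard contact constraint zeroes non-contact pairs and matches the solver", {
  skip_if_not_installed("pracma")
  sc <- synthetic_scenario(n = 40, seed = 9)
  fit <- fit_maxent(sc$connectome, "k+c", contactome = sc$contactome)
  # every probability outside the contactome is exactly zero
  pr_all <- predict(fit, pairs = t(utils::combn(node_ids(sc$connectome), 2)))
  mask_keys <- neuromaxent:::edge_keys(sc$contactome$edge_idx)
  pairs_idx <- t(utils::combn(40, 2))
  outside <- !(neuromaxent:::edge_keys(pairs_idx) %in% mask_keys)
  expect_true(all(pr_all[outside] == 0))

  k <- degree_sequence(sc$connectome)
  A_mask <- adjacency_from_edges(40, sc$contactome$edge_idx)
  if (!has_boundary_node(k, A_mask)) {
    P_o <- oracle_degree_probabilities(k, A_mask)
    expect_equal(pr_all[!outside], P_o[pairs_idx][!outside],
                 tolerance = 1e-5)
  }

  # infeasible target degree: more synaptic than contact partners
  pos <- random_positions(4, seed = 1)
  conn <- make_net(pos, rbind(c(1, 2), c(1, 3)))
  cont <- make_net(pos, rbind(c(1, 2), c(1, 3)))
  # hand-raise the degree target beyond the mask degree via a denser conn
  conn2 <- make_net(pos, rbind(c(1, 2), c(1, 3), c(1, 4)))
  expect_error(fit_maxent(conn2, "k+c", contactome = conn),
               "outside the contactome|infeasible")
})

test_that("degree+wiring model collapses to the degree model in degenerate geometry", {
  # regular tetrahedron: all pairwise distances equal, so the distance
  # factor is absorbed and p must match model k
  pos <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  net <- make_net(pos, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
  fit_kl <- fit_maxent(net, "k+L", tol_L = 1e-6)
  expect_equal(predict(fit_kl)$p, rep(2 / 3, 6), tolerance = 1e-5)

  # d0 -> infinity limit: with the target length set to the degree-only
  # model's expected length, multipliers match model k
  pos2 <- random_positions(30, seed = 11)
  edges2 <- random_edges(30, 0.2, seed = 12)
  net2 <- make_net(pos2, edges2)
  fit_k <- fit_maxent(net2, "k")
  L_k <- expected_wiring_length(fit_k)
  core <- neuromaxent:::fit_degree_wiring_core(
    net2, tol = 1e-10, max_iter = 10000L, tol_L = 1e-6,
    d0_bracket = c(1e-3, 1e9), L_star = L_k)
  expect_gt(core$d0, 100)  # far beyond the geometry scale
  expect_equal(core$y[fit_k$y > 0] / fit_k$y[fit_k$y > 0],
               rep(1, sum(fit_k$y > 0)), tolerance = 1e-3)
})

test_that("degree+wiring calibration hits the wiring target and is monotone in d0", {
  sc <- synthetic_scenario(n = 200, seed = 21)
  net <- sc$connectome
  fit <- fit_maxent(net, "k+L")
  L_obs <- wiring_length(net)
  expect_lt(abs(expected_wiring_length(fit) - L_obs) / L_obs, 1e-4)
  ke <- expected_degree(fit)
  k <- degree_sequence(net)
  act <- k > 0
  expect_lt(max(abs(ke - k)[act] / pmax(k[act], 1)), 1e-6)

  # <L>(d0) is nondecreasing in d0 at converged multipliers
  D <- neuromaxent:::distance_matrix(net)
  Ls <- vapply(c(0.5, 1, 2) * fit$d0, function(d0) {
    W <- exp(-D / d0)
    sol <- neuromaxent:::solve_degrees(k, W = W, tol = 1e-8,
                                       max_iter = 10000L)
    M <- outer(sol$y, sol$y) * W
    P <- M / (1 + M)
    diag(P) <- 0
    sum(P * D) / 2
  }, numeric(1))
  expect_true(all(diff(Ls) > 0))
})

test_that("distance model preserves the edge count exactly", {
  # one bin: p = edges/pairs uniformly (6 pairs, 1 edge)
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  net <- make_net(pos, rbind(c(1, 2)))
  fit1 <- fit_maxent(net, "d", n_bins = 1L)
  expect_equal(unique(predict(fit1)$p), 1 / 6)
  expect_equal(expected_edge_count(fit1), 1)
  # restricted to 4 contact pairs with 1 edge -> p = 1/4 on those pairs
  cont4 <- make_net(pos, rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 4)))
  fit1c <- fit_maxent(net, "d+c", contactome = cont4, n_bins = 1L)
  expect_equal(unique(predict(fit1c)$p), 0.25)

  # toy network, 2 bins: sum of p over pairs = |E| exactly
  pos2 <- random_positions(6, seed = 31)
  net2 <- make_net(pos2, random_edges(6, 0.5, seed = 32))
  fit2 <- fit_maxent(net2, "d", n_bins = 2L)
  expect_equal(expected_edge_count(fit2), n_edges(net2))

  # default is 50 linear bins spanning [0, max distance]
  fit50 <- fit_maxent(net2, "d")
  expect_equal(nrow(fit50$bin_table), 50L)
  expect_equal(fit50$bin_table$bin_lo[1], 0)
  expect_equal(fit50$bin_table$bin_hi[50], max(pairwise_distances(net2)))
  expect_equal(expected_edge_count(fit50), n_edges(net2))

  # conditional variant: denominator and support are contact pairs
  sc <- synthetic_scenario(n = 120, seed = 33)
  fdc <- fit_maxent(sc$connectome, "d+c", contactome = sc$contactome)
  expect_equal(expected_edge_count(fdc), n_edges(sc$connectome))
  expect_true(all(predict(fdc)$p >= 0 & predict(fdc)$p <= 1))
})

test_that("uniform contact model divides edge counts", {
  pos <- random_positions(12, seed = 41)
  cont <- make_net(pos, t(utils::combn(12, 2))[1:40, ])
  conn <- make_net(pos, cont$edge_idx[1:10, ])
  fit <- fit_maxent(conn, "c", contactome = cont)
  expect_equal(fit$p_uniform, 0.25)
  expect_equal(unique(predict(fit)$p), 0.25)

  conn0 <- make_net(pos, NULL)
  fit0 <- fit_maxent(conn0, "c", contactome = cont)
  expect_equal(unique(predict(fit0)$p), 0)

  # printed mouse layer sizes imply p ~ 0.08125
  ref <- reference_networks()
  E_syn <- ref$n_edges[ref$organism == "mouse" & ref$layer == "synaptic"]
  E_cont <- ref$n_edges[ref$organism == "mouse" & ref$layer == "contact"]
  expect_equal(E_syn / E_cont, 0.08125, tolerance = 2e-4)
})

test_that("edge probabilities follow the closed forms", {
  pos <- rbind(c(0, 0, 0), c(2, 0, 0))
  net <- make_net(pos)
  # theta_i = theta_j = 0 (y = 1): p = 1/2
  mk <- manual_ensemble("k", net, y = c(1, 1))
  expect_equal(predict(mk, pairs = cbind("v001", "v002")), 0.5)
  # k+L at d = d0: p = 1/(1+e)
  mkl <- manual_ensemble("k+L", net, y = c(1, 1), d0 = 2)
  expect_equal(predict(mkl, pairs = cbind("v001", "v002")), 1 / (1 + exp(1)))
  # probabilities are symmetric in the pair
  expect_equal(predict(mkl, pairs = cbind("v002", "v001")),
               predict(mkl, pairs = cbind("v001", "v002")))
  expect_error(predict(mk, pairs = cbind("v001", "nope")), "unknown node")
})

test_that("ensemble sampling is seeded, unbiased and respects hard masks", {
  # p = 1 on a fixed pair set: every realization equals that set
  pos <- random_positions(5, seed = 51)
  net <- make_net(pos, rbind(c(1, 2), c(3, 4)))
  cont <- make_net(pos, rbind(c(1, 2), c(3, 4)))
  fit1 <- fit_maxent(net, "c", contactome = cont)  # p = 2/2 = 1
  for (r in simulate(fit1, nsim = 5, seed = 3))
    expect_equal(unname(r[, 1:2]), unname(net$edge_idx))

  # identical seeds give identical realizations
  sc <- synthetic_scenario(n = 50, seed = 53)
  fit <- fit_maxent(sc$connectome, "k")
  s1 <- simulate(fit, nsim = 3, seed = 7)
  s2 <- simulate(fit, nsim = 3, seed = 7)
  expect_identical(s1, s2)
  # prefix property: realization r depends only on seed + r
  s3 <- simulate(fit, nsim = 2, seed = 7)
  expect_identical(s1[1:2], s3)

  # per-node mean sampled degree within 3 binomial SEs for >= 95% of nodes
  R <- 100L
  sims <- simulate(fit, nsim = R, seed = 11)
  kbar <- Reduce(`+`, lapply(sims, function(e)
    tabulate(c(e[, 1], e[, 2]), nbins = 50))) / R
  pr <- predict(fit)
  var_k <- numeric(50)
  v <- pr$p * (1 - pr$p)
  for (r in seq_len(nrow(pr))) {
    var_k[pr$i[r]] <- var_k[pr$i[r]] + v[r]
    var_k[pr$j[r]] <- var_k[pr$j[r]] + v[r]
  }
  k <- degree_sequence(sc$connectome)
  se <- sqrt(var_k / R)
  ok <- abs(kbar - k) <= 3 * pmax(se, 1e-12)
  expect_gte(mean(ok), 0.95)

  # hard-constrained samples never contain non-contact edges
  fkc <- fit_maxent(sc$connectome, "k+c", contactome = sc$contactome)
  mask_keys <- neuromaxent:::edge_keys(sc$contactome$edge_idx)
  for (e in simulate(fkc, nsim = 20, seed = 13))
    expect_true(all(neuromaxent:::edge_keys(e[, 1:2, drop = FALSE])
                    %in% mask_keys))
})

test_that("log-likelihood handles hard zeros and favours the generating model", {
  pos <- rbind(c(0, 0, 0), c(1, 0, 0))
  net <- make_net(pos, rbind(c(1, 2)))
  mc <- manual_ensemble("c", net, p_uniform = 0.5,
                        mask = rbind(c(1L, 2L)))
  expect_equal(as.numeric(logLik(mc)), log(0.5))

  # observed edge outside the hard mask: -Inf with the pair listed
  pos3 <- random_positions(3, seed = 61)
  conn <- make_net(pos3, rbind(c(1, 2), c(1, 3)))
  cont <- make_net(pos3, rbind(c(1, 2), c(2, 3)))
  fit <- fit_maxent(make_net(pos3, rbind(c(1, 2))), "c", contactome = cont)
  ll <- logLik(fit, observed = conn)
  expect_identical(as.numeric(ll), -Inf)
  expect_true("1-3" %in% attr(ll, "offending_pairs"))

  # data simulated from a k+L truth is best explained by the k+L fit
  set.seed(71)
  n <- 150
  pos_n <- random_positions(n, scale = 40, seed = 71)
  truth_net <- make_net(pos_n)
  y_true <- exp(rnorm(n, 0, 0.8)) * 0.5
  truth <- manual_ensemble("k+L", truth_net, y = y_true, d0 = 8)
  e <- simulate(truth, nsim = 1, seed = 5)[[1]]
  obs <- truth_net
  obs$edge_idx <- e[, 1:2, drop = FALSE]
  storage.mode(obs$edge_idx) <- "integer"
  ll_kl <- logLik(fit_maxent(obs, "k+L"))
  ll_k <- logLik(fit_maxent(obs, "k"))
  ll_d <- logLik(fit_maxent(obs, "d"))
  expect_gt(ll_kl, ll_k)
  expect_gt(ll_kl, ll_d)
})

test_that("fitted probabilities satisfy the shared ensemble invariants", {
  sc <- synthetic_scenario(n = 80, seed = 81)
  models <- list(
    fit_maxent(sc$connectome, "k"),
    fit_maxent(sc$connectome, "d"),
    fit_maxent(sc$connectome, "c", contactome = sc$contactome),
    fit_maxent(sc$connectome, "d+c", contactome = sc$contactome),
    fit_maxent(sc$connectome, "k+c", contactome = sc$contactome))
  E <- n_edges(sc$connectome)
  for (m in models) {
    p <- predict(m)$p
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(expected_edge_count(m), E, tolerance = 1e-5)
  }
})
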