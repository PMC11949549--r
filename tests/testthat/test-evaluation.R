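test_that("graphlet counts match canonical small graphs", {
  K3 <- adjacency_from_edges(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(graphlet_counts(K3),
               c(triangle = 1L, square = 0L, diamond = 0L, k4 = 0L))
  C4 <- adjacency_from_edges(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)))
  expect_equal(graphlet_counts(C4),
               c(triangle = 0L, square = 1L, diamond = 0L, k4 = 0L))
  K4 <- adjacency_from_edges(4, t(utils::combn(4, 2)))
  expect_equal(graphlet_counts(K4),
               c(triangle = 4L, square = 0L, diamond = 0L, k4 = 1L))
  Dia <- adjacency_from_edges(4, rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3),
                                       c(2, 4)))
  expect_equal(graphlet_counts(Dia),
               c(triangle = 2L, square = 0L, diamond = 1L, k4 = 0L))
})

test_that("graphlet counter equals exhaustive enumeration on random graphs", {
  set.seed(1)
  for (s in 1:200) {
    n <- sample(4:10, 1)
    A <- adjacency_from_edges(n, random_edges(n, runif(1, 0.2, 0.8),
                                              seed = 1000 + s))
    expect_identical(graphlet_counts(A), enumerate_graphlets(A),
                     label = paste("graph", s))
  }
})

test_that("network measures match hand-computed values", {
  pos3 <- random_positions(3, seed = 2)
  P3 <- make_net(pos3, rbind(c(1, 2), c(2, 3)))
  m <- network_measures(P3)
  expect_equal(m$diameter, 2)
  expect_equal(m$avg_shortest_path, 4 / 3)
  expect_equal(m$transitivity, 0)
  expect_equal(m$lcc_size, 3)
  # E_global over ordered pairs: delta = 1,1,2 -> (1+1+1/2)/3
  expect_equal(m$E_global, (1 + 1 + 1 / 2) / 3)
  # end nodes have k < 2 -> C_i = 0; middle node's neighbours unconnected
  expect_equal(m$avg_clustering, 0)

  K3 <- make_net(pos3, rbind(c(1, 2), c(2, 3), c(1, 3)))
  mk <- network_measures(K3)
  expect_equal(mk$avg_clustering, 1)
  expect_equal(mk$transitivity, 1)
  expect_equal(mk$E_local, 1)
  expect_equal(mk$diameter, 1)

  # isolated node: excluded from the LCC, C_i = 0, disconnected pairs
  # contribute zero to E_global
  pos4 <- random_positions(4, seed = 3)
  iso <- make_net(pos4, rbind(c(1, 2), c(2, 3), c(1, 3)))
  mi <- network_measures(iso)
  expect_equal(mi$lcc_size, 3)
  expect_equal(mi$avg_clustering, 3 / 4)
  expect_equal(mi$E_global, 6 / 12)  # 6 ordered connected pairs at delta 1

  expect_error(network_measures(make_net(matrix(numeric(0), 0, 3))))
})

test_that("transitivity of near-uniform ensembles approaches edge density", {
  # sampled regular-degree model: every pair equally likely at p = k/(n-1)
  pos <- random_positions(40, seed = 4)
  ring <- cbind(1:40, c(2:40, 1))
  ring2 <- cbind(1:40, c(3:40, 1, 2))
  net <- make_net(pos, rbind(ring, ring2))  # 4-regular
  fit <- fit_maxent(net, "k")
  p_target <- 4 / 39
  sims <- simulate(fit, nsim = 60, seed = 5)
  tr <- vapply(sims, function(e) {
    g <- igraph::graph_from_edgelist(e[, 1:2, drop = FALSE],
                                     directed = FALSE)
    t <- igraph::transitivity(g, type = "global")
    if (is.nan(t)) 0 else t
  }, numeric(1))
  expect_lt(abs(mean(tr) - p_target), 3 * sd(tr) / sqrt(length(tr)) + 0.01)
})

test_that("degree statistics use all nodes and interpolated quartiles", {
  s <- degree_stats(c(1, 2, 3, 10))
  expect_equal(s$mean, 4)
  expect_equal(s$median, 2.5)
  expect_equal(s$mean_over_median, 1.6)
  s2 <- degree_stats(rep(7, 12))
  expect_equal(s2$iqr, 0)
  expect_equal(s2$mean_over_median, 1)
  # isolated nodes count: mean = 2E/N
  pos <- random_positions(5, seed = 6)
  net <- make_net(pos, rbind(c(1, 2)))
  expect_equal(degree_stats(degree_sequence(net))$mean,
               2 * n_edges(net) / n_nodes(net))
})

test_that("wiring shuffle test matches exhaustive permutation enumeration", {
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0), c(3, 1, 1))
  net <- make_net(pos, rbind(c(1, 2), c(2, 3), c(3, 4)))
  # exhaustive distribution over all 4! position assignments
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
  L_exact <- apply(perms, 1, function(pm) {
    sum(sqrt(rowSums((pos[pm[net$edge_idx[, 1]], , drop = FALSE] -
                      pos[pm[net$edge_idx[, 2]], , drop = FALSE])^2)))
  })
  res <- wiring_shuffle_test(net, n_perm = 4000, seed = 7)
  expect_equal(mean(res$L_perm), mean(L_exact), tolerance = 0.02)
  expect_true(all(round(res$L_perm, 9) %in% round(L_exact, 9)))
  expect_equal(res$L_obs, wiring_length(net))
  # exact permutation p-value at add-one smoothing
  p_exact <- mean(L_exact <= res$L_obs)
  expect_equal(res$p_value, p_exact, tolerance = 0.03)

  # under the null (random positions) the p-value is roughly uniform
  set.seed(8)
  pvals <- replicate(120, {
    netr <- make_net(random_positions(8, seed = sample.int(1e6, 1)),
                     random_edges(8, 0.4, seed = sample.int(1e6, 1)))
    wiring_shuffle_test(netr, n_perm = 99,
                        seed = sample.int(1e6, 1))$p_value
  })
  expect_gt(mean(pvals), 0.35)
  expect_lt(mean(pvals), 0.65)
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.001)
})

test_that("classification curves handle separation, ties and match pROC", {
  labs <- c(1, 1, 1, 0, 0, 0, 0, 0)
  perfect <- edge_classification_curves(c(9, 8, 7, 3, 2, 1, 1, 0), labs)
  expect_equal(perfect$auc_roc, 1)
  expect_equal(perfect$auc_pr, 1)

  const <- edge_classification_curves(rep(0.4, 8), labs)
  expect_equal(const$auc_roc, 0.5)
  expect_equal(const$auc_pr, 3 / 8)  # positive prevalence

  expect_error(edge_classification_curves(1:4, c(1, 1, 1, 1)), "both classes")

  skip_if_not_installed("pROC")
  set.seed(9)
  sc <- runif(300)
  y <- rbinom(300, 1, plogis(4 * sc - 2))
  if (length(unique(y)) == 2) {
    ours <- edge_classification_curves(sc, y)
    ref <- suppressMessages(pROC::auc(pROC::roc(y, sc, direction = "<")))
    expect_equal(ours$auc_roc, as.numeric(ref), tolerance = 1e-10)
  }

  # a model scored on data sampled from itself beats chance
  scn <- synthetic_scenario(n = 100, seed = 10)
  fit <- fit_maxent(scn$connectome, "d")
  e <- simulate(fit, nsim = 1, seed = 11)[[1]]
  pr <- predict(fit)
  lab <- paste(pr$i, pr$j) %in% paste(e[, 1], e[, 2])
  expect_gt(edge_classification_curves(pr$p, lab)$auc_roc, 0.5)
})

test_that("weight correlation reproduces rank arithmetic", {
  p <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  expect_equal(weight_correlation(p, c(1, 2, 5, 9, 11))$r_s, 1)
  # one tie, hand-ranked: ranks w = (1, 2.5, 2.5, 4, 5)
  w <- c(1, 3, 3, 7, 9)
  hand <- cor(rank(p), rank(w), method = "pearson")
  got <- weight_correlation(p, w)
  expect_equal(got$r_s, hand)
  expect_true(got$p_value > 0 && got$p_value < 1)
  expect_true(is.na(weight_correlation(p, rep(2, 5))$r_s))
  expect_error(weight_correlation(1:2, 1:2), "at least 3")
})

test_that("ensemble comparison computes fold changes, z and stars", {
  ec <- ensemble_compare(10, c(9, 10, 11, 10))
  expect_equal(ec$z, 0)
  expect_equal(ec$p_two_sided, 1)
  expect_equal(ec$significance, "n.s.")
  expect_equal(ec$inverse_fold_change, 1)

  mv <- rnorm(100)
  mv <- (mv - mean(mv)) / sd(mv)  # mean 0, sd 1 exactly
  ec2 <- ensemble_compare(2, mv)
  expect_equal(ec2$p_two_sided, 2 * (1 - pnorm(2)), tolerance = 1e-12)
  expect_equal(ec2$significance, "*")
  ec3 <- ensemble_compare(5, mv)
  expect_equal(ec3$significance, "***")
  expect_equal(ec3$inverse_fold_change, 0)

  ec4 <- ensemble_compare(3, c(2, 2))
  expect_true(is.na(ec4$p_two_sided))
})
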