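test_that("Fisher aggregation is exact on constant inputs and symmetric", {
  expect_equal(fisher_mean_rho(rep(0.7, 5)), 0.7, tolerance = 1e-12)
  expect_equal(fisher_mean_rho(c(0.5, -0.5)), 0)
  expect_equal(fisher_z_inv(fisher_z(0.83)), 0.83, tolerance = 1e-12)
})

test_that("correlation reports match a direct computation with Fisher CI", {
  set.seed(10)
  x <- rnorm(10); y <- x + rnorm(10, 0, 0.5)
  cr <- correlate(x, y)
  # brute-force Pearson formula
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cr$rho, r_direct, tolerance = 1e-12)
  expect_equal(cr$ci, tanh(atanh(r_direct) + c(-1, 1) * 1.96 / sqrt(10 - 3)),
               tolerance = 1e-12)
  expect_equal(cr$p_value, cor.test(x, y)$p.value, tolerance = 1e-10)
  expect_equal(correlate(x, x)$rho, 1)
  expect_equal(correlate(x, -x)$rho, -1)
  expect_error(correlate(x[1:2], y[1:2]), "fewer than 3")
  expect_error(correlate(x, rep(1, 10)), "zero variance")
})

test_that("the neighbour threshold filters the correlation sample only", {
  set.seed(11)
  x <- rnorm(30); y <- x + rnorm(30, 0, .2)
  deg <- rep(c(1L, 5L), 15)
  cr <- correlate(x, y, neighbor_threshold = 3L, n_neighbors = deg)
  expect_equal(cr$n, 15L)
  expect_equal(cr$rho, cor(x[deg >= 3], y[deg >= 3]))
  expect_error(correlate(x, y, neighbor_threshold = 3L), "n_neighbors")
})

test_that("cross-validation recovers planted structure and reports coverage", {
  fx <- random_fixture(41, n_clusters = 5L, words_per_cluster = 14L,
                       coverage = 0.6)
  mt <- match_nodes(fx$net, fx$lexicon, "word")
  cv <- cross_validate(fx$net, mt, propagation_config(), reps = 5L, seed = 3)
  expect_gt(cv$rho[["valence"]], 0.5)
  expect_true(cv$pct_computable > 50 && cv$pct_computable <= 100)
  expect_equal(nrow(cv$per_rep), 5L)
  # train_frac = 1 degenerates to the full-network analysis path
  cv1 <- cross_validate(fx$net, mt, propagation_config(), train_frac = 1)
  fa <- full_network_analysis(fx$net, mt, propagation_config())
  expect_equal(cv1$rho[["valence"]], fa$correlations$valence$rho,
               tolerance = 1e-10)
})

test_that("cross-validation with constant ratings exercises the error path", {
  net <- path_net(letters[1:12])
  seeds <- seed_df(letters[1:10], rep(0.5, 10))
  expect_error(
    suppressWarnings(cross_validate(net, seeds, propagation_config(),
                                    reps = 2L, seed = 1)),
    "no repetition")
})

test_that("permuted-values null is centred at zero and reproducible under a seed", {
  set.seed(12)
  x <- rnorm(60); y <- x + rnorm(60, 0, .3)
  nm1 <- null_permuted_values(x, y, reps = 500L, seed = 99)
  nm2 <- null_permuted_values(x, y, reps = 500L, seed = 99)
  expect_identical(nm1$null_rho, nm2$null_rho)
  expect_lt(abs(nm1$mean_rho), 0.05)
  expect_lt(nm1$p_empirical, 0.05)
  # add-one rule bounds the p-value away from zero
  expect_gte(nm1$p_empirical, 1 / 501)
  # constant estimates are flagged, not fatal
  nm3 <- null_permuted_values(x, rep(1, 60), reps = 50L, seed = 1)
  expect_true(nm3$undefined_flag)
  expect_equal(nm3$mean_rho, 0)
})

test_that("random-neighbours null preserves degrees, is seeded, and centres at zero", {
  fx <- random_fixture(43, n_clusters = 5L, words_per_cluster = 16L,
                       coverage = 0.5)
  mt <- match_nodes(fx$net, fx$lexicon, "word")
  nm1 <- null_random_neighbors(fx$net, mt, propagation_config(),
                               reps = 100L, seed = 7)
  nm2 <- null_random_neighbors(fx$net, mt, propagation_config(),
                               reps = 100L, seed = 7)
  expect_identical(nm1$null_rho, nm2$null_rho)
  expect_lt(abs(nm1$mean_rho), 0.15)
  expect_lt(nm1$p_empirical, 0.05)
})

test_that("language-threshold sweeps reproduce the unfiltered run at t = 1", {
  fx <- random_fixture(45, n_clusters = 4L, words_per_cluster = 12L,
                       coverage = 0.6)
  tab <- language_threshold_sweep(fx$net, fx$lexicon, propagation_config(),
                                  thresholds = c(1L, 2L, 50L))
  expect_equal(nrow(tab), 3L)
  mt <- match_nodes(fx$net, fx$lexicon, "word")
  fa <- full_network_analysis(fx$net, mt, propagation_config())
  expect_equal(tab$rho[1], fa$correlations$valence$rho, tolerance = 1e-8)
  # monotone edge counts; an emptying threshold flags rather than fails
  expect_true(all(diff(tab$n_edges) <= 0))
  expect_true(tab$flagged[3])
})

test_that("dominance-residual analysis is exact at the extremes and affine-invariant", {
  set.seed(13)
  V <- rnorm(200); D <- 0.7 * V + rnorm(200)
  # perfect estimate explains all residual variance
  expect_equal(dominance_residual_analysis(V, D, D)$pct_residual_explained, 100,
               tolerance = 1e-9)
  # estimate collinear with valence is flagged with 0
  out <- dominance_residual_analysis(V, D, 2 * V + 3)
  expect_true(out$collinear_flag)
  expect_equal(out$pct_residual_explained, 0)
  # affine rescaling of all three inputs changes nothing
  Dh <- 0.7 * V + 0.5 * (D - 0.7 * V) + rnorm(200, 0, .5)
  a <- dominance_residual_analysis(V, D, Dh)
  b <- dominance_residual_analysis(2 * V - 1, 10 * D + 3, 0.1 * Dh - 7)
  expect_equal(a$pct_residual_explained, b$pct_residual_explained,
               tolerance = 1e-8)
  # independent estimate explains nothing, in expectation
  z <- dominance_residual_analysis(V, D, rnorm(200))
  expect_lt(z$pct_residual_explained, 5)
})
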