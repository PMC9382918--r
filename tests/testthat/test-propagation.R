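test_that("weighted neighbour means follow the edge weights", {
  net <- make_net(a = rep("x", 3), b = c("p", "q", "r"),
                  lw = c(3, 2, 1), fw = c(2, 2, 1))
  vals <- c(p = 0.9, q = 0.5, r = 0.1)
  expect_equal(weighted_neighbor_mean("x", vals, net, "language"), 3.8 / 6)
  expect_equal(weighted_neighbor_mean("x", vals, net, "unweighted"), 0.5)
  # single valued neighbour is returned as-is whatever the weight
  expect_equal(weighted_neighbor_mean("x", c(p = 0.7), net, "language"), 0.7)
  # no valued neighbour is NA, not zero
  expect_true(is.na(weighted_neighbor_mean("x", c(zz = 1), net, "language")))
  expect_true(is.na(weighted_neighbor_mean("isolated", vals, net, "language")))
})

test_that("a path with fixed endpoints converges to the harmonic interpolant", {
  net <- path_net(letters[1:5])
  seeds <- seed_df(c("a", "e"), c(0, 1))
  res <- propagate(net, seeds, propagation_config(convergence_tol = 1e-10))
  est <- res$estimates
  v <- stats::setNames(est$valence, est$node)
  expect_equal(unname(v[c("b", "c", "d")]), c(0.25, 0.5, 0.75), tolerance = 1e-7)
  # 3-node path midpoint
  net3 <- path_net(c("a", "b", "c"))
  r3 <- propagate(net3, seed_df(c("a", "c"), c(0, 1)), propagation_config())
  expect_equal(r3$estimates$valence[r3$estimates$node == "b"], 0.5,
               tolerance = 1e-6)
})

test_that("components without seeds are discarded and tracked in coverage", {
  net <- make_net(c("a", "c"), c("b", "d"), c(1, 1))
  seeds <- seed_df("a", 0.4)
  res <- propagate(net, seeds, propagation_config())
  expect_setequal(res$discarded_nodes, c("c", "d"))
  expect_equal(res$coverage, 0.5)
  expect_false(any(c("c", "d") %in% res$estimates$node))
  expect_error(propagate(net, seed_df("nowhere", 1), propagation_config()),
               "no seeded nodes")
})

test_that("seeds hold their values and matching estimates are leave-self-out", {
  # triangle with two seeds: third node 0.5, seed-0 estimate mean(1, 0.5)
  net <- make_net(c("a", "a", "b"), c("b", "c", "c"), c(1, 1, 1))
  seeds <- seed_df(c("a", "c"), c(0, 1))
  cfg <- propagation_config(convergence_tol = 1e-12)
  res <- propagate(net, seeds, cfg)
  est <- res$estimates
  expect_equal(est$valence[est$node == "a"], 0)   # clamped
  expect_equal(est$valence[est$node == "b"], 0.5, tolerance = 1e-8)
  lso <- estimate_matching(net, seeds, res, cfg)
  expect_equal(lso$valence[lso$node == "a"], 0.75, tolerance = 1e-8)
  expect_equal(lso$valence[lso$node == "c"], 0.25, tolerance = 1e-8)
})

test_that("a seed whose only neighbour is seeded inherits that value; stars are fixed points", {
  net <- make_net("a", "b", 1)
  seeds <- seed_df(c("a", "b"), c(0.4, 0.8))
  res <- propagate(net, seeds, propagation_config())
  lso <- estimate_matching(net, seeds, res, propagation_config())
  expect_equal(lso$valence[lso$node == "a"], 0.8)
  expect_equal(lso$valence[lso$node == "b"], 0.4)
  # star: leaves converge to the centre value, centre estimate equals itself
  star <- make_net(rep("hub", 4), paste0("leaf", 1:4), rep(2, 4))
  s <- seed_df("hub", 0.3)
  r <- propagate(star, s, propagation_config())
  expect_true(all(abs(r$estimates$valence - 0.3) < 1e-8))
  l <- estimate_matching(star, s, r, propagation_config())
  expect_equal(l$valence[l$node == "hub"], 0.3, tolerance = 1e-8)
})

test_that("converged values agree with the direct harmonic solution", {
  cfg <- propagation_config(convergence_tol = 1e-10)
  for (s in 1:6) {
    fx <- random_fixture(s)
    mt <- match_nodes(fx$net, fx$lexicon, "word")
    res <- propagate(fx$net, mt, cfg)
    oracle <- harmonic_solve_oracle(fx$net, mt$ratings, "language", "valence")
    est <- stats::setNames(res$estimates$valence, res$estimates$node)
    common <- intersect(names(est), names(oracle)[!is.na(oracle)])
    expect_gt(length(common), 10)
    expect_lt(max(abs(est[common] - oracle[common])), 1e-6)
  }
})

test_that("estimates respect the maximum principle and node relabelling", {
  cfg <- propagation_config()
  fx <- random_fixture(17)
  mt <- match_nodes(fx$net, fx$lexicon, "word")
  res <- propagate(fx$net, mt, cfg)
  rng <- range(mt$ratings$valence)
  expect_true(all(res$estimates$valence >= rng[1] - 1e-9 &
                    res$estimates$valence <= rng[2] + 1e-9))
  # permuting the node order leaves per-node results unchanged
  net2 <- fx$net
  perm <- sample(seq_along(net2$nodes))
  net2$nodes <- net2$nodes[perm]
  res2 <- propagate(net2, mt, cfg)
  v1 <- stats::setNames(res$estimates$valence, res$estimates$node)
  v2 <- stats::setNames(res2$estimates$valence, res2$estimates$node)
  expect_equal(v1[sort(names(v1))], v2[sort(names(v1))], tolerance = 1e-10)
})

test_that("unweighted mode equals language mode when language weights are constant", {
  net <- path_net(letters[1:6])
  seeds <- seed_df(c("a", "f"), c(0.1, 0.9))
  r1 <- propagate(net, seeds, propagation_config("language",
                                                 convergence_tol = 1e-10))
  r2 <- propagate(net, seeds, propagation_config("unweighted",
                                                 convergence_tol = 1e-10))
  expect_equal(r1$estimates$valence, r2$estimates$valence, tolerance = 1e-9)
})

test_that("hitting the iteration cap warns and flags non-convergence", {
  net <- path_net(letters[1:10])
  seeds <- seed_df(c("a", "j"), c(0, 1))
  expect_warning(
    res <- propagate(net, seeds, propagation_config(max_iterations = 3L)),
    "max_iterations")
  expect_false(res$converged[["valence"]])
})

test_that("neighbour SDs are unweighted sample SDs with a two-neighbour minimum", {
  net <- make_net(rep("x", 2), c("p", "q"), c(5, 1))
  expect_equal(neighbor_sd(net, "x", c(p = 0.5, q = 0.5)), 0)
  expect_equal(neighbor_sd(net, "x", c(p = 0, q = 1)), sqrt(0.5),
               tolerance = 1e-12)
  expect_true(is.na(neighbor_sd(net, "p", c(x = 1))))  # single neighbour
  # vectorised version agrees with the per-node one
  fx <- random_fixture(31)
  vals <- stats::setNames(fx$truth$valence, fx$truth$word)
  sds <- neighbor_sd_all(fx$net, vals)
  for (nd in names(sds)[1:5])
    expect_equal(unname(sds[nd]), neighbor_sd(fx$net, nd, vals),
                 tolerance = 1e-12)
})
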