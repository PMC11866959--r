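make_pool <- function(n = 5, seed = 33, q = seq(0.005, 0.4, length.out = 120)) {
  base <- make_helix(8)
  ens <- perturb_ensemble(base, n, magnitude = 1.2, seed = seed)
  lapply(unclass(ens), function(m) debye_intensity(m, q, c2 = 0))
}

test_that("a single member reduces to the plain scale fit", {
  pool <- make_pool(1)
  q <- pool[[1]]$q
  exp <- saxs_profile(q, 2.4 * pool[[1]]$I, 0.01 * pool[[1]]$I)
  ms <- fit_state_weights(exp, pool)
  direct <- fit_chi2(exp, pool[[1]])
  expect_equal(ms$fit$chi2, direct$chi2, tolerance = 1e-10)
  expect_equal(ms$c, direct$c, tolerance = 1e-10)
  expect_equal(ms$weights, 1)
})

test_that("a planted two-state mixture is recovered with its weights", {
  pool <- make_pool(5)
  q <- pool[[1]]$q
  mix <- 0.7 * pool[[2]]$I + 0.3 * pool[[4]]$I
  exp <- saxs_profile(q, mix, 0.01 * mix)
  ms <- fit_state_weights(exp, pool[c(2, 4)], members = c(2, 4))
  expect_equal(ms$weights, c(0.7, 0.3), tolerance = 1e-3, ignore_attr = TRUE)
  expect_lt(ms$fit$chi2, 1e-10)
  expect_equal(sum(ms$weights), 1, tolerance = 1e-9)
  # the true pair wins among all five decoys at state count 2
  scan <- enumerate_states(exp, pool, max_states = 2, K = Inf)
  expect_equal(sort(scan$models[[2]]$members), c(2, 4))
  w <- scan$models[[2]]$weights[order(scan$models[[2]]$members)]
  expect_equal(w, c(0.7, 0.3), tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("duplicated members change the weight split but not the fit", {
  pool <- make_pool(2)
  q <- pool[[1]]$q
  exp <- saxs_profile(q, pool[[1]]$I, 0.01 * pool[[1]]$I)
  a <- fit_state_weights(exp, pool[c(1, 1)])
  b <- fit_state_weights(exp, pool[1])
  expect_equal(a$fit$chi2, b$fit$chi2, tolerance = 1e-9)
  expect_equal(a$fit$profile$I_fit, b$fit$profile$I_fit, tolerance = 1e-9)
})

test_that("NNLS weights match a dense simplex grid search on two members", {
  pool <- make_pool(2, seed = 44)
  q <- pool[[1]]$q
  mix <- 0.7 * pool[[1]]$I + 0.3 * pool[[2]]$I
  exp <- saxs_profile(q, mix, 0.01 * mix)
  ms <- fit_state_weights(exp, pool)
  # simplex grid, step 0.01, analytic scale at each node
  grid_chi2 <- vapply(seq(0, 1, by = 0.01), function(w1) {
    I_mix <- w1 * pool[[1]]$I + (1 - w1) * pool[[2]]$I
    oracle_chi2(exp$I, I_mix, exp$sigma)
  }, numeric(1))
  expect_lte(ms$fit$chi2, min(grid_chi2) + 1e-6)
  expect_gte(ms$fit$chi2, -1e-12)
  # planted optimum lies on the grid, so the two agree tightly
  expect_equal(ms$fit$chi2, min(grid_chi2), tolerance = 1e-6)
})

test_that("best chi2 is non-increasing in the state count", {
  pool <- make_pool(5, seed = 55)
  q <- pool[[1]]$q
  mix <- 0.5 * pool[[1]]$I + 0.3 * pool[[3]]$I + 0.2 * pool[[5]]$I
  exp <- saxs_profile(q, mix * (1 + rnorm(length(q), 0, 0.005)), 0.01 * mix)
  scan <- enumerate_states(exp, pool, max_states = 4, K = 10)
  expect_true(all(diff(scan$summary$chi2) <= 1e-9))
  # adding members never hurts the optimum relative to the best single member
  singles <- vapply(pool, function(p) fit_chi2(exp, p)$chi2, numeric(1))
  expect_lte(scan$summary$chi2[2], min(singles) + 1e-9)
})

test_that("exhaustive pair search equals the K = Inf beam", {
  pool <- make_pool(5, seed = 66)
  q <- pool[[1]]$q
  mix <- 0.6 * pool[[2]]$I + 0.4 * pool[[5]]$I
  exp <- saxs_profile(q, mix, 0.01 * mix)
  scan <- enumerate_states(exp, pool, max_states = 2, K = Inf)
  pair_chi2 <- sapply(utils::combn(5, 2, simplify = FALSE), function(sub)
    fit_state_weights(exp, pool[sub])$fit$chi2)
  expect_equal(scan$summary$chi2[2], min(pair_chi2), tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  pool <- make_pool(1)
  q <- pool[[1]]$q
  exp <- saxs_profile(q, pool[[1]]$I, 0.01 * pool[[1]]$I)
  zero <- saxs_profile(q, rep(0, length(q)))
  expect_error(fit_state_weights(exp, list(zero)), "zero")
  expect_error(enumerate_states(exp, pool, max_states = 2), "max_states")
})
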