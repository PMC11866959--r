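test_that("subprofile decomposition is exact against the direct Debye oracle", {
  fix <- ion_fixture()
  cache <- fix$cache
  # empty subset: RNA profile exactly
  expect_equal(assemble_subset(cache, integer(0))$I, cache$I_rna)
  expect_equal(cache$I_rna,
               debye_intensity(fix$helix, fix$q)$I, tolerance = 1e-12)
  with_ions <- function(subset) {
    debye_intensity(atomic_model(dplyr::bind_rows(
      tibble::as_tibble(fix$helix)[, c("element", "x", "y", "z", "role", "sasa")],
      tibble::tibble(element = "MG", x = fix$cand$x[subset],
                     y = fix$cand$y[subset], z = fix$cand$z[subset],
                     role = "MG", sasa = NA_real_))), fix$q)$I
  }
  for (subset in list(3L, c(2L, 5L), 1:8)) {
    direct <- with_ions(subset)
    asm <- assemble_subset(cache, subset)$I
    expect_equal(asm, direct, tolerance = 1e-8)
  }
})

test_that("assembly is permutation-invariant and rejects duplicates", {
  cache <- ion_fixture()$cache
  expect_equal(assemble_subset(cache, c(5, 2, 7))$I,
               assemble_subset(cache, c(7, 5, 2))$I)
  expect_error(assemble_subset(cache, c(2, 2)), "duplicate")
})

test_that("candidates clashing with RNA atoms are rejected with a warning", {
  fix <- ion_fixture()
  bad <- rbind(fix$cand[1:2, ],
               data.frame(x = fix$helix$x[1], y = fix$helix$y[1],
                          z = fix$helix$z[1]))
  expect_warning(cache <- precompute_subprofiles(fix$helix, bad, q = fix$q),
                 "rejected")
  expect_equal(cache$M, 2)
})

test_that("branch-and-bound with a wide beam equals exhaustive enumeration", {
  fix <- ion_fixture()
  cand6 <- fix$cand[1:6, ]
  cache <- precompute_subprofiles(fix$helix, cand6, q = fix$q)
  target <- assemble_subset(cache, c(2, 6))
  sigma <- 0.01 * target$I + 0.002 * target$I[1] * fix$q / max(fix$q)
  exp <- saxs_profile(fix$q, target$I, sigma)
  bb <- branch_and_bound(exp, cache, K = Inf, max_ions = 3)
  # exhaustive oracle: best subset and best chi2 per size
  best <- list(chi2 = oracle_chi2(exp$I, cache$I_rna, exp$sigma),
               subset = integer(0))
  best_by_size <- c()
  for (n in 1:3) {
    size_best <- Inf
    for (subset in utils::combn(6, n, simplify = FALSE)) {
      chi2 <- oracle_chi2(exp$I, assemble_subset(cache, subset)$I, exp$sigma)
      size_best <- min(size_best, chi2)
      if (chi2 < best$chi2) best <- list(chi2 = chi2, subset = subset)
    }
    best_by_size <- c(best_by_size, size_best)
  }
  expect_equal(bb$subset, best$subset)
  expect_equal(bb$fit$chi2, best$chi2, tolerance = 1e-10)
  # with K = Inf every visited level's best equals the brute-force best of
  # that size (the search stops once a level fails to improve, per the
  # termination rule, so only improving levels appear in the trajectory)
  lv <- bb$trajectory$chi2[-1]
  expect_gte(length(lv), 2)
  expect_equal(lv, best_by_size[seq_along(lv)], tolerance = 1e-10)
})

test_that("a planted ion subset is recovered exactly from a noise-free simulation", {
  fix <- ion_fixture()
  exp <- simulate_profile(fix$helix, fix$q, noise_model(scale = 0),
                          ions = fix$cand[c(2, 5), ], seed = 9)
  bb <- branch_and_bound(exp, fix$cache, K = 50)
  expect_identical(bb$subset, c(2L, 5L))
  expect_lt(bb$fit$chi2, 1e-10)
})

test_that("search stops immediately when no ion improves the fit", {
  fix <- ion_fixture()
  rna_only <- debye_intensity(fix$helix, fix$q)
  sigma <- 0.01 * rna_only$I + 1e-6
  exp <- saxs_profile(fix$q, rna_only$I, sigma)
  bb <- branch_and_bound(exp, fix$cache, K = 10)
  expect_identical(bb$subset, integer(0))
  expect_lt(bb$fit$chi2, 1e-15)
  expect_equal(nrow(bb$trajectory), 1)
})

test_that("chi2 trajectory is non-increasing and beams are ordered sanely", {
  fix <- ion_fixture()
  exp <- simulate_profile(fix$helix, fix$q, noise_model(),
                          ions = fix$cand[c(1, 3, 6), ], seed = 21)
  wide <- branch_and_bound(exp, fix$cache, K = Inf)
  greedy <- branch_and_bound(exp, fix$cache, K = 1)
  expect_true(all(diff(wide$trajectory$chi2) <= 1e-12))
  expect_true(all(diff(greedy$trajectory$chi2) <= 1e-12))
  # the wide beam can never be beaten by the greedy beam
  expect_lte(wide$fit$chi2, greedy$fit$chi2 + 1e-12)
  # trajectory tidier mirrors the trajectory
  td <- tidy(wide)
  expect_equal(nrow(td), nrow(wide$trajectory))
})
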