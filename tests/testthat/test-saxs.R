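q21 <- seq(0, 0.5, length.out = 21)

test_that("vacuum form factors reproduce electron counts at q = 0", {
  z <- c(H = 1, C = 6, N = 7, O = 8, P = 15, MG = 12)
  for (el in names(z))
    expect_equal(ff_vacuum(el, 0), unname(z[el]), tolerance = 0.02)
  expect_equal(ff_water(0), 10, tolerance = 0.02)
})

test_that("effective form factor honours the c1/c2 contract", {
  q <- q21
  # c2 = 0: no hydration term regardless of accessibility
  expect_equal(effective_form_factor("O", q, c2 = 0, sasa = 1),
               ff_vacuum("O", q) - ff_dummy("O", q))
  # buried atom (s = 0): independent of c2
  expect_equal(effective_form_factor("P", q, c2 = 2, sasa = 0),
               effective_form_factor("P", q, c2 = -1, sasa = 0))
  # q = 0, c1 = 1, c2 = 0: electron count minus displaced-solvent electrons
  expect_equal(effective_form_factor("C", 0, c2 = 0),
               ff_vacuum("C", 0) - 0.334 * 16.44, tolerance = 1e-10)
  expect_error(effective_form_factor("C", q, c1 = 0.5), "c1")
  expect_error(effective_form_factor("C", q, c2 = 5), "c2")
})

test_that("Debye intensity matches the naive double-loop oracle", {
  for (n in c(5, 25)) {
    m <- random_model(n, seed = n)
    prof <- debye_intensity(m, q21, c2 = 0)
    F <- t(vapply(m$element,
                  function(e) ff_vacuum(e, q21) - ff_dummy(e, q21),
                  numeric(length(q21))))
    I <- naive_debye(as.matrix(m[, c("x", "y", "z")]), F, q21)
    expect_equal(prof$I, I, tolerance = 1e-10)
  }
})

test_that("Debye intensity is non-negative, rigid-motion invariant, with exact I(0)", {
  m <- random_model(30, seed = 7)
  prof <- debye_intensity(m, q21, c2 = 0)
  expect_true(all(prof$I >= 0))
  f0 <- sum(vapply(m$element, function(e) ff_vacuum(e, 0) - ff_dummy(e, 0),
                   numeric(1)))
  expect_equal(prof$I[1], f0^2, tolerance = 1e-12)
  rot <- rotate_model(m)
  expect_equal(debye_intensity(rot, q21, c2 = 0)$I, prof$I,
               tolerance = 1e-9)
})

test_that("single- and two-atom Debye limits behave as sinc limits demand", {
  one <- atomic_model(data.frame(element = "MG", x = 0, y = 0, z = 0))
  prof <- debye_intensity(one, q21, c2 = 0)
  f <- ff_vacuum("MG", q21) - ff_dummy("MG", q21)
  expect_equal(prof$I, f^2)
  # two identical atoms 10 A apart: at q = pi/10 the sinc term vanishes
  two <- atomic_model(data.frame(element = c("MG", "MG"), x = c(0, 10),
                                 y = 0, z = 0))
  qq <- pi / 10
  p2 <- debye_intensity(two, c(0, qq), c2 = 0)
  f2 <- ff_vacuum("MG", qq) - ff_dummy("MG", qq)
  expect_equal(p2$I[2], 2 * f2^2, tolerance = 1e-12)
})

test_that("chi2 fitting recovers scale and matches the closed form", {
  q <- c(0.1, 0.2, 0.3)
  calc <- saxs_profile(q, c(1, 1, 1))
  # identical profiles: chi2 = 0, c = 1
  f0 <- fit_chi2(saxs_profile(q, c(1, 1, 1), c(1, 1, 1)), calc)
  expect_equal(f0$chi2, 0)
  expect_equal(f0$c, 1)
  # pure scale
  f3 <- fit_chi2(saxs_profile(q, c(3, 3, 3), c(1, 1, 1)), calc)
  expect_equal(f3$chi2, 0)
  expect_equal(f3$c, 3)
  # closed form: I_exp = (2,1,1) -> c = 4/3, chi2 = 2/9
  fc <- fit_chi2(saxs_profile(q, c(2, 1, 1), c(1, 1, 1)), calc)
  expect_equal(fc$c, 4 / 3)
  expect_equal(fc$chi2, 2 / 9)
  # dense grid search over c confirms the analytic optimum
  grid <- vapply(seq(0.5, 2.5, by = 1e-4),
                 function(cc) mean((c(2, 1, 1) - cc)^2), numeric(1))
  expect_lte(fc$chi2, min(grid) + 1e-9)
})

test_that("chi2 is invariant under joint rescaling of data and errors", {
  set.seed(2)
  q <- seq(0.01, 0.4, length.out = 50)
  I_mod <- 100 * exp(-q^2 * 50)
  I_exp <- I_mod * 1.7 + rnorm(50, 0, 1)
  sg <- 0.02 * I_exp + 0.5
  f1 <- fit_chi2(saxs_profile(q, I_exp, sg), saxs_profile(q, I_mod))
  f2 <- fit_chi2(saxs_profile(q, 5 * I_exp, 5 * sg), saxs_profile(q, I_mod))
  expect_equal(f1$chi2, f2$chi2, tolerance = 1e-12)
  expect_equal(f2$c, 5 * f1$c, tolerance = 1e-12)
})

test_that("optimizing c1/c2 never fits worse than the fixed default", {
  helix <- ion_fixture()$helix
  q <- seq(0.01, 0.4, length.out = 60)
  target <- debye_intensity(helix, q, c1 = 1.02, c2 = 0.5)
  exp <- saxs_profile(q, target$I, 0.01 * target$I)
  fixed <- fit_chi2(exp, helix)
  opt <- fit_chi2(exp, helix, optimize_c1c2 = TRUE)
  expect_lte(opt$chi2, fixed$chi2)
  expect_equal(opt$c1, 1.02, tolerance = 0.011)
  expect_lt(opt$chi2, 0.05)
  # tidiers expose the parameters
  expect_identical(tidy(opt)$term, c("c", "c1", "c2"))
  expect_equal(glance(opt)$chi2, opt$chi2)
})

test_that("fit_chi2 validates errors and grid overlap", {
  q <- c(0.1, 0.2, 0.3)
  expect_error(fit_chi2(saxs_profile(q, c(1, 1, 1)), saxs_profile(q, 1:3)),
               "errors")
  expect_error(
    fit_chi2(saxs_profile(q, c(1, 1, 1), c(1, 1, 1)),
             saxs_profile(c(0.15, 0.25), c(1, 1))),
    "range")
  # interpolation path: finer computed grid
  fine <- saxs_profile(seq(0.05, 0.35, by = 0.01),
                       seq(0.05, 0.35, by = 0.01) * 2)
  f <- fit_chi2(saxs_profile(q, 2 * q, c(1, 1, 1)), fine)
  expect_equal(f$chi2, 0, tolerance = 1e-20)
})

test_that("profile text round trip is stable and tolerates comments", {
  f <- withr::local_tempfile(fileext = ".dat")
  q <- seq(0.01, 0.4, length.out = 100)
  p <- saxs_profile(q, 100 * exp(-q^2 * 30), 0.01 * 100 * exp(-q^2 * 30))
  write_profile(p, f)
  p2 <- read_profile(f)
  expect_equal(nrow(p2), 100)
  expect_equal(p2$q, p$q, tolerance = 1e-6)
  expect_equal(p2$I, p$I, tolerance = 1e-6)
  expect_equal(p2$sigma, p$sigma, tolerance = 1e-6)
  # comment lines are skipped; 2-column files are computed profiles
  writeLines(c("# a header", "# another", "0.1 5.0", "0.2 4.0"), f)
  p3 <- read_profile(f)
  expect_equal(nrow(p3), 2)
  expect_false(ionsaxs:::is_experimental(p3))
  writeLines(c("0.2 5.0", "0.1 4.0"), f)
  expect_error(read_profile(f), "increasing")
})
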