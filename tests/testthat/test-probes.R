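test_that("probes on an isolated atom sit exactly on its accessible sphere", {
  one <- atomic_model(data.frame(element = "O", x = 1, y = 2, z = 3,
                                 vdw = 1.5))
  ps <- generate_surface_probes(one, probe_radius = 1.5, density = 0.5)
  d <- sqrt((ps$x - 1)^2 + (ps$y - 2)^2 + (ps$z - 3)^2)
  expect_true(all(abs(d - 3.0) < 1e-9))
  expect_gt(nrow(ps), 10)
})

test_that("probes never penetrate vdW spheres; distant atoms give disjoint shells", {
  two <- atomic_model(data.frame(element = c("P", "P"), x = c(0, 100),
                                 y = 0, z = 0))
  ps <- generate_surface_probes(two, probe_radius = 1.5)
  d1 <- sqrt(ps$x^2 + ps$y^2 + ps$z^2)
  d2 <- sqrt((ps$x - 100)^2 + ps$y^2 + ps$z^2)
  expect_true(all(pmin(d1, d2) >= 1.8 - 1e-9))       # vdW of P
  expect_true(all(pmin(d1, d2) <= 1.8 + 2 * 1.5 + 1e-9))
  expect_true(any(d1 < 50) && any(d2 < 50))
})

test_that("probe count scales with the requested density", {
  m <- random_model(30, seed = 13, spread = 6)
  n1 <- nrow(generate_surface_probes(m, density = 0.2, dedup_spacing = 0))
  n2 <- nrow(generate_surface_probes(m, density = 0.4, dedup_spacing = 0))
  expect_gt(n2 / n1, 2 * 0.8)
  expect_lt(n2 / n1, 2 * 1.2)
})

test_that("probe generation is deterministic and deduplication thins clusters", {
  m <- random_model(20, seed = 17, spread = 5)
  a <- generate_surface_probes(m)
  b <- generate_surface_probes(m)
  expect_identical(a, b)
  dense <- generate_surface_probes(m, density = 2, dedup_spacing = 0)
  thinned <- generate_surface_probes(m, density = 2, dedup_spacing = 1)
  expect_lt(nrow(thinned), nrow(dense))
})

test_that("neighborhood extraction honours the radius cutoff exactly", {
  m <- atomic_model(data.frame(element = c("O", "O"), x = c(7.9, 8.1),
                               y = 0, z = 0, sasa = 0.5))
  g <- extract_neighborhood(m, c(0, 0, 0), radius = 8)
  expect_equal(nrow(g$nodes), 1)
  expect_equal(g$nodes$dist, 7.9)
  # probe in vacuum: empty-neighborhood signal
  expect_null(extract_neighborhood(m, c(100, 100, 100), radius = 8))
})

test_that("neighborhood node count matches a brute-force distance scan", {
  m <- random_model(100, seed = 19, spread = 10)
  m$sasa <- 0.5
  probe <- c(2, -1, 3)
  g <- extract_neighborhood(m, probe, radius = 8)
  d <- sqrt((m$x - 2)^2 + (m$y + 1)^2 + (m$z - 3)^2)
  expect_equal(nrow(g$nodes), sum(d <= 8))
  # edges: all pairs within the cutoff, carrying their distances
  xyz <- as.matrix(g$nodes[, c("x", "y", "z")])
  dm <- as.matrix(dist(xyz))
  expect_equal(nrow(g$edges), sum(upper.tri(dm) & dm <= 5))
})

test_that("neighborhood graphs are invariant under rigid motion", {
  m <- random_model(40, seed = 23, spread = 6)
  m$sasa <- runif(40)
  probe <- c(1, 1, 1)
  g1 <- extract_neighborhood(m, probe, radius = 8)
  rot <- rotate_model(m)
  # transform the probe the same way
  u <- c(1, 2, 3) / sqrt(14); angle <- 0.7
  ct <- cos(angle); st <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  R <- diag(3) * ct + st * ux + (1 - ct) * tcrossprod(u)
  probe2 <- as.vector(probe %*% t(R)) + c(5, -3, 2)
  g2 <- extract_neighborhood(rot, probe2, radius = 8)
  expect_equal(g2$nodes$dist, g1$nodes$dist, tolerance = 1e-9)
  expect_identical(g2$nodes$element, g1$nodes$element)
  expect_equal(g2$edges$dist, g1$edges$dist, tolerance = 1e-9)
  expect_identical(g2$edges[, c("i", "j")], g1$edges[, c("i", "j")])
})

test_that("probe pseudo-atom export writes one record per probe", {
  m <- random_model(5, seed = 3, spread = 4)
  ps <- generate_surface_probes(m, density = 0.05)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_probes_pdb(ps, f)
  lines <- readLines(f)
  expect_equal(sum(startsWith(lines, "HETATM")), nrow(ps))
})
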