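# Independent oracles and shared fixtures for the test suite.

# Naive O(N^2 S) double-loop Debye sum, independent of the compiled kernel.
naive_debye <- function(xyz, F, q) {
  n <- nrow(xyz)
  I <- numeric(length(q))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      x <- q * d
      s <- ifelse(x < 1e-12, 1, sin(x) / x)
      I <- I + F[i, ] * F[j, ] * s
    }
  }
  I
}

# chi2 with the analytic scale, written independently of the package.
oracle_chi2 <- function(I_exp, I_mod, sigma) {
  cc <- sum(I_exp * I_mod / sigma^2) / sum(I_mod^2 / sigma^2)
  mean(((I_exp - cc * I_mod) / sigma)^2)
}

random_model <- function(n, seed = 1, spread = 8) {
  set.seed(seed)
  atomic_model(data.frame(
    element = sample(c("C", "N", "O", "P"), n, replace = TRUE),
    x = rnorm(n, 0, spread), y = rnorm(n, 0, spread), z = rnorm(n, 0, spread)
  ))
}

rotate_model <- function(model, angle = 0.7, axis = c(1, 2, 3), shift = c(5, -3, 2)) {
  u <- axis / sqrt(sum(axis^2))
  ct <- cos(angle); st <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  R <- diag(3) * ct + st * ux + (1 - ct) * tcrossprod(u)
  xyz <- as.matrix(model[, c("x", "y", "z")]) %*% t(R)
  out <- model
  out$x <- xyz[, 1] + shift[1]
  out$y <- xyz[, 2] + shift[2]
  out$z <- xyz[, 3] + shift[3]
  out
}

# Small shared fixture: a 10-bp helix with accessibility plus 8 candidate
# surface sites, and a subprofile cache on a modest q grid. Built once per
# test run.
.fixture_env <- new.env(parent = emptyenv())

ion_fixture <- function() {
  if (is.null(.fixture_env$fix)) {
    helix <- assign_accessibility(make_helix(10))
    q <- seq(0, 0.5, length.out = 201)
    probes <- generate_surface_probes(helix, density = 0.05)
    set.seed(3)
    cand <- as.data.frame(probes[sample(nrow(probes), 8), ])
    cache <- precompute_subprofiles(helix, cand, q = q)
    .fixture_env$fix <- list(helix = helix, q = q, cand = cand, cache = cache)
  }
  .fixture_env$fix
}

# A helix decorated with oxygen-rich coordination pockets: a structure on
# which the neighborhood classifier genuinely fires.
pocket_model <- function() {
  helix <- make_helix(8)
  pocket <- function(center, seed) {
    set.seed(seed)
    octa <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1))
    dirs <- octa + matrix(rnorm(15, 0, 0.05), 5, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    xyz <- sweep(dirs * runif(5, 2.0, 2.2), 2, center, "+")
    tibble::tibble(element = "O", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   role = "RNA")
  }
  assign_accessibility(atomic_model(dplyr::bind_rows(
    tibble::as_tibble(helix)[, c("element", "x", "y", "z", "role")],
    pocket(c(14, 0, 2), 1), pocket(c(-14, 3, 18), 2)),
    label = "helix_pockets"))
}

# A quickly trained classifier, shared across test files.
shared_classifier <- function() {
  if (is.null(.fixture_env$classifier)) {
    graphs <- make_neighborhoods(150, 150, seed = 5)
    .fixture_env$classifier <-
      train_site_classifier(graphs, folds = 2, seed = 2, epochs = 120)
  }
  .fixture_env$classifier
}
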