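test_that("cross-validated training separates synthetic Mg shells from water shells", {
  cl <- shared_classifier()
  expect_s3_class(cl, "ion_classifier")
  expect_gte(min(cl$cv$auroc), 0.95)
  # training loss decreases
  expect_lt(cl$history[length(cl$history)], cl$history[1])
  expect_lt(min(cl$history), 0.1)
  expect_identical(names(glance(cl)),
                   c("auroc_mean", "auroc_sd", "folds", "hidden", "final_loss"))
})

test_that("shuffled labels give chance-level AUROC", {
  graphs <- make_neighborhoods(100, 100, seed = 6)
  set.seed(77)
  labels <- sample(c(rep(1L, 100), rep(0L, 100)))
  shuffled <- lapply(seq_along(graphs), function(i) {
    g <- graphs[[i]]; g$label <- labels[i]; g
  })
  cl <- train_site_classifier(shuffled, folds = 2, seed = 3, epochs = 60)
  expect_lt(abs(cl$auroc_mean - 0.5), 0.15)
})

test_that("training is reproducible and rejects degenerate inputs", {
  graphs <- make_neighborhoods(40, 40, seed = 9)
  a <- train_site_classifier(graphs, folds = 2, seed = 7, epochs = 30)
  b <- train_site_classifier(graphs, folds = 2, seed = 7, epochs = 30)
  expect_identical(a$cv$auroc, b$cv$auroc)
  expect_identical(a$params, b$params)
  pos_only <- make_neighborhoods(10, 0, seed = 1)
  expect_error(train_site_classifier(pos_only, folds = 2), "both classes")
})

test_that("predictions are probabilities, rigid-motion invariant, and class-separating", {
  cl <- shared_classifier()
  held <- make_neighborhoods(60, 60, seed = 123)   # fresh draw, same generator
  p <- predict(cl, held)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(median(p[1:60]), median(p[61:120]))
  # rotation of the source coordinates leaves the graph, hence the
  # probability, unchanged
  m <- random_model(50, seed = 41, spread = 5)
  m$sasa <- runif(50)
  g1 <- extract_neighborhood(m, c(0, 0, 0))
  g2 <- extract_neighborhood(rotate_model(m), c(5, -3, 2))  # probe moved along
  expect_equal(predict(cl, g1), predict(cl, g2), tolerance = 1e-9)
})

test_that("classifier checkpoints round trip through text and detect schema drift", {
  cl <- shared_classifier()
  f <- withr::local_tempfile(fileext = ".txt")
  write_classifier(cl, f)
  cl2 <- read_classifier(f)
  g <- make_neighborhoods(3, 0, seed = 2)
  expect_equal(predict(cl2, g), predict(cl, g), tolerance = 1e-12)
  # a graph extracted beyond the training radius is refused
  far <- probe_graph(tibble::tibble(element = "O", dist = 9.5, sasa = 0.5,
                                    x = 9.5, y = 0, z = 0))
  expect_error(predict(cl, far), "schema")
})

test_that("site selection clusters greedily and respects separation", {
  probes <- tibble::tibble(x = c(0, 1, 30), y = 0, z = 0)
  # close pair: only the higher-probability probe survives
  s <- select_sites(probes[1:2, ], c(0.9, 0.8), min_separation = 2)
  expect_equal(nrow(s), 1)
  expect_equal(s$probability, 0.9)
  # below threshold: empty result
  expect_equal(nrow(select_sites(probes, c(0.4, 0.3, 0.2))), 0)
  # mutually distant: all retained, sorted by probability
  far <- tibble::tibble(x = c(0, 20, 40), y = 0, z = 0)
  s3 <- select_sites(far, c(0.6, 0.95, 0.7), min_separation = 2)
  expect_equal(s3$probability, c(0.95, 0.7, 0.6))
})

test_that("selected sites are pairwise separated and monotone in threshold", {
  set.seed(15)
  n <- 150
  probes <- tibble::tibble(x = runif(n, 0, 30), y = runif(n, 0, 30),
                           z = runif(n, 0, 30))
  prob <- runif(n)
  for (ms in c(2, 5)) {
    s <- select_sites(probes, prob, threshold = 0.3, min_separation = ms)
    if (nrow(s) > 1) {
      dmin <- min(dist(as.matrix(s[, c("x", "y", "z")])))
      expect_gte(dmin, ms)
    }
  }
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th)
    nrow(select_sites(probes, prob, threshold = th, min_separation = 3)),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})
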