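# Training, cross-validation and site selection for the Mg2+ / water
# neighborhood classifier.

#' Train the Mg2+ binding-site classifier
#'
#' Trains the graph neural network (attention + convolution layers, mean
#' pooling, logistic read-out) on labelled probe neighborhoods with
#' full-batch Adam, after k-fold cross-validation to estimate the AUROC.
#' Folds are stratified by class; class imbalance is handled by subsampling
#' the majority class to 1:1 each epoch. Fully reproducible given `seed`.
#'
#' @param graphs List of labelled [probe_graph()] objects (labels 0/1).
#' @param folds Number of cross-validation folds (>= 2).
#' @param seed Integer seed controlling initialisation, fold assignment and
#'   subsampling.
#' @param hidden Hidden width of every layer.
#' @param n_att,n_conv Number of attention and convolution layers.
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param radius Neighborhood radius the graphs were extracted with
#'   (feature scaling; part of the stored schema).
#' @return An `ion_classifier`: fitted parameters, per-fold AUROC tibble
#'   (`cv`), training-loss history and the feature schema.
#' @export
train_site_classifier <- function(graphs, folds = 4, seed = 1, hidden = 16,
                                  n_att = 1, n_conv = 1, epochs = 150,
                                  lr = 0.02, radius = 8) {
  stopifnot(folds >= 2, length(graphs) >= 2 * folds)
  labels <- vapply(graphs, function(g) as.numeric(g$label), numeric(1))
  if (anyNA(labels) || length(unique(labels)) < 2)
    stop("training needs labelled graphs of both classes", call. = FALSE)
  arch <- list(hidden = hidden, n_att = n_att, n_conv = n_conv)
  # stratified fold assignment
  set.seed(seed)
  fold_id <- integer(length(graphs))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  for (f in seq_len(folds)) {
    if (length(unique(labels[fold_id == f])) < 2)
      stop("every fold must contain both classes", call. = FALSE)
  }
  cv <- purrr::map_dfr(seq_len(folds), function(f) {
    tr <- gnn_train_core(graphs[fold_id != f], arch, epochs, lr,
                         seed = seed + f, radius = radius)
    p <- gnn_predict_core(tr$params, graphs[fold_id == f], radius = radius)
    auc <- as.numeric(pROC::auc(pROC::roc(
      response = labels[fold_id == f], predictor = p,
      quiet = TRUE, direction = "<", levels = c(0, 1))))
    tibble::tibble(fold = f, auroc = auc, n_test = sum(fold_id == f))
  })
  final <- gnn_train_core(graphs, arch, epochs, lr, seed = seed,
                          radius = radius)
  structure(list(params = final$params, arch = arch,
                 schema = gnn_schema_string(radius), radius = radius,
                 cv = cv, history = final$history,
                 auroc_mean = mean(cv$auroc), auroc_sd = sd(cv$auroc),
                 seed = seed),
            class = "ion_classifier")
}

#' @export
print.ion_classifier <- function(x, ...) {
  cat(sprintf(
    "Mg2+ site classifier: %d+%d layers, width %d; CV AUROC %.3f +/- %.3f (%d folds)\n",
    x$arch$n_att, x$arch$n_conv, x$arch$hidden,
    x$auroc_mean, x$auroc_sd, nrow(x$cv)))
  invisible(x)
}

#' Predict Mg2+ site probabilities for probe neighborhoods
#'
#' @param object An `ion_classifier`.
#' @param graphs A single [probe_graph()] or a list of them. The feature
#'   schema (element set, neighborhood radius) must match training.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict.ion_classifier <- function(object, graphs, ...) {
  if (inherits(graphs, "probe_graph")) graphs <- list(graphs)
  stopifnot(length(graphs) >= 1,
            all(vapply(graphs, inherits, TRUE, "probe_graph")))
  if (!identical(object$schema, gnn_schema_string(object$radius)))
    stop("feature schema mismatch", call. = FALSE)
  too_far <- vapply(graphs, function(g) any(g$nodes$dist > object$radius + 1e-9),
                    logical(1))
  if (any(too_far))
    stop("graph contains nodes beyond the training radius: schema mismatch",
         call. = FALSE)
  gnn_predict_core(object$params, graphs, radius = object$radius)
}

#' Serialise / restore a classifier checkpoint
#'
#' The checkpoint is plain JSON-free R `dput` text embedding the feature
#' schema, so `predict()` can detect a schema mismatch after reload.
#'
#' @param object An `ion_classifier`.
#' @param path File path.
#' @return `read_classifier()` returns the restored `ion_classifier`.
#' @export
write_classifier <- function(object, path) {
  stopifnot(inherits(object, "ion_classifier"))
  dput(unclass(object), file = path,
       control = c("keepNA", "keepInteger", "niceNames", "showAttributes",
                   "hexNumeric"))
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- dget(path)
  obj$cv <- tibble::as_tibble(obj$cv)
  structure(obj, class = "ion_classifier")
}

#' Cluster confident predictions into binding sites
#'
#' Greedy iterative clustering: repeatedly accept the highest-probability
#' probe above `threshold`, then discard every remaining probe within
#' `min_separation` of it; stops at `max_sites` or exhaustion. Ties are
#' broken by probe index. Raising the threshold can only shrink the
#' selection.
#'
#' @param probes A `probe_set` (or data frame with x, y, z), aligned with
#'   `probabilities`.
#' @param probabilities Numeric vector of per-probe probabilities.
#' @param threshold Probability cutoff (default 0.5; use 0.9 for a strict
#'   selection).
#' @param min_separation Minimum distance between accepted sites, Angstrom.
#' @param max_sites Cap on the number of accepted sites.
#' @return A tibble with `x`, `y`, `z`, `probability`, sorted by
#'   probability descending (possibly empty).
#' @export
select_sites <- function(probes, probabilities, threshold = 0.5,
                         min_separation = 3.5, max_sites = Inf) {
  stopifnot(nrow(probes) == length(probabilities),
            threshold > 0, threshold < 1, min_separation >= 0)
  xyz <- as.matrix(as.data.frame(probes)[, c("x", "y", "z")])
  avail <- which(probabilities >= threshold)
  out <- integer(0)
  while (length(avail) > 0 && length(out) < max_sites) {
    best <- avail[which.max(probabilities[avail])]  # ties: lowest index
    out <- c(out, best)
    d <- sqrt(colSums((t(xyz[avail, , drop = FALSE]) - xyz[best, ])^2))
    avail <- avail[d >= min_separation & avail != best]
  }
  tibble::tibble(x = xyz[out, 1], y = xyz[out, 2], z = xyz[out, 3],
                 probability = probabilities[out])
}
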