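# End-to-end pipeline: conformer scoring -> probe generation -> site
# classification -> ion subset selection -> (if needed) multistate fitting.

#' Run the full SAXS-guided modelling pipeline
#'
#' For each conformation: score the RNA-only fit; for the `top_conformers`
#' best, generate surface probes, classify their neighborhoods, cluster
#' confident predictions into candidate sites and select the ion subset by
#' branch-and-bound. If the best single-state chi2 (with ions) exceeds
#' `chi2_noise_cutoff` — i.e. no single conformation fits within the noise
#' — multistate models are enumerated over the ion-augmented conformer
#' profiles. `c1` and `c2` stay fixed at 1 unless `optimize_c1c2` is set
#' (optimising them together with ion placement invites overfitting).
#'
#' @param models An [rna_ensemble()], a list of `atomic_model`s, or a
#'   single `atomic_model`. The first member is taken as the starting
#'   structure.
#' @param exp Experimental [saxs_profile()] with errors.
#' @param classifier An `ion_classifier`, or `NULL` to skip ion placement.
#' @param threshold Site probability cutoff (default 0.5).
#' @param min_separation Minimum separation of accepted sites, Angstrom.
#' @param max_sites Cap on candidate sites per conformation.
#' @param K Beam width for subset searches.
#' @param max_ions Maximum ions per conformation.
#' @param max_states Maximum states for the multistate stage.
#' @param chi2_noise_cutoff Fit-within-noise criterion (default 1.3).
#' @param top_conformers Number of best RNA-only conformations that enter
#'   ion placement.
#' @param probe_density Surface probe density, probes per square Angstrom.
#' @param probe_radius Probe sphere radius for candidate generation,
#'   Angstrom. The default 1.5 samples the water-accessible surface; a
#'   small radius (~0.5, the bare-ion scale) lets probes reach tight
#'   coordination pockets.
#' @param optimize_c1c2 Optimise c1/c2 for the final reported fits.
#' @return A list of class `saxs_pipeline`: `summary` (per-conformer
#'   tibble), `best` (best single-state result), `multistate` (a
#'   `state_scan` or `NULL`), `config`.
#' @export
run_pipeline <- function(models, exp, classifier = NULL,
                         threshold = 0.5, min_separation = 3.5,
                         max_sites = 30, K = 50, max_ions = 30,
                         max_states = 4, chi2_noise_cutoff = 1.3,
                         top_conformers = 50, probe_density = 0.25,
                         probe_radius = 1.5, optimize_c1c2 = FALSE) {
  if (is_atomic_model(models)) models <- list(models)
  models <- unclass(models)
  stopifnot(length(models) >= 1, inherits(exp, "saxs_profile"))
  config <- list(threshold = threshold, min_separation = min_separation,
                 max_sites = max_sites, K = K, max_ions = max_ions,
                 max_states = max_states,
                 chi2_noise_cutoff = chi2_noise_cutoff,
                 top_conformers = top_conformers,
                 probe_density = probe_density, probe_radius = probe_radius,
                 optimize_c1c2 = optimize_c1c2)
  # stage: RNA-only scoring of every conformation
  models <- lapply(models, function(m) {
    if (anyNA(m$sasa)) assign_accessibility(m) else m
  })
  rna_fits <- lapply(models, function(m) fit_chi2(exp, m, optimize_c1c2))
  chi2_rna <- vapply(rna_fits, `[[`, numeric(1), "chi2")
  sel <- order(chi2_rna)[seq_len(min(top_conformers, length(models)))]
  # stage: ion placement on the selected conformations
  results <- vector("list", length(models))
  for (k in sel) {
    m <- models[[k]]
    res <- list(n_sites = 0L, chi2_ions = chi2_rna[k], selection = NULL)
    if (!is.null(classifier)) {
      probes <- generate_surface_probes(m, probe_radius = probe_radius,
                                        density = probe_density)
      graphs <- lapply(seq_len(nrow(probes)), function(i)
        extract_neighborhood(m, unlist(probes[i, c("x", "y", "z")]),
                             radius = classifier$radius))
      keep <- !vapply(graphs, is.null, logical(1))
      if (!any(keep)) {
        warning("conformation ", k, ": empty probe set, skipped", call. = FALSE)
      } else {
        probs <- predict(classifier, graphs[keep])
        sites <- select_sites(probes[keep, ], probs, threshold = threshold,
                              min_separation = min_separation,
                              max_sites = max_sites)
        if (nrow(sites) > 0) {
          cache <- precompute_subprofiles(m, sites, q = exp$q)
          bb <- branch_and_bound(exp, cache, K = K, max_ions = max_ions)
          res <- list(n_sites = length(bb$subset), chi2_ions = bb$fit$chi2,
                      selection = bb)
        }
      }
    }
    results[[k]] <- res
  }
  summary <- purrr::map_dfr(seq_along(models), function(k) {
    tibble::tibble(
      conformer = k,
      label = model_label(models[[k]]),
      chi2_rna = chi2_rna[k],
      chi2_ions = if (is.null(results[[k]])) NA_real_ else results[[k]]$chi2_ions,
      n_ions = if (is.null(results[[k]])) NA_integer_ else results[[k]]$n_sites,
      starting = k == 1L
    )
  })
  best_k <- sel[which.min(vapply(sel, function(k) results[[k]]$chi2_ions,
                                 numeric(1)))]
  best <- list(conformer = best_k,
               chi2 = results[[best_k]]$chi2_ions,
               selection = results[[best_k]]$selection,
               model = models[[best_k]])
  # stage: multistate models if no single state fits within the noise
  multistate <- NULL
  if (best$chi2 > chi2_noise_cutoff && length(sel) > 1) {
    pool <- lapply(sel, function(k) {
      r <- results[[k]]
      if (!is.null(r$selection))
        assemble_subset_for(models[[k]], r$selection, exp$q)
      else debye_intensity(models[[k]], exp$q)
    })
    ms <- enumerate_states(exp, pool,
                           max_states = min(max_states, length(pool)), K = K)
    ms$pool_conformers <- sel
    multistate <- ms
  }
  structure(list(summary = summary, best = best, multistate = multistate,
                 config = config),
            class = "saxs_pipeline")
}

# profile of a conformation plus its selected ions
assemble_subset_for <- function(model, selection, q) {
  if (length(selection$subset) == 0) return(debye_intensity(model, q))
  m <- tibble::as_tibble(model)[, c("element", "x", "y", "z", "role", "sasa")]
  ions <- selection$sites
  extra <- tibble::tibble(element = "MG", x = ions$x, y = ions$y, z = ions$z,
                          role = "MG", sasa = NA_real_)
  debye_intensity(atomic_model(dplyr::bind_rows(m, extra)), q)
}

#' @export
print.saxs_pipeline <- function(x, ...) {
  cat("SAXS pipeline run\n")
  cat(sprintf("  conformations scored: %d\n", nrow(x$summary)))
  cat(sprintf("  starting structure chi2 (RNA only): %.4f\n",
              x$summary$chi2_rna[x$summary$starting][1]))
  cat(sprintf("  best single state: conformer %d, chi2 = %.4f, %d ion(s)\n",
              x$best$conformer, x$best$chi2,
              length(x$best$selection$subset %||% integer(0))))
  if (!is.null(x$multistate)) {
    b <- x$multistate$summary
    cat(sprintf("  multistate: best chi2 = %.4f with %d state(s)\n",
                min(b$chi2), b$n_states[which.min(b$chi2)]))
  } else {
    cat("  multistate stage not needed (single state fits within the noise)\n")
  }
  invisible(x)
}
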