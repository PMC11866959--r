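# Scattering profiles, the Debye formula with excluded-volume / hydration
# adjustments, and chi-square fitting against experimental data.

#' Construct a scattering profile
#'
#' A scattering profile is a tibble with columns `q` (momentum transfer,
#' 1/Angstrom; \eqn{q = 4\pi \sin\theta / \lambda} with \eqn{2\theta} the
#' scattering angle and \eqn{\lambda} the X-ray wavelength), `I` (intensity,
#' arbitrary units) and `sigma` (experimental error; `NA` for computed,
#' error-free profiles).
#'
#' @param q Strictly increasing, non-negative numeric vector.
#' @param I Intensities, same length as `q`.
#' @param sigma Optional experimental errors (> 0), same length as `q`.
#' @return A tibble of class `saxs_profile`.
#' @export
saxs_profile <- function(q, I, sigma = NULL) {
  stopifnot(length(q) == length(I), all(q >= 0), all(diff(q) > 0))
  if (is.null(sigma)) sigma <- rep(NA_real_, length(q))
  stopifnot(length(sigma) == length(q))
  if (!all(is.na(sigma)) && any(sigma <= 0, na.rm = TRUE))
    stop("experimental errors must be positive", call. = FALSE)
  structure(tibble::tibble(q = q, I = I, sigma = sigma),
            class = c("saxs_profile", class(tibble::tibble())))
}

is_experimental <- function(profile) !all(is.na(profile$sigma))

#' Default computed q grid
#'
#' 501 points on 0 to 0.5 1/Angstrom, covering typical measured ranges.
#' @export
default_q_grid <- function() seq(0, 0.5, length.out = 501)

#' Read / write 3-column SAXS profiles
#'
#' Whitespace-delimited text with columns q (1/Angstrom), intensity and
#' (optionally) experimental error; `#` comment lines are skipped. A file
#' without an error column is marked as a computed, error-free profile.
#'
#' @param path File path.
#' @return `read_profile()` returns a [saxs_profile()].
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.table(path, comment.char = "#", header = FALSE)
  if (ncol(tab) < 2) stop("expected at least 2 columns", call. = FALSE)
  names(tab)[1:2] <- c("q", "I")
  if (any(diff(tab$q) <= 0)) stop("q must be strictly increasing", call. = FALSE)
  sigma <- if (ncol(tab) >= 3 && !all(is.na(tab[[3]]))) tab[[3]] else NULL
  saxs_profile(tab$q, tab$I, sigma)
}

#' @rdname read_profile
#' @param profile A [saxs_profile()].
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "saxs_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# q (1/A)  I  sigma", con)
  cols <- if (is_experimental(profile)) c("q", "I", "sigma") else c("q", "I")
  tab <- as.data.frame(lapply(as.data.frame(profile)[, cols],
                              formatC, digits = 9, format = "g"))
  write.table(tab, con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- form factors on a model -------------------------------------------------

check_c1c2 <- function(c1, c2) {
  if (c1 < 0.95 || c1 > 1.05)
    stop("c1 out of range [0.95, 1.05]: ", c1, call. = FALSE)
  if (c2 < -2 || c2 > 4)
    stop("c2 out of range [-2, 4]: ", c2, call. = FALSE)
  invisible(TRUE)
}

# Fill missing accessibilities under the scattering convention: RNA
# accessibility is a property of the RNA solute (computed from RNA atoms
# alone; placed ions do not occlude it), and each MG ion's accessibility is
# computed against the RNA plus that ion only. This keeps the per-atom
# factors identical whether a profile is computed directly or assembled
# from precomputed subprofiles.
ensure_sasa <- function(model) {
  idx_rna <- which(model$role == "RNA")
  idx_mg <- which(model$role == "MG")
  if (!anyNA(model$sasa[c(idx_rna, idx_mg)])) return(model)
  if (anyNA(model$sasa[idx_rna])) {
    rna <- assign_accessibility(model[idx_rna, , drop = FALSE])
    model$sasa[idx_rna] <- rna$sasa
  }
  for (k in idx_mg[is.na(model$sasa[idx_mg])]) {
    tmp <- atomic_model(tibble::as_tibble(
      model[c(idx_rna, k), c("element", "x", "y", "z", "role", "vdw")]))
    tmp <- assign_accessibility(tmp)
    model$sasa[k] <- tmp$sasa[nrow(tmp)]
  }
  model
}

# Per-atom factor matrices (n x S) for the scattering atoms of a model.
# sasa is required only when the hydration term is active (c2 != 0).
model_factor_matrices <- function(model, q, need_sasa = TRUE) {
  m <- scattering_atoms(model)
  if (need_sasa && anyNA(m$sasa)) {
    m <- ensure_sasa(m)
  }
  els <- unique(m$element)
  fv <- vapply(els, ff_vacuum, q = q, numeric(length(q)))
  fs <- vapply(els, ff_dummy, q = q, numeric(length(q)))
  fw <- ff_water(q)
  i <- match(m$element, els)
  s <- ifelse(is.na(m$sasa), 0, m$sasa)
  list(
    coords = coords_matrix(m),
    FV = t(fv)[i, , drop = FALSE],
    FS = t(fs)[i, , drop = FALSE],
    FW = outer(s, fw),
    rm = mean(dummy_radius(m$element))
  )
}

#' Effective atomic form factor
#'
#' \eqn{f_i(q) = f_v(q) - c_1 G(q, c_1) f_s(q) + c_2 s_i f_w(q)}, where
#' \eqn{G} is the standard excluded-volume q-dependent adjustment (so that
#' \eqn{c_1 G} equals \eqn{c_1^3 \exp(-(4\pi/3)^{3/2} q^2 r_m^2 (c_1^2-1) /
#' 16\pi)}) and \eqn{s_i} is the atom's fractional solvent accessibility.
#' At \eqn{c_1 = 1} the excluded-volume term reduces to plain
#' vacuum-minus-dummy.
#'
#' @param element Element symbol.
#' @param q Momentum transfer grid (1/Angstrom).
#' @param c1 Excluded-volume parameter, in `[0.95, 1.05]`.
#' @param c2 Hydration-layer parameter, in `[-2, 4]`.
#' @param sasa Fractional solvent accessibility \eqn{s_i} of the atom.
#' @param rm Mean dummy-atom radius of the model (defaults to the element's
#'   own dummy radius).
#' @return Numeric vector of effective form factor values.
#' @export
effective_form_factor <- function(element, q, c1 = 1, c2 = 1, sasa = 0,
                                  rm = dummy_radius(element)) {
  check_c1c2(c1, c2)
  ff_vacuum(element, q) -
    c1 * excluded_volume_adjustment(q, c1, rm) * ff_dummy(element, q) +
    c2 * sasa * ff_water(q)
}

# u(q) such that I(q) = Ivv - 2 u Ivs + u^2 Iss + 2 c2 Ivw - 2 u c2 Isw + c2^2 Iww
ev_scale <- function(q, c1, rm) c1 * excluded_volume_adjustment(q, c1, rm)

intensity_from_partials <- function(partials, q, c1, c2, rm) {
  u <- ev_scale(q, c1, rm)
  partials[1, ] - 2 * u * partials[2, ] + u^2 * partials[3, ] +
    2 * c2 * partials[4, ] - 2 * u * c2 * partials[5, ] + c2^2 * partials[6, ]
}

#' Theoretical SAXS intensity by the Debye formula
#'
#' \eqn{I(q) = \sum_i \sum_j f_i(q) f_j(q) \sin(q d_{ij}) / (q d_{ij})} over
#' the model's scattering atoms (RNA and MG roles; waters are excluded), with
#' the \eqn{i = j} and \eqn{q \to 0} limits of the sinc taken as 1. Per-atom
#' factors are the effective form factors at the given `c1`, `c2`.
#'
#' @param model An `atomic_model`.
#' @param q Momentum transfer grid (default [default_q_grid()]).
#' @param c1,c2 Excluded-volume and hydration parameters (defaults 1).
#' @return A computed [saxs_profile()].
#' @export
debye_intensity <- function(model, q = default_q_grid(), c1 = 1, c2 = 1) {
  check_c1c2(c1, c2)
  fm <- model_factor_matrices(model, q, need_sasa = c2 != 0)
  u <- ev_scale(q, c1, fm$rm)
  Feff <- fm$FV - sweep(fm$FS, 2, u, "*") + c2 * fm$FW
  I <- cpp_debye_cross(fm$coords, Feff, fm$coords, Feff, q)
  saxs_profile(q, I)
}

# --- chi-square fitting ------------------------------------------------------

# analytic weighted-least-squares optimum of the scale c, and the resulting
# chi2 = (1/S) sum ((I_exp - c I_m) / sigma)^2
chi2_scale <- function(I_exp, I_mod, sigma) {
  w <- 1 / sigma^2
  cc <- sum(w * I_exp * I_mod) / sum(w * I_mod^2)
  list(c = cc, chi2 = mean(((I_exp - cc * I_mod) / sigma)^2))
}

new_saxs_fit <- function(chi2, c, c1, c2, profile) {
  structure(list(chi2 = chi2, c = c, c1 = c1, c2 = c2, profile = profile,
                 n = nrow(profile)),
            class = "saxs_fit")
}

#' @export
print.saxs_fit <- function(x, ...) {
  cat(sprintf("SAXS fit: chi2 = %.4f  c = %.4g  c1 = %.3f  c2 = %.3f  (S = %d)\n",
              x$chi2, x$c, x$c1, x$c2, x$n))
  invisible(x)
}

#' Fit a computed profile (or model) to an experimental profile
#'
#' Minimises \eqn{\chi^2 = S^{-1} \sum_i ((I_{exp}(q_i) - c I(q_i, c_1, c_2))
#' / \sigma(q_i))^2}. The scale \eqn{c} is always the analytic
#' weighted-least-squares optimum. When `calc` is an `atomic_model` and
#' `optimize_c1c2 = TRUE`, \eqn{(c_1, c_2)} are optimised by a deterministic
#' grid search (step 0.005 on `[0.95, 1.05]`, step 0.05 on `[-2, 4]`) over
#' precomputed partial intensities; otherwise they are fixed at 1.
#'
#' @param exp An experimental [saxs_profile()] with errors.
#' @param calc A computed [saxs_profile()] (interpolated onto `exp`'s grid if
#'   needed) or an `atomic_model` (evaluated directly on `exp`'s grid).
#' @param optimize_c1c2 Optimise the excluded-volume / hydration parameters
#'   (model input only).
#' @return A `saxs_fit`: chi2, c, c1, c2 and the fitted curve (columns `q`,
#'   `I_exp`, `sigma`, `I_fit`).
#' @export
fit_chi2 <- function(exp, calc, optimize_c1c2 = FALSE) {
  stopifnot(inherits(exp, "saxs_profile"))
  if (!is_experimental(exp) || any(exp$sigma <= 0))
    stop("experimental profile must carry positive errors", call. = FALSE)
  if (is_atomic_model(calc)) {
    fm <- model_factor_matrices(calc, exp$q, need_sasa = TRUE)
    partials <- cpp_debye_partials(fm$coords, fm$FV, fm$FS, fm$FW, exp$q)
    if (optimize_c1c2) {
      best <- NULL
      for (c1 in seq(0.95, 1.05, by = 0.005)) {
        for (c2 in seq(-2, 4, by = 0.05)) {
          I_mod <- intensity_from_partials(partials, exp$q, c1, c2, fm$rm)
          sc <- chi2_scale(exp$I, I_mod, exp$sigma)
          if (is.null(best) || sc$chi2 < best$chi2)
            best <- list(chi2 = sc$chi2, c = sc$c, c1 = c1, c2 = c2, I = I_mod)
        }
      }
    } else {
      I_mod <- intensity_from_partials(partials, exp$q, 1, 1, fm$rm)
      sc <- chi2_scale(exp$I, I_mod, exp$sigma)
      best <- list(chi2 = sc$chi2, c = sc$c, c1 = 1, c2 = 1, I = I_mod)
    }
  } else {
    stopifnot(inherits(calc, "saxs_profile"))
    if (optimize_c1c2)
      stop("optimizing c1/c2 requires an atomic model, not a fixed profile",
           call. = FALSE)
    I_mod <- if (isTRUE(all.equal(calc$q, exp$q))) calc$I else {
      if (min(exp$q) < min(calc$q) || max(exp$q) > max(calc$q))
        stop("experimental grid outside the computed profile's range",
             call. = FALSE)
      approx(calc$q, calc$I, xout = exp$q)$y
    }
    sc <- chi2_scale(exp$I, I_mod, exp$sigma)
    best <- list(chi2 = sc$chi2, c = sc$c, c1 = 1, c2 = 1, I = I_mod)
  }
  fitted <- tibble::tibble(q = exp$q, I_exp = exp$I, sigma = exp$sigma,
                           I_fit = best$c * best$I)
  new_saxs_fit(best$chi2, best$c, best$c1, best$c2, fitted)
}
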