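# Guinier, dimensionless Kratky and model-based P(r) analytics.

#' Guinier estimate of the radius of gyration
#'
#' Weighted linear fit of \eqn{\ln I} against \eqn{q^2} over the low-q
#' window, giving \eqn{R_g = \sqrt{-3 \times slope}}. The window is trimmed
#' iteratively until \eqn{q_{max} R_g \le} `qmax_rg` is self-consistent.
#'
#' @param profile A [saxs_profile()].
#' @param qmax_rg Dimensionless window limit (default 1.3, the usual
#'   convention for compact particles).
#' @param min_points Minimum number of points required in the final window.
#' @return A list of class `guinier_fit`: `rg`, `rg_se`, `i0`, `i0_se`,
#'   `n_points`, `qrg_max`.
#' @export
guinier_rg <- function(profile, qmax_rg = 1.3, min_points = 5) {
  stopifnot(inherits(profile, "saxs_profile"), qmax_rg > 0)
  keep <- profile$q > 0 & profile$I > 0
  q <- profile$q[keep]; I <- profile$I[keep]; sg <- profile$sigma[keep]
  if (length(q) < min_points) stop("too few usable points", call. = FALSE)
  w <- if (all(is.na(sg))) rep(1, length(q)) else (I / sg)^2  # var(ln I) = (sigma/I)^2
  fit_window <- function(idx) {
    fit <- lm(log(I[idx]) ~ I(q[idx]^2), weights = w[idx])
    slope <- coef(fit)[2]
    if (!is.finite(slope) || slope >= 0)
      stop("Guinier slope is non-negative: Rg^2 < 0", call. = FALSE)
    list(fit = fit, rg = sqrt(-3 * slope))
  }
  idx <- seq_len(max(min_points, min(length(q), 15L)))
  rg_prev <- -Inf
  for (iter in 1:50) {
    f <- fit_window(idx)
    new_idx <- which(q * f$rg <= qmax_rg)
    if (length(new_idx) < min_points)
      stop("fewer than ", min_points, " points with q*Rg <= ", qmax_rg,
           call. = FALSE)
    if (identical(new_idx, idx) || abs(f$rg - rg_prev) < 1e-10) break
    rg_prev <- f$rg
    idx <- new_idx
  }
  sm <- suppressWarnings(summary(f$fit))$coefficients
  slope <- sm[2, 1]; slope_se <- sm[2, 2]
  rg <- sqrt(-3 * slope)
  structure(list(
    rg = rg,
    rg_se = if (is.finite(slope_se)) 3 * slope_se / (2 * rg) else NA_real_,
    i0 = exp(sm[1, 1]),
    i0_se = if (is.finite(sm[1, 2])) exp(sm[1, 1]) * sm[1, 2] else NA_real_,
    n_points = length(idx),
    qrg_max = max(q[idx]) * rg
  ), class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf("Guinier fit: Rg = %.3f +/- %.3g A, I(0) = %.4g (%d points, qRg_max = %.2f)\n",
              x$rg, x$rg_se, x$i0, x$n_points, x$qrg_max))
  invisible(x)
}

#' Dimensionless Kratky transform
#'
#' Returns the curve \eqn{(qR_g, (qR_g)^2 I(q)/I(0))} together with its peak
#' location and height (refined by a local parabola through the three points
#' around the grid maximum). For a compact globular particle the peak sits
#' at \eqn{qR_g = \sqrt{3} \approx 1.73} with height \eqn{3/e \approx 1.1};
#' the curve is invariant to rescaling the intensities.
#'
#' @param profile A [saxs_profile()].
#' @param rg Radius of gyration; if `NULL`, estimated by [guinier_rg()].
#' @param i0 Forward intensity \eqn{I(0)}; if `NULL`, taken from the Guinier
#'   fit.
#' @return A list of class `kratky_curve`: `curve` (tibble with `x`, `y`),
#'   `peak_x`, `peak_height`, `rg`.
#' @export
dimensionless_kratky <- function(profile, rg = NULL, i0 = NULL) {
  stopifnot(inherits(profile, "saxs_profile"))
  if (is.null(rg) || is.null(i0)) {
    g <- guinier_rg(profile)
    if (is.null(rg)) rg <- g$rg
    if (is.null(i0)) i0 <- g$i0
  }
  if (rg <= 0) stop("rg must be positive", call. = FALSE)
  x <- profile$q * rg
  y <- x^2 * profile$I / i0
  k <- which.max(y)
  if (k > 1 && k < length(x)) {
    # parabola through the three points around the grid maximum
    xs <- x[(k - 1):(k + 1)]; ys <- y[(k - 1):(k + 1)]
    pf <- coef(lm(ys ~ xs + I(xs^2)))
    px <- -pf[2] / (2 * pf[3])
    ph <- pf[1] + pf[2] * px + pf[3] * px^2
  } else {
    px <- x[k]; ph <- y[k]
  }
  structure(list(curve = tibble::tibble(x = x, y = y),
                 peak_x = unname(px), peak_height = unname(ph), rg = rg),
            class = "kratky_curve")
}

#' Model-based pair-distance distribution P(r)
#'
#' Histogram of all interatomic distances of the model's scattering atoms,
#' weighted by \eqn{f_i(0) f_j(0)} (both orders counted), so the histogram
#' total equals \eqn{(\sum_i f_i(0))^2 - \sum_i f_i(0)^2} (all pairs minus
#' the self terms). The support ends at \eqn{D_{max}}, the maximum pairwise
#' distance.
#'
#' @param model An `atomic_model`.
#' @param bin_width Histogram bin width in Angstrom.
#' @return A list of class `pr_dist`: `pr` (tibble with bin centre `r` and
#'   weight `p`) and `dmax`.
#' @export
model_pr <- function(model, bin_width = 1) {
  stopifnot(bin_width > 0)
  m <- scattering_atoms(model)
  f0 <- vapply(m$element, function(e) ff_vacuum(e, 0), numeric(1))
  if (nrow(m) == 1) {
    pr <- tibble::tibble(r = 0, p = 0)
    return(structure(list(pr = pr, dmax = 0), class = "pr_dist"))
  }
  d <- as.vector(stats::dist(coords_matrix(m)))
  w <- 2 * utils::combn(f0, 2, FUN = prod)
  dmax <- max(d)
  breaks <- seq(0, dmax + bin_width, by = bin_width)
  bin <- findInterval(d, breaks, rightmost.closed = TRUE)
  p <- vapply(seq_len(length(breaks) - 1),
              function(b) sum(w[bin == b]), numeric(1))
  structure(list(
    pr = tibble::tibble(r = breaks[-length(breaks)] + bin_width / 2, p = p),
    dmax = dmax
  ), class = "pr_dist")
}
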