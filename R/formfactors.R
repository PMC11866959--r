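# Atomic scattering factors and element constants.
#
# Vacuum form factors are the standard five-term (four Gaussians + constant)
# Cromer-Mann parameterisation, f(q) = c + sum_k a_k exp(-b_k (q/4pi)^2).
# The dummy-solvent (excluded volume) factor follows the Fraser model,
# f_s(q) = rho0 V exp(-q^2 V^{2/3} / (4 pi)), with rho0 the bulk electron
# density of water and V the displaced atomic volume.

.cromer_mann <- list(
  H  = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
            b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305),
  C  = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
            b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N  = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
            b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O  = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
            b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  P  = list(a = c(6.43450, 4.17910, 1.78000, 1.49080),
            b = c(1.90670, 27.1570, 0.526000, 68.1645), c = 1.11490),
  MG = list(a = c(5.42040, 2.17350, 1.22690, 2.30730),
            b = c(2.82750, 79.2611, 0.380800, 7.19370), c = 0.858400)
)

# Displaced volumes (A^3): Fraser, MacRae & Suzuki values for the organic
# elements; Mg2+ from its ionic radius (0.72 A), since the dehydrated ion
# displaces very little solvent.
.dummy_volume <- c(H = 5.15, C = 16.44, N = 2.49, O = 9.13, P = 5.73,
                   MG = 4 / 3 * pi * 0.72^3)

# Bondi van der Waals radii (A); Mg from its crystallographic vdW radius.
.vdw_radius <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, MG = 1.73)

.rho_water <- 0.334  # bulk water electron density, e / A^3

supported_elements <- function() names(.cromer_mann)

#' Vacuum atomic form factor
#'
#' Five-term Cromer-Mann scattering factor \eqn{f_v(q)} for a supported
#' element. At \eqn{q = 0} this equals the element's electron count (to the
#' precision of the published coefficients).
#'
#' @param element Element symbol, one of `"H"`, `"C"`, `"N"`, `"O"`, `"P"`,
#'   `"MG"`.
#' @param q Numeric vector of momentum transfer values (1/Angstrom).
#' @return Numeric vector of form factor values (electrons).
#' @export
ff_vacuum <- function(element, q) {
  cm <- .cromer_mann[[toupper(element)]]
  if (is.null(cm)) stop("unsupported element: ", element, call. = FALSE)
  s2 <- (q / (4 * pi))^2
  out <- rep(cm$c, length(q))
  for (k in 1:4) out <- out + cm$a[k] * exp(-cm$b[k] * s2)
  out
}

#' Dummy-solvent (excluded volume) form factor
#'
#' Scattering factor of the solvent displaced by an atom,
#' \eqn{f_s(q) = \rho_0 V \exp(-q^2 V^{2/3} / 4\pi)}.
#'
#' @inheritParams ff_vacuum
#' @return Numeric vector of form factor values (electrons).
#' @export
ff_dummy <- function(element, q) {
  v <- .dummy_volume[[toupper(element)]]
  if (is.null(v)) stop("unsupported element: ", element, call. = FALSE)
  .rho_water * v * exp(-q^2 * v^(2 / 3) / (4 * pi))
}

#' Water form factor
#'
#' Composite vacuum form factor of a water molecule (O + 2 H), used for the
#' hydration-layer term.
#'
#' @inheritParams ff_vacuum
#' @return Numeric vector of form factor values (electrons).
#' @export
ff_water <- function(q) {
  ff_vacuum("O", q) + 2 * ff_vacuum("H", q)
}

#' Element constant lookup
#'
#' @param element Character vector of element symbols.
#' @return `vdw_radius()` returns Bondi van der Waals radii (Angstrom);
#'   `dummy_radius()` the radius of the displaced-solvent sphere.
#' @export
vdw_radius <- function(element) {
  r <- .vdw_radius[toupper(element)]
  if (anyNA(r)) stop("unsupported element(s): ",
                     paste(unique(element[is.na(r)]), collapse = ", "),
                     call. = FALSE)
  unname(r)
}

#' @rdname vdw_radius
#' @export
dummy_radius <- function(element) {
  v <- .dummy_volume[toupper(element)]
  if (anyNA(v)) stop("unsupported element(s)", call. = FALSE)
  unname((3 * v / (4 * pi))^(1 / 3))
}

# Excluded-volume q-dependent adjustment. The scattering of the displaced
# solvent is scaled so that the total excluded-volume term becomes
# c1^3 exp(-(4pi/3)^{3/2} q^2 rm^2 (c1^2 - 1) / (16 pi)) f_s(q);
# rm is the average dummy radius of the model. G is defined so that
# c1 * G(q, c1) equals that prefactor, and G(q, 1) = 1.
excluded_volume_adjustment <- function(q, c1, rm) {
  c1^2 * exp(-(4 * pi / 3)^(3 / 2) * q^2 * rm^2 * (c1^2 - 1) / (16 * pi))
}
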