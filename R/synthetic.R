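# Synthetic fixtures: idealized helices, perturbed ensembles (a stand-in
# for an external kinematics-based conformational sampler), noisy
# "experimental" profiles with known ground truth, and labelled
# coordination-shell neighborhoods for the classifier.

# Per-nucleotide pseudo-atom template: (element, radial offset dr from the
# backbone radius, angular offset in rad, axial offset in A). Six coarse
# centres stand in for phosphate, sugar and base moieties; scattering-level
# realism is all the tests need, and Debye cost scales as N^2.
.nt_template <- data.frame(
  element = c("P", "O", "C", "C", "N", "O"),
  dr = c(0.0, -0.8, -2.2, -4.0, -5.8, -3.0),
  dang = c(0.00, 0.25, 0.10, 0.30, 0.15, -0.20),
  dz = c(0.0, 1.2, 0.4, 0.9, 0.5, -0.6)
)

#' Idealized A-form-like double helix
#'
#' Builds a deterministic double helix from a fixed per-nucleotide
#' pseudo-atom template (backbone radius 9.4 A, rise 2.81 A per base pair,
#' twist 32.7 degrees), two antiparallel strands. Useful as a toy RNA whose
#' size (and radius of gyration) grows with `n_bp`.
#'
#' @param n_bp Number of base pairs (>= 1).
#' @param atoms_per_nt Template atoms per nucleotide (1..6).
#' @return An `atomic_model` with `resid` (base-pair index) and `strand`
#'   columns.
#' @export
make_helix <- function(n_bp, atoms_per_nt = 6) {
  stopifnot(atoms_per_nt >= 1, atoms_per_nt <= nrow(.nt_template))
  if (n_bp < 1) stop("n_bp must be >= 1", call. = FALSE)
  tmpl <- .nt_template[seq_len(atoms_per_nt), ]
  rise <- 2.81; twist <- 32.7 * pi / 180; r0 <- 9.4
  rows <- list()
  for (strand in 1:2) {
    for (t in seq_len(n_bp)) {
      ang <- (t - 1) * twist + if (strand == 2) pi * 0.85 else 0
      sgn <- if (strand == 2) -1 else 1
      z <- (t - 1) * rise
      a <- ang + sgn * tmpl$dang
      rr <- r0 + tmpl$dr
      rows[[length(rows) + 1]] <- tibble::tibble(
        element = tmpl$element,
        x = rr * cos(a), y = rr * sin(a), z = z + sgn * tmpl$dz,
        role = "RNA", resid = t + (strand - 1) * n_bp, strand = strand
      )
    }
  }
  atomic_model(dplyr::bind_rows(rows),
               label = sprintf("helix_%dbp", n_bp))
}

rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  ct <- cos(angle); st <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) * ct + st * ux + (1 - ct) * tcrossprod(u)
}

#' Perturbed conformational ensemble
#'
#' Hinge-style sampler standing in for an external kinematics-based
#' conformational engine: for each conformation, a few backbone pivots are
#' chosen and the downstream segment is rigidly rotated about a random axis
#' through the pivot, by an angle drawn uniformly from
#' `[-magnitude, magnitude]`. Atom count and ordering are preserved, and
#' intra-segment geometry is exactly rigid.
#'
#' @param model An `atomic_model` (with a `resid` column; atom order is the
#'   segmentation order).
#' @param n_conformations Number of conformations to generate.
#' @param magnitude Rotation-angle cap in radians (0 reproduces the input).
#' @param seed Integer seed.
#' @param n_pivots Hinges per conformation.
#' @return An [rna_ensemble()] of `n_conformations` models.
#' @export
perturb_ensemble <- function(model, n_conformations, magnitude = 0.5,
                             seed = 1, n_pivots = 2) {
  stopifnot(is_atomic_model(model), n_conformations >= 1, magnitude >= 0)
  set.seed(seed)
  n <- nrow(model)
  # hinge only at residue boundaries so intra-residue geometry stays rigid
  if ("resid" %in% names(model)) {
    bounds <- cumsum(rle(model$resid)$lengths)
    pivot_pool <- bounds[-length(bounds)]
  } else {
    pivot_pool <- seq(2, n - 1)
  }
  confs <- lapply(seq_len(n_conformations), function(k) {
    xyz <- coords_matrix(model)
    pivots <- sort(sample(pivot_pool, min(n_pivots, length(pivot_pool))))
    for (pv in pivots) {
      angle <- runif(1, -magnitude, magnitude)
      axis <- rnorm(3)
      R <- rotation_matrix(axis, angle)
      tail_idx <- (pv + 1):n
      origin <- xyz[pv, ]
      xyz[tail_idx, ] <- sweep(sweep(xyz[tail_idx, , drop = FALSE], 2, origin) %*% t(R),
                               2, origin, "+")
    }
    out <- model
    out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
    attr(out, "label") <- sprintf("%s_conf%d", model_label(model), k)
    out
  })
  rna_ensemble(confs)
}

#' Noise model for simulated profiles
#'
#' \eqn{\sigma(q) = floor \cdot I(q) + growth \cdot I(0) \cdot q/q_{max}}:
#' a relative error floor plus a q-dependent growth term mimicking the
#' increasing relative error at high q typical of solution scattering.
#' `scale` multiplies the Gaussian noise actually added (0 gives noise-free
#' intensities while keeping the error column).
#'
#' @param rel_floor Relative error floor.
#' @param q_growth Error growth coefficient.
#' @param scale Noise amplitude multiplier.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(rel_floor = 0.01, q_growth = 0.002, scale = 1) {
  stopifnot(rel_floor > 0, q_growth >= 0, scale >= 0)
  structure(list(rel_floor = rel_floor, q_growth = q_growth, scale = scale),
            class = "noise_model")
}

#' Simulate an experimental profile with known ground truth
#'
#' Computes the Debye intensity of the model (plus optional placed ions),
#' attaches \eqn{\sigma(q)} from the noise model and adds seeded Gaussian
#' noise `scale * N(0, sigma(q))`.
#'
#' @param model An `atomic_model`.
#' @param q Momentum transfer grid.
#' @param noise A [noise_model()].
#' @param ions Optional data frame / matrix of ion coordinates added as MG.
#' @param seed Integer seed for the noise draw.
#' @param c1,c2 Parameters passed to [debye_intensity()].
#' @return An experimental [saxs_profile()] (with `sigma`).
#' @export
simulate_profile <- function(model, q = default_q_grid(),
                             noise = noise_model(), ions = NULL, seed = 1,
                             c1 = 1, c2 = 1) {
  stopifnot(inherits(noise, "noise_model"))
  if (!is.null(ions) && NROW(ions) > 0) {
    im <- as.data.frame(ions)[, 1:3]
    names(im) <- c("x", "y", "z")
    extra <- tibble::tibble(element = "MG", x = im$x, y = im$y, z = im$z,
                            role = "MG")
    base <- tibble::as_tibble(model)[, c("element", "x", "y", "z", "role", "sasa")]
    extra$sasa <- NA_real_
    model <- atomic_model(dplyr::bind_rows(base, extra),
                          label = model_label(model))
  }
  ideal <- debye_intensity(model, q, c1 = c1, c2 = c2)
  sigma <- noise$rel_floor * ideal$I + noise$q_growth * ideal$I[1] * q / max(q)
  set.seed(seed)
  I_noisy <- ideal$I + noise$scale * rnorm(length(q), 0, sigma)
  saxs_profile(q, I_noisy, sigma)
}

#' Labelled synthetic coordination-shell neighborhoods
#'
#' Generates training data for the site classifier. Positives emulate an
#' Mg2+ inner coordination shell: 4-6 oxygen atoms at 2.0-2.2 A from the
#' probe on jittered octahedral directions, plus random background atoms
#' within the neighborhood radius. Negatives emulate water-like
#' surroundings: looser element-mixed shells whose nearest atom sits at
#' 2.6-3.5 A. Solvent accessibilities are drawn uniformly (uninformative).
#'
#' @param n_pos,n_neg Class counts.
#' @param seed Integer seed.
#' @param radius Neighborhood radius (A).
#' @return List of labelled [probe_graph()] objects, positives first.
#' @export
make_neighborhoods <- function(n_pos, n_neg, seed = 1, radius = 8) {
  stopifnot(n_pos >= 0, n_neg >= 0)
  set.seed(seed)
  octa <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  rand_dir <- function(n) {
    v <- matrix(rnorm(3 * n), n, 3)
    v / sqrt(rowSums(v^2))
  }
  shell_nodes <- function(dirs, dists, elements) {
    xyz <- dirs * dists
    tibble::tibble(element = elements,
                   dist = sqrt(rowSums(xyz^2)),
                   sasa = runif(length(elements), 0.2, 0.9),
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  background <- function() {
    nb <- rpois(1, 8)
    if (nb == 0) return(NULL)
    shell_nodes(rand_dir(nb), runif(nb, 3.0, radius),
                sample(c("C", "N", "O", "P"), nb, replace = TRUE,
                       prob = c(0.35, 0.2, 0.35, 0.1)))
  }
  one_pos <- function() {
    k <- sample(4:6, 1)
    dirs <- octa[sample(6, k), , drop = FALSE] + matrix(rnorm(3 * k, 0, 0.08), k, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    nodes <- dplyr::bind_rows(
      shell_nodes(dirs, runif(k, 2.0, 2.2), rep("O", k)),
      background())
    probe_graph(nodes, label = 1L)
  }
  one_neg <- function() {
    k <- sample(3:7, 1)
    nodes <- dplyr::bind_rows(
      shell_nodes(rand_dir(k), runif(k, 2.6, 3.5),
                  sample(c("C", "N", "O", "H"), k, replace = TRUE)),
      background())
    probe_graph(nodes, label = 0L)
  }
  c(lapply(seq_len(n_pos), function(i) one_pos()),
    lapply(seq_len(n_neg), function(i) one_neg()))
}
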