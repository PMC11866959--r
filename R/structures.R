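# Atomistic models: tibble-backed containers plus PDB I/O (via bio3d) and
# Shrake-Rupley solvent accessibility.

#' Construct an atomistic model
#'
#' An atomistic model is a tibble with one row per atom and columns
#' `element`, `x`, `y`, `z`, `role` (one of `"RNA"`, `"MG"`, `"WATER"`,
#' `"PROBE"`), `vdw` (van der Waals radius, Angstrom) and `sasa` (fractional
#' solvent accessibility in `[0, 1]`, `NA` until assigned).
#'
#' @param atoms Data frame with at least `element`, `x`, `y`, `z`; `role`
#'   defaults to `"RNA"`, `vdw` is filled from the built-in radius table.
#' @param label Free-text identifier carried as an attribute.
#' @return A tibble of class `atomic_model`.
#' @export
atomic_model <- function(atoms, label = "model") {
  atoms <- tibble::as_tibble(atoms)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  if (nrow(atoms) == 0) stop("empty model: no atoms", call. = FALSE)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates", call. = FALSE)
  atoms$element <- toupper(atoms$element)
  bad <- !atoms$element %in% supported_elements()
  if (any(bad)) {
    warning(sum(bad), " atom(s) with unsupported element skipped: ",
            paste(unique(atoms$element[bad]), collapse = ", "), call. = FALSE)
    atoms <- atoms[!bad, , drop = FALSE]
    if (nrow(atoms) == 0) stop("empty model after element filtering", call. = FALSE)
  }
  if (!"role" %in% names(atoms)) atoms$role <- "RNA"
  stopifnot(all(atoms$role %in% c("RNA", "MG", "WATER", "PROBE")))
  if (!"vdw" %in% names(atoms)) atoms$vdw <- vdw_radius(atoms$element)
  if (!"sasa" %in% names(atoms)) atoms$sasa <- NA_real_
  ok <- is.na(atoms$sasa) | (atoms$sasa >= 0 & atoms$sasa <= 1)
  stopifnot(all(ok), all(atoms$vdw > 0))
  structure(atoms, label = label,
            class = c("atomic_model", class(tibble::tibble())))
}

is_atomic_model <- function(x) inherits(x, "atomic_model")

model_label <- function(model) attr(model, "label") %||% "model"

`%||%` <- function(a, b) if (is.null(a)) b else a

coords_matrix <- function(model) {
  as.matrix(model[, c("x", "y", "z")])
}

#' Scattering atoms of a model
#'
#' Returns the atoms that contribute to the computed profile: RNA and MG by
#' default. Crystallographic waters are parsed but excluded from scattering
#' (they serve as classifier negatives, not as part of the solute).
#'
#' @param model An `atomic_model`.
#' @param roles Character vector of roles to keep.
#' @return An `atomic_model` restricted to those roles.
#' @export
scattering_atoms <- function(model, roles = c("RNA", "MG")) {
  keep <- model$role %in% roles
  if (!any(keep)) stop("no scattering atoms with roles ",
                       paste(roles, collapse = "/"), call. = FALSE)
  atomic_model(model[keep, , drop = FALSE], label = model_label(model))
}

#' Construct an ensemble of conformations
#'
#' @param models List of `atomic_model` objects sharing atom count and
#'   ordering (element and role sequences must be identical).
#' @return A list of class `rna_ensemble`.
#' @export
rna_ensemble <- function(models) {
  stopifnot(length(models) >= 1, all(vapply(models, is_atomic_model, TRUE)))
  ref <- models[[1]]
  for (m in models[-1]) {
    if (nrow(m) != nrow(ref) || !identical(m$element, ref$element) ||
        !identical(m$role, ref$role))
      stop("ensemble members must share atom count and ordering", call. = FALSE)
  }
  structure(models, class = "rna_ensemble")
}

# --- PDB I/O (bio3d behind the scenes) --------------------------------------

.element_from_record <- function(elesy, elety) {
  el <- toupper(trimws(elesy))
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    # fall back to atom-name heuristics: strip digits/primes, MG special-cased
    nm <- toupper(gsub("[^A-Z]", "", elety[miss]))
    el[miss] <- ifelse(substr(nm, 1, 2) == "MG", "MG", substr(nm, 1, 1))
  }
  el
}

#' Read an atomistic model (or ensemble) from a PDB file
#'
#' ATOM records become RNA atoms; HETATM records for MG and HOH/WAT are
#' recognised as ions and waters. Multi-MODEL files yield an
#' [rna_ensemble()]. Atoms with unsupported elements are skipped with a
#' warning.
#'
#' @param path Path to a PDB file.
#' @return An `atomic_model`, or an `rna_ensemble` for multi-model files.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("unparseable PDB file: ",
                                           conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (nrow(at) == 0) stop("empty model: no atoms in ", path, call. = FALSE)
  element <- .element_from_record(at$elesy, at$elety)
  resid <- toupper(trimws(at$resid))
  role <- rep("RNA", nrow(at))
  role[resid %in% c("HOH", "WAT")] <- "WATER"
  role[element == "MG" | resid == "MG"] <- "MG"
  element[role == "MG"] <- "MG"
  nmodel <- nrow(pdb$xyz)
  build_one <- function(k) {
    xyz <- matrix(pdb$xyz[k, ], ncol = 3, byrow = TRUE)
    atomic_model(tibble::tibble(
      element = element, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      role = role, resid = at$resno
    ), label = sprintf("%s#%d", basename(path), k))
  }
  if (is.null(nmodel) || nmodel <= 1) {
    m <- build_one(1)
    attr(m, "label") <- basename(path)
    return(m)
  }
  rna_ensemble(lapply(seq_len(nmodel), build_one))
}

#' Write an atomistic model (plus placed ions) to a PDB file
#'
#' Writes the model's atoms as ATOM/HETATM records per their role, followed
#' by one `HETATM ... MG` record (occupancy 1.00) per placed ion.
#'
#' @param model An `atomic_model`.
#' @param path Output file path.
#' @param ions Optional matrix or data frame of ion coordinates (columns
#'   x, y, z).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path, ions = NULL) {
  stopifnot(is_atomic_model(model))
  el <- model$element
  role <- model$role
  xyz <- coords_matrix(model)
  if (!is.null(ions) && NROW(ions) > 0) {
    im <- as.matrix(as.data.frame(ions)[, 1:3])
    if (!all(is.finite(im))) stop("non-finite ion coordinates", call. = FALSE)
    xyz <- rbind(xyz, im)
    el <- c(el, rep("MG", nrow(im)))
    role <- c(role, rep("MG", nrow(im)))
  }
  n <- length(el)
  type <- ifelse(role == "RNA", "ATOM", "HETATM")
  resid <- c(RNA = "RNA", MG = "MG", WATER = "HOH", PROBE = "PRB")[role]
  elety <- ifelse(role == "MG", "MG", paste0(el, "1"))
  bio3d::write.pdb(
    file = path, xyz = as.vector(t(xyz)), type = type,
    resno = seq_len(n), resid = resid, eleno = seq_len(n),
    elety = elety, chain = "A", o = rep(1.00, n), b = rep(0.00, n),
    elesy = el
  )
  invisible(path)
}

# --- Solvent accessibility ---------------------------------------------------

# Deterministic quasi-uniform points on the unit sphere (golden-spiral
# lattice); the same point set is used for SASA and surface probes.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Assign fractional solvent accessibility
#'
#' Shrake-Rupley dot sampling: each atom's solvent-accessible sphere
#' (radius `vdw + probe_radius`) is sampled with a fixed deterministic point
#' set and the fraction of dots not occluded by any other atom's accessible
#' sphere is stored in `sasa`. This fraction is the \eqn{s_i} weight of the
#' hydration-layer term of the computed profile. A single-atom model gets
#' accessibility 1 by convention.
#'
#' @param model An `atomic_model`.
#' @param probe_radius Water-probe radius in Angstrom (default 1.4).
#' @param n_dots Dots per atom (default 100).
#' @param roles Roles whose atoms occlude and receive accessibility.
#' @return The model with `sasa` filled in.
#' @export
assign_accessibility <- function(model, probe_radius = 1.4, n_dots = 100,
                                 roles = c("RNA", "MG")) {
  stopifnot(is_atomic_model(model), probe_radius > 0, n_dots >= 10)
  idx <- which(model$role %in% roles)
  xyz <- coords_matrix(model)[idx, , drop = FALSE]
  rad <- model$vdw[idx] + probe_radius
  n <- length(idx)
  dots <- sphere_points(n_dots)
  sasa <- numeric(n)
  if (n == 1) {
    sasa <- 1
  } else {
    for (i in seq_len(n)) {
      pts <- dots * rad[i]
      pts <- sweep(pts, 2, xyz[i, ], "+")
      # only neighbours whose accessible sphere can reach atom i's surface
      d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
      nb <- which(d2 < (rad[i] + rad)^2 & seq_len(n) != i)
      free <- rep(TRUE, n_dots)
      for (j in nb) {
        dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
          (pts[, 3] - xyz[j, 3])^2
        free <- free & dj2 > rad[j]^2
        if (!any(free)) break
      }
      sasa[i] <- mean(free)
    }
  }
  model$sasa[idx] <- sasa
  model
}

#' Radius of gyration of a model
#'
#' Electron-weighted radius of gyration computed from the coordinates, using
#' \eqn{f_v(0)} (the electron count) of each atom as its weight.
#'
#' @param model An `atomic_model`.
#' @return Radius of gyration in Angstrom.
#' @export
model_rg <- function(model) {
  m <- scattering_atoms(model)
  w <- vapply(m$element, function(e) ff_vacuum(e, 0), numeric(1))
  xyz <- coords_matrix(m)
  ctr <- colSums(xyz * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, ctr)^2)) / sum(w))
}
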