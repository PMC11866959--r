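# Candidate ion positions on the RNA surface and the 8 A atomic
# neighborhoods handed to the classifier.

#' Generate surface probes
#'
#' Samples the solvent-accessible surface with an occlusion-filtered dot
#' surface: each atom's sphere of radius `vdw + probe_radius` is covered by
#' a fixed deterministic point lattice and dots falling inside any other
#' atom's accessible sphere are removed. Surviving dots closer than
#' `dedup_spacing` to each other are deduplicated by grid snapping (the
#' retained probe keeps its exact coordinates).
#'
#' @param model An `atomic_model` (only RNA atoms are used).
#' @param probe_radius Probe sphere radius, Angstrom (default 1.5,
#'   ionic/water scale).
#' @param density Target dot density, probes per square Angstrom (before
#'   occlusion and deduplication).
#' @param dedup_spacing Grid spacing used to thin near-duplicate probes.
#' @return A tibble of class `probe_set` with columns `x`, `y`, `z` and
#'   attribute `source_model`.
#' @export
generate_surface_probes <- function(model, probe_radius = 1.5, density = 0.5,
                                    dedup_spacing = 1.0) {
  stopifnot(is_atomic_model(model), probe_radius > 0, density > 0)
  m <- model[model$role == "RNA", , drop = FALSE]
  if (nrow(m) == 0) stop("model has no RNA atoms", call. = FALSE)
  xyz <- as.matrix(m[, c("x", "y", "z")])
  rad <- m$vdw + probe_radius
  pts <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    n_dots <- max(8L, ceiling(density * 4 * pi * rad[i]^2))
    p <- sphere_points(n_dots) * rad[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    # drop dots occluded by any other atom's accessible sphere
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (rad[i] + rad)^2 & seq_len(nrow(m)) != i)
    free <- rep(TRUE, n_dots)
    for (j in nb) {
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & dj2 > rad[j]^2 * (1 - 1e-12)
      if (!any(free)) break
    }
    pts[[i]] <- p[free, , drop = FALSE]
  }
  all_pts <- do.call(rbind, pts)
  if (nrow(all_pts) > 0 && dedup_spacing > 0) {
    key <- paste(round(all_pts[, 1] / dedup_spacing),
                 round(all_pts[, 2] / dedup_spacing),
                 round(all_pts[, 3] / dedup_spacing))
    all_pts <- all_pts[!duplicated(key), , drop = FALSE]
  }
  structure(tibble::tibble(x = all_pts[, 1], y = all_pts[, 2], z = all_pts[, 3]),
            source_model = model_label(model),
            class = c("probe_set", class(tibble::tibble())))
}

#' Export probes as a PDB of pseudo-atoms
#'
#' Writes one `HETATM` record of element X per probe, for visualization.
#'
#' @param probes A `probe_set` (or any data frame with x, y, z).
#' @param path Output path.
#' @export
write_probes_pdb <- function(probes, path) {
  lines <- sprintf(
    "HETATM%5d  X   PRB A%4d    %8.3f%8.3f%8.3f  1.00  0.00           X",
    seq_len(nrow(probes)) %% 100000, seq_len(nrow(probes)) %% 10000,
    probes$x, probes$y, probes$z)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Extract the atomic neighborhood of a probe
#'
#' Collects all RNA atoms within `radius` of the probe as graph nodes.
#' Node features are the element (one-hot), the distance to the probe and
#' the fractional solvent accessibility; edges connect atom pairs closer
#' than `edge_cutoff` and carry their distance. The representation encodes
#' only distances, so it is invariant to rigid motion of model and probe.
#'
#' @param model An `atomic_model` (with `sasa` assigned; missing values are
#'   treated as 0).
#' @param probe Numeric length-3 coordinate of the probe.
#' @param radius Neighborhood radius in Angstrom (default 8).
#' @param edge_cutoff Edge distance cutoff in Angstrom (default 5).
#' @return A `probe_graph` (list with `nodes`, `edges`, `label`), or `NULL`
#'   if no atom lies within `radius` (callers must skip such probes).
#' @export
extract_neighborhood <- function(model, probe, radius = 8, edge_cutoff = 5) {
  stopifnot(is_atomic_model(model), length(probe) == 3, radius > 0)
  m <- model[model$role == "RNA", , drop = FALSE]
  xyz <- as.matrix(m[, c("x", "y", "z")])
  d <- sqrt(colSums((t(xyz) - as.numeric(probe))^2))
  keep <- which(d <= radius)
  if (length(keep) == 0) return(NULL)
  nodes <- tibble::tibble(
    element = m$element[keep],
    dist = d[keep],
    sasa = ifelse(is.na(m$sasa[keep]), 0, m$sasa[keep]),
    x = m$x[keep], y = m$y[keep], z = m$z[keep]
  )
  probe_graph(nodes, edge_cutoff = edge_cutoff)
}

#' Build a probe neighborhood graph from node coordinates
#'
#' @param nodes Tibble with `element`, `dist` (to the probe), `sasa`, `x`,
#'   `y`, `z`.
#' @param edge_cutoff Edge distance cutoff in Angstrom.
#' @param label Optional class label (1 = Mg site, 0 = water site).
#' @return A list of class `probe_graph`.
#' @export
probe_graph <- function(nodes, edge_cutoff = 5, label = NA_integer_) {
  stopifnot(nrow(nodes) >= 1)
  xyz <- as.matrix(nodes[, c("x", "y", "z")])
  if (nrow(nodes) > 1) {
    dm <- as.matrix(stats::dist(xyz))
    idx <- which(upper.tri(dm) & dm <= edge_cutoff, arr.ind = TRUE)
    edges <- tibble::tibble(i = idx[, 1], j = idx[, 2],
                            dist = dm[idx])
  } else {
    edges <- tibble::tibble(i = integer(), j = integer(), dist = numeric())
  }
  structure(list(nodes = nodes, edges = edges, label = label),
            class = "probe_graph")
}
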