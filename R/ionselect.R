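# Selection of the Mg2+ subset that minimises chi2: precomputed subprofiles
# give O(|subset|^2 S) profile assembly, enumerated with a beam-style
# branch-and-bound.

#' Precompute subprofiles for candidate ions
#'
#' Decomposes the Debye intensity of RNA plus any candidate subset A into
#' \deqn{I_{RNA} + \sum_{k \in A} (I_{kk} + X_k) + \sum_{k<l \in A} C_{kl}}
#' with \eqn{I_{kk}} the ion self term, \eqn{X_k = 2\sum_{i \in RNA} f_i f_k
#' sinc(q d_{ik})} the RNA cross term, and \eqn{C_{kl}} the ion-ion cross
#' terms. The decomposition is exact: assembling a subset reproduces the
#' direct Debye intensity of RNA plus those ions.
#'
#' @param rna An `atomic_model` (RNA atoms; accessibility is assigned if
#'   missing).
#' @param candidates Data frame or matrix of candidate ion coordinates
#'   (columns x, y, z), e.g. from [select_sites()].
#' @param q Momentum transfer grid.
#' @param c1,c2 Excluded-volume / hydration parameters used throughout
#'   (defaults 1, the recommended fixed policy).
#' @param min_clearance Candidates closer than this to an RNA atom are
#'   rejected with a warning (Angstrom).
#' @return A list of class `subprofile_cache`.
#' @export
precompute_subprofiles <- function(rna, candidates, q = default_q_grid(),
                                   c1 = 1, c2 = 1, min_clearance = 1) {
  check_c1c2(c1, c2)
  cand <- as.matrix(as.data.frame(candidates)[, c("x", "y", "z")])
  colnames(cand) <- c("x", "y", "z")
  if (nrow(cand) == 0) stop("no candidate ions", call. = FALSE)
  rna <- scattering_atoms(rna, roles = "RNA")
  if (c2 != 0 && anyNA(rna$sasa)) rna <- assign_accessibility(rna)
  # clearance check against RNA atoms
  rxyz <- coords_matrix(rna)
  dmin <- apply(cand, 1, function(p) sqrt(min(colSums((t(rxyz) - p)^2))))
  if (any(dmin < min_clearance)) {
    warning(sum(dmin < min_clearance),
            " candidate(s) within ", min_clearance,
            " A of an RNA atom rejected", call. = FALSE)
    cand <- cand[dmin >= min_clearance, , drop = FALSE]
    if (nrow(cand) == 0) stop("all candidates rejected", call. = FALSE)
  }
  M <- nrow(cand)
  fm <- model_factor_matrices(rna, q, need_sasa = c2 != 0)
  u <- ev_scale(q, c1, fm$rm)
  Feff_rna <- fm$FV - sweep(fm$FS, 2, u, "*") + c2 * fm$FW
  I_rna <- cpp_debye_cross(fm$coords, Feff_rna, fm$coords, Feff_rna, q)
  # per-candidate Mg form factor: accessibility computed against the RNA alone
  sasa_ion <- vapply(seq_len(M), function(k) {
    tmp <- atomic_model(tibble::tibble(
      element = c(rna$element, "MG"),
      x = c(rna$x, cand[k, 1]), y = c(rna$y, cand[k, 2]),
      z = c(rna$z, cand[k, 3]),
      role = c(rna$role, "MG")))
    if (c2 == 0) 0 else assign_accessibility(tmp)$sasa[nrow(tmp)]
  }, numeric(1))
  f_mg_base <- ff_vacuum("MG", q) - u * ff_dummy("MG", q)
  Fmg <- t(vapply(seq_len(M),
                  function(k) f_mg_base + c2 * sasa_ion[k] * ff_water(q),
                  numeric(length(q))))
  I_self <- Fmg^2                               # M x S ion self terms
  X <- 2 * cpp_debye_cross_rows(fm$coords, Feff_rna, cand, Fmg, q)
  # pairwise ion-ion cross terms, indexed k < l
  npair <- M * (M - 1) / 2
  C <- matrix(0, max(npair, 1), length(q))
  if (M > 1) {
    r <- 1L
    for (k in 1:(M - 1)) {
      for (l in (k + 1):M) {
        d <- sqrt(sum((cand[k, ] - cand[l, ])^2))
        x <- q * d
        sc <- ifelse(x < 1e-12, 1, sin(x) / x)
        C[r, ] <- 2 * Fmg[k, ] * Fmg[l, ] * sc
        r <- r + 1L
      }
    }
  }
  structure(list(q = q, I_rna = I_rna, I_self = I_self, X = X, C = C,
                 candidates = cand, M = M, c1 = c1, c2 = c2),
            class = "subprofile_cache")
}

pair_index <- function(k, l, M) {
  # row of the k < l pair in the packed pair matrix
  a <- pmin(k, l); b <- pmax(k, l)
  (a - 1) * M - a * (a - 1) / 2 + (b - a)
}

#' Assemble the profile of an ion subset from the cache
#'
#' Exact O(|subset|^2 S) summation of the precomputed subprofiles;
#' independent of the RNA size and invariant to the ordering of the subset.
#'
#' @param cache A `subprofile_cache`.
#' @param subset Integer vector of distinct candidate indices (possibly
#'   empty, giving the RNA-only profile).
#' @return A computed [saxs_profile()].
#' @export
assemble_subset <- function(cache, subset = integer(0)) {
  stopifnot(inherits(cache, "subprofile_cache"))
  subset <- as.integer(subset)
  if (anyDuplicated(subset)) stop("duplicate candidate index", call. = FALSE)
  stopifnot(all(subset >= 1 & subset <= cache$M))
  I <- cache$I_rna
  if (length(subset) > 0) {
    I <- I + colSums(cache$I_self[subset, , drop = FALSE]) +
      colSums(cache$X[subset, , drop = FALSE])
    if (length(subset) > 1) {
      pr <- utils::combn(sort(subset), 2)
      idx <- pair_index(pr[1, ], pr[2, ], cache$M)
      I <- I + colSums(cache$C[idx, , drop = FALSE])
    }
  }
  saxs_profile(cache$q, I)
}

#' Branch-and-bound selection of the best ion subset
#'
#' Level n keeps the `K` best-chi2 subsets of size n and extends each by one
#' unused candidate to form level n+1 (canonicalised and deduplicated, ties
#' broken by lexicographic subset order); the search stops when the best
#' chi2 no longer improves or `max_ions` is reached. With `K = Inf` the
#' search is exhaustive over all subset sizes visited. The scale `c` is
#' optimised analytically for every subset; `c1`, `c2` are those the cache
#' was built with.
#'
#' @param exp Experimental [saxs_profile()] on the cache's q grid.
#' @param cache A [precompute_subprofiles()] result.
#' @param K Beam width (subsets kept per level).
#' @param max_ions Maximum subset size.
#' @return A list of class `ion_selection`: `subset` (best indices),
#'   `sites` (their coordinates), `fit` (a `saxs_fit`), and `trajectory`
#'   (tibble of level, best chi2, best subset) tracing the best chi2 per
#'   level visited.
#' @export
branch_and_bound <- function(exp, cache, K = 50,
                             max_ions = min(cache$M, 30)) {
  stopifnot(inherits(exp, "saxs_profile"), inherits(cache, "subprofile_cache"),
            K >= 1, max_ions >= 0)
  if (!isTRUE(all.equal(exp$q, cache$q)))
    stop("experimental profile and cache must share the q grid", call. = FALSE)
  if (!is_experimental(exp)) stop("experimental errors required", call. = FALSE)
  score <- function(I) chi2_scale(exp$I, I, exp$sigma)
  sc0 <- score(cache$I_rna)
  best <- list(subset = integer(0), chi2 = sc0$chi2, c = sc0$c,
               I = cache$I_rna)
  traj <- tibble::tibble(level = 0L, chi2 = sc0$chi2,
                         subset = list(integer(0)))
  level <- list(list(subset = integer(0), I = cache$I_rna, chi2 = sc0$chi2))
  n <- 0L
  while (n < max_ions) {
    n <- n + 1L
    children <- list()
    seen <- character(0)
    for (parent in level) {
      unused <- setdiff(seq_len(cache$M), parent$subset)
      for (m in unused) {
        child_sub <- sort(c(parent$subset, m))
        key <- paste(child_sub, collapse = ",")
        if (key %in% seen) next
        seen <- c(seen, key)
        I <- parent$I + cache$I_self[m, ] + cache$X[m, ]
        if (length(parent$subset) > 0) {
          idx <- pair_index(rep(m, length(parent$subset)), parent$subset,
                            cache$M)
          I <- I + colSums(cache$C[idx, , drop = FALSE])
        }
        sc <- score(I)
        children[[length(children) + 1]] <-
          list(subset = child_sub, I = I, chi2 = sc$chi2, c = sc$c, key = key)
      }
    }
    if (length(children) == 0) break
    keys <- vapply(children, `[[`, character(1), "key")
    chis <- vapply(children, `[[`, numeric(1), "chi2")
    ord <- order(chis, keys)             # chi2, then lexicographic subset
    keep <- ord[seq_len(min(length(ord), K))]
    level <- children[keep]
    lv_best <- level[[1]]
    if (lv_best$chi2 < best$chi2 - 1e-12) {
      best <- lv_best
      traj <- dplyr::bind_rows(traj, tibble::tibble(
        level = n, chi2 = lv_best$chi2, subset = list(lv_best$subset)))
    } else {
      break  # the score can no longer be improved
    }
  }
  fitted <- tibble::tibble(q = exp$q, I_exp = exp$I, sigma = exp$sigma,
                           I_fit = best$c * best$I)
  structure(list(
    subset = best$subset,
    sites = tibble::as_tibble(as.data.frame(
      cache$candidates[best$subset, , drop = FALSE])),
    fit = new_saxs_fit(best$chi2, best$c, cache$c1, cache$c2, fitted),
    trajectory = traj
  ), class = "ion_selection")
}

#' @export
print.ion_selection <- function(x, ...) {
  cat(sprintf("Ion subset selection: %d ion(s) {%s}, chi2 = %.4f\n",
              length(x$subset), paste(x$subset, collapse = ","),
              x$fit$chi2))
  invisible(x)
}
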