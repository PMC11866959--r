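# Multistate (ensemble) fitting: when no single conformation fits within
# the noise, a small set of conformers with non-negative weights is fitted
# by NNLS and conformer subsets are enumerated with the same beam machinery
# as the ion selection.

#' Fit non-negative state weights to an experimental profile
#'
#' Minimises the chi2 of \eqn{c \sum_m w_m I_m(q)} over the scale
#' \eqn{c \ge 0} and weights \eqn{w_m \ge 0} by non-negative least squares
#' on the sigma-normalised member profiles (Lawson-Hanson, convex and
#' deterministic); the weights are then normalised to sum 1 and the scale
#' absorbs the norm. With a single member this reduces to the analytic
#' scale fit of [fit_chi2()] (when its optimal scale is non-negative).
#'
#' @param exp Experimental [saxs_profile()] with errors.
#' @param profiles List of computed [saxs_profile()]s on `exp`'s grid.
#' @param members Optional integer labels for the profiles (defaults to
#'   their positions).
#' @return A list of class `multistate_model`: `members`, `weights`
#'   (summing to 1), `c`, and `fit` (a `saxs_fit`).
#' @export
fit_state_weights <- function(exp, profiles, members = seq_along(profiles)) {
  stopifnot(inherits(exp, "saxs_profile"), length(profiles) >= 1)
  if (!is_experimental(exp)) stop("experimental errors required", call. = FALSE)
  A <- vapply(profiles, function(p) {
    stopifnot(inherits(p, "saxs_profile"))
    if (!isTRUE(all.equal(p$q, exp$q)))
      stop("member profiles must share the experimental q grid", call. = FALSE)
    p$I / exp$sigma
  }, numeric(nrow(exp)))
  if (all(abs(A) < 1e-300)) stop("all member profiles are zero", call. = FALSE)
  x <- pracma::lsqnonneg(A, exp$I / exp$sigma)$x
  if (sum(x) <= 0)
    stop("NNLS assigned zero weight to every member", call. = FALSE)
  I_mix <- as.vector(vapply(profiles, `[[`, numeric(nrow(exp)), "I") %*% x)
  chi2 <- mean(((exp$I - I_mix) / exp$sigma)^2)
  fitted <- tibble::tibble(q = exp$q, I_exp = exp$I, sigma = exp$sigma,
                           I_fit = I_mix)
  structure(list(members = members, weights = x / sum(x), c = sum(x),
                 fit = new_saxs_fit(chi2, sum(x), 1, 1, fitted)),
            class = "multistate_model")
}

#' @export
print.multistate_model <- function(x, ...) {
  cat(sprintf("Multistate model: %d state(s), chi2 = %.4f\n",
              length(x$members), x$fit$chi2))
  for (i in seq_along(x$members))
    cat(sprintf("  state %s  weight %.3f\n", x$members[i], x$weights[i]))
  invisible(x)
}

#' Enumerate multistate models by state count
#'
#' Branch-and-bound over conformer subsets (beam of width `K`, subsets
#' canonicalised and deduplicated per level) with [fit_state_weights()] as
#' the subset scorer. Because NNLS can zero out a member, the best chi2 is
#' non-increasing in the state count. Returns the best model for each state
#' count 1..`max_states`.
#'
#' @param exp Experimental [saxs_profile()].
#' @param profiles Pool of computed member profiles on `exp`'s grid.
#' @param max_states Largest state count to consider.
#' @param K Beam width.
#' @return A list of class `state_scan`: `models` (best
#'   `multistate_model` per state count) and `summary` (tibble of
#'   `n_states`, `chi2`, `members`, `weights`).
#' @export
enumerate_states <- function(exp, profiles, max_states = 4, K = 50) {
  stopifnot(length(profiles) >= 1, max_states >= 1,
            max_states <= length(profiles), K >= 1)
  P <- length(profiles)
  best_per_size <- vector("list", max_states)
  level <- list(integer(0))
  for (n in seq_len(max_states)) {
    children <- list()
    seen <- character(0)
    for (parent in level) {
      for (m in setdiff(seq_len(P), parent)) {
        sub <- sort(c(parent, m))
        key <- paste(sub, collapse = ",")
        if (key %in% seen) next
        seen <- c(seen, key)
        children[[length(children) + 1]] <- sub
      }
    }
    scored <- lapply(children, function(sub)
      fit_state_weights(exp, profiles[sub], members = sub))
    chis <- vapply(scored, function(s) s$fit$chi2, numeric(1))
    keys <- vapply(children, paste, character(1), collapse = ",")
    ord <- order(chis, keys)
    best_per_size[[n]] <- scored[[ord[1]]]
    keep <- ord[seq_len(min(length(ord), K))]
    level <- children[keep]
  }
  summary <- purrr::map_dfr(seq_len(max_states), function(n) {
    m <- best_per_size[[n]]
    tibble::tibble(n_states = n, chi2 = m$fit$chi2,
                   members = list(m$members), weights = list(m$weights))
  })
  structure(list(models = best_per_size, summary = summary),
            class = "state_scan")
}

#' @export
print.state_scan <- function(x, ...) {
  cat("Multistate scan:\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %d state(s): chi2 = %.4f  members {%s}\n",
                x$summary$n_states[i], x$summary$chi2[i],
                paste(x$summary$members[[i]], collapse = ",")))
  invisible(x)
}
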