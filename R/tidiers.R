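# broom-style tidiers for the fitted objects.

#' Tidy a SAXS fit
#'
#' @param x A `saxs_fit`.
#' @param ... Unused.
#' @return One row per fitted parameter (`c`, `c1`, `c2`).
#' @export
tidy.saxs_fit <- function(x, ...) {
  tibble::tibble(term = c("c", "c1", "c2"),
                 estimate = c(x$c, x$c1, x$c2))
}

#' @rdname tidy.saxs_fit
#' @return `glance()` returns a one-row summary with `chi2`, `c`, `c1`,
#'   `c2` and the number of profile points `n`.
#' @export
glance.saxs_fit <- function(x, ...) {
  tibble::tibble(chi2 = x$chi2, c = x$c, c1 = x$c1, c2 = x$c2, n = x$n)
}

#' @rdname tidy.saxs_fit
#' @return `augment()` returns the fitted curve with residuals.
#' @export
augment.saxs_fit <- function(x, ...) {
  dplyr::mutate(x$profile,
                .resid = (.data$I_exp - .data$I_fit) / .data$sigma)
}

#' Tidy a Guinier fit
#'
#' @param x A `guinier_fit`.
#' @param ... Unused.
#' @export
tidy.guinier_fit <- function(x, ...) {
  tibble::tibble(term = c("rg", "i0"),
                 estimate = c(x$rg, x$i0),
                 std.error = c(x$rg_se, x$i0_se))
}

#' @rdname tidy.guinier_fit
#' @export
glance.guinier_fit <- function(x, ...) {
  tibble::tibble(rg = x$rg, rg_se = x$rg_se, i0 = x$i0,
                 n_points = x$n_points, qrg_max = x$qrg_max)
}

#' Tidy a multistate model
#'
#' @param x A `multistate_model`.
#' @param ... Unused.
#' @return One row per state with its weight.
#' @export
tidy.multistate_model <- function(x, ...) {
  tibble::tibble(member = x$members, weight = x$weights)
}

#' @rdname tidy.multistate_model
#' @export
glance.multistate_model <- function(x, ...) {
  tibble::tibble(n_states = length(x$members), chi2 = x$fit$chi2, c = x$c)
}

#' Tidy an ion subset selection
#'
#' @param x An `ion_selection`.
#' @param ... Unused.
#' @return The chi2 trajectory: one row per accepted level.
#' @export
tidy.ion_selection <- function(x, ...) {
  dplyr::mutate(x$trajectory,
                subset = vapply(.data$subset, paste, character(1),
                                collapse = ","))
}

#' @rdname tidy.ion_selection
#' @export
glance.ion_selection <- function(x, ...) {
  tibble::tibble(n_ions = length(x$subset), chi2 = x$fit$chi2, c = x$fit$c)
}

#' Tidy a site classifier
#'
#' @param x An `ion_classifier`.
#' @param ... Unused.
#' @return Per-fold cross-validation AUROC.
#' @export
tidy.ion_classifier <- function(x, ...) x$cv

#' @rdname tidy.ion_classifier
#' @export
glance.ion_classifier <- function(x, ...) {
  tibble::tibble(auroc_mean = x$auroc_mean, auroc_sd = x$auroc_sd,
                 folds = nrow(x$cv), hidden = x$arch$hidden,
                 final_loss = x$history[length(x$history)])
}

#' Tidy a state scan
#'
#' @param x A `state_scan`.
#' @param ... Unused.
#' @export
tidy.state_scan <- function(x, ...) {
  tidyr::unnest(
    dplyr::mutate(x$summary,
                  members = lapply(.data$members, paste, collapse = ","),
                  weights = NULL),
    "members")
}

#' @rdname tidy.state_scan
#' @export
glance.state_scan <- function(x, ...) {
  k <- which.min(x$summary$chi2)
  tibble::tibble(best_n_states = x$summary$n_states[k],
                 best_chi2 = x$summary$chi2[k])
}
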