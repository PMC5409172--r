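# broom-style tidiers

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom rlang %||%
NULL

#' Tidy an AUC estimate
#'
#' @param x An `auc_estimate`.
#' @param ... Unused.
#' @return A one-row tibble with `estimate`, `std.error`, `conf.low`,
#'   `conf.high`, `estimator`.
#' @exportS3Method generics::tidy
tidy.auc_estimate <- function(x, ...) {
  tibble::tibble(estimate = x$auc, std.error = x$se,
                 conf.low = x$ci_lower, conf.high = x$ci_upper,
                 estimator = x$estimator)
}

#' @rdname tidy.auc_estimate
#' @exportS3Method generics::glance
glance.auc_estimate <- function(x, ...) {
  tibble::tibble(n_cases = x$n_cases, n_controls = x$n_controls,
                 conf.level = x$conf_level, variance = x$variance,
                 degenerate = x$degenerate)
}

#' Tidy an ICC estimate
#'
#' @param x An `icc_estimate`.
#' @param ... Unused.
#' @return A one-row tibble with the ICC, its components and standard error.
#' @exportS3Method generics::tidy
tidy.icc_estimate <- function(x, ...) {
  tibble::tibble(estimate = x$icc, std.error = x$se,
                 var.between = x$var_between, var.within = x$var_within,
                 scale = x$scale, group = x$group, clamped = x$clamped)
}

#' @rdname tidy.icc_estimate
#' @exportS3Method generics::glance
glance.icc_estimate <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects,
                 mean_replicates = x$mean_replicates, k_eff = x$k_eff)
}

#' Tidy a corrected-AUC result
#'
#' @param x A `correction_result`.
#' @param ... Unused.
#' @return A one-row tibble with the corrected estimate, interval, and the
#'   attenuation diagnostics.
#' @exportS3Method generics::tidy
tidy.correction_result <- function(x, ...) {
  tibble::tibble(method = x$method, estimate = x$auc_corrected,
                 conf.low = x$ci_lower, conf.high = x$ci_upper,
                 auc.obs = x$auc_obs, inflation = x$inflation,
                 theta2 = x$theta2, clamped = x$clamped)
}
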