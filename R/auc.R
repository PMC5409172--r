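# Observed (uncorrected) AUC estimators.
#
# Orientation convention throughout: larger biomarker values indicate cases,
# AUC = Pr(control value < case value) + Pr(tie)/2.  No automatic flipping
# of estimates below 0.5.

# rank-based kernel: AUC point estimate plus DeLong structural components.
# x = cases, y = controls.
.mw_kernel <- function(x, y) {
  m <- length(x)
  n <- length(y)
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(m)] - rank(x)) / n        # placement of each case among controls
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y)) / m
  auc <- mean(v10)
  var_delong <- 0
  if (m > 1L) var_delong <- var_delong + stats::var(v10) / m
  if (n > 1L) var_delong <- var_delong + stats::var(v01) / n
  list(auc = auc, var_delong = max(var_delong, 0), m = m, n = n)
}

.hanley_var <- function(auc, m, n) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  (auc * (1 - auc) + (m - 1) * (q1 - auc^2) + (n - 1) * (q2 - auc^2)) / (m * n)
}

.auc_ci <- function(auc, se, conf_level, ci_scale) {
  z <- .z_two_sided(conf_level)
  if (se == 0) return(c(auc, auc))
  if (ci_scale == "logit" && auc > 0 && auc < 1) {
    l <- stats::qlogis(auc)
    se_l <- se / (auc * (1 - auc))
    stats::plogis(c(l - z * se_l, l + z * se_l))
  } else {
    .clip(c(auc - z * se, auc + z * se), 0, 1)
  }
}

#' Nonparametric (Mann-Whitney) AUC with confidence interval
#'
#' Estimates AUC = Pr(Y < X) + Pr(Y = X)/2 for case values `cases` and
#' control values `controls` as the proportion of correctly ordered
#' case-control pairs, ties counted one half.  The default standard error is
#' the DeLong structural-components estimator; the Hanley-McNeil
#' exponential-approximation formula is available via `variance`.
#'
#' @param cases,controls Numeric vectors of finite biomarker values (larger
#'   values indicate cases).
#' @param conf_level Two-sided confidence level, default 0.95.
#' @param variance `"delong"` (default) or `"hanley"`.
#' @param ci_scale `"probability"` (symmetric interval truncated to
#'   \[0, 1\], default) or `"logit"` (useful for small samples).
#' @return An object of class `auc_estimate`: a list with elements `auc`,
#'   `se`, `ci_lower`, `ci_upper`, `estimator`, `n_cases`, `n_controls`,
#'   `conf_level`, and `degenerate` (TRUE when all pooled values are
#'   identical, in which case `auc = 0.5` with `se = 0`).
#' @seealso [estimate_auc()] for the data-frame interface, [binormal_auc()]
#'   for the normal-theory closed form.
#' @examples
#' mann_whitney_auc(c(1, 2, 3), c(0, 1.5))  # 5/6 from the 6 pairs
#' @export
mann_whitney_auc <- function(cases, controls, conf_level = 0.95,
                             variance = c("delong", "hanley"),
                             ci_scale = c("probability", "logit")) {
  variance <- match.arg(variance)
  ci_scale <- match.arg(ci_scale)
  .check_finite(cases, "cases")
  .check_finite(controls, "controls")
  if (length(cases) < 1L || length(controls) < 1L) {
    stop("need at least one case and one control value.", call. = FALSE)
  }
  k <- .mw_kernel(cases, controls)
  degenerate <- length(unique(c(cases, controls))) == 1L
  se <- if (degenerate) 0 else {
    switch(variance,
      delong = sqrt(k$var_delong),
      hanley = sqrt(max(.hanley_var(k$auc, k$m, k$n), 0))
    )
  }
  ci <- .auc_ci(k$auc, se, conf_level, ci_scale)
  structure(
    list(auc = k$auc, se = se, ci_lower = ci[1], ci_upper = ci[2],
         estimator = "mann_whitney", n_cases = k$m, n_controls = k$n,
         conf_level = conf_level, degenerate = degenerate,
         variance = variance, ci_scale = ci_scale),
    class = "auc_estimate"
  )
}

#' Binormal AUC
#'
#' Closed-form AUC when both groups are normal:
#' \eqn{\Phi\{(\mu_X - \mu_Y)/\sqrt{\sigma^2_X + \sigma^2_Y}\}}.
#'
#' @param mu_x,mu_y Group means (cases, controls).
#' @param var_x,var_y Strictly positive group variances.
#' @return AUC in (0, 1).  Vectorised over its arguments.
#' @examples
#' binormal_auc(1, 0, 1, 1)  # 0.760
#' @export
binormal_auc <- function(mu_x, mu_y, var_x, var_y) {
  .check_finite(mu_x, "mu_x"); .check_finite(mu_y, "mu_y")
  .check_finite(var_x, "var_x"); .check_finite(var_y, "var_y")
  if (any(var_x <= 0) || any(var_y <= 0)) {
    stop("variances must be strictly positive.", call. = FALSE)
  }
  stats::pnorm((mu_x - mu_y) / sqrt(var_x + var_y))
}

# normal-theory observed AUC from data, with a delta-method CI on the
# standardized mean difference. Provided as a diagnostic companion to the
# Mann-Whitney estimator; sensitive to non-normality.
.binormal_obs <- function(x, y, conf_level = 0.95) {
  m <- length(x); n <- length(y)
  d <- mean(x) - mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  v <- vx + vy
  delta <- d / sqrt(v)
  var_delta <- (vx / m + vy / n) / v +
    d^2 / (4 * v^3) * (2 * vx^2 / (m - 1) + 2 * vy^2 / (n - 1))
  z <- .z_two_sided(conf_level)
  se_delta <- sqrt(var_delta)
  list(auc = stats::pnorm(delta),
       ci = stats::pnorm(c(delta - z * se_delta, delta + z * se_delta)),
       delta = delta, se_delta = se_delta)
}

#' Estimate the observed AUC from a biomarker data frame
#'
#' Data-frame-first wrapper around [mann_whitney_auc()].  Only the designated
#' primary replicate contributes to the observed AUC; additional replicates
#' are reserved for reliability (ICC) estimation.
#'
#' @param data A biomarker data frame with columns `subject`, `group`
#'   (`"case"`/`"control"`), `replicate`, `value`; see [as_biomarker()].
#' @param primary_replicate Replicate index used as the main measurement,
#'   default 1.
#' @inheritParams mann_whitney_auc
#' @return An `auc_estimate` object.
#' @examples
#' dat <- simulate_biomarkers(sim_config(model = "I", m = 40, n = 40), seed = 1)
#' estimate_auc(dat)
#' @export
estimate_auc <- function(data, primary_replicate = 1, conf_level = 0.95,
                         variance = c("delong", "hanley"),
                         ci_scale = c("probability", "logit")) {
  .check_biomarker(data)
  primary <- data[data$replicate == primary_replicate, , drop = FALSE]
  if (nrow(primary) == 0L) {
    stop("no rows with replicate == ", primary_replicate, ".", call. = FALSE)
  }
  mann_whitney_auc(
    cases    = primary$value[primary$group == "case"],
    controls = primary$value[primary$group == "control"],
    conf_level = conf_level, variance = variance, ci_scale = ci_scale
  )
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("Mann-Whitney AUC: %.4f (se %.4f), %g%% CI [%.4f, %.4f]\n",
              x$auc, x$se, 100 * x$conf_level, x$ci_lower, x$ci_upper))
  cat(sprintf("  %d cases, %d controls; variance: %s%s\n",
              x$n_cases, x$n_controls, x$variance,
              if (x$degenerate) "; DEGENERATE (constant data)" else ""))
  invisible(x)
}
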