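# Measurement-error corrections of the observed AUC: probit-shift (rank
# based, driven by probit-scale ICCs), Reiser's normal-theory correction
# from replicate variance components, and Faraggi's known-theta^2 formula.
# All corrected estimates carry delta-method confidence limits.

#' Probit-shift correction of an observed AUC
#'
#' Deattenuates an observed AUC using the probit-scale reliabilities of the
#' case and control measurements:
#' \deqn{AUC_{true} = \Phi\left[\Phi^{-1}(AUC_{obs})\,
#'   \sqrt{\tfrac{1}{2}\left(1/ICC_X + 1/ICC_Y\right)}\right].}
#' With perfectly reliable measurements (both ICCs equal to 1) the correction
#' is the identity; an observed AUC of 0.5 is a fixed point.
#'
#' @param auc_obs Observed AUC, strictly inside (0, 1).
#' @param icc_x,icc_y Probit-scale intraclass correlations of the case and
#'   control measurements, in (0, 1].
#' @return Corrected AUC in (0, 1).  Vectorised.
#' @examples
#' probit_shift_correct(0.589, 0.648, 0.498)  # 0.618
#' probit_shift_correct(0.5, 0.7, 0.3)        # 0.5 (null fixed point)
#' @export
probit_shift_correct <- function(auc_obs, icc_x, icc_y) {
  .check_prob_open(auc_obs, "auc_obs")
  .check_finite(icc_x, "icc_x"); .check_finite(icc_y, "icc_y")
  if (any(icc_x <= 0 | icc_x > 1) || any(icc_y <= 0 | icc_y > 1)) {
    stop("ICCs must lie in (0, 1].", call. = FALSE)
  }
  b <- sqrt((1 / icc_x + 1 / icc_y) / 2)
  stats::pnorm(stats::qnorm(auc_obs) * b)
}

#' Faraggi correction for known error-to-signal variance ratio
#'
#' Normal-theory correction
#' \eqn{AUC_{true} = \Phi\{\Phi^{-1}(AUC_{obs})\sqrt{1+\theta^2}\}} where
#' \eqn{\theta^2} is the known ratio of error variance to true
#' (between-subject) variance.
#'
#' @param auc_obs Observed AUC in (0, 1).
#' @param theta2 Nonnegative error-to-signal variance ratio.
#' @return Corrected AUC in (0, 1).  Vectorised.
#' @examples
#' faraggi_correct(pnorm(0.5), 1)  # pnorm(0.5 * sqrt(2))
#' @export
faraggi_correct <- function(auc_obs, theta2) {
  .check_prob_open(auc_obs, "auc_obs")
  .check_finite(theta2, "theta2")
  if (any(theta2 < 0)) stop("`theta2` must be nonnegative.", call. = FALSE)
  stats::pnorm(stats::qnorm(auc_obs) * sqrt(1 + theta2))
}

.new_correction_result <- function(method, auc_obs, auc_corrected, inflation,
                                   theta2, se_ab, ci, conf_level,
                                   clamped = FALSE, extra = list()) {
  structure(
    c(list(method = method, auc_obs = auc_obs, auc_corrected = auc_corrected,
           inflation = inflation, theta2 = theta2, se_ab = se_ab,
           ci_lower = ci[1], ci_upper = ci[2], conf_level = conf_level,
           clamped = clamped), extra),
    class = "correction_result"
  )
}

# clip an observed AUC away from 0/1 before the probit; resolution 1/(2mn)
.clip_auc_obs <- function(auc, m, n) {
  eps <- 1 / (2 * m * n)
  clipped <- auc <= 0 || auc >= 1
  if (clipped) {
    warning("observed AUC at the boundary; clipped to [",
            format(eps), ", ", format(1 - eps), "] before correction.",
            call. = FALSE)
  }
  list(auc = .clip(auc, eps, 1 - eps), clipped = clipped)
}

#' Probit-shift corrected AUC with a delta-method confidence interval
#'
#' Combines an observed AUC estimate with probit-scale ICC estimates for the
#' two groups.  Writing \eqn{\hat a = \Phi^{-1}(\widehat{AUC}_{obs})} and
#' \eqn{\hat b = \sqrt{(1/ICC_X + 1/ICC_Y)/2}}, the corrected AUC is
#' \eqn{\Phi(\hat a \hat b)} and the interval is
#' \eqn{\Phi\{\hat a\hat b \pm z_{1-\alpha/2}\, se(\hat a\hat b)\}} with
#' \deqn{se^2(\hat a\hat b) = \hat b^2\,var(\hat a) + \hat a^2\,var(\hat b),}
#' \eqn{var(\hat a) = var(\widehat{AUC}_{obs})/\phi(\hat a)^2} and
#' \eqn{var(\hat b)} propagated from the two ICC variances
#' (\eqn{\partial b/\partial ICC = -1/(4 b\, ICC^2)}), treating the three
#' components as independent.
#'
#' @param auc An [mann_whitney_auc()] / [estimate_auc()] result for the
#'   primary measurements.
#' @param icc_x,icc_y [estimate_icc()] results (probit scale) for cases and
#'   controls.
#' @param conf_level Two-sided confidence level, default 0.95.
#' @return A `correction_result` with `method = "probit_shift"`; its
#'   `inflation` element is \eqn{\hat b} and `theta2` is \eqn{\hat b^2 - 1}.
#'   `clamped = TRUE` (wide-interval warning) when either ICC was clamped.
#' @examples
#' dat <- simulate_biomarkers(sim_config(model = "I", m = 60, n = 60), seed = 3)
#' probit_shift_ci(estimate_auc(dat),
#'                 probit_icc(dat, "case"), probit_icc(dat, "control"))
#' @export
probit_shift_ci <- function(auc, icc_x, icc_y, conf_level = 0.95) {
  stopifnot(inherits(auc, "auc_estimate"),
            inherits(icc_x, "icc_estimate"), inherits(icc_y, "icc_estimate"))
  cl <- .clip_auc_obs(auc$auc, auc$n_cases, auc$n_controls)
  a <- stats::qnorm(cl$auc)
  b <- sqrt((1 / icc_x$icc + 1 / icc_y$icc) / 2)
  var_a <- auc$se^2 / stats::dnorm(a)^2
  var_b <- (icc_x$se^2 / icc_x$icc^4 + icc_y$se^2 / icc_y$icc^4) / (16 * b^2)
  se_ab <- sqrt(b^2 * var_a + a^2 * var_b)
  z <- .z_two_sided(conf_level)
  ci <- stats::pnorm(c(a * b - z * se_ab, a * b + z * se_ab))
  clamped <- isTRUE(icc_x$clamped) || isTRUE(icc_y$clamped)
  if (clamped) {
    warning("an ICC estimate was clamped; the corrected AUC interval may be unreliable.",
            call. = FALSE)
  }
  .new_correction_result(
    "probit_shift", auc$auc, stats::pnorm(a * b), inflation = b,
    theta2 = b^2 - 1, se_ab = se_ab, ci = ci, conf_level = conf_level,
    clamped = clamped || cl$clipped,
    extra = list(icc_x = icc_x$icc, icc_y = icc_y$icc)
  )
}

# Reiser correction kernel from per-group ANOVA component lists (as returned
# by .anova_kernel / .anova_balanced). Group means are means of subject means.
.reiser_kernel <- function(comp_x, comp_y, conf_level) {
  mean_g <- function(comp) mean(comp$subject_means)
  var_mean <- function(comp) {
    # variance of the mean of subject means: subject i contributes vb + vw/k_i
    (comp$var_between + comp$var_within * mean(1 / comp$k_i)) / comp$n_subjects
  }
  var_vb <- function(comp) {
    # chi-square approximations for the two mean squares
    (2 * comp$msb^2 / (comp$n_subjects - 1) +
       2 * comp$msw^2 / (comp$n_obs - comp$n_subjects)) / comp$k_eff^2
  }
  v_true <- comp_x$var_between + comp_y$var_between
  clamped <- v_true <= 0
  if (clamped) v_true <- 0.01 * (comp_x$msw + comp_y$msw)
  d <- mean_g(comp_x) - mean_g(comp_y)
  delta <- d / sqrt(v_true)
  var_delta <- (var_mean(comp_x) + var_mean(comp_y)) / v_true +
    d^2 / (4 * v_true^3) * (var_vb(comp_x) + var_vb(comp_y))
  se_delta <- sqrt(var_delta)
  z <- .z_two_sided(conf_level)
  theta2 <- (comp_x$msw + comp_y$msw) / v_true
  list(auc = stats::pnorm(delta),
       ci = stats::pnorm(c(delta - z * se_delta, delta + z * se_delta)),
       delta = delta, se_delta = se_delta, theta2 = theta2, clamped = clamped)
}

#' Reiser's normal-theory corrected AUC from replicate measurements
#'
#' Estimates the true-scale AUC \eqn{\Phi(\hat\delta_{true})} with
#' \eqn{\hat\delta_{true} = (\bar X - \bar Y)/
#' \sqrt{\hat\sigma^2_{X,true} + \hat\sigma^2_{Y,true}}}, where the true
#' (between-subject) variances come from one-way ANOVA components of the
#' raw-scale replicates in each group and the group means are means of
#' subject means.  The confidence interval is a delta-method interval on
#' \eqn{\hat\delta_{true}} using large-sample variances of the group means
#' and chi-square variances for the ANOVA mean squares, assuming
#' independence across groups; it is then mapped through \eqn{\Phi}.
#'
#' Valid under normally distributed true values and errors; with skewed data
#' both the point estimate and the interval can be badly biased -- this is
#' the scenario the rank-based probit-shift correction addresses.
#'
#' @param data A biomarker data frame with replicate measurements in both
#'   groups (see [as_biomarker()]).
#' @param conf_level Two-sided confidence level, default 0.95.
#' @return A `correction_result` with `method = "reiser"`, carrying the
#'   estimated \eqn{\theta^2 = (\hat\sigma^2_\epsilon + \hat\sigma^2_\xi)/
#'   (\hat\sigma^2_{X,true} + \hat\sigma^2_{Y,true})} and
#'   `inflation` \eqn{= \sqrt{1+\theta^2}}.  When the summed true-variance
#'   estimate is nonpositive it is floored at 1% of the summed error
#'   variance and `clamped = TRUE` is set.
#' @param primary_replicate Replicate index reported as `auc_obs` (the
#'   accompanying uncorrected Mann-Whitney estimate), default 1.
#' @examples
#' dat <- simulate_biomarkers(sim_config(model = "I", m = 60, n = 60), seed = 4)
#' reiser_correct(dat)
#' @export
reiser_correct <- function(data, conf_level = 0.95, primary_replicate = 1) {
  .check_biomarker(data)
  cases <- data[data$group == "case", , drop = FALSE]
  ctrls <- data[data$group == "control", , drop = FALSE]
  comp_x <- .anova_kernel(cases$subject, cases$value)
  comp_y <- .anova_kernel(ctrls$subject, ctrls$value)
  k <- .reiser_kernel(comp_x, comp_y, conf_level)
  if (k$clamped) {
    warning("nonpositive true-variance estimate; floored at 1% of the error variance.",
            call. = FALSE)
  }
  obs <- estimate_auc(data, primary_replicate = primary_replicate,
                      conf_level = conf_level)
  .new_correction_result(
    "reiser", obs$auc, k$auc, inflation = sqrt(1 + k$theta2),
    theta2 = k$theta2, se_ab = k$se_delta, ci = k$ci,
    conf_level = conf_level, clamped = k$clamped,
    extra = list(delta_true = k$delta)
  )
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf("%s corrected AUC: %.4f, %g%% CI [%.4f, %.4f]%s\n",
              x$method, x$auc_corrected, 100 * x$conf_level,
              x$ci_lower, x$ci_upper,
              if (isTRUE(x$clamped)) " [clamped]" else ""))
  cat(sprintf("  observed AUC %.4f; inflation factor %.4f; theta2 %.4f\n",
              x$auc_obs, x$inflation, x$theta2))
  invisible(x)
}

#' Subject-bootstrap standard error for a corrected AUC
#'
#' Nonparametric bootstrap oracle for the delta-method standard errors:
#' resamples subjects with replacement within each group and recomputes the
#' full correction pipeline (Mann-Whitney AUC on the primary replicate plus
#' per-group probit ICCs for `"probit"`, or ANOVA components for
#' `"reiser"`).
#'
#' @param data A biomarker data frame.
#' @param method `"probit"` or `"reiser"`.
#' @param B Number of bootstrap replicates, default 1000.
#' @param seed RNG seed (the bootstrap is deterministic given `seed`).
#' @param conf_level Confidence level used inside each replicate fit.
#' @param primary_replicate Primary replicate index for the observed AUC.
#' @return A list with `se_ab` (bootstrap SD of the probit-scale product
#'   \eqn{\hat a \hat b}, or of \eqn{\hat\delta_{true}} for Reiser) and
#'   `se_auc` (bootstrap SD of the corrected AUC).
#' @export
bootstrap_correction_se <- function(data, method = c("probit", "reiser"),
                                    B = 1000, seed = NULL, conf_level = 0.95,
                                    primary_replicate = 1) {
  method <- match.arg(method)
  .check_biomarker(data)
  if (!is.null(seed)) set.seed(seed)
  groups <- lapply(c("case", "control"), function(g) {
    d <- data[data$group == g, , drop = FALSE]
    split(d[c("replicate", "value")], factor(d$subject))
  })
  resample <- function(subjects, prefix) {
    idx <- sample.int(length(subjects), replace = TRUE)
    parts <- subjects[idx]
    out <- do.call(rbind, parts)
    out$subject <- rep(paste0(prefix, seq_along(idx)),
                       vapply(parts, nrow, integer(1)))
    out
  }
  draws <- vapply(seq_len(B), function(b) suppressWarnings({
    cs <- resample(groups[[1]], "x"); cs$group <- "case"
    ct <- resample(groups[[2]], "y"); ct$group <- "control"
    boot <- rbind(cs, ct)
    if (method == "probit") {
      res <- probit_shift_ci(
        estimate_auc(boot, primary_replicate = primary_replicate,
                     conf_level = conf_level),
        probit_icc(boot, "case"), probit_icc(boot, "control"),
        conf_level = conf_level
      )
      c(stats::qnorm(res$auc_corrected), res$auc_corrected)
    } else {
      res <- reiser_correct(boot, conf_level = conf_level,
                            primary_replicate = primary_replicate)
      c(res$delta_true, res$auc_corrected)
    }
  }), numeric(2))
  list(se_ab = stats::sd(draws[1, ]), se_auc = stats::sd(draws[2, ]))
}
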