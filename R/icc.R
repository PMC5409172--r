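# Intraclass correlation from distinguishable replicate measurements via
# one-way ANOVA variance components, on the raw or normal-scores (probit)
# scale.  On the probit scale ICC = 1/(1 + sigma_e^2), the reliability that
# drives the probit-shift AUC correction.

# general one-way ANOVA kernel; subject is any vector coercible to factor.
# Subjects contributing a single measurement are excluded (they carry no
# within-subject information).
.anova_kernel <- function(subject, value) {
  f <- factor(subject)
  ki <- tabulate(f)
  keep <- ki[as.integer(f)] >= 2L
  if (sum(ki >= 2L) < 2L) {
    stop("ICC requires at least 2 subjects with at least 2 replicates each.",
         call. = FALSE)
  }
  value <- value[keep]
  f <- droplevels(f[keep])
  ki <- tabulate(f)
  s <- length(ki)
  N <- length(value)
  sums <- as.vector(rowsum(value, f))
  ss_cells <- sum(sums^2 / ki)
  ssw <- sum(value^2) - ss_cells
  ssb <- ss_cells - sum(value)^2 / N
  msw <- ssw / (N - s)
  msb <- ssb / (s - 1)
  k_eff <- (N - sum(ki^2) / N) / (s - 1)   # k0 for unbalanced designs
  list(msb = msb, msw = msw, k_eff = k_eff,
       var_between = max(0, (msb - msw) / k_eff), var_within = msw,
       n_subjects = s, n_obs = N, subject_means = sums / ki, k_i = ki)
}

# balanced fast path used heavily by the simulation harness (s x k matrix)
.anova_balanced <- function(mat) {
  s <- nrow(mat)
  k <- ncol(mat)
  means <- rowMeans(mat)
  msb <- k * stats::var(means)
  msw <- sum((mat - means)^2) / (s * (k - 1))
  list(msb = msb, msw = msw, k_eff = k,
       var_between = max(0, (msb - msw) / k), var_within = msw,
       n_subjects = s, n_obs = s * k, subject_means = means,
       k_i = rep.int(k, s))
}

# Fisher's large-sample variance of the one-way consistency ICC
.icc_fisher_var <- function(icc, k, s) {
  2 * (1 - icc)^2 * (1 + (k - 1) * icc)^2 / (k * (k - 1) * (s - 1))
}

.icc_from_components <- function(comp, icc_floor = 0.01) {
  vb <- comp$var_between
  vw <- comp$var_within
  clamped <- (comp$msb - comp$msw) / comp$k_eff < 0
  icc <- if (vb + vw == 0) 1 else vb / (vb + vw)   # exact agreement -> 1
  if (icc < icc_floor) {
    icc <- icc_floor
    clamped <- TRUE
    vb <- vw * icc / (1 - icc)      # keep icc == vb/(vb+vw) after clamping
  }
  icc <- min(icc, 1)
  se <- sqrt(.icc_fisher_var(icc, comp$k_eff, comp$n_subjects))
  list(icc = icc, var_between = vb, var_within = vw, se = se,
       clamped = clamped)
}

#' One-way ANOVA variance components of replicate measurements
#'
#' Decomposes replicate biomarker measurements into between-subject and
#' within-subject variance via the one-way random-effects ANOVA.  Subjects
#' with a single measurement are excluded.  For unbalanced designs the
#' between-subject component uses the effective replicate count
#' \eqn{k_0 = (N - \sum k_i^2/N)/(s - 1)}.
#'
#' @param data Data frame with one row per measurement.
#' @param subject,value Column names (strings) of the subject identifier and
#'   the measurement.
#' @return A one-row tibble: `var_between`, `var_within`, `msb`, `msw`,
#'   `k_eff`, `n_subjects`, `n_obs`.  A negative moment estimate of the
#'   between-subject component is truncated at zero.
#' @examples
#' anova_components(data.frame(subject = c("A", "A", "B", "B"),
#'                             value   = c(0, 1, 1, 2)))
#' @export
anova_components <- function(data, subject = "subject", value = "value") {
  stopifnot(is.data.frame(data), subject %in% names(data), value %in% names(data))
  .check_finite(data[[value]], value)
  comp <- .anova_kernel(data[[subject]], data[[value]])
  tibble::tibble(
    var_between = comp$var_between, var_within = comp$var_within,
    msb = comp$msb, msw = comp$msw, k_eff = comp$k_eff,
    n_subjects = comp$n_subjects, n_obs = comp$n_obs
  )
}

.new_icc_estimate <- function(est, comp, scale, group, convention = NA_character_) {
  structure(
    list(icc = est$icc, var_between = est$var_between,
         var_within = est$var_within, se = est$se,
         n_subjects = comp$n_subjects,
         mean_replicates = comp$n_obs / comp$n_subjects,
         k_eff = comp$k_eff, clamped = est$clamped,
         scale = scale, group = group, convention = convention),
    class = "icc_estimate"
  )
}

#' Intraclass correlation from a replicate data frame
#'
#' Estimates the one-way consistency ICC, on the raw measurement scale or on
#' the probit (normal-scores) scale.  On the probit scale each replicate
#' column is transformed with [normal_scores()] separately -- every subject's
#' replicate-`r` values within the selected group form one transform batch --
#' so the estimate is invariant to any strictly monotone distortion applied
#' uniformly within a replicate column.
#'
#' Because the downstream AUC correction divides by the ICC, estimates below
#' `icc_floor` (and negative between-subject components) are clamped, with
#' `clamped = TRUE` recorded on the result.
#'
#' @param data A biomarker data frame (see [as_biomarker()]), or any data
#'   frame with `subject`, `replicate`, `value` columns when `group = NULL`.
#' @param group `"case"` or `"control"` to select one group, or `NULL` to use
#'   all rows as a single cohort.
#' @param scale `"probit"` (default) or `"raw"`.
#' @param convention ECDF offset passed to [normal_scores()].
#' @param icc_floor Lower clamp for the ICC, default 0.01.
#' @param se_method `"fisher"` for the large-sample approximation (default)
#'   or `"bootstrap"` for a subject-level nonparametric bootstrap.
#' @param boot,seed Bootstrap replicate count (default 1000) and RNG seed,
#'   used only when `se_method = "bootstrap"`.
#' @return An object of class `icc_estimate`: `icc`, `var_between`,
#'   `var_within`, `se`, `n_subjects`, `mean_replicates`, `k_eff`,
#'   `clamped`, `scale`, `group`.
#' @examples
#' dat <- simulate_biomarkers(sim_config(model = "I", m = 50, n = 50), seed = 2)
#' estimate_icc(dat, group = "case")
#' estimate_icc(dat, group = "control", scale = "raw")
#' @export
estimate_icc <- function(data, group = NULL, scale = c("probit", "raw"),
                         convention = c("vdw", "blom"), icc_floor = 0.01,
                         se_method = c("fisher", "bootstrap"),
                         boot = 1000, seed = NULL) {
  scale <- match.arg(scale)
  convention <- match.arg(convention)
  se_method <- match.arg(se_method)
  stopifnot(is.data.frame(data))
  if (!is.null(group)) {
    group <- match.arg(group, c("case", "control"))
    .check_biomarker(data)
    data <- data[data$group == group, , drop = FALSE]
    if (nrow(data) == 0L) stop("no rows in group '", group, "'.", call. = FALSE)
  }
  stopifnot(all(c("subject", "replicate", "value") %in% names(data)))
  .check_finite(data$value, "value")

  work <- if (scale == "probit") {
    transformed <- data
    transformed$value <- stats::ave(
      data$value, data$replicate,
      FUN = function(v) normal_scores(v, convention = convention)
    )
    transformed
  } else {
    data
  }

  comp <- .anova_kernel(work$subject, work$value)
  est <- .icc_from_components(comp, icc_floor = icc_floor)
  if (se_method == "bootstrap") {
    est$se <- .icc_boot_se(work, icc_floor = icc_floor, boot = boot, seed = seed)
  }
  .new_icc_estimate(est, comp, scale = scale, group = group %||% "all",
                    convention = if (scale == "probit") convention else NA_character_)
}

#' Probit-scale intraclass correlation for one group
#'
#' Convenience wrapper: `estimate_icc(data, group, scale = "probit")`.
#'
#' @inheritParams estimate_icc
#' @return An `icc_estimate`.
#' @export
probit_icc <- function(data, group = c("case", "control"),
                       convention = c("vdw", "blom"), icc_floor = 0.01) {
  group <- match.arg(group)
  estimate_icc(data, group = group, scale = "probit",
               convention = convention, icc_floor = icc_floor)
}

# subject-level nonparametric bootstrap SE of the ICC; resamples subjects
# with replacement, keeping each subject's replicate set intact.
.icc_boot_se <- function(data, icc_floor, boot = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  by_subj <- split(data$value, factor(data$subject))
  by_subj <- by_subj[lengths(by_subj) >= 2L]
  s <- length(by_subj)
  stats <- vapply(seq_len(boot), function(b) {
    idx <- sample.int(s, s, replace = TRUE)
    vals <- by_subj[idx]
    comp <- .anova_kernel(rep(seq_len(s), lengths(vals)), unlist(vals, use.names = FALSE))
    .icc_from_components(comp, icc_floor = icc_floor)$icc
  }, numeric(1))
  stats::sd(stats)
}

#' @export
print.icc_estimate <- function(x, ...) {
  cat(sprintf("ICC (%s scale, group = %s): %.4f (se %.4f)%s\n",
              x$scale, x$group, x$icc, x$se,
              if (x$clamped) " [clamped]" else ""))
  cat(sprintf("  var between %.4f, var within %.4f; %d subjects, mean %.2f replicates\n",
              x$var_between, x$var_within, x$n_subjects, x$mean_replicates))
  invisible(x)
}
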