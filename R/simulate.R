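# Monte-Carlo study: generators for three case-control measurement-error
# models and an evaluation harness reporting bias, MSE, and coverage of the
# uncorrected and corrected AUC estimators.
#
# Model I   : normal true values + additive normal errors.
# Model II  : lognormal true values + additive normal errors.
# Model III : lognormal true values + additive lognormal errors (the errors
#             are strictly positive with mean exp(sigma^2/2); no centering).
#
# Replicates share the subject's true value and carry independent error
# draws, so the k measurements of one subject are dependent.

#' Configuration of a Monte-Carlo simulation study
#'
#' Defaults are the package's reference study conditions: 100 cases and 100
#' controls with two replicates each; unit between-subject variances; error
#' variance 0.5 under Model I and 1 under Models II/III (log-scale
#' variances for the lognormal components); control location 0 and
#' `lambda = 0`.
#'
#' @param model `"I"`, `"II"`, or `"III"` (also accepts 1, 2, 3).
#' @param mu_x,mu_y Location of cases and controls: means under Model I,
#'   log-scale means (offset by `lambda`) under Models II/III.
#' @param lambda Baseline log-scale location for Models II/III.
#' @param m,n Numbers of cases and controls per dataset.
#' @param k Replicates per subject (default 2).
#' @param var_x_true,var_y_true Between-subject (true-value) variances;
#'   log-scale under Models II/III.
#' @param var_err_x,var_err_y Error variances (Model III: log-scale variance
#'   of the lognormal error).  Default 0.5 for Model I, 1 otherwise.
#' @param n_datasets Datasets generated per run (default 1000).
#' @param n_runs Independent runs over which performance measures are
#'   averaged (default 100).
#' @param conf_level Confidence level of the per-dataset intervals.
#' @param base_seed Base RNG seed; every dataset's seed is derived
#'   deterministically from it.
#' @return A `sim_config` list.
#' @examples
#' sim_config(model = "II", mu_x = 1)
#' @export
sim_config <- function(model = c("I", "II", "III"), mu_x = 1, mu_y = 0,
                       lambda = 0, m = 100, n = 100, k = 2,
                       var_x_true = 1, var_y_true = 1,
                       var_err_x = NULL, var_err_y = NULL,
                       n_datasets = 1000, n_runs = 100,
                       conf_level = 0.95, base_seed = 1L) {
  if (is.numeric(model)) model <- c("I", "II", "III")[model]
  model <- match.arg(model)
  default_err <- if (model == "I") 0.5 else 1
  var_err_x <- var_err_x %||% default_err
  var_err_y <- var_err_y %||% default_err
  cfg <- list(model = model, mu_x = mu_x, mu_y = mu_y, lambda = lambda,
              m = as.integer(m), n = as.integer(n), k = as.integer(k),
              var_x_true = var_x_true, var_y_true = var_y_true,
              var_err_x = var_err_x, var_err_y = var_err_y,
              n_datasets = as.integer(n_datasets),
              n_runs = as.integer(n_runs),
              conf_level = conf_level, base_seed = as.integer(base_seed))
  stopifnot(cfg$m >= 1L, cfg$n >= 1L, cfg$k >= 1L,
            cfg$n_datasets >= 1L, cfg$n_runs >= 1L,
            cfg$var_x_true > 0, cfg$var_y_true > 0,
            cfg$var_err_x >= 0, cfg$var_err_y >= 0,
            cfg$conf_level > 0, cfg$conf_level < 1)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation Model %s: m=%d cases, n=%d controls, k=%d replicates\n",
              x$model, x$m, x$n, x$k))
  cat(sprintf("  mu_x=%g mu_y=%g lambda=%g; true var (%g, %g); error var (%g, %g)\n",
              x$mu_x, x$mu_y, x$lambda, x$var_x_true, x$var_y_true,
              x$var_err_x, x$var_err_y))
  cat(sprintf("  %d datasets x %d runs, conf level %g, base seed %d; true AUC %.3f\n",
              x$n_datasets, x$n_runs, x$conf_level, x$base_seed, true_auc(x)))
  invisible(x)
}

#' Analytic true AUC of a simulation configuration
#'
#' Under Model I, \eqn{\Phi\{(\mu_X-\mu_Y)/\sqrt{\sigma^2_{X,true} +
#' \sigma^2_{Y,true}}\}}.  Under Models II/III the same expression applies to
#' the log-scale locations and variances, because the log is a strictly
#' increasing transform and the AUC is rank-based.
#'
#' @param config A [sim_config()].
#' @return The true AUC in (0, 1).
#' @examples
#' true_auc(sim_config(model = "I", mu_x = 0.5))  # 0.638
#' @export
true_auc <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  stats::pnorm((config$mu_x - config$mu_y) /
                 sqrt(config$var_x_true + config$var_y_true))
}

# draw one dataset as case/control s x k matrices (fast path)
.sim_draw <- function(config) {
  m <- config$m; n <- config$n; k <- config$k
  err <- function(nn, v, lognorm) {
    if (v == 0) return(matrix(0, nn, k))
    e <- stats::rnorm(nn * k, 0, sqrt(v))
    matrix(if (lognorm) exp(e) else e, nn, k)
  }
  if (config$model == "I") {
    xt <- stats::rnorm(m, config$mu_x, sqrt(config$var_x_true))
    yt <- stats::rnorm(n, config$mu_y, sqrt(config$var_y_true))
    lognorm <- FALSE
  } else {
    xt <- exp(stats::rnorm(m, config$lambda + config$mu_x, sqrt(config$var_x_true)))
    yt <- exp(stats::rnorm(n, config$lambda + config$mu_y, sqrt(config$var_y_true)))
    lognorm <- config$model == "III"
  }
  list(x = xt + err(m, config$var_err_x, lognorm),
       y = yt + err(n, config$var_err_y, lognorm))
}

#' Generate one simulated biomarker dataset
#'
#' Draws `m` cases and `n` controls, each with `k` replicate measurements
#' that share the subject's true value and carry independent error draws.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed for this dataset (default the config's `base_seed`).
#' @return A long-format biomarker tibble with columns `subject`, `group`,
#'   `replicate`, `value`.
#' @examples
#' simulate_biomarkers(sim_config(model = "I", m = 3, n = 2), seed = 1)
#' @export
simulate_biomarkers <- function(config, seed = config$base_seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  d <- .sim_draw(config)
  ids <- c(sprintf("case_%04d", seq_len(config$m)),
           sprintf("ctrl_%04d", seq_len(config$n)))
  tibble::tibble(
    subject = rep(ids, each = config$k),
    group = rep(c("case", "control"), times = c(config$m, config$n) * config$k),
    replicate = rep(seq_len(config$k), times = config$m + config$n),
    value = as.vector(t(rbind(d$x, d$y)))
  )
}

# fast probit-scale ICC from a balanced s x k matrix; returns icc + variance
.probit_icc_mat <- function(mat, convention = "vdw", icc_floor = 0.01) {
  s <- nrow(mat)
  p <- apply(mat, 2, rank) / (s + 1)
  if (convention == "blom") p <- (apply(mat, 2, rank) - 3 / 8) / (s + 1 / 4)
  comp <- .anova_balanced(stats::qnorm(p))
  est <- .icc_from_components(comp, icc_floor = icc_floor)
  list(icc = est$icc, var = est$se^2, clamped = est$clamped)
}

# one dataset -> estimate + CI per requested method
.eval_one <- function(d, methods, conf_level, z, variance = "delong") {
  m <- nrow(d$x); n <- nrow(d$y)
  out <- matrix(NA_real_, length(methods), 3,
                dimnames = list(methods, c("est", "lo", "hi")))
  mw <- .mw_kernel(d$x[, 1], d$y[, 1])
  se <- if (variance == "hanley") sqrt(max(.hanley_var(mw$auc, m, n), 0)) else sqrt(mw$var_delong)
  if ("mw" %in% methods) {
    out["mw", ] <- c(mw$auc, .clip(c(mw$auc - z * se, mw$auc + z * se), 0, 1))
  }
  if ("binormal" %in% methods) {
    b <- .binormal_obs(d$x[, 1], d$y[, 1], conf_level)
    out["binormal", ] <- c(b$auc, b$ci)
  }
  if ("probit" %in% methods) {
    ix <- .probit_icc_mat(d$x)
    iy <- .probit_icc_mat(d$y)
    eps <- 1 / (2 * m * n)
    a <- stats::qnorm(.clip(mw$auc, eps, 1 - eps))
    b <- sqrt((1 / ix$icc + 1 / iy$icc) / 2)
    var_a <- se^2 / stats::dnorm(a)^2
    var_b <- (ix$var / ix$icc^4 + iy$var / iy$icc^4) / (16 * b^2)
    se_ab <- sqrt(b^2 * var_a + a^2 * var_b)
    out["probit", ] <- stats::pnorm(c(a * b, a * b - z * se_ab, a * b + z * se_ab))
  }
  if ("reiser" %in% methods) {
    r <- .reiser_kernel(.anova_balanced(d$x), .anova_balanced(d$y), conf_level)
    out["reiser", ] <- c(r$auc, r$ci)
  }
  out
}

#' Run a Monte-Carlo evaluation of the AUC estimators
#'
#' For each of `n_runs` runs, generates `n_datasets` datasets under the
#' configured model and computes, per dataset, each requested estimator with
#' its confidence interval.  Per run, bias = mean(estimate) - true AUC,
#' MSE = mean\{(estimate - true AUC)^2\}, and coverage = fraction of
#' intervals containing the true AUC.  The report gives per-method means
#' across runs with 95% intervals `mean +/- 1.96 * SD` of the run-level
#' values (the spread of a single run's result); `se_mean` is the Monte-Carlo
#' standard error of the reported mean itself (SD / sqrt(n_runs)).
#'
#' Estimation methods: `"mw"` (uncorrected Mann-Whitney on the primary
#' replicate with a DeLong interval), `"reiser"`, `"probit"`, and optionally
#' `"binormal"` (uncorrected normal-theory estimate, a diagnostic for
#' non-normality).  Corrections use the replicates only through the ICC /
#' variance components; the observed AUC always comes from replicate 1.
#'
#' Every dataset's seed is `base_seed + 1000003 * run + dataset`, so reports
#' are bit-identical for identical configurations and base seeds.  A dataset
#' on which a method fails is dropped from that method's summaries; more
#' than 1% failures aborts the study.
#'
#' @param config A [sim_config()].
#' @param methods Subset of `c("mw", "reiser", "probit", "binormal")`.
#' @param variance Variance estimator for the Mann-Whitney interval.
#' @return A `sim_report` tibble with one row per method: the simulation
#'   conditions, `auc_true`, `bias_x1000`, `mse_x10000`, `coverage_pct`,
#'   each with `*_lo`/`*_hi` interval bounds, `se_mean_*` Monte-Carlo
#'   standard errors, and `n_failed`.
#' @examples
#' cfg <- sim_config(model = "I", mu_x = 1, m = 40, n = 40,
#'                   n_datasets = 50, n_runs = 2, base_seed = 7)
#' run_sim_study(cfg)
#' @export
run_sim_study <- function(config, methods = c("mw", "reiser", "probit"),
                          variance = c("delong", "hanley")) {
  stopifnot(inherits(config, "sim_config"))
  variance <- match.arg(variance)
  methods <- match.arg(methods, c("mw", "reiser", "probit", "binormal"),
                       several.ok = TRUE)
  z <- .z_two_sided(config$conf_level)
  target <- true_auc(config)
  n_methods <- length(methods)

  per_run <- array(NA_real_, c(config$n_runs, n_methods, 3),
                   dimnames = list(NULL, methods, c("bias", "mse", "coverage")))
  n_failed <- stats::setNames(integer(n_methods), methods)

  for (run in seq_len(config$n_runs)) {
    est <- array(NA_real_, c(config$n_datasets, n_methods, 3))
    for (d_idx in seq_len(config$n_datasets)) {
      set.seed(config$base_seed + 1000003L * run + d_idx)
      d <- .sim_draw(config)
      res <- tryCatch(
        suppressWarnings(.eval_one(d, methods, config$conf_level, z, variance)),
        error = function(e) NULL
      )
      if (!is.null(res)) est[d_idx, , ] <- res
    }
    for (j in seq_len(n_methods)) {
      e <- est[, j, 1]
      ok <- is.finite(e)
      n_failed[j] <- n_failed[j] + sum(!ok)
      per_run[run, j, "bias"] <- mean(e[ok]) - target
      per_run[run, j, "mse"] <- mean((e[ok] - target)^2)
      per_run[run, j, "coverage"] <-
        mean(est[ok, j, 2] <= target & target <= est[ok, j, 3])
    }
  }
  total <- config$n_runs * config$n_datasets
  if (any(n_failed / total >= 0.01)) {
    stop("more than 1% of datasets failed for method(s): ",
         paste(methods[n_failed / total >= 0.01], collapse = ", "),
         call. = FALSE)
  }

  summarise_metric <- function(vals, scale) {
    mu <- mean(vals) * scale
    sdv <- stats::sd(vals) * scale
    if (is.na(sdv)) sdv <- 0   # n_runs == 1
    c(mu, mu - 1.96 * sdv, mu + 1.96 * sdv, sdv / sqrt(length(vals)))
  }
  rows <- purrr::map(seq_len(n_methods), function(j) {
    b <- summarise_metric(per_run[, j, "bias"], 1000)
    m <- summarise_metric(per_run[, j, "mse"], 10000)
    cv <- summarise_metric(per_run[, j, "coverage"], 100)
    tibble::tibble(
      model = config$model, lambda = config$lambda,
      mu_y = config$mu_y, mu_x = config$mu_x, auc_true = target,
      method = c(mw = "mann_whitney", reiser = "reiser",
                 probit = "probit_shift", binormal = "binormal")[[methods[j]]],
      bias_x1000 = b[1], bias_lo = b[2], bias_hi = b[3], se_mean_bias = b[4],
      mse_x10000 = m[1], mse_lo = m[2], mse_hi = m[3], se_mean_mse = m[4],
      coverage_pct = cv[1], coverage_lo = cv[2], coverage_hi = cv[3],
      se_mean_coverage = cv[4],
      n_datasets = config$n_datasets, n_runs = config$n_runs,
      n_failed = n_failed[[j]]
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sim_report", class(out))
  attr(out, "config") <- config
  out
}
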