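test_that("analytic true AUC matches the closed form for each model", {
  expect_equal(round(true_auc(sim_config("I", mu_x = 0.25)), 2), 0.57)
  expect_equal(round(true_auc(sim_config("I", mu_x = 0.5)), 3), 0.638)
  expect_equal(round(true_auc(sim_config("II", mu_x = 1)), 2), 0.76)
  expect_equal(true_auc(sim_config("III", mu_x = 1)), pnorm(1 / sqrt(2)))
  expect_equal(true_auc(sim_config("I", mu_x = 0.3, mu_y = 0.3)), 0.5)
  expect_equal(true_auc(sim_config("I", mu_x = 1, var_x_true = 2)),
               pnorm(1 / sqrt(3)))
})

test_that("datasets are reproducible and shaped as declared", {
  cfg <- sim_config("II", m = 7, n = 5, k = 3)
  d1 <- simulate_biomarkers(cfg, seed = 61)
  d2 <- simulate_biomarkers(cfg, seed = 61)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), (7 + 5) * 3)
  expect_equal(sum(d1$group == "case"), 7 * 3)
  expect_equal(sort(unique(d1$replicate)), 1:3)
  expect_equal(dplyr::n_distinct(d1$subject), 12)
  # replicates of one subject share the truth but differ through error
  expect_gt(min(tapply(d1$value, d1$subject, sd)), 0)
})

test_that("zero error variance makes replicates identical", {
  cfg <- sim_config("I", m = 10, n = 10, var_err_x = 0, var_err_y = 0)
  dat <- simulate_biomarkers(cfg, seed = 62)
  expect_equal(max(tapply(dat$value, dat$subject, sd)), 0)
})

test_that("generator moments match the configured populations", {
  set.seed(63)
  # Model I reliability: icc = 1/(1+0.5) = 2/3 across many subjects
  cfg1 <- sim_config("I", m = 2000, n = 2)
  d <- aucorrect:::.sim_draw(cfg1)
  r <- cor(d$x[, 1], d$x[, 2])
  se_r <- (1 - (2 / 3)^2) / sqrt(2000)
  expect_lt(abs(r - 2 / 3), 3 * se_r)
  # Model II case truths: log-mean lambda + mu_x
  cfg2 <- sim_config("II", mu_x = 1, lambda = 2, m = 2000, n = 2,
                     var_err_x = 0, var_err_y = 0)
  d2 <- aucorrect:::.sim_draw(cfg2)
  expect_lt(abs(mean(log(d2$x[, 1])) - 3), 3 / sqrt(2000))
  # Model III errors are strictly positive (lognormal, uncentered)
  cfg3 <- sim_config("III", m = 500, n = 500, var_x_true = 1e-12,
                     var_y_true = 1e-12)
  d3 <- aucorrect:::.sim_draw(cfg3)
  expect_true(all(d3$x > exp(1)))  # truth e^1 plus positive error
  err <- d3$y - exp(0)
  expect_lt(abs(mean(err) - exp(0.5)), 3 * sd(err) / sqrt(length(err)))
})

test_that("study reports are bit-identical for identical configurations", {
  cfg <- sim_config("III", mu_x = 0.5, m = 30, n = 30, n_datasets = 40,
                    n_runs = 2, base_seed = 64)
  r1 <- run_sim_study(cfg)
  r2 <- run_sim_study(cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_true(all(r1$coverage_pct >= 0 & r1$coverage_pct <= 100))
  expect_true(all(r1$mse_x10000 >= 0))
  expect_true(all(r1$bias_lo <= r1$bias_x1000 & r1$bias_x1000 <= r1$bias_hi))
})

test_that("all estimators are calibrated at the null", {
  cfg <- sim_config("I", mu_x = 0, m = 50, n = 50, n_datasets = 300,
                    n_runs = 1, base_seed = 65)
  rep0 <- run_sim_study(cfg)
  for (j in seq_len(nrow(rep0))) {
    mc_se_bias <- sqrt(rep0$mse_x10000[j] / 1e4 / cfg$n_datasets) * 1000
    expect_lt(abs(rep0$bias_x1000[j]), 3 * mc_se_bias)
    cov_se <- 100 * sqrt(0.95 * 0.05 / cfg$n_datasets)
    expect_lt(abs(rep0$coverage_pct[j] - 95), 4 * cov_se)
  }
})

test_that("attenuation is toward the null and corrections restore ordering", {
  cfg <- sim_config("II", mu_x = 1, m = 60, n = 60, n_datasets = 300,
                    n_runs = 1, base_seed = 66)
  rep1 <- run_sim_study(cfg)
  bias <- function(m) rep1$bias_x1000[rep1$method == m]
  # both uncorrected and normal-theory estimates are pulled toward 0.5 by
  # lognormal data; the rank-based correction stays closest to the truth
  expect_lt(bias("mann_whitney"), 0)
  expect_lt(bias("reiser"), 0)
  expect_lt(abs(bias("probit_shift")), abs(bias("reiser")))
  expect_lt(abs(bias("probit_shift")), abs(bias("mann_whitney")))
})

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config("I", m = 0))
  expect_error(sim_config("II", var_x_true = -1))
  expect_error(sim_config("IV"))
  expect_silent(sim_config(2))
})
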