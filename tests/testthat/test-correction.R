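test_that("probit-shift correction reproduces the worked screening example", {
  # observed AUC 0.589 with probit-scale reliabilities 0.648 / 0.498
  expect_equal(round(probit_shift_correct(0.589, 0.648, 0.498), 3), 0.618)
})

test_that("probit-shift correction has the right fixed points and identities", {
  expect_equal(probit_shift_correct(0.5, 0.9, 0.2), 0.5)
  for (a0 in c(0.05, 0.3, 0.6, 0.95)) {
    expect_equal(probit_shift_correct(a0, 1, 1), a0)
    # equal ICCs collapse onto the Faraggi form with theta2 = 1/icc - 1
    for (icc in c(0.3, 0.6, 0.9)) {
      expect_equal(probit_shift_correct(a0, icc, icc),
                   faraggi_correct(a0, 1 / icc - 1))
    }
  }
  expect_equal(faraggi_correct(0.77, 0), 0.77)
  expect_equal(faraggi_correct(0.5, 10), 0.5)
  expect_equal(faraggi_correct(pnorm(0.5), 1), pnorm(0.5 * sqrt(2)))
})

test_that("correction moves estimates away from the null, symmetrically", {
  set.seed(51)
  for (i in 1:50) {
    a0 <- runif(1, 0.02, 0.98)
    icc_x <- runif(1, 0.2, 1)
    icc_y <- runif(1, 0.2, 1)
    corrected <- probit_shift_correct(a0, icc_x, icc_y)
    # attenuation direction: |probit| never shrinks
    expect_gte(abs(qnorm(corrected)) + 1e-12, abs(qnorm(a0)))
    # complement equivariance
    expect_equal(probit_shift_correct(1 - a0, icc_x, icc_y), 1 - corrected,
                 tolerance = 1e-10)
  }
  # monotonicity in each ICC on either side of the null
  iccs <- seq(0.2, 1, by = 0.1)
  up <- probit_shift_correct(0.8, iccs, 0.7)
  expect_true(all(diff(up) < 0))
  down <- probit_shift_correct(0.3, iccs, 0.7)
  expect_true(all(diff(down) > 0))
})

test_that("correction rejects boundary and invalid inputs", {
  expect_error(probit_shift_correct(0, 0.5, 0.5), "inside")
  expect_error(probit_shift_correct(1, 0.5, 0.5), "inside")
  expect_error(probit_shift_correct(0.7, 0, 0.5), "ICC")
  expect_error(probit_shift_correct(0.7, 0.5, 1.2), "ICC")
  expect_error(faraggi_correct(0.7, -0.5), "nonnegative")
})

test_that("noise-free components collapse the interval onto the point", {
  fake_auc <- structure(
    list(auc = 0.7, se = 0, ci_lower = 0.7, ci_upper = 0.7,
         estimator = "mann_whitney", n_cases = 50, n_controls = 50,
         conf_level = 0.95, degenerate = FALSE, variance = "delong",
         ci_scale = "probability"),
    class = "auc_estimate")
  fake_icc <- function(icc) structure(
    list(icc = icc, var_between = icc, var_within = 1 - icc, se = 0,
         n_subjects = 50, mean_replicates = 2, k_eff = 2, clamped = FALSE,
         scale = "probit", group = "case", convention = "vdw"),
    class = "icc_estimate")
  res <- probit_shift_ci(fake_auc, fake_icc(0.8), fake_icc(0.6))
  expect_equal(res$ci_lower, res$auc_corrected)
  expect_equal(res$ci_upper, res$auc_corrected)
  expect_equal(res$auc_corrected, probit_shift_correct(0.7, 0.8, 0.6))
})

test_that("delta-method se of the corrected probit agrees with the bootstrap", {
  cfg <- sim_config(model = "I", mu_x = 1, m = 100, n = 100)
  dat <- simulate_biomarkers(cfg, seed = 520)
  fit <- probit_shift_ci(estimate_auc(dat),
                         probit_icc(dat, "case"), probit_icc(dat, "control"))
  boot <- bootstrap_correction_se(dat, method = "probit", B = 600, seed = 521)
  expect_lt(abs(fit$se_ab - boot$se_ab) / boot$se_ab, 0.15)
})

test_that("Reiser correction reduces to the binormal AUC without error", {
  # replicates identical -> msw = 0, theta2 = 0
  cfg <- sim_config(model = "I", mu_x = 1, m = 400, n = 400, var_err_x = 0,
                    var_err_y = 0)
  dat <- simulate_biomarkers(cfg, seed = 530)
  res <- reiser_correct(dat)
  expect_equal(res$theta2, 0)
  cases <- dat$value[dat$group == "case" & dat$replicate == 1]
  ctrls <- dat$value[dat$group == "control" & dat$replicate == 1]
  # with k identical replicates the ANOVA between-variance is the sample
  # variance of the subject values, so the corrected AUC is the binormal AUC
  # of the sample moments
  expect_equal(res$auc_corrected,
               binormal_auc(mean(cases), mean(ctrls), var(cases), var(ctrls)))
})

test_that("Reiser correction is nearly unbiased under its own model", {
  cfg <- sim_config(model = "I", mu_x = 1, n_datasets = 400, n_runs = 1,
                    base_seed = 54)
  rep1 <- run_sim_study(cfg, methods = "reiser")
  mc_se <- sqrt(rep1$mse_x10000 / 1e4 / cfg$n_datasets)
  expect_lt(abs(rep1$bias_x1000 / 1000), 3 * mc_se)
})

test_that("the full correction report is coherent and degenerates sanely", {
  dat <- simulate_biomarkers(sim_config(model = "II", m = 60, n = 60), seed = 55)
  tbl <- correct_auc(dat, theta2 = 0.5,
                     methods = c("mw", "reiser", "probit", "faraggi"))
  expect_s3_class(tbl, "auc_correction_tbl")
  expect_setequal(tbl$method,
                  c("mann_whitney", "reiser", "probit_shift", "faraggi"))
  expect_true(all(tbl$conf_low <= tbl$estimate & tbl$estimate <= tbl$conf_high,
                  na.rm = TRUE))
  expect_true(all(tbl$inflation >= 1, na.rm = TRUE))
  # zero replicate variation: probit ICCs are 1 and the probit row equals MW
  dup <- dat
  dup$value <- ave(dup$value, dup$subject, FUN = function(v) v[1])
  tbl2 <- correct_auc(dup)
  mw <- tbl2[tbl2$method == "mann_whitney", ]
  pr <- tbl2[tbl2$method == "probit_shift", ]
  expect_equal(pr$estimate, mw$estimate)
  expect_equal(pr$inflation, 1)
  # no replicates at all: corrections are skipped with a warning
  solo <- dat[dat$replicate == 1, ]
  expect_warning(tbl3 <- correct_auc(solo), "skipping")
  expect_equal(tbl3$method, "mann_whitney")
})
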