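test_that("ANOVA components match the hand-computed two-subject fixture", {
  comp <- anova_components(two_subject_fixture())
  expect_equal(comp$msb, 1)
  expect_equal(comp$msw, 0.5)
  expect_equal(comp$var_between, 0.25)
  expect_equal(comp$var_within, 0.5)
  expect_equal(comp$k_eff, 2)
  icc <- estimate_icc(two_subject_fixture(), scale = "raw")
  expect_equal(icc$icc, 1 / 3)
})

test_that("ANOVA components agree with direct summation on balanced data", {
  set.seed(41)
  for (i in 1:10) {
    groups <- lapply(1:8, function(j) rnorm(3, mean = j))
    dat <- data.frame(subject = rep(letters[1:8], each = 3),
                      value = unlist(groups))
    comp <- anova_components(dat)
    direct <- direct_anova(groups)
    expect_equal(comp$msb, direct$msb)
    expect_equal(comp$msw, direct$msw)
  }
})

test_that("unbalanced designs use the effective replicate count k0", {
  dat <- data.frame(subject = rep(c("A", "B", "C"), times = c(2, 3, 4)),
                    value = c(1, 2, 4, 5, 6, 0, 1, 0, 2))
  comp <- anova_components(dat)
  ki <- c(2, 3, 4); N <- 9; s <- 3
  expect_equal(comp$k_eff, (N - sum(ki^2) / N) / (s - 1))
  # direct unbalanced mean squares
  direct <- direct_anova(split(dat$value, dat$subject))
  expect_equal(comp$msb, direct$msb)
  expect_equal(comp$msw, direct$msw)
})

test_that("degenerate reliability cases clamp with a faithful flag", {
  # perfect duplicates: no within-subject noise, icc = 1
  dup <- data.frame(subject = rep(c("A", "B"), each = 2),
                    replicate = rep(1:2, 2), value = c(3, 3, 7, 7))
  fit <- estimate_icc(dup, scale = "raw")
  expect_equal(fit$icc, 1)
  expect_equal(fit$var_within, 0)
  expect_false(fit$clamped)
  # pure noise: between-subject component vanishes, icc floored
  set.seed(42)
  noise <- data.frame(subject = rep(sprintf("s%02d", 1:40), each = 2),
                      replicate = rep(1:2, 40), value = rnorm(80))
  fit2 <- suppressWarnings(estimate_icc(noise, scale = "raw"))
  expect_true(fit2$icc >= 0.01)
  if (fit2$icc == 0.01) expect_true(fit2$clamped)
  # the reported components stay consistent with the clamped icc
  expect_equal(fit2$icc, fit2$var_between / (fit2$var_between + fit2$var_within))
  # single-replicate-only data cannot support an ICC
  single <- data.frame(subject = c("A", "B", "C"), value = 1:3)
  expect_error(anova_components(single), "at least 2 subjects")
})

test_that("variance components are recovered on simulated replicates", {
  set.seed(43)
  s <- 200; k <- 2
  truth <- rnorm(s, 0, 1)                       # var_between = 1
  dat <- data.frame(subject = rep(sprintf("s%03d", 1:s), each = k),
                    value = rep(truth, each = k) + rnorm(s * k, 0, sqrt(0.5)))
  comp <- anova_components(dat)
  # large-sample SEs: var(vb) ~ 2(msb^2/(s-1)+msw^2/(N-s))/k^2
  se_vb <- sqrt((2 * comp$msb^2 / (s - 1) + 2 * comp$msw^2 / (s * k - s)) / k^2)
  se_vw <- sqrt(2 * comp$msw^2 / (s * k - s))
  expect_lt(abs(comp$var_between - 1), 3 * se_vb)
  expect_lt(abs(comp$var_within - 0.5), 3 * se_vw)
})

test_that("icc is invariant to location/scale (raw) and monotone maps (probit)", {
  set.seed(44)
  dat <- data.frame(subject = rep(sprintf("s%02d", 1:30), each = 2),
                    replicate = rep(1:2, 30),
                    value = rep(rnorm(30), each = 2) + rnorm(60, 0, 0.6))
  raw <- estimate_icc(dat, scale = "raw")
  shifted <- dat; shifted$value <- 5 + 2.5 * dat$value
  expect_equal(estimate_icc(shifted, scale = "raw")$icc, raw$icc)
  pro <- estimate_icc(dat, scale = "probit")
  # distort one replicate column with a strictly increasing map
  bent <- dat
  r2 <- bent$replicate == 2
  bent$value[r2] <- exp(bent$value[r2])
  expect_equal(estimate_icc(bent, scale = "probit")$icc, pro$icc)
  expect_true(pro$icc >= 0.01 && pro$icc <= 1)
})

test_that("probit-scale icc approximates the raw icc for normal columns", {
  cfg <- sim_config(model = "I", m = 500, n = 50)
  set.seed(45)
  diffs <- replicate(30, {
    dat <- simulate_biomarkers(cfg, seed = sample.int(1e6, 1))
    probit_icc(dat, "case")$icc - estimate_icc(dat, "case", scale = "raw")$icc
  })
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)) + 0.005)
})

test_that("probit icc recovers the log-scale reliability under lognormal truth", {
  # truths lognormal, errors applied on the log scale: probit sees icc = 0.5
  set.seed(46)
  s <- 200
  iccs <- replicate(25, {
    truth <- rnorm(s)
    vals <- exp(rep(truth, each = 2) + rnorm(2 * s, 0, 1))
    dat <- data.frame(subject = rep(sprintf("s%03d", 1:s), each = 2),
                      replicate = rep(1:2, s), value = vals)
    estimate_icc(dat, scale = "probit")$icc
  })
  mc_se <- sd(iccs) / sqrt(length(iccs))
  expect_lt(abs(mean(iccs) - 0.5), 3 * mc_se + 0.01)
})

test_that("bootstrap and Fisher ICC standard errors agree to first order", {
  cfg <- sim_config(model = "I", m = 100, n = 30)
  dat <- simulate_biomarkers(cfg, seed = 470)
  fisher <- estimate_icc(dat, "case")
  boot <- estimate_icc(dat, "case", se_method = "bootstrap",
                       boot = 500, seed = 471)
  expect_lt(abs(boot$se - fisher$se) / fisher$se, 0.35)
})
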