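# shared fixtures and independent oracles (kept deliberately naive)

# brute-force AUC: enumerate every case-control pair
brute_force_auc <- function(cases, controls) {
  total <- 0
  for (x in cases) {
    for (y in controls) {
      total <- total + (y < x) + 0.5 * (y == x)
    }
  }
  total / (length(cases) * length(controls))
}

# textbook balanced one-way ANOVA by direct summation
direct_anova <- function(groups) { # list of numeric vectors
  s <- length(groups)
  ki <- lengths(groups)
  grand <- mean(unlist(groups))
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(ki * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  list(msb = ssb / (s - 1), msw = ssw / (sum(ki) - s))
}

# two-subject replicate fixture with hand-computed components:
# msb = 1, msw = 0.5, var_between = 0.25, var_within = 0.5, icc = 1/3
two_subject_fixture <- function() {
  data.frame(subject = c("A", "A", "B", "B"),
             replicate = c(1L, 2L, 1L, 2L),
             value = c(0, 1, 1, 2))
}

# small balanced biomarker tibble built by hand
tiny_biomarker <- function() {
  as_biomarker(data.frame(
    subject = rep(c("a", "b", "c", "d"), each = 2),
    group = rep(c("case", "case", "control", "control"), each = 2),
    replicate = rep(1:2, 4),
    value = c(2.1, 2.3, 3.0, 2.8, 1.0, 1.2, 0.7, 0.9)
  ))
}
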