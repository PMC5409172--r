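---
title: "Correcting AUC attenuation from measurement error: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting AUC attenuation from measurement error: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aucorrect)
```

## The estimand and why it is biased

For a continuous biomarker with case values $X$ and control values $Y$, the
area under the ROC curve is $AUC = \Pr(Y < X)$ (ties counted one half). What
we can estimate from data, however, is $AUC_{obs} = \Pr(Y_{obs} < X_{obs})$
for noisy measurements $X_{obs} = X_{true} + \varepsilon$. Independent
within-subject noise mixes the two distributions and pulls $AUC_{obs}$
toward 0.5; a 0.76-AUC marker measured with moderate noise can present as
0.70 or less. The goal of this package is to recover $AUC_{true}$ (and an
interval for it) from $AUC_{obs}$ plus replicate measurements on the same
subjects.

## The probit-shift model

Normal-theory corrections assume $X_{true}$, $Y_{true}$ and the errors are
Gaussian. We instead assume a *probit-shift*: after the probit transform
$H(x) = \Phi^{-1}\{F(x)\}$, which maps any continuous distribution onto a
standard-normal scale, the case and control distributions differ only by a
location shift $\mu$:

$$\Phi^{-1}\{F_{Y,true}(z)\} = \Phi^{-1}\{F_{X,true}(z)\} + \mu.$$

This holds exactly for any pair of distributions linked by a monotone map to
two normals with equal variance — e.g. any lognormal pair with equal
log-scale variance — and replaces the (scale-dependent) location-shift
assumption with a rank-based one. Under it, a first-order Taylor
approximation gives $AUC_{true}(\mu) \approx \Phi(\mu/\sqrt 2)$.

Measurement error is modelled additively *on the probit scale*:
$H_{obs} = H_{true} + e$, $e \sim N(0, \sigma_e^2)$ independently per group.
The reliability of a single measurement on that scale is the intraclass
correlation $ICC = 1/(1+\sigma_e^2)$, and the attenuation works out to

$$AUC_{true}(\mu) \approx \Phi\!\left[\Phi^{-1}\{AUC_{obs}(\mu)\}\, b\right],
\qquad b = \sqrt{\tfrac12\left(\tfrac{1}{ICC_X} + \tfrac{1}{ICC_Y}\right)} .$$

`probit_shift_correct()` is exactly this map. Two sanity anchors are built
into its tests: $b = 1$ (perfect reliability) gives the identity, and with
equal ICCs it coincides with the classical known-$\theta^2$ correction
`faraggi_correct()` through $\theta^2 = 1/ICC - 1$.

## Estimating the ingredients

**Observed AUC.** The Mann-Whitney statistic on the *primary* measurement
(default: replicate 1), because the probit transform is rank-invariant.
Replicates never enter the observed AUC — they would artificially reduce
noise for subjects that happen to have more of them; they feed only the
reliability estimates. The default variance is the DeLong
structural-components estimator; the Hanley-McNeil exponential
approximation is available (`variance = "hanley"`) and agrees closely at
these sample sizes. Intervals are symmetric on the probability scale,
truncated to $[0,1]$; a logit-scale option exists for small samples.

**Reliabilities.** For each group, each replicate column is transformed with
`normal_scores()` — all subjects' replicate-$r$ values in the group form one
transform batch, so each replicate gets its own probit scale — and the
one-way ANOVA variance components of the transformed table give
$ICC = \sigma^2_b/(\sigma^2_b + \sigma^2_w)$. Subjects with a single
measurement are excluded from the ANOVA (they carry no within-subject
information) but still contribute to the AUC. Unbalanced designs use the
effective replicate count $k_0 = (N - \sum_i k_i^2/N)/(s-1)$. An
alternative would be to build one probit scale from all measurements pooled
across replicates; we chose the per-column construction because it keeps
each replicate's measurement occasion on its own scale (robust to, say, a
calibration drift between visits) and is exactly invariant to per-occasion
monotone distortions, which the tests verify.

**Confidence limits.** With $\hat a = \Phi^{-1}(\widehat{AUC}_{obs})$ and
$\hat b$ as above, the corrected AUC is $\Phi(\hat a \hat b)$ and

$$se^2(\hat a\hat b) = \hat b^2\, var(\hat a) + \hat a^2\, var(\hat b),
\qquad var(\hat a) = \frac{var(\widehat{AUC}_{obs})}{\phi(\hat a)^2},$$

with $var(\hat b)$ propagated from Fisher's large-sample ICC variances via
$\partial b/\partial ICC = -1/(4 b\, ICC^2)$, treating $\hat a$, $ICC_X$,
$ICC_Y$ as independent (they involve disjoint sources of variation to first
order: between-group ordering vs within-group scatter). The interval is
computed on the $\hat a\hat b$ scale and mapped through $\Phi$, so it always
brackets the point estimate inside $(0,1)$. The independence approximation
is checked two ways: a subject-resampling bootstrap
(`bootstrap_correction_se()`) reproduces the delta-method $se(\hat a\hat b)$
within 15% on a reference dataset, and the Monte-Carlo harness shows
near-nominal coverage under all three generators (see below).

**Competing corrections.** `reiser_correct()` implements the normal-theory
replicate-based correction: raw-scale ANOVA components per group,
$\hat\delta_{true} = (\bar X - \bar Y)/\sqrt{\hat\sigma^2_{X,true} +
\hat\sigma^2_{Y,true}}$, and a delta-method interval using large-sample
variances of the group means and chi-square variances for the mean squares.
Its published variance derivation is not reproduced here; our delta-method
construction is validated by its near-nominal coverage under the
normal-data generator. Under skewed data its behaviour (like the point
estimate's) degrades, and the detailed degradation depends on the variance
construction, so coverage figures under misspecification should be read as
indicative. The package also exposes an uncorrected normal-theory estimate
$\Phi(\hat\delta_{obs})$ (`run_sim_study(methods = "binormal")`) as a
diagnostic: comparing it with the Mann-Whitney estimate on the same data is
a quick check of how much normality is distorting a naive analysis.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `convention` | `"vdw"` | ECDF offset $r/(n+1)$ in `normal_scores()`; guarantees finite scores. `"blom"` $(r-3/8)/(n+1/4)$ is nearly identical beyond $n \approx 20$. |
| `primary_replicate` | 1 | which measurement is "the" test result; the others estimate reliability only. |
| `icc_floor` | 0.01 | the correction divides by the ICC, and moment estimators can reach 0 or below; estimates are clamped (flagged `clamped = TRUE`) and the components are re-expressed consistently with the clamped value. |
| `conf_level` | 0.95 | two-sided; $z_{0.975} = 1.959964$. |
| `variance` | `"delong"` | Mann-Whitney variance estimator. |
| `se_method` | `"fisher"` | ICC standard error; `"bootstrap"` (subject-level, seeded, default $B = 1000$) is the slower, assumption-light alternative. |

Degenerate inputs are handled explicitly rather than by failure: constant
pooled data give AUC 0.5 with a `degenerate` flag and zero SE; an observed
AUC at 0 or 1 (perfect separation) is clipped to
$[1/(2mn),\, 1 - 1/(2mn)]$ with a warning before $\Phi^{-1}$; exact
replicate agreement gives ICC 1; ties everywhere are midranked.

## What the synthetic generator emulates

`sim_config()` / `simulate_biomarkers()` implement three case-control
generators with $k$ replicates per subject, replicates sharing the
subject's true value with independent error draws:

* **Model I** — normal truths (variance 1), additive normal errors
  (variance 0.5): the home turf of the normal-theory corrections.
* **Model II** — lognormal truths (unit log-scale variance), additive
  normal errors (variance 1): skewed signal, symmetric noise.
* **Model III** — lognormal truths *and* lognormal errors (unit log-scale
  variances): the errors are strictly positive with mean $e^{1/2}$, and are
  deliberately not mean-centred; a common-mean offset does not change any
  rank-based quantity, but it does stress the normal-theory estimators.

Defaults — 100 cases, 100 controls, two replicates, control location 0,
case shift $\mu_X \in \{0.25, 0.5, 1\}$ giving true AUCs 0.570, 0.638,
0.760 — are the package's reference study conditions and are fixed, not
tuned. The analytic truth is $\Phi\{(\mu_X-\mu_Y)/\sqrt{\sigma^2_{X,true}
+ \sigma^2_{Y,true}}\}$ for all three models (log-scale parameters for
II/III, by rank invariance).

What the generators do *not* emulate: unequal true variances between groups
(reachable through `var_x_true`/`var_y_true`, but then the probit-shift
assumption itself is violated and the correction is only approximate);
heteroscedastic errors that grow with the true value; discrete or censored
markers; correlated case-control sampling (matched designs); drift between
replicate occasions. Passing the simulation suite therefore demonstrates
correct behaviour under independent additive noise on a monotone scale, not
under arbitrary real-data error structure.

## The evaluation harness and its reporting conventions

`run_sim_study()` evaluates each estimator per dataset, then per run
computes bias, MSE and coverage over `n_datasets` datasets, then averages
over `n_runs` runs. The reported 95% interval for each performance measure
is $\text{mean} \pm 1.96\,SD$ of the run-level values — the spread one run
of this size would show — while `se_mean_*` columns give the Monte-Carlo SE
of the reported mean itself ($SD/\sqrt{n\_runs}$). Seeds: every dataset is
generated after `set.seed(base_seed + 1000003\cdot run + dataset)`, so
reports are bit-identical for identical configurations and any failure is
reproducible in isolation. A method failing on more than 1% of datasets
aborts the study; isolated failures are dropped and counted (`n_failed`).

Problem sizes used by the package's own checks, chosen to keep a full
verification run on a desktop within minutes: the reference studies use 10
runs of 1000 datasets (10,000 datasets per model); the nine-cell
parameter-recovery check uses 500 datasets per cell; the bootstrap oracle
uses $B$ between 600 and 2000. At those sizes the Monte-Carlo SE of a
coverage estimate is about 0.4 percentage points, and of a bias estimate
about 1.3×10⁻³ — small relative to the effects being measured.

## Known limitations

* The correction relies on the first-order approximation
  $AUC_{true} \approx \Phi(\mu/\sqrt2)$ and on additivity of probit-scale
  error; both are approximations, and the corrected estimator carries a
  small residual bias (order a few ×10⁻³ at these sample sizes) that is
  largest for skewed data at moderate shifts. Its interval remains close to
  nominal because the bias is small relative to the sampling SD.
* Reliabilities enter through $1/ICC$: with ICCs below ~0.2 the correction
  inflates noise aggressively and the intervals become very wide; the
  `clamped` flag marks the pathological end of that regime.
* The equal-probit-variance assumption (one shift $\mu$) is the analogue of
  the equal-variance binormal model; a two-parameter extension
  $H_Y = c_1 H_X + c_2$ would relax it and is a natural next step.
* The delta-method interval treats the ICCs and the observed AUC as
  independent; the bootstrap alternative is provided precisely so users can
  check this on their own data.
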