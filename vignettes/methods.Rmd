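---
title: "Models and methods in agingnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in agingnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agingnet)
```

# The structural model

`agingnet` studies the joint behaviour of demographic variables, six
biological-aging biomarkers, and all-cause mortality through a recursive
structural model on a DAG. Nodes come in three families:

* **tier 0, exogenous demographics** — `AGE` (years; entered in all
  equations as a z-score), `SEX` (1 = female), and three mutually exclusive
  race/ethnicity dummies `NHB`, `HISP`, `OTHER` (non-Hispanic White is the
  reference);
* **tier 1, biomarkers** — four epigenetic age-acceleration metrics
  (Horvath, Hannum, Pheno/Levine, GrimAge; residuals of DNA-methylation age
  on chronological age), the Dunedin pace-of-aging measure, and mean
  leukocyte telomere length, all as z-scores;
* **tier 2, survival** — the death indicator `DIED`, which never has
  children.

Each continuous child is linear in its parents with a Gaussian residual:
continuous parents enter per standard deviation, binary parents per 0-to-1
change. When `target_unit_variance` is set (the default) the residual SD of
every continuous child is solved so that its marginal variance is exactly 1,
which makes the coefficients standardized betas; a configuration whose edge
weights leave no room for positive residual variance is rejected with the
offending node named. `implied_covariance()` propagates exact first and
second moments through the system (binary exogenous variance $p(1-p)$,
multinomial covariance $-p_ip_j$ between race dummies) and doubles as the
oracle the generator is tested against.

Mortality follows a Weibull proportional-hazards law
$$h(t \mid x) = \kappa \lambda_0 t^{\kappa-1} e^{x^\top\beta},$$
with coefficients on the log-hazard-ratio (LnHR) scale, and administrative
censoring at the cohort horizon: every subject either dies before the
horizon or is censored exactly at it.

## Default configurations and their parameters

`load_default_config()` ships two cohort emulations whose demographic mix,
edge coefficients, and crude mortality rates follow published population
cohorts of US adults:

| parameter | NHANES-like | HRS-like | note |
|---|---|---|---|
| n | 2522 | 1029 | subjects |
| age mean | 64.0 | 73.1 | years |
| age SD | 10 | 9 | chosen; see below |
| age range | 50–85 | 58–95 | truncation interval |
| % female | 54.4 | 59.0 | |
| % NHB / HISP / OTHER | 8.7 / 9.4 / 3.3 | 7.7 / 7.3 / 2.5 | |
| horizon | 20 y | 7 y | administrative censoring |
| target crude rate | 32.2 | 37.7 | per 1000 person-years |
| Weibull shape κ | 1.5 | 1.5 | chosen; see below |

Two generator parameters are not pinned down by the published descriptives
and were fixed once as modelling choices:

* **Age dispersion.** Only the mean age (with its design-based standard
  error) is published. An SD of 10 years (NHANES-like) and 9 years
  (HRS-like), truncated to the study age ranges, is typical survey
  dispersion for 50+/58+ samples; both are ordinary `demographics_config`
  fields and can be changed.
* **Weibull shape.** κ = 1.5 encodes a hazard rising with time, as expected
  for all-cause mortality at these ages; the published analyses do not
  report a shape. The baseline rate λ₀ is never guessed: the shipped values
  are the output of `calibrate_baseline_hazard()` run against each cohort's
  published crude mortality rate, and the calibration can be re-run at any
  time (it bisects on λ₀, in log space, against a large fixed-seed cohort
  whose exogenous draws and uniform quantiles are held fixed, which makes
  the crude rate strictly increasing in λ₀ and the search deterministic).

Sampling-design columns default to weight 1 and a single PSU; the
`weight_heterogeneity` flag draws lognormal(0, 0.5) weights (normalized to
mean 1) over 30 PSUs to exercise the design-adjusted estimator.

## What the generator emulates, and what it does not

The generator reproduces the *statistical structure* the analysis assumes:
marginal demographics, standardized linear relations among biomarkers,
proportional-hazards mortality, and administrative censoring. It does not
emulate raw CpG arrays or qPCR telomere assays, survey nonresponse,
left-truncated or staggered entry, competing causes of death, or
measurement-batch structure. Passing tests therefore demonstrate that the
estimators recover the generating process under its own assumptions — not
that real cohort data satisfy those assumptions.

# Discrete-time encoding

`to_person_period()` expands each subject into `ceiling(time / 2)` rows of
2-year periods (the interval width is an argument). A partial final period
counts as a full row; this keeps the expansion event-conserving
(`sum(death_k)` equals the cohort's death count) at the cost of slightly
over-stating exposure in the last period, which is immaterial for the
structure-learning stage the encoding feeds. All period dummies
`PER_1..PER_K` are emitted one-hot; the reference (`PER_1`) is dropped at
fit time rather than at encoding time so the table stays self-describing.

For the network stage every continuous covariate is discretized to decile
medians: values are cut at sample percentile boundaries (ties fall into the
lower bin; duplicate boundaries collapse bins with a warning) and each value
is replaced by its bin median. Ten bins is a choice — enough resolution to
preserve monotone signal, coarse enough to stabilize the person-period GLMs.
The coding is monotone and idempotent.

# Structure learning

The network score is decomposable over child/parent-set families. Two
scores are available:

* **BIC (default)** — maximized log-likelihood of the child's GLM minus
  $\tfrac{k}{2}\log N$, with $k = |Pa|+2$ for Gaussian children (residual
  variance counts) and $|Pa|+1$ for binomial. Deterministic and prior-free,
  hence the default for testing and reproducibility.
* **Laplace** — Laplace-approximate log marginal likelihood with
  independent Normal(0, 1000) coefficient priors, the convention of the ABN
  literature; for Gaussian children the residual variance is profiled at its
  MLE rather than integrated.

Collinear parent sets and separated logistic fits score $-\infty$ with a
diagnostic and can never enter a solution. Gaussian families are scored
from one cross-product matrix of the data (the sub-model RSS is a Schur
complement), so exhaustive caches over thousands of families cost a single
pass over the rows; binomial families are IRLS fits warm-started from the
retained-dummies-only model.

`most_probable_dag()` finds the *globally* score-maximal DAG under the
constraints by dynamic programming over node subsets (per-node
best-parent-set tables via a subset zeta transform, then a best-sink
decomposition), not by hill climbing; `brute_force_dag()` enumerates all
labelled DAGs on up to five nodes and serves as the test oracle. Ties are
fully specified so results are reproducible: scores equal within 1e-9 are
tied; among tied solutions the fewest arcs win; remaining ties prefer the
lexicographically ranked arc set (the arc-indicator vector read as a binary
number, exact in doubles wherever the oracle-equality guarantee applies).
The exact search is capped at 25 nodes by default — subset tables grow as
$2^n$, and the default mortality network uses 12.

Constraints encode the biology: demographics are exogenous (tier 0, never
children), biomarkers are free to point at each other within tier 1, `DIED`
is childless at tier 2. Period dummies are *retained* parents of `DIED`
only, banned elsewhere, and — deliberately — not counted against the parent
limit: limits of 1–3 parents per child are meaningful only for substantive
arcs, since the dummies alone outnumber them. `fit_across_parent_limits()`
solves the problem exactly at each limit (one cache, restricted per limit),
and `select_parent_limit()` picks the smallest limit whose gain to the next
is at most 1% (`delta_fraction`) of the whole trajectory's range — the
leveling-off rule; with no leveling, the largest limit wins.

One caveat is inherited from standard discrete-time practice: person-period
rows repeat each subject's covariates, and the node GLMs treat rows as
independent. This inflates the effective $N$ in the score penalty for the
biomarker nodes, which tends to admit more arcs at a given limit. The
package accepts this (as the discrete-time hazards convention does) and
documents it rather than switching to mixed-effects node models.

# The path model

`fit_path_model()` re-estimates a chosen DAG as a *series of independent
node-wise equations* — weighted least squares for each Gaussian child, the
Weibull proportional-hazards likelihood for `DIED` — rather than one joint
likelihood. Under node-wise estimation the equations share no parameters,
which is also why `indirect_effect()` may treat the per-edge estimates as
independent in its first-order delta-method variance
$\operatorname{Var}(\prod_j \hat\beta_j) \approx \sum_j \prod_{i\neq j}
\hat\beta_i^2 \, \mathrm{se}_j^2$.

The Weibull node is maximized by BFGS with an analytic gradient in
$(\log\kappa, \log\lambda_0, \beta)$ from a closed-form exponential start
($\kappa = 1$, $\lambda_0 = \sum w d / \sum w t$, $\beta = 0$); standard
errors come from the observed information, cross-checked in the tests
against `survival::survreg` (AFT-to-PH conversion) to 5 decimals.

Two variance regimes mirror the survey context:

* `model1_srs` — unweighted, classical standard errors;
* `model2_weighted` — sampling weights plus a PSU cluster-robust sandwich
  (each subject self-representing when there is a single PSU). Full
  stratified Taylor linearization is deliberately omitted: strata are
  accepted and reported but do not enter the variance, whose stratum effects
  are second-order at these design sizes. Estimates and robust errors are
  invariant to rescaling all weights.

All continuous variables are z-scored with the sample SD
(denominator $n-1$) before fitting, so recovered coefficients are on the
generating (standardized) scale; p-values are large-sample normal with no
small-sample t corrections.

# Classical companions — conventions

* **Tertiles** are computed unweighted (ties go to the lower group);
  Kaplan–Meier curves and log-rank tests are weighted. The weighted
  log-rank uses the score-test form with weights normalized to mean 1 (thus
  rescale-invariant); with unit weights it reproduces the classical test and
  `survival::survdiff` exactly.
* **Cox models** use Efron tie handling by default (generated continuous
  times essentially never tie); Breslow is available for cross-checks.
  Schoenfeld diagnostics use the identity time transform.
* **Harrell's C** is computed unweighted even for weighted Cox fits, with
  ties in the risk score counted one half; the test suite pins it to
  brute-force pair counting on instances up to 30 subjects.
* **LASSO** penalizes only the clock covariates; age, sex, and
  race/ethnicity are forced. Three penalty choices (10-fold CV, minimum BIC
  along the path, adaptive with weights $1/|\hat\beta_{OLS}|$) are computed
  on a seeded half sample stratified on the event indicator; the simplest
  selection (ties toward min-BIC) is refit by OLS on the full sample, and
  fit is compared across the halves.

# Numerical choices and degenerate inputs

* Score-tie tolerance 1e-9 (absolute), applied identically in the DP and
  the brute-force oracle; decomposability of reported totals is maintained
  to the same tolerance.
* Bisection for λ₀ proceeds in log space to a rate tolerance of 1.0 per
  1000 person-years by default, with explicit bracket expansion and a
  reported bracket on failure.
* Zero-variance columns, cyclic edge sets, arcs out of `DIED` or into
  tier-0 nodes, missing seeds, non-positive follow-up times, all-censored
  tables, and perfect separation are rejected with messages naming the
  offender rather than propagated.
* Constant vectors discretize to themselves (with a warning if more than
  one bin was requested); all-equal score caches collapse to the empty DAG
  through the tie-break.

# Problem sizes used by the test suite

The shipped tests run the recovery experiment at the default cohort sizes
(200 replicates each of n = 2522 and n = 1029), the structure-recovery
experiment at 25 replicates of the person-period-encoded NHANES-like
configuration, interval-coverage at 800 replicates, the type-I-error
calibrations of the log-rank and Schoenfeld tests at 1000 null replicates,
and the moment checks at cohorts of 10⁵. These sizes were chosen so the
full suite completes on a single CPU in minutes while leaving the
Monte-Carlo error of each check well below the tolerance it asserts.

# Known limitations

* Node equations are estimated independently; no joint (full-information)
  SEM estimation, latent variables, or missing-data machinery.
* Structure search is exact but exponential in the node count; beyond
  roughly 20 nodes memory becomes the binding constraint.
* The person-period independence caveat above applies to the learned
  structures; bootstrap arc-confidence averaging is out of scope.
* Survey variance uses weights + PSU clustering, not full stratified
  linearization; cause-specific mortality and time-varying covariates are
  not modelled.
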