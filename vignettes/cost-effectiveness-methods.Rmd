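---
title: "Within-trial cost-effectiveness of PlGF testing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-trial cost-effectiveness of PlGF testing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Placental growth factor (PlGF) testing helps triage women presenting with
suspected pre-eclampsia between 20 and 37 weeks' gestation.  A revealed PlGF
result (normal > 100 pg/ml, low 12–100 pg/ml, very low < 12 pg/ml), combined
with a management algorithm, lets clinicians step down surveillance for
low-risk women and step it up for high-risk women.  The economic question is
whether revealed testing saves money for the NHS within the pregnancy
episode, and at what price per test the saving disappears.

`plgfcea` implements the within-trial evaluation pipeline for a
stepped-wedge cluster-randomised comparison of revealed testing against
usual care, from an NHS cost perspective, with maternal adverse events
avoided (not QALYs) as the effectiveness outcome:

1. a synthetic trial generator (`build_design()`, `simulate_trial()`),
2. per-category resource-use models (`select_resource_model()`,
   `adjusted_means()`),
3. weighted unit costing (`weighted_unit_cost()`, `cost_profile()`),
4. a probabilistic Monte Carlo cost model (`run_psa()`), and
5. reporting and national extrapolation (`render_outputs()`,
   `scale_to_population()`).

# The stepped-wedge generator

`build_design(n_clusters, n_steps)` indexes 6-week periods `0 ..
n_steps - 1`.  All clusters begin under usual care; at each step one
randomly ordered cluster crosses over, so the design needs
`n_steps >= n_clusters + 1` for a final all-intervention period.  Cluster
enrolment weights default to a 3000–9000 deliveries/year ramp, mimicking
units of varying size.

Each woman is allocated a (centre, step) cell, her arm following from the
design, and a subgroup from the nine PlGF × final-diagnosis cells.  The
defaults use the trial's enrolment (434 usual care, 571 revealed) and its
marginal PlGF proportions (38.2% / 38.3% / 23.5%).  The diagnosis split
within each band is **synthetic** — the source material reports it only
graphically — and is chosen so that normal outcomes dominate when PlGF is
normal and pre-eclampsia dominates when PlGF is very low (70/22/8%,
40/35/25% and 10/25/65% across the three bands).

## Resource use

Each of seven resource categories (outpatient attendances; antenatal,
labour-ward, postnatal and maternal ICU/HDU bed days; infant ICU/HDU and
SCBU days) follows a two-part (hurdle) process per woman *i* in centre *c*
at step *t*:

* use: $\Pr(Y_i > 0) = \operatorname{logit}^{-1}(\operatorname{logit}(p) + u_c + \beta_t t)$,
* quantity given use: zero-truncated negative binomial with baseline
  conditional mean $\mu^+$ and dispersion $k$ ($k = \infty$ recovers the
  truncated Poisson), with the same $u_c + \beta_t t$ shift applied on the
  log scale of the parent (untruncated) mean.

The shared centre intercept $u_c \sim N(0, \sigma_c^2)$ and the linear
secular trend mirror the adjustment terms of the analysis model; we chose a
single shared intercept across both parts because the analysis model's
random-effect structure is otherwise underdetermined.  Defaults
$\sigma_c = 0.3$, $\beta_t = 0.005$ per step are realistic mild values for
between-maternity-unit practice variation and secular drift.

$\mu^+$ is parameterised as the *conditional* mean of the positive draw, so
the closed-form hurdle identity $E[Y] = p\,\mu^+$ holds exactly at baseline
— this is what the generator's calibration tests check.  Because the
positive support is $\{1, 2, \dots\}$, a conditional mean must exceed 1;
the validator enforces $\mu^+ > 1$ wherever $p > 0$.  Internally the parent
mean is recovered from $(\mu^+, k)$ by `uniroot` on the monotone
conditional-mean map, and the centre/time shifts act on the parent log
scale so the fitted truncated-NB GLMM is correctly specified.

Per-category baseline values of $(p, \mu^+, k)$ by subgroup and arm are
synthetic, scaled so severity (diagnosis) and risk band (PlGF) raise both
admission probability and length of stay, with the intervention reducing
outpatient surveillance in every subgroup and redirecting inpatient use
toward high-risk women.  Neonatal ICU/HDU use is structurally zero for the
very-low-PlGF/normal-outcome subgroup, which exercises the fixed-zero path
the published cost tables show for that cell.  Severe maternal adverse
events are Bernoulli at the arm's observed rate (24/447 vs 22/573).
Delivery modes are drawn per arm from mixes solved so that, under the
packaged unit costs, the mixture means equal the reported arm-level
delivery costs (GBP 3,318 usual / 3,372 revealed).

What the generator does *not* emulate: gestational-age dynamics, repeat
presentations and repeat testing, correlation between resource categories
within a woman beyond the shared centre effect, and any perinatal outcome
other than neonatal unit use.  Passing tests therefore demonstrate that the
pipeline recovers the structure it assumes, not that real trial data meet
those assumptions.

# Resource-use models

For every category the same fixed covariate set is used: one indicator per
subgroup × arm combination (reference `gt100:normal`/usual — so each of the
9 × 2 cells has its own adjusted mean, which the per-cell cost tables
require), the step index centred at its sample mean, and a centre random
intercept.  Four candidate families are compared by AIC: two-part truncated
negative binomial, two-part truncated Poisson, and single-part negative
binomial and Poisson GLMMs.  Exact AIC ties go to the model with fewer
parameters.

Engines: the binomial hurdle part uses `lme4::glmer` with adaptive
Gauss–Hermite quadrature (7 nodes by default; the likelihood has a single
scalar random effect, where AGQ is accurate and cheap).  The truncated and
plain count parts and the gamma delivery model use `glmmTMB`, whose Laplace
approximation is the only available likelihood for truncated count families
with random effects; with 11 clusters of ~90 women each the Laplace error
is negligible relative to sampling noise.  The two part-likelihoods
factorise, so the two-part log-likelihood, degrees of freedom and AIC are
sums over parts.

## Degenerate cells and convergence

Subgroup × arm combinations whose hurdle indicator is all-zero (or whose
records are absent) are held out of estimation and emitted as fixed zeros
with zero variance; all-one combinations get $\hat p = 1$ with zero part-1
variance.  This prevents complete separation from wrecking the optimiser
while keeping every 9 × 2 cell in the output — nothing is silently
dropped.  A fit counts as converged only if it yields finite coefficients
and standard errors below 10 on the link scale and (for `glmmTMB`) a
positive-definite Hessian; effectively unidentified parameters from
near-empty cells therefore register as non-convergence.  If no candidate
converges the category escalates to the fallback: plain logistic regression
for admission and linear regression for length of stay among the admitted,
combined as $\hat p \times \widehat{\text{days}}$ — the same rule the
original analysis applied to neonatal ICU/HDU.  Convergence tolerances are
the engines' defaults (relative deviance change ~1e-8).

## Adjusted means and standard errors

Adjusted means are predicted at the centre random effect's centre (0) and,
by default, with the time covariate fixed at its sample mean
(`standardise = "conditional"`); a `"marginal"` mode averages predictions
over the observed secular times instead.  The conditional mode is the
default because the prediction time point of the original analysis is
unstated and the conditional prediction is the cleaner estimand.

Standard errors use the delta method with a second-order curvature
correction, $\operatorname{Var}[g(\hat\eta)] \approx g'(\eta)^2 v +
\tfrac12 g''(\eta)^2 v^2$, and the exact product-variance formula for the
two independent parts.  The first-order delta method visibly understates
the spread of the convex truncated-mean transform at realistic cell sizes
(by 10–30% for cells with link-scale SEs around 0.1–0.2); the corrected
version agrees with a coefficient-resampling check to within a few percent.
Uncertainty in the dispersion $k$ and in $\sigma_c$ is not propagated into
cell SEs.  `bootstrap_adjusted_se()` provides the independent resampling
cross-check used by the tests.

# Costing

Unit costs follow the NHS-reference-cost convention: where several
Healthcare Resource Groups map to one activity, the applied cost is the
activity-weighted mean $\sum c_i a_i / \sum a_i$
(`weighted_unit_cost()`, and `read_unit_costs()` collapses HRG-level CSVs
automatically).  Both neonatal categories share a single weighted cost per
bed day.  The packaged table is **synthetic with realistic magnitudes**
(e.g. GBP 120 per outpatient attendance, GBP 450 per antenatal bed day,
GBP 1,000 per neonatal bed day, 2016/17 prices); the original schedule is
not in the public main text, so no packaged number claims to be it.
Delivery is costed per mode (GBP 2,100–5,000) but reported separately and
excluded from the Monte Carlo totals: bed-day reference costs already
embed delivery activity, and adding it would double-count.  The PlGF test
defaults to GBP 70 with a GBP 50–200 sensitivity sweep.

# The probabilistic model

`run_psa()` samples every adjusted mean from its tagged distribution —
normal truncated at zero by default, degenerate for fixed cells, with a
moment-matched beta available for probability-type cells — multiplies by
unit costs, and forms per-cell differences (revealed − usual; **saving is
negative**).  Subgroup weights (observed cell proportions, pooled across
arms by default; a per-arm mode exists because the original description is
ambiguous) convert cell differences to per-woman values.  Per iteration,
maternal + infant = combined exactly, and the weighted total is exactly the
weight-sum of cell values — these identities are asserted to 1e-9 GBP in
the tests.

Adverse events use the mean-preserving parameterisation
$p_a \sim \text{Beta}(r_a, n_a - r_a)$, whose mean is the observed rate
$r_a/n_a$; with the trial's counts the mean difference is
$24/447 - 22/573 = 0.0153$, i.e. 15.3 (printed 15) events avoided per
1000 women.  The add-one rule would give 15.7 → 16, which is why the
mean-preserving rule is the default; a zero-event arm falls back to
Beta(r+½, n−r+½) with a note.  The CEAC evaluates, per willingness-to-pay
λ (GBP 0–50,000 in 1,000 steps), the fraction of iterations with
$\lambda \,\Delta E_{1000} - \Delta C_{1000} > 0$, where the cost per 1000
women includes the test price.  "Percentage cost-saving" uses strict
inequality: a zero difference is not a saving.  The default 5,000
iterations give Monte-Carlo SEs below 0.008 on any probability and ~0.19
on the events-avoided mean.

# Reporting and national scaling

`render_outputs()` writes the per-cell cost tables (three statistic rows —
actual, weighted, percent cost-saving — by nine subgroup columns plus a
total), the price sweep, the CEAC and run metadata; values are stored as
raw floats and rounded only for display.  `scale_to_population()` rounds
eligible women to the nearest integer *before* multiplying:
646,794 births × 10% suspected × 30% preterm = 19,403.8 → 19,404 women,
× GBP 149 = GBP 2,891,196 per year.  (A prose figure of "approximately
38,800 women per year" circulates for this calculation but is
arithmetically inconsistent with both the product and the printed annual
saving; the package follows the consistent chain and takes no position on
the discrepancy.)

# Problem sizes used by the test-suite

Simulation-based checks pick sizes where the asymptotics they test are
informative: generator calibration at n = 100,000 with 3σ Monte-Carlo
bands; parameter recovery over 100 replicate fits at n = 5,000
(σ_c = 0.3, 50 equal-weight centres — with only ~10 clusters, z-based Wald
intervals on between-centre-dominated terms undercover and would need
t-style small-sample corrections, a property of the design rather than the
estimator) requiring ≥ 90% per-coefficient coverage of 95% Wald intervals;
model-selection consistency at n = 2,000 per replicate;
delta-vs-resampling SE agreement at n = 4,000 with 15% relative tolerance;
the full synthetic pipeline at the trial's own n = 1,005.  Monte-Carlo
stability is checked as a maximum deviation below 0.02 across ten seeds at
5,000 iterations.

# Known limitations

* The exact per-subgroup means, SEs and sampling distributions behind the
  published tables are supplementary material of the trial and are not
  redistributed; the published summary figures are reproduced only when
  those inputs are supplied (see the README).  The packaged defaults are a
  calibrated synthetic stand-in.
* SEs omit dispersion and random-effect-variance uncertainty.
* The generator draws resource categories independently given subgroup,
  arm, centre and step; real resource use is more strongly correlated
  within a woman.
* No QALYs, no discounting (within-pregnancy horizon), no costs beyond
  primary postnatal discharge, and no repeat-testing economics.
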