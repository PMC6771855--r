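# plgfcea

Within-trial cost-effectiveness analysis of placental growth factor (PlGF)
testing for suspected pre-eclampsia.

## The problem

Around 10% of pregnant women are investigated for suspected pre-eclampsia.
A revealed PlGF result (normal > 100, low 12–100, very low < 12 pg/ml) used
alongside a management algorithm lets maternity services step surveillance
down for low-risk women and up for high-risk women.  In a stepped-wedge
cluster-randomised comparison (11 maternity units crossing from usual care
to revealed testing at 6-week intervals), this changed how resources were
used and roughly halved severe maternal adverse events (5.4% → 3.8%).  The
question for the NHS: does revealed testing save money per woman tested,
and how does the answer move with the price of the test?

`plgfcea` implements the full evaluation pipeline as a tested R package,
usable with real trial records or with its own synthetic generator:

* **Synthetic stepped-wedge trial data** — `build_design()`,
  `simulate_trial()`: centre random effects, a linear secular trend,
  nine PlGF × diagnosis subgroups, zero-inflated over-dispersed resource
  use, binomial adverse events.
* **Resource-use models** — per category, AIC selection among two-part
  (hurdle) truncated-NB/Poisson and single-part NB/Poisson mixed models
  (`select_resource_model()`), with a logistic + linear fallback when
  nothing converges; adjusted means with curvature-corrected delta-method
  SEs (`adjusted_means()`).  The two-part model for a count Y is

  P(Y > 0) = logit⁻¹(xβ₁ + u_c),  Y | Y > 0 ~ truncated-NB(exp(xβ₂ + u_c), k),

  with centre intercept u_c ~ N(0, σ_c²) and adjusted mean
  E[Y] = p̂ × E[Y | Y > 0].
* **Costing** — activity-weighted NHS-reference-style unit costs
  (`weighted_unit_cost()`, `read_unit_costs()`); one weighted cost per
  neonatal bed day; delivery costed per mode but excluded from simulation
  totals to avoid double counting.
* **Probabilistic model** — `run_psa()`: 5,000-iteration Monte Carlo over
  the adjusted means (normal truncated at 0), subgroup-weighted per-woman
  cost differences (saving is negative), Beta(r, n−r) adverse-event draws,
  cost-saving probabilities with/without the £70 test, a £50–£200 price
  sweep and the cost-effectiveness acceptability curve (CEAC), i.e.
  P(λ·ΔE₁₀₀₀ − ΔC₁₀₀₀ > 0) over willingness-to-pay λ.
* **Reporting** — publication-shaped CSV tables, CEAC, run metadata
  (`render_outputs()`), national extrapolation (`scale_to_population()`),
  and a CLI (`inst/cli/plgf-cea`, subcommands `simulate | fit | psa |
  report | all`).

## Worked example

```r
library(plgfcea)

design <- build_design(n_clusters = 11, n_steps = 12, seed = 1)
trial  <- simulate_trial(design, default_generator_params(), seed = 1)
fitted <- fit_all_resources(trial)          # ~40 s: 7 categories x 4 candidates
psa    <- run_psa(fitted$adjusted_means, default_unit_costs(),
                  weights = cell_weights(trial), seed = 2)
print(psa)
```

```
Probabilistic cost model: 5000 iterations, seed 2 (2016/17 GBP (synthetic))
  Weighted per-woman cost difference (PlGF - usual), before test:
    maternal     -720 GBP  (100.0% of iterations cost-saving)
    infant         36 GBP  (44.9% cost-saving)
    combined     -684 GBP  (95.8% cost-saving)
  Including PlGF test at 70 GBP: combined     -614 GBP (93.8% cost-saving)
  Maternal adverse events avoided per 1000 women: 15.5 (reported 16)
  Dominant (cheaper and more effective): TRUE
```

Reading it: negative weighted differences are savings per woman tested.  On
this synthetic dataset revealed testing saves ~£720/woman on maternal care
(driven by outpatient attendances), costs slightly more on neonatal care,
and remains cost-saving in ~94% of iterations after paying £70 per test,
while preventing ~15 maternal adverse events per 1000 women — testing
*dominates* usual care (cheaper and more effective).  The cell-level
tables, test-price sweep and CEAC are in `summary(psa)` and `plot(psa)`;
`scale_to_population(646794, 0.10, 0.30, saving)` converts a per-woman
saving to an annual national figure (e.g. £149/woman → 19,404 women and
£2,891,196/year).

The synthetic defaults are calibrated to the trial's design (11 clusters,
434/571 women by arm, PlGF marginals 38.2/38.3/23.5%, adverse events
24/447 vs 22/573, delivery costs £3,318/£3,372), but the per-subgroup
resource-use levels and the packaged unit-cost table are synthetic, so the
cost magnitudes above are illustrative, not the published ones.

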