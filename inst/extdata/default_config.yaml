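# Default run configuration for the within-trial cost-effectiveness pipeline.
# Generator parameters not listed here come from default_generator_params().
seed: 20160101
n_clusters: 11
n_steps: 12
n_iterations: 5000
test_cost: 70
test_cost_sweep: [50, 100, 150, 200]
wtp_max: 50000
wtp_step: 1000
weights_mode: pooled        # pooled | per_arm
standardise: conditional    # conditional | marginal
sigma_c: 0.3                # centre random-intercept SD (link scale)
beta_t: 0.005               # secular trend per 6-week step (link scale)
nAGQ: 7                     # quadrature points, binomial hurdle part
adverse:
  events_usual: 24
  n_usual: 447
  events_plgf: 22
  n_plgf: 573
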