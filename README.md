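# socialrl

Simulation and computational modelling of social reinforcement learning,
for researchers studying how people update social expectancies from
rewarding and punishing feedback — e.g. in computational psychiatry
studies of social anxiety and of interventions (such as interpretation
bias modification) that might change social learning.

The package covers two paradigms end to end:

* **Social probabilistic selection task** — six neutral faces with
  complementary reward contingencies (80/20, 70/30, 60/40) are learned by
  trial and error during training (chosen faces turn happy or angry), then
  recombined into all 15 pairs in a no-feedback testing phase. Learning is
  modelled by Q-learning with separate reward and punishment learning
  rates,

  Q ← Q + α·(o − Q),  α = α_reward if o − Q > 0, else α_punish,

  with softmax choice P(a) = 1 / (1 + exp(−β·(Q_a − Q_b))). The nested
  single-rate model (α_reward = α_punish) is compared against the dual
  model with LOOIC (Pareto-smoothed importance-sampling leave-one-out;
  AIC fallback for point fits). Testing-phase behaviour is summarized as
  choose-reward and avoid-punish accuracy.

* **Speech-expectancies task** — 20 self-rated statements about an
  upcoming speech (10 good-performance, 10 poor-performance items, 0–100
  scale) receive false feedback equal to the self-rating plus a uniform
  random integer in [−50, 50], clipped to [0, 100]. Each item yields one
  single-shot **update weight** w = (post − pre)/(feedback − pre),
  aggregated per subject under four schemes (overall, by prediction-error
  valence, by item valence, or both), with Cook's-style case-deletion
  screening of influential observations.

A synthetic-cohort generator (`simulate_study()`) produces complete
studies — 51 + 55 subjects in two arms, two sessions of the selection
task played by Q-learning agents with known parameters, session-2 speech
records from known update weights — so that estimation, model comparison
and the mixed-effects inference stage (lme4/lmerTest/emmeans:
session × condition × valence models with a participant random intercept,
Tukey-adjusted marginal-mean contrasts, Cohen's d standardized by the
total random SD) can all be verified by parameter recovery.

## Worked example

```r
library(socialrl)

# a full synthetic study with a planted session-by-condition shift of
# -0.04 on the true learning rates
cfg <- study_config(
  task = list(rates = list(effects = list(session_condition = -0.04))),
  seed = 42
)
study <- simulate_study(cfg, seed = 42)
#> <srl_study> 106 subjects (51 CBM-I / 55 EMA-only); 63600 trials; 2120 speech items

fit <- fit_rl(study$trials, model = "dual", seed = 42)
glance(fit)
#>   model method n_subject_sessions n_trials   nll n_parameters   aic
#> 1 dual  mle                   212    50880 20827.          636 42925.

rates <- rates_from_fit(fit)
m <- fit_lmm(rates,
             learning_rate ~ session * condition * pe_valence + (1 | subject_id))
tidy(m)[c(1, 5), c("term", "estimate", "std.error", "df", "p.value")]
#>   term                    estimate std.error    df  p.value
#> 1 (Intercept)              0.228     0.00859  104. 4.39e-48
#> 2 session2:conditionCBM-I  0.00111   0.0238   312. 9.63e- 1

effect_size(emm_contrasts(m, "session", by = "condition"), m)
#>   contrast            condition estimate std.error    df t.ratio p.value cohens_d
#> 1 session1 - session2 EMA-only  -0.00953    0.0165  312.  -0.578   0.564  -0.0691
#> 2 session1 - session2 CBM-I     -0.0106     0.0171  312.  -0.621   0.535  -0.0771
```

Reading the output: the intercept (0.228) is the grand-mean learning rate
under ±1/2 effects coding, matching the generator's mean of 0.23. The
planted −0.04 interaction on the *true* rates is estimated at 0.001 ±
0.024 from per-subject maximum-likelihood rates — consistent with the
truth within 2 SE, but illustrating how estimator noise at 240 trials per
session attenuates group effects; `fit_hierarchical()` recovers individual
rates with roughly half the error (see the methods vignette). The contrast
table reports Tukey-family session contrasts within each condition on the
rate scale with Cohen's d = estimate / √(τ₀₀ + σ²).

Ground truth for every simulated quantity is in `study$truth`, so the same
pipeline doubles as a recovery test bench. Plot helpers
(`plot_learning_rates()`, `plot_accuracy()`, `plot_update_weights()`,
`autoplot()` on fits) draw the standard figures.

A thin command-line wrapper is included:

```sh
Rscript exec/socialrl.R simulate --seed 17 --out-dir runs/a
Rscript exec/socialrl.R fit-rl --trials runs/a/trials.csv --model dual --out fits.json
Rscript exec/socialrl.R compare-models --trials runs/a/trials.csv --out loo_table.csv
Rscript exec/socialrl.R speech-weights --speech runs/a/speech.csv \
  --scheme pe_valence --screen-outliers --out weights.csv
Rscript exec/socialrl.R infer --trials runs/a/trials.csv --speech runs/a/speech.csv --out report.md
```

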