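---
title: "Models and methods behind socialrl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind socialrl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialrl)
```

## The two paradigms

`socialrl` implements the computational pipeline for two social
reinforcement-learning tasks and the statistical stage that sits on top of
them.

**Social probabilistic selection task.** Six neutral faces carry fixed,
complementary reward contingencies. During training the faces appear only
in three pairs — 80/20, 70/30 and 60/40 — and the chosen face turns happy
with its assigned probability, angry otherwise. In a later testing phase
the faces are recombined into all 15 possible pairs and no feedback is
delivered. Face identifiers in this package name their contingency
(`"p80"` … `"p20"`), which makes trial tables self-describing and needs no
separate lookup.

**Speech-expectancies task.** Participants rate 20 statements about an
upcoming stressful speech — 10 describing good performance and 10
describing poor performance — on a 0–100 scale, then receive false
"judge" feedback computed as their own rating plus a uniform random
integer in \[-50, 50\], clipped to the scale, and finally re-rate each
item. Each item therefore provides exactly one observed belief update.

## The Q-learning model

Expected values $Q$ of each face start at 0.5 (the indifference point with
outcomes coded happy = 1, angry = 0) and are updated after every training
outcome for the chosen face only:

$$Q \leftarrow Q + \alpha \,(o - Q), \qquad
\alpha = \begin{cases}
\alpha_{\text{reward}} & o - Q > 0\\
\alpha_{\text{punish}} & o - Q < 0
\end{cases}$$

The dual-learning-rate model separates the weight given to positive and
negative prediction errors; the single-rate model is the nested constraint
$\alpha_{\text{reward}} = \alpha_{\text{punish}}$. Choices follow a
softmax (logistic) rule with inverse temperature $\beta$:
$P(a) = 1/(1 + e^{-\beta (Q_a - Q_b)})$.

Numerical conventions worth stating explicitly:

* With outcomes in \{0, 1\} and $Q$ in the open interval, a zero
  prediction error is unreachable; at the boundary ($Q$ exactly 0 or 1)
  the outcome's valence decides the rate (reward rate for happy,
  punishment rate for angry). This removes an undefined branch.
* The update keeps $Q$ in \[0, 1\] for any trial sequence, so values stay
  interpretable as reward probabilities.
* $\beta$ is estimated on the log scale with a cap (default 20): beyond
  that, choice is effectively deterministic and the likelihood is flat in
  $\beta$.
* Learning rates are estimated on the logit scale.

### Estimation

`fit_rl()` is the deterministic default: per-subject-session bounded
maximum likelihood (L-BFGS-B on the transformed scales, best of five
seeded restarts), with a likelihood-ratio diagnostic against the
random-choice model ($\beta = 0$, giving $n\log 2$) that flags subjects
whose data carry no evidence of value-guided choice.

`fit_hierarchical()` partially pools all subject-sessions through group
location/scale priors on the transformed scales — Normal(0, 1) means and
half-Normal(1) scales, standard weakly informative choices. Sampling is by
adaptive random-walk Metropolis within Gibbs. We use the *centered*
parameterization with a conjugate normal draw for the group means and a
cheap scalar Metropolis step for the group scales: with a gradient-free
sampler this avoids recomputing every subject's trial likelihood at each
group-parameter proposal, which a non-centered parameterization would
force. Convergence is monitored by split R-hat on the group means and by
acceptance rates; a suspect chain is carried as a warning in the result,
never silenced. Posterior draws of the pointwise log-likelihoods are
retained for model comparison.

The two sessions are fit independently per subject (no cross-session
pooling) because the downstream mixed model treats session as a repeated
measure on the estimated rates.

### What recovery can and cannot achieve

The test suite runs a recovery study at the scale the pipeline targets:
100 agents, 240 training trials each, learning rates drawn uniformly from
\[0.1, 0.5\] and $\beta$ from \[2, 10\]. Median absolute error is about
0.05 per learning rate. Correlation between true and recovered rates is
about 0.75 for the punishment rate and about 0.67 for the reward rate.
The latter is not an estimator deficiency: an oracle posterior-mean
estimator supplied with the true generating distribution attains the same
correlation on the same cohort, so ~0.67–0.72 is the information ceiling
of 240 training trials for this parameter. Learning agents spend most of
training choosing the better faces, so reward prediction errors shrink as
values converge while punishing outcomes keep producing large errors —
punishment rates are simply better identified in this design.

## Model comparison

`loo_psis()` computes the expected log pointwise predictive density by
Pareto-smoothed importance sampling over posterior draws: per observation,
the largest importance ratios are replaced by expected order statistics of
a generalized Pareto distribution fit to the tail (an empirical-Bayes
profile-likelihood fit), truncated at the raw maximum. LOOIC is
$-2\,\mathrm{elpd}$; per-observation Pareto tail-shape values are reported
as reliability diagnostics. The pointwise unit is the trial, matching the
likelihood factorization; grouping by condition and session is exposed in
`compare_fits()` because the comparison is reported per group. For MLE
fits there are no posterior draws, so `compare_fits()` falls back to AIC
and labels the criterion accordingly. Observations whose log-likelihood is
constant across draws (e.g. a first trial, whose choice probability is 0.5
for any parameters) contribute their exact value with a zero tail shape.

## Testing-phase metrics

Accuracy is defined only for test pairs that contain the most rewarding
face (`p80`) or the most punishing face (`p20`) together with an
intermediate face (70/60/40/30): these are the choose-reward and
avoid-punish trial types. The `p80`-vs-`p20` pair and the six
intermediate-only pairs belong to neither type and are excluded. A trial
is correct when the face with the higher reward probability was chosen.
Of the 15 recombined pairs, 4 are choose-reward, 4 avoid-punish and 7
excluded. Trial-level binary records feed a logistic mixed model; per-cell
proportions are also provided.

## Update weights

The single-shot analogue of a learning rate for the speech task is
$w = (\text{post} - \text{pre}) / (\text{feedback} - \text{pre})$ — the
fraction of the distance toward the feedback that the expectancy moved.
Items where feedback equals the pre-rating have an undefined weight (zero
prediction error) and are excluded with a recorded reason; under the
uniform feedback rule this affects roughly 1 in 101 items. Weights are
deliberately *not* clipped: overshooting ($w > 1$) and counter-updating
($w < 0$) are real phenomena and are exactly what influence screening is
there to catch.

Prediction-error valence reverses for poor-performance items: on "I will
appear to be sweating", feedback *below* one's own rating is good news.

Weights are aggregated per subject as the arithmetic mean of item weights
within a category, under four schemes: one overall weight, two weights by
PE valence, two by item valence, or four for each PE-by-item-valence cell.
The mean is the simplest estimator consistent with one update per item; a
regression-through-the-origin alternative (slope of post − pre on
feedback − pre) is available behind the `estimator` argument.

## Outlier screening

"Influential" observations are identified by case deletion on the mixed
model of interest: observation $i$'s influence is the mean squared
standardized change in the fixed effects,
$D_i = \tfrac1p \sum_j \left((\hat\beta_j - \hat\beta_{j(-i)}) / SE_j\right)^2$,
a Cook's-distance analogue, with the conventional threshold $4/n$ and a
single removal pass. Both metric and threshold are exposed as arguments.
On clean cohorts this rule typically removes a few percent of
observations, which matches the removal counts reported for this kind of
analysis.

## The inference stage

* **Learning rates:** linear mixed model, learning rate ~ session ×
  condition × PE valence with a random intercept per participant, fit by
  REML with Satterthwaite degrees of freedom. Rates are analyzed on the
  raw \[0, 1\] scale.
* **Accuracy:** trial-level binomial GLMM (logit link), session ×
  condition × trial type, random intercept per participant; fixed effects
  reported as odds ratios, with the latent-scale residual fixed at
  $\pi^2/3$ for ICC and variance-explained summaries.
* **Update weights:** linear mixed models per aggregation scheme,
  category × condition.

All two-level factors use ±1/2 effects coding with fixed orientations
(session 2, CBM-I, positive PE, poor items and choose-reward trials on the
positive side), so the intercept is the grand mean and every coefficient
is a cell-mean difference. Marginal means and their Tukey-adjusted
pairwise contrasts come from `emmeans`; for logit models, contrasts stay
on the logit scale. The standardized effect size divides a contrast by the
model's total random SD, $\sqrt{\tau_{00} + \sigma^2}$ — with variance
components near $\sigma^2 = 0.01$ and $\tau_{00} = 0$, a 0.03 difference
in learning rate maps to $d \approx 0.3$; this convention is used
throughout and stated wherever d is reported. Variance explained is reported as marginal and
conditional $R^2$ in the Nakagawa sense.

## The synthetic cohort

Because no participant-level dataset is deposited, the package generates
cohorts with known ground truth; every default below is the condition
under which the pipeline's properties are verified.

* **Design:** 51 subjects in the CBM-I arm and 55 in the EMA-only arm,
  both lab sessions for everyone; speech records exist only at session 2
  (feedback was only ethical to deliver on the day of debriefing).
* **Selection task:** 20 presentations per training pair per block × 4
  blocks = 240 training trials, and all 15 recombined pairs × 4
  repetitions = 60 test trials, per session. Published implementations of
  this paradigm vary in their exact counts; these defaults match the
  scale typical of the task and give estimation enough trials, and both
  are configurable. Left/right placement is randomized but not modeled.
* **Agent parameters:** true learning rates follow the additive model the
  inference stage targets — grand mean 0.23, between-subject SD 0.04,
  cell SD 0.09, clipped to \[0.02, 0.98\] — with all session/condition/
  valence effects zero by default (the null scenario); non-null scenarios
  are supplied as configured effect sizes, never hard-coded. Inverse
  temperatures are log-normal around 5 (SD 0.25 on the log scale).
* **Speech task:** pre-ratings uniform on 20–80 so that clipping is rare
  and the noiseless recovery property stays exercisable; post-rating noise
  SD of 8 rating points, applied before clipping; true update weights per
  condition built additively from a base weight plus PE-valence and
  item-valence effects. The defaults give the EMA-only arm biased updating
  (more from positive PEs, more on poor items) and the CBM-I arm balanced
  updating — the qualitative pattern the method is designed to resolve.
* **Reproducibility:** every randomized operation takes an explicit seed,
  and cohort generation derives independent per-subject substreams from
  the master seed, so any subject can be regenerated in isolation and
  identical seeds give byte-identical tables.

What the generator deliberately does not emulate: reaction times, trial
timing, practice or fatigue effects, stimulus-identity effects (faces are
exchangeable given their contingency), and any dependence of speech
updating on selection-task parameters within subject. Passing tests on
synthetic cohorts therefore demonstrate that the estimators recover the
generative process they assume — not that real participants follow that
process.

## Problem sizes used in the checks

The package's own verification uses: 100,000 outcome draws per face for
contingency fidelity; exhaustive enumeration of all 101 × 101 feedback
cases; 20 random 10-trial fixtures against a straight-line replay oracle
(agreement to 1e-10); the 100-agent × 240-trial recovery study described
above; 200 null cohorts of n = 30 for type-I calibration of the three-way
interaction (nominal 5% test observed within \[1%, 10%\]); and an
8-observation conjugate-normal toy where PSIS-LOO is compared with exact
refit leave-one-out (agreement within 0.1). These sizes are the package's
reference conditions and are stated here so that reruns scale them
knowingly.

## Known limitations

* The hierarchical sampler is a random-walk method: it needs thousands of
  sweeps where a gradient-based sampler would need hundreds, and its
  effective sample size per sweep is modest. R-hat and acceptance-rate
  diagnostics are attached to every fit.
* MLE estimates of learning rates at 240 trials are noisy (see the
  recovery discussion); group-level analyses of MLE rates inherit that
  attenuation. The hierarchical fit is preferable whenever runtime
  allows.
* The update-weight ratio estimator is heavy-tailed when feedback lands
  close to the pre-rating; the mean aggregate is kept for transparency,
  with screening expected to handle the resulting extremes, and the
  regression estimator available as a robustness check.
* AIC and LOOIC answer slightly different questions; the AIC fallback for
  point fits is labeled so the two are never silently mixed.
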