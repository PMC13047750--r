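---
title: "Modelling play-or-pass Iowa Gambling Task development: methods and design choices"
author: "poporl package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling play-or-pass Iowa Gambling Task development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Reward learning is thought to be refined across adolescence, and blunted
reward processing is a candidate mechanism for the familial transmission of
depression. The play-or-pass variant of the Iowa Gambling Task (PoP-IGT)
offers one deck per trial and a play/pass decision, dissociating reward
approach (plays on net-gain decks) from punishment avoidance (passes on
net-loss decks). `poporl` implements the full analysis chain for studying how
performance on this task changes with age: a task simulator, the four
parameter PoP-ORL reinforcement-learning model with hierarchical estimation,
traditional proportion-play scoring, correlation-based secondary analyses,
and multilevel growth models with a depression-risk moderator — plus a
synthetic accelerated-longitudinal cohort generator so every stage can be
validated end-to-end against known ground truth.

## The task environment

Decks A and B lose money on net, C and D gain. Payout magnitudes follow the
classic Iowa Gambling Task block structure: A and B pay +100 per play and
lose 250 net per 10-play block (A via five graded losses from −150 to −350,
B via a single −1250), C and D pay +50 and gain 250 net per block (C via
five −50 losses, so some plays net to exactly $0; D via one −250). Defaults
are 120 trials, 30 presentations per deck, a starting bank of 2000, and a
4-second response window; all are configurable (`task_config()`). The deck
presentation order and each deck's outcome sequence are fixed across
participants; the shipped order was generated once from a fixed build seed
and is stored in `inst/extdata/task_default.yaml`. Two task versions map
physical deck positions to payout structures differently;
`recode_to_canonical()` restores canonical labels, and every canonical-deck
statistic is invariant to version. Trials that time out are recorded as
passes with a timeout flag. Trials are 1-based throughout, in memory and in
files.

## The PoP-ORL model

Choices are Bernoulli in the logistic of a value signal. For deck $j$ on
trial $t$,

$$Y_{jt} \sim \mathrm{Bernoulli}\!\left(\frac{1}{1 + e^{-V_{jt}}}\right),
\qquad V_{jt} = EV_{jt} + EF_{jt}\,\beta_f + \beta_b,$$

with the value of passing fixed at 0. $EV$ tracks outcome magnitude and $EF$
outcome frequency; both start at 0 and update only on plays, by
Rescorla–Wagner delta rules with valence-gated learning rates:

$$EV_{j} \mathrel{+}= A\,( x/100 - EV_j), \qquad
  EF_{j} \mathrel{+}= A\,(\operatorname{sign}(x) - EF_j),$$

where $A = A_{rew}$ when the outcome $x \ge 0$ and $A = A_{pun}$ otherwise.
The published model summary fixes the choice rule and value signal but not
the update equations; the delta rules above are the parent
outcome-representation-learning (ORL) model's structure with the decay and
perseverance components removed, which is what reduces the model to four free
parameters. Three further conventions are housed in `model_config()`:

* `outcome_scale = 100` — raw currency is divided by 100 before $EV$
  updates, keeping $EV$ on roughly the unit scale of $EF$;
* `fictive_updating = TRUE`, `fictive_attenuation = 3` — the three
  unpresented decks' $EF$ move toward $-\operatorname{sign}(x)/3$ at the
  opposite-valence learning rate, the parent ORL frequency mechanism; a flag
  disables it and the test suite exercises both settings;
* $0 outcomes count as gains ($x \ge 0$ selects $A_{rew}$), and
  $\operatorname{sign}(0) = 0$, so a zero outcome nudges $EF$ toward zero.

The likelihood uses the state *before* each trial's update (prediction
precedes outcome) and is computed by a compiled trial loop in a numerically
stable log-logistic form; the test suite pins it to a literal R reference
loop at 1e-10.

## Hierarchical estimation

The model is fit separately at each assessment wave. The default backend,
`map_eb`, is penalized-likelihood empirical Bayes: learning rates live on an
unconstrained scale through the standard-normal CDF link (the probit of the
rate), $\beta_f$ and $\beta_b$ are identity-linked, and subjects are normal
around group means. Subject-level MAP estimates (multi-start BFGS; starts at
the prior mean and ±0.5 prior SD, best penalized likelihood wins) alternate
with group moment updates until the group means move less than `tolerance`
(default 1e-3, cap 20 rounds). The group-variance update is the EM form —
squared deviations *plus* each subject's Laplace posterior variance from the
MAP Hessian. The naive moment update (variance of the point estimates alone)
demonstrably collapses the group SD toward zero here, over-shrinking until
recovery correlations degrade; the Laplace term is what keeps the estimated
group SD near the generating one. Initial group means are 0 (rates 0.5) and
initial SDs 1, except $\beta_f$ at 2. Rates are clipped to
$[10^{-6}, 1-10^{-6}]$ before the inverse-CDF transform. The estimator is
deterministic: the multi-start offsets are fixed rather than random, so
duplicated sessions provably receive identical estimates.

MAP-EB group means carry a small mode-versus-mean attenuation toward zero
relative to a full posterior (roughly 0.1–0.4 generating-SD units at
n = 80–100 in the shipped validation settings); correlations, shrinkage
ordering and downstream trajectory signs are unaffected, and the test suite
documents the attenuation bound it holds the estimator to. A full-MCMC
backend is a recognised configuration contract (`fit_config(backend =
"mcmc")`) but is not implemented in this build; requesting it errors
immediately rather than silently degrading.

Validation harnesses: `parameter_recovery()` simulates subjects from
configurable generator distributions, refits, and correlates true with
recovered parameters on the unconstrained scale — the scale on which
subjects are generated, modelled, and consumed by the growth stage.
`posterior_predictive_check()` re-simulates each subject at the estimate and
compares per-deck per-block play proportions with a 95% simulation interval.

Under the shipped conditions (120 trials, generator SDs 0.5/0.5/2/0.75 on
the unconstrained scale), recovery is about 0.7 for the reward learning
rate, 0.8 for the punishment learning rate and go bias, and 0.55–0.6 for the
frequency sensitivity. The last is an information limit of the play/pass
design at these settings: a sizable share of simulated subjects play nearly
every trial, and saturated choice probabilities leave $\beta_f$ only weakly
identified — with a flat prior its per-subject MLE correlates with truth at
only ~0.48, and shrinkage recovers most but not all of the gap.

## Traditional scoring

`compute_summary()` returns the proportion of plays on good decks and on bad
decks — each over that pair's presentations — and the net score, good minus
bad. Timeouts count as passes (in the denominator, not the numerator).
Pair-specific denominators match a pooled definition exactly at the default
balanced design. No high-timeout exclusion is applied by default; the
session logs carry the flags needed to impose one.

## Growth models

Each metric (net/good/bad proportion play; probit reward and punishment
learning rates; $\beta_f$; $\beta_b$) enters a random-intercept,
random-age-slope multilevel model, estimated by maximum likelihood — not
REML — so every nested likelihood-ratio test in the ladder is valid. Age is
centered at the fixed constant 10.98 years (the average baseline age of the
design this package emulates), never recomputed from the data, so
"baseline" effects are group contrasts at ~11 years. The ladder: model 1
(unconditional linear), model 2 (unconditional quadratic, kept only if the
LRT wins at $\alpha = .05$), model 3 (winner plus maternal-history main
effect and age interactions), model 4 (model 3 plus IQ, sex, administration
modality). Age-effect p-values for the four computational parameters are
Benjamini–Hochberg adjusted as one family. Conventions, each configurable or
at least explicit: IQ is centered at 100; sex is coded female = 1; onsite is
coded 1 for in-lab administration; fixed-effect t tests and CIs use residual
degrees of freedom $n_{obs} - n_{fixed}$; singular random-effect fits are
simplified (drop the intercept–slope correlation, then the random slope) and
the simplification is recorded; `pseudo_r2_total` is the squared correlation
between observed values and fitted values including random effects — a
common definition adopted because none is canonical, tested for determinism
rather than for matching any published table. Because the reference model
for the model-4 LRT is ambiguous when the quadratic wins, the ladder emits
the comparison against both the winning unconditional model and model 1.

## The synthetic cohort

`generate_cohort()` emulates an accelerated-longitudinal design: two
recruitment cohorts (baseline ages uniform on 9–10 and 12–13), five waves
0.75 years apart, exact wave counts 208/157/135/98/73 (scaled
proportionally for other baseline sizes), 36% maternal-history prevalence,
59% female, IQ ~ N(101.8, 15), administration fully on-site through wave 3
then 89% and 41% on-site. Attrition is monotone and missing-at-random by
default; a covariate-dependent mode (lower-IQ families drop earlier) exists
for robustness studies. True per-wave parameters come from a per-parameter
linear predictor (`default_effect_map()`) on the unconstrained scale —
intercept, age and quadratic terms, maternal offset and interaction,
covariate effects, subject random intercepts/slopes, wave-level noise — with
learning rates mapped through the standard-normal CDF. Fixed-effect defaults
mirror the conditional-growth coefficients this task typically yields in
adolescence, including the three headline signs: reward learning rate falls
with age, frequency sensitivity rises, and maternal depression history
lowers reward learning rate. Covariate conventions in the generator: IQ
effects apply per point above 100, modality effects as
$\mathrm{coef} \times (\mathrm{onsite} - 1)$, so the intercepts are
interpretable at average IQ and in-lab administration.

The random-effect and residual SDs are true-score calibration choices:
variance components reported for fitted growth models describe *estimated*
parameter values after shrinkage, not the latent true scores, so they cannot
be copied in directly. They were set once so that fitted estimates show
poor-to-fair nine-month test-retest reliability, the band reported for this
family of tasks, and were not revisited afterwards. At the default study
size the simulated chain yields adjacent-wave retest r of 0.32–0.56 for the
four fitted parameters and 0.14–0.39 for net proportion play.

What the generator does not emulate: practice effects across repeated
administrations, pubertal or medication covariates, non-monotone missingness,
and any dependence of attrition on task behaviour. Passing tests therefore
show that the estimation chain is correct and well-calibrated under the
stated generative model — not that real adolescent data satisfy that model.

## Problem sizes used in validation

Parameter recovery runs at 100 subjects × 120 trials. Growth-model CI
coverage uses 200 subjects × 5 waves × 200 replications with the covariate
shifts that would bend the marginal trajectory removed, so the generating
slope is the estimand. Full-pipeline sign recovery uses 50 replications of a
120-subject cohort (about 390 sessions each) with a 12-round fitting cap —
past the point where estimates move meaningfully. These sizes were chosen as
the smallest at which the quantities of interest are stable.

## Orchestration

`run_pipeline()` chains simulate → fit → score → associate → growth →
report, writing every product as CSV/JSON plus a manifest (seed, config
echo, stage status, file list) under one output directory; any stage can be
re-run from a previous run's files. A single-wave study refuses the growth
stage with a recorded reason while earlier stages complete. Identical
config and seed reproduce identical report files byte for byte.

## Known limitations

* Point estimates, not posteriors, feed the growth stage; uncertainty in the
  learning parameters does not propagate (a joint model is out of scope).
* The map_eb backend's group means are mildly attenuated toward zero
  relative to full MCMC (documented above).
* $\beta_f$ recovery sits at the edge of the good range under the shipped
  generator (documented above).
* The update-rule conventions (outcome scale, fictive updating) are
  documented defaults for an under-specified published model; exact
  replication of that model would require reconciling them against its full
  specification.
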