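---
title: "Methods: the treatment-decision and patient digital-twin dyad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the treatment-decision and patient digital-twin dyad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The decision problem

Oropharyngeal-cancer therapy involves three sequential binary decisions:
induction chemotherapy before radiotherapy (D1), concurrent chemotherapy
versus radiotherapy alone (D2), and neck dissection after treatment (D3).
`oncotwin` models this as a finite-horizon Markov decision process with
three stages and a terminal-only reward, and implements two coupled models:

* a **treatment-decision twin** — three stage-wise Q-functions trained
  backward from the outcome, which prescribe a treatment at each junction;
* a **patient twin** — per-feature transition classifiers that simulate how
  a patient's chart evolves under any decision sequence, used for
  off-policy evaluation of the first twin.

The state at stage 0 is the encoded pretreatment chart (group 1); stage 1
appends the post-induction features (group 2) and a one-hot of D1; stage 2
appends the post-concurrent features (group 3) and a one-hot of D2. States
therefore carry the complete recorded history up to the decision. The final
outcomes (group 4: 4-year overall survival `os`, feeding-tube dependence at
6 months `ft`, aspiration after therapy `ar_after`) never enter any state;
the layout is constructed from the schema's stage groups, so leakage is
excluded by construction rather than by convention.

## Reward

The composite reward, evaluated once after D3, is

```
R = os - (ft + ar_after - ar_before)
```

Survival is credited; feeding-tube dependence and aspiration after therapy
are penalized; aspiration that already existed before therapy is not held
against the treatment (a patient whose aspiration resolves scores +1 on
that term). Over binary inputs the image is exactly {-2, -1, 0, 1, 2}.
Because the first two decisions carry zero reward, no discount factor is
involved — the objective equals the terminal reward, and the discount is
fixed at 1 rather than exposed as a knob. A survival-only mode
(`outcome = "os"`) replaces the composite with `os` alone.

## Preprocessing

* **Imputation**: median for numeric features, mode for all others, fitted
  on the training table and reused for held-out rows. The one exception is
  HPV/P16 status: "unknown" is a real clinical category, encoded as the
  distinguished value 0 (it sits between the negative and positive poles in
  the ordinal coding), and is never imputed away.
* **Encoding**: ordinals (pathological grade, T and N category, AJCC stage,
  prescribed chemotherapy none<single<doublet<triplet<quadruplet) become
  consecutive integers; unordered categoricals are one-hot expanded; every
  column is affinely mapped to [-1, +1] using the training min/max. A
  constant column maps to 0 (keeps it inert without dividing by zero);
  held-out values outside the training range are clipped, preserving the
  range contract. Decision one-hots use two 0/1 slots with the slot index
  equal to the decision value.
* **Radiomics**: a supplied numeric block is reduced by PCA (centering
  only — the rescaled inputs are already commensurate) keeping the minimal
  number of leading components whose cumulative explained variance reaches
  90%. The component count is data-driven by the variance rule; a fixed-`k`
  override exists. The projection is fit on training rows only, which is
  the leakage-safe choice where the provenance of the published fit is
  unstated.
* **Split**: 75/25 with half-up rounding, so 536 patients give 402/134.

## The synthetic cohort generator

The clinical cohort is single-institution and private, so the package
ships a generator whose defaults are transcribed from the published
marginal tables: pretreatment feature frequencies, physician decision
rates (D1 36.2%, D2 76.5%, D3 20.7%), and outcome marginals (survival
85.3%, feeding tube 18.3%, aspiration 18.3%). Structure:

* Pretreatment features are independent draws from the printed marginals;
  grade, AJCC and packs/year carry the printed missing-cell rates so the
  imputation path is exercised.
* Treatment-coupled blocks are generated conditionally on the enabling
  decision: the prescribed-chemotherapy regimen, induction responses and
  dose-limiting toxicity exist only when D1 = 1 (their conditional
  frequencies are the printed counts renormalized over the induction
  subgroup), and the concurrent regimen and second toxicity block only when
  D2 = 1. The imaging flag is a deterministic copy of D1, which the printed
  counts imply exactly — this deliberately reproduces the one trivially
  predictable feature in the published accuracy table.
* The printed pooled toxicity counts are inconsistent by a few patients
  with the printed per-grade counts; the generator resolves this by drawing
  the grade and defining the binary toxicity flag as grade > 0. Per-organ
  toxicity flags are not printed individually; their conditional rates are
  plausible small values chosen once and recorded in
  `default_conditionals()`.
* Outcomes and late-response features follow Bernoulli laws whose log-odds
  are the calibrated marginal plus additive decision effects **centered at
  the physician decision rates**, so nonzero effects leave the calibrated
  marginals in place. Default effect sizes are modest (0.1–0.8 log-odds),
  enough to make the decision sequence consequential without distorting
  the margins. Label-flip noise is available and folds into the exact
  value computation analytically.
* The physician policy is logistic per decision; by default it is
  state-independent at the printed rate (the tables publish no
  state-dependence to calibrate against), with optional weights on binary
  state features.

Because outcome probabilities depend on the decisions only,
`true_sequence_values()` computes the exact expected reward of each of the
8 open-loop sequences in closed form — the ground truth for recovery tests.
Two presets exist for testing: `config_noiseless()` makes every transition
deterministic in the decisions (a perfect simulator should then be exactly
100% accurate), and `config_dominant()` rescales the survival margin to
50% and applies ±2–2.5 log-odds effects so that one sequence, (1, 1, 0),
dominates all others by ≥ 0.3 expected reward.

What the generator does **not** emulate: correlations among intermediate
features beyond those induced by the decisions (they are conditionally
independent given history and decision, mirroring the per-feature
architecture of the patient twin), survival times beyond the binary 4-year
endpoint, and radiomics texture (the optional block is low-rank correlated
Gaussian noise). Tests passing on this generator therefore validate the
machinery — calibration, backward training, protocol hygiene — not
clinical performance on real charts.

## Backward Q-learning

The stage-3 network regresses the terminal reward on (s2, one-hot a3);
stage 2 regresses `max_a3 Q3(s2, a3)` on (s1, one-hot a2); stage 1
regresses `max_a2 Q2(s1, a2)` on (s0, one-hot a1). At prescription time the
stack is used in the forward order and each stage takes the argmax, with
exact ties broken toward action 0 (no intervention — deterministic and
clinically conservative). The action enters as an appended one-hot rather
than as two output heads, matching the state-construction convention;
capacity is equivalent.

The regressor is a small fully-connected ReLU network trained by
full-batch Adam on squared error. Full batch is deliberate: the data are a
few hundred fixed episodes, so batching noise buys nothing and
bit-reproducibility is free. Training stops when the largest per-epoch
parameter change drops below 1e-4 (the weights have converged) or at the
epoch cap; the learning rate is halved on loss plateaus so the convergence
criterion is actually reachable. A non-finite loss aborts with the
learning rate in the message. Depth 0 is an honest linear model trained
the same way.

Defaults: width 64, learning rate 1e-2, cap 2000 epochs. The width is not
published; 64 is generous for these input sizes and is recorded in the
spec object. For consistency experiments on synthetic data we deliberately
use narrower networks (16–32 nodes): with a few thousand episodes the
dominant failure mode is variance, not bias, and the oracle-equivalence
checks below bear this out.

Bootstrap ensembles refit the whole stack on resamples with replacement;
every downstream interval is a percentile (2.5, 97.5) interval across
members. Each member is self-consistent — its own Q3 generates its Q2
targets — because the alternative (sharing a pooled Q3) would break the
exchangeability the percentile interval relies on. Ensembles default to
B = 100 in examples; the checks in this package use B = 10 per depth,
which is enough to exercise the interval machinery (the published analysis
used B = 1000 on a GPU cluster).

## The patient twin

One RBF support-vector classifier per output feature per stage: stage 1
maps (group 1, one-hot D1) to each group-2 feature, stage 2 maps
(groups 1–2, one-hots D1–D2) to each group-3 feature, stage 3 maps
(groups 1–3, all three one-hots) to each final outcome. `cost` and `gamma`
are tuned by 5-fold cross-validation maximizing macro-averaged F1 (macro
because several features are multiclass and heavily imbalanced), with
per-example class weights inversely proportional to class frequency,
normalized to mean 1. The default grid is cost ∈ {0.1, 1, 10, 100} x
gamma ∈ {1e-3, 1e-2, 1e-1, 1}; the published full grid is in a
supplementary table that is not public, so the default here is the
standard log grid, recorded in `default_svc_grid()` and overridable.

Choices worth noting:

* Predictions are hard labels — the published accuracy table implies value
  prediction, not sampling. (The generator, not the twin, carries the
  stochasticity switch.)
* A single-class output feature yields a constant predictor with a logged
  warning, not an error: rare events (e.g. quadruplet regimens) vanish in
  small training splits and should not kill the pipeline.
* Fold assignment derives from the feature *name*, so adding or removing
  one output feature cannot perturb any other feature's tuning — the
  per-feature models are exactly isolated.
* Each fitted stage records its training patient ids; every evaluation
  entry point refuses test tables that overlap them, which makes the
  train/test decoupling protocol checkable rather than aspirational.

One-step accuracy predicts each next-stage feature under the physician's
recorded action and compares with the recorded value; CIs are percentile
intervals over bootstrap resamples of the test set stratified by the
evaluated feature's class (the stratification variable is not named in the
published caption; per-feature stratification preserves the class balance
the accuracy depends on). Start-to-finish accuracy chains the three
simulated transitions under the recorded decisions and scores the final
outcomes, with dysphagia defined as `ft OR ar_after`.

## Evaluation protocol

The policy is trained on observed trajectories only, never on the twin;
the twin simulates the test-time environment only. At evaluation, each
ensemble member rolls every test patient forward: the member picks the
action from the current simulated state (it never sees the simulator's
future), the twin produces the next stage. Reported: simulated OS rate and
DP-free rate, ensemble means with percentile CIs, against the observed
test-set baselines.

Similarity to physicians is computed on *recorded* histories — the
published description explicitly needs no simulator, which forces this
reading over counterfactual rollouts. Overall similarity is the mean of
the three per-decision similarities. Prescription deltas are model yes-rate
minus physician yes-rate, in points, with the prescribed-patient counts.
Similarity CIs, where produced, are bootstrapped over ensemble members
(the published bootstrap unit is unstated; members are the unit already
used for every other interval here).

The compliance audit implements the guideline that advanced-stage patients
(T3–4 or N1–3) must receive chemotherapy at D1 or D2; a violation is an
advanced-stage patient prescribed neither. Unknown tumour codes (Tx) count
as non-advanced on the T axis and are reported in their own row — the
audit runs on the raw (pre-imputation) table, since imputing Tx away would
silently reclassify those patients. No multiple-testing correction is
applied anywhere, matching the published analysis.

## Problem sizes in the shipped checks

The test suite validates the machinery at sizes chosen for a single CPU:
oracle-equivalence uses 20 random tabular processes (≤ 4 states/stage,
5000 sampled episodes each) and requires the learned greedy policy to come
within 0.05 of the dynamic-programming optimum on at least 95% of seeds;
sequence recovery uses the dominant-sequence generator at n = 4000 with a
width-16 stack; the depth sweep runs all of 0–8 hidden layers at B = 10;
twin checks use noiseless cohorts of a few hundred patients where the
correct accuracy is exactly 100%. Generator calibration is checked at the
study size (n = 536) against three binomial standard errors.

## Known limitations

* The generator's conditional-independence assumption matches the twin's
  architecture; it cannot reveal failure modes caused by correlated
  intermediate features (a correlated-noise stress switch on the radiomics
  block exists, but not for the clinical features).
* Exact sequence values are available only while outcome laws depend on
  decisions alone; adding covariate-dependent outcome effects would
  require the Monte-Carlo path.
* The SVC grid and network width are defaults chosen here, not published
  values; both are recorded in config objects and overridable.
* The schema ships a faithful but not exhaustive mirror of the published
  feature tables (the per-organ toxicity flags are summarized); the schema
  file is the authority and can be replaced wholesale via `read_schema()`.
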