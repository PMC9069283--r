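# oncotwin

Dynamic treatment regimes for oropharyngeal cancer as a pair of digital
twins: a **treatment-decision twin** (finite-horizon fitted Q-learning over
the three sequential therapy decisions) evaluated against a **patient twin**
(per-feature support-vector transition models that simulate a patient's
course under any decision sequence).

The package is for biostatisticians and clinical-ML researchers working on
sequential decision problems with observational cohorts: it implements the
full modelling pipeline — schema-driven cohort preprocessing, backward
Q-network training with bootstrap ensembles, transition-model simulation,
off-policy evaluation with percentile confidence intervals, physician
similarity and prescription-delta metrics, and a guideline-compliance
audit — plus a synthetic cohort generator calibrated to published marginal
frequencies, since the underlying clinical cohort (N = 536, single
institution) is not public.

## The model

Therapy is a 3-stage Markov decision process. The decisions are binary:

| stage | decision | choice |
|---|---|---|
| D1 | induction chemotherapy (IC) | yes / no |
| D2 | concurrent chemotherapy (CC) | CC / radiotherapy alone |
| D3 | neck dissection (ND) | yes / no |

State s0 is the encoded pretreatment chart; s1 appends the post-IC
features and one-hot(D1); s2 appends the post-CC features and one-hot(D2).
The reward is terminal-only (so the discount is 1):

```
R = OS − (FT + AR_after − AR_before)
```

with OS = 4-year overall survival, FT = feeding tube at 6 months, AR =
aspiration (after/before therapy); dysphagia DP = FT ∨ AR_after. Over
binary inputs R ∈ {−2, …, 2}.

Q-functions are trained backward with no discounting:

```
Q3(s2, a3) ← R            Q2(s1, a2) ← max_a3 Q3(s2, a3)        Q1(s0, a1) ← max_a2 Q2(s1, a2)
```

each a small ReLU regression network (0–8 hidden layers; 0 = linear),
then used in the forward order: the prescribed action is argmax_a Q(s, a),
ties toward "no intervention". Uncertainty comes from bootstrap ensembles
of whole stacks with percentile (2.5, 97.5) intervals.

The patient twin is one RBF support-vector classifier per next-stage
feature (group 2 from s0 + D1; group 3 from s1 + D2; the final outcomes
from s2 + D3), tuned by 5-fold CV over macro-F1 with
inverse-class-frequency example weights. Policies are evaluated off-policy
by rolling test patients through the twin under the policy's decisions and
comparing simulated OS / DP-free rates with the observed physician
baselines. Training and evaluation are strictly decoupled: the policy
never trains on the twin, the twin records its training patients and
refuses evaluation on them.

## Worked example

```r
library(oncotwin)

# 1. a calibrated synthetic cohort at the study size, split 75/25
cohort <- generate_cohort(generator_config(n = 536, seed = 1))
parts  <- split_cohort(cohort, 0.75, seed = 1)    # 402 / 134

# 2. preprocessing fitted on the training split only
train   <- impute_missing(parts$train)
test    <- impute_missing(parts$test, stats = attr(train, "imputation_stats"))
scaling <- attr(encode_features(train), "scaling")

# 3. patient twin
twin <- fit_twin(train, scaling,
                 grid = expand.grid(cost = c(1, 10), gamma = c(0.01, 0.1)),
                 seed = 1)
acc <- one_step_accuracy(twin, test, scaling, B = 200, seed = 1)
attr(acc, "summary")
#>   mean_accuracy median_accuracy
#> 1          83.6            89.9

# 4. backward-trained Q-learning ensemble
traj <- assemble_trajectories(train, scaling, outcome = "os_dp")
ens  <- fit_bootstrap_ensemble(traj,
          network_spec(n_hidden_layers = 2, width = 16, max_epochs = 300),
          B = 10, seed = 1)

# 5. off-policy evaluation against the twin
report <- evaluate_policy(ens, twin, test, scaling)
tidy(report)
#>   metric       simulated lower upper baseline delta
#> 1 os_rate           93.1  86.5  96.8     86.6  6.49
#> 2 dp_free_rate      65.7  59.6  76.2     67.9 -2.16
```

Reading the numbers: the twin predicts individual next-stage chart
features with 83.6% mean (89.9% median) one-step accuracy on held-out
patients; under the learned policy the twin-simulated survival rate is
93.1% (95% CI 86.5–96.8) against the 86.6% physician baseline in this
synthetic cohort, a +6.5-point delta, while the dysphagia-free rate is
essentially unchanged (−2.2, CI spanning zero). `similarity()`,
`prescription_delta()` and `nccn_compliance()` complete the report, and
`autoplot()` methods visualize depth sweeps, accuracy tables and
prescription deltas. `run_pipeline()` executes the whole chain from a YAML
config and writes `report.json` plus CSV tables; a thin CLI lives at
`inst/cli/oncotwin.R`.

All of this runs on synthetic data: the generator reproduces the published
marginal structure (decision rates, outcome rates, treatment-conditional
feature blocks) with configurable causal effects of decisions, and
`true_sequence_values()` gives the exact expected reward of all 8 fixed
decision sequences for ground-truth comparisons. See the methods vignette
(`vignettes/oncotwin-methods.Rmd`) for the generative model, the numerical
choices, and what synthetic results do and do not establish.

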