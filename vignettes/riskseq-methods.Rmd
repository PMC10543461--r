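---
title: "riskseq: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{riskseq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`riskseq` implements a pipeline for short-horizon adverse-event prediction
from longitudinal electronic-medical-record (EMR) style data, and for
screening risk and protective factors by perturbing a trained sequence
model. This vignette documents the models, the statistics, and the design
choices that were genuinely open, so that a reader can judge what the
package's validation does and does not demonstrate.

## The prediction problem

Patients enter the cohort at a first *qualifying diagnosis* (in the
motivating setting, a dual diagnosis of two psychiatric conditions; in the
package, any configurable code set). The task is binary: given everything
recorded up to an *index date*, will a *new* adverse event of a watched type
occur within the next prediction window (90 days by default)?

Cohort construction follows the case/control-with-augmentation design:

* **Cases.** For each patient whose first new-onset adverse event falls
  after qualification, every encounter between qualification and that onset
  whose 90-day window still contains the onset becomes one training sample.
  This encounter-level augmentation multiplies the effective case count and
  exposes the model to histories of varying depth.
* **Controls.** Encounters of qualifying patients with no adverse-event
  record inside the window are sampled uniformly (seeded, without
  replacement) to approximately the case-sample count (ratio configurable).
  By default a case patient's off-window encounters may *not* serve as
  controls, keeping the two groups disjoint by patient.
* **New onset by type.** A patient who already had one adverse-event type at
  or before qualification remains eligible for *other* types; the
  pre-existing type's records stay in the history as ordinary features.
* **Splitting.** Train/validation/test is 8:1:1 **by patient**, not by
  sample: augmentation creates near-duplicate sequences for one patient, and
  letting them straddle folds would leak and inflate discrimination
  estimates. A greedy largest-deficit assignment over a seeded patient order
  tracks the target proportions as closely as patient granularity allows.

## Encoding

Events are tokenized by modality: diagnoses (`DX:`, optionally through a
user-supplied clustering map), medications (`RX:`, optionally through a
drug-id map), lab results only when flagged `ABNORMAL`/`HIGH`/`LOW`
(`LAB:<code>:<flag>`; unflagged results carry little signal and are
dropped), individual social determinants of health (`SD:`, with age binned
to decades), and zip-linked neighborhood indices discretized into
dataset-quantile bins (`NB:<feature>:Q<k>`, quintiles by default — the
embedding model consumes discrete codes, so continuous indices must be
binned; `NB:MISSING` marks an unknown zip). A visit is the set of distinct
tokens sharing one calendar date; sequences keep the most recent
`max_visits` (200 by default). Static SDoH tokens are prepended as a
pseudo-visit, and the `include_sdoh = FALSE` switch implements the "-SDoH"
ablation arm.

The vocabulary is built **from the training fold only**, keeping tokens
carried by at least `min_patient_count` distinct training patients (10 by
default; the threshold for excluding low-frequency features is a free
parameter of this design). Everything else, including every unseen token in
validation or test, maps to `<UNK>`.

## Models

Two recurrent classifiers share one parameter layout and training loop:

* **tanh-LSTM** (`tlstm`): stacked LSTM layers whose input/forget/output
  gates use tanh activation instead of sigmoid, bounding gate outputs in
  (−1, 1) for stronger gradient signal; the candidate update keeps tanh and
  the output head keeps sigmoid (a probability is required). Sigmoid gates
  remain available (`gate_activation = "sigmoid"`) for ablation. Visit input
  is the sum of token embeddings (mean available), and the final hidden
  state feeds an affine + sigmoid head.
* **RETAIN-style attention** (`retain`): two single-layer recurrent nets run
  over the *reversed* visit sequence; one produces scalar visit scores that
  softmax-normalize to attention weights α, the other produces tanh-bounded
  variable-level gates β. The context vector Σⱼ αⱼ (βⱼ ⊙ vⱼ) feeds an
  affine + sigmoid head. α is exposed per visit (`retain_attention()`) and
  sums to 1.

Default hyperparameters follow the reference configuration for this model
family: embedding 128, hidden 128, dropout 0.2, 8 stacked layers, early
stopping patience 3. "Layers" is read as stacked recurrent layers; since
that reading is unusually deep and not recoverable from the source
framework's conventions, the depth is fully configurable and the package's
own validation uses 2 layers. Optimisation is Adam (lr 1e-3, batch 64, ≤50
epochs by default), binary cross-entropy loss, everything seeded: epoch
shuffling and dropout draw from R's RNG, so training logs are
bit-reproducible.

Two numerical choices matter and were made after observing failures, on
grounds that hold generally:

* **Gate bias initialisation.** With tanh gates and small random weights,
  every gate starts near tanh(0) = 0, which multiplies both the forward
  signal and the gradient by ≈0 and can stall training entirely on short
  sequences. The input/forget/output gate biases therefore start at 1
  (the classic forget-bias trick, applied to all three gates).
* **Early-stopping metric.** Model selection monitors validation *loss*,
  not AUROC. A ranking metric can sit far above chance before the network
  has learned anything — sequence length alone separates cases from
  controls under augmentation — so patience-3 AUROC stopping can return an
  essentially untrained model whose downstream attributions are noise. The
  AUROC criterion remains available (`early_stopping_metric = "auroc"`).

Evaluation reports AUROC by the midrank Mann–Whitney statistic (verified in
the tests against exhaustive pairwise comparison), plus precision, recall
and F1 at a 0.5 threshold. `repeat_experiment()` re-splits, re-trains and
re-evaluates under derived seeds and reports per-repeat columns with the
mean and sample standard deviation.

## Perturbation contributions and the RC statistic

For a trained model, the contribution of a token to one sample is the drop
in the model's output when the token is removed (*occlusion*, deterministic
and the default) or perturbed with seeded Gaussian embedding noise (*noise*
mode, K draws). A patient's **feature contribution (FC)** aggregates these
drops over the patient's samples, separately per label group.

Four measurement choices deserve emphasis because the naive alternatives
are demonstrably confounded; each is a documented, switchable default:

* **Scale** (`scale = "logit"`). On the probability scale every drop is
  multiplied by the sigmoid slope at the patient's operating point, so
  mid-curve patients (predominantly cases) show uniformly larger drops for
  *every* feature and outcome-independent features drift away from RC = 1.
  Log-odds drops are comparable across operating points.
* **Granularity** (`granularity = "token"`). All occurrences of a token in
  a sample are removed at once, giving one drop per (sample, token).
  Removing a single occurrence of a persistently recorded exposure is
  diluted by redundancy — the remaining occurrences keep carrying the
  signal, leaving near-zero drops of unstable sign — and per-occurrence
  *totals* scale with history length, which is label-associated in an
  augmented cohort. The per-occurrence-and-sum definition remains available
  (`granularity = "occurrence"`).
* **Within-sample normalization** (`normalize = "sample"`). Each drop is
  centred on the sample's median drop and scaled by the mean absolute
  deviation from it, so a token's FC is its *excess* response over the
  sequence's typical occlusion response. Raw drops are label-associated
  regardless of feature (short, recent, high-risk histories react far
  more, and more uniformly in one direction, to any occlusion than long
  saturated low-risk ones), and no downstream statistic can restore error
  control once the contribution itself carries the label.
* **Per-patient aggregation.** Token-level drops average over the
  patient's samples (mean); occurrence-level drops sum, matching the
  "total value within the patient" convention of that definition.

The **relative contribution** of a feature is

  RC = (Σ FC over event patients / m) / (Σ FC over no-event patients / n),

with m and n the event/no-event patient counts of the analysis set;
patients who never carry the feature contribute FC = 0 (so RC behaves as a
differential-prevalence-and-strength measure: risk features concentrate
positive FC among cases, protective features concentrate negative FC among
controls). The delta-method variance on the log scale is the sum of squared
coefficients of variation over the group sizes,

  Var(ln RC) = (sd_e/mean_e)²/m + (sd_c/mean_c)²/n,

the 95% CI is exp(ln RC ± 1.96 √Var), and a two-sided z-test on ln RC gives
the raw p-value. Inference proceeds whenever both group means share a
nonzero sign — ln RC is then defined, and the squared-CV variance is
sign-invariant, which is what permits protective features (both group means
negative) to be tested at all. Opposite signs, a zero mean, or fewer than
two patients per group suppress the CI and p-value and classify the feature
`UNDEFINED`. RC > 1 is classified `RISK`, RC < 1 `PROTECTIVE`.

Raw p-values are corrected across the features actually tested: Bonferroni
(min(1, M·p)) and Benjamini–Hochberg FDR, both via `stats::p.adjust`.
Reports are ranked by FDR q with undefined rows last, in the conventional
column layout (`Feature Name`, `RC`, `95%CIup`, `95%CIdown`, `FDR_Q`,
`Bonferroni corrected p-value`).

By default the screen attributes on the validation + test folds: validation
samples never produced a gradient update, and pooling roughly doubles the
carrier counts behind each RC, which is what decides significance for
borderline protective effects. `fc_folds = "test"` gives strictly-held-out
attribution; adding `"train"` gives a descriptive screen over the cohort.

## The synthetic cohort generator

No public data with this structure exists, so `generate_dataset()` emulates
the essential features: per-patient irregular encounter timelines; a
qualifying diagnosis at the first encounter; multimodal vocabularies
(diagnoses, medications, labs with ABNORMAL/HIGH/LOW flags, individual SDoH
including age/sex/race, zip-linked numeric neighborhood indices); optional
pre-existing adverse events before qualification (exercising the
new-onset-by-type rule); and outcome onset driven by *known planted
effects*.

The outcome model is discrete-time: follow-up after qualification is cut
into 90-day windows (the prediction horizon is the generator's native
unit), and each window's event probability is the baseline hazard times the
product of odds factors of planted codes present in the preceding 365 days,
clamped to [0, 1]. Design details chosen for testability:

* All window-level randomness (Bernoulli draws, onset offsets, event types)
  is pre-drawn per patient before any hazard is evaluated, so raising an
  odds factor can only turn non-events into events — planted-effect
  monotonicity holds exactly under a fixed seed.
* Each patient's substream seed derives from the master seed and the
  patient index, so growing `n_patients` never reshuffles earlier patients.
* Planted-code carriers form **disjoint strata** (default prevalence 0.40
  per code) and emit their code at every encounter (persistent exposure,
  like a chronic prescription). Disjointness keeps each effect estimable
  without co-carriage confounding. The prevalence default comes from a
  design calculation: with a risk odds factor of 4 and a protective factor
  of 0.25 on a baseline window hazard of 0.08 over ~10 windows, strata of
  0.4/0.4/0.2 give a Bayes-optimal patient-level AUROC near 0.89, leaving
  realistic headroom for a trained model to clear 0.85; with independent
  co-carriage at the same prevalences the Bayes ceiling drops to ~0.73 and
  no model could demonstrate recovery.
* Calendar time is integer day offsets internally; I/O uses ISO-8601 dates.

What the generator does **not** emulate — and therefore what passing tests
cannot show about real data: realistic code co-occurrence and progression
structure, coding errors and missingness, informative visit timing,
time-varying effects, competing risks, and care-pattern confounding
(exposure here is randomized by construction, so RC recovery on synthetic
data says nothing about causal interpretation in observational data).

## Problem sizes used in validation

The package's own test suite and acceptance script run at deliberately
modest scale, chosen to exercise every code path with comfortable
statistical margins: end-to-end recovery uses 3,000-patient cohorts, a
2-layer tanh-LSTM with embedding/hidden size 32, batch 64, at most 20
epochs with patience 3; the statistic-level checks use 1,000 random FC
tables, 2,000-replicate CI calibration at m = n = 200, and 500 random
p-vectors. Determinism is asserted by bitwise comparison of two full
occlusion-mode pipeline runs.

## Known limitations

* The delta-method CI is a first-order approximation; with very few
  carriers of a feature its normal assumption is fragile, and heavy-tailed
  FC distributions widen it slowly.
* RC compares group means of a model-derived quantity; it inherits every
  bias of the fitted model and is a screening statistic, not a causal
  estimate.
* The tanh-gate LSTM reading (tanh replacing sigmoid in all three gates,
  sigmoid head retained) is one defensible interpretation of that model
  family; the sigmoid-gate variant is provided for comparison.
* Training is CPU-bound, single-threaded and dense; it is sized for cohorts
  of thousands of patients, not millions.
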