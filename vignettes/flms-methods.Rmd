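---
title: "Ranking predictions from small multimodal sensing panels: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking predictions from small multimodal sensing panels: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of what it computes, which knobs
matter, what the synthetic data generator does and does not emulate, and
where the design was genuinely open.

## The modeling problem

The input is a longitudinal multimodal panel: for each participant and week,
a vector of sensor-derived features tagged by modality (calls, location,
screen, conversation, Fitbit, Wi-Fi in the canonical layout), plus a weekly
severity score on a 0–27 instrument scale. The prediction target is the
week-over-week *change* `W_m − W_{m−1}`, computed only across consecutive
observed weeks — differencing across a gap would conflate multi-week drift
with weekly change, so gaps simply produce no target. After encoding
(change ≤ 0 → 0, > 0 → 1) the task read out by all evaluation is binary:
did this participant's severity rise this week?

Such panels are small (a few hundred target slots), so the framework's
premise is to spend compute instead of data: enumerate every modality
subset, run several regressors under four cross-validation strategies
spanning the user-agnostic/personalized axis, and let an explicit ranking —
not a prior commitment to one paradigm — decide what reaches the final
prediction.

## Stages and their assumptions

**Stage 1 (fusion).** Each of the `2^Z − 1` modality subsets becomes a wide
matrix whose rows are target slots. Preprocessing is fit per training fold:
KNN imputation (k = 5, mean-squared-difference distance on mutually observed
columns), z-scoring, optional signed `log1p` for features named in
`log_features`, zero-variance drop, and greedy correlated-feature removal
(keep-first in deterministic column order when |r| > 0.9). Fold-wise fitting
is the default because a global fit leaks held-out statistics into training;
`global_preprocessing = TRUE` restores the global behaviour for comparison.
Participants missing more than 60% of their feature cells are excluded up
front (`participant_missing_max`).

**Stage 2 (modeling).** The suite defaults to seven regressors: OLS,
elastic net (alpha 0.5, fixed lambda 0.1 — cross-validating lambda inside
folds of a dozen rows is noise), random forest and extra-trees (ranger, 100
trees), gradient boosting and XGBoost (two xgboost parameterizations), and
AdaBoost.R2 over depth-3 rpart trees. AdaBoost.R2 is implemented in-package
(no CRAN regressor variant is available) using instance weights directly in
each weak fit rather than weighted resampling; this is the deterministic
variant of the algorithm and removes one source of run-to-run noise. All
learners sit behind a fit/predict contract, so a user can register a subset
or different algorithms via `flms_config(suite = ...)`.

The four split planners define the paradigms precisely:

* **LOPO** — all slots of one participant held out; needs ≥ 2 participants.
* **LTXO** — all participants' slots at one time unit held out.
* **ATU** — per participant, an expanding window: first `w0 = 2` slots train,
  slot `w0 + 1` is predicted; the window grows by `step = 1` (both
  configurable) until slots are exhausted. Training slots always strictly
  precede the predicted slot, so the forecasting strategy can never see the
  future. Slot positions (a participant's ordered target slots) are used
  rather than calendar weeks, which makes the planner robust to observation
  gaps.
* **LOTPO** — per participant, each slot predicted from all their other
  slots, past and future; participants with fewer than `lotpo_min_units = 3`
  slots are skipped (training a regression on a single point is not
  meaningful).

Per participant, the algorithm minimizing the absolute sum error over
held-out slots is selected, with ties broken by suite order. Note what this
means: held-out labels inform model *selection*, which is optimistic. This
is the framework's reference behaviour and is kept as the default;
`honest_selection = TRUE` restricts the selection sum to the first half of
each participant's predicted slots, which is the cheap honest alternative
when the optimism matters. For LTXO, where a participant's slots span many
splits, selection is per participant across all splits of the strategy
(predictions are pooled into per-participant arrays first).

**Stage 3 (ranking).** Candidates per strategy are both every individual
combination tensor and every per-cardinality mean aggregate
(`fusion_scope = "both"`); either view can be selected alone. All candidates
are encoded and ranked by hamming distance to the encoded truth, ascending,
with ties broken by smaller cardinality (prefer fewer sensors at equal
error) then lexicographic identity — every ordering in the package is
deterministic so that reruns are byte-identical.

**Stage 4 (ensemble).** Weights are normalized inverse distances,
`w_k ∝ 1/(D_k + 1e-9)`. The guard `epsilon` only matters for a perfect
candidate (D = 0), which then correctly dominates. Inverse weighting is the
simplest monotone map from distances to weights; a softmax alternative
(`weighting = "softmax"`, `w_k ∝ exp(−D_k)`) is provided since the choice is
a design decision, not something the ranking statistic dictates. The
ensemble fuses *encoded* tensors and re-thresholds at 0.5 (exact ties go up:
a 2–2 split among equally trusted strategies predicts "risen", the
clinically cautious direction; `tie_rule = "half_down"` flips this).
Strategies do not cover identical slots — ATU has no predictions inside its
initial window — so weights renormalize over the strategies present at each
slot rather than discarding partially covered slots. Setting
`ensemble_on_raw = TRUE` averages raw regression tensors instead and encodes
once at the end.

## The synthetic cohort generator

`simulate_cohort()` exists so every stage is testable without any real
cohort. Each participant gets a latent AR(1) trajectory
`u_t = ρ u_{t−1} + e_t` (ρ = 0.7) around a personal offset (SD τ = 0.8);
the weekly score is `clamp(round(4 (offset + u_t) + 10), 0, 27)`. Informative
modalities' features load linearly half on the level `u_t` and half on the
innovation `e_t` — so week-over-week change is in principle linearly
recoverable from concurrent features — plus Gaussian noise (σ = 0.5) and a
per-participant log-normal scale factor emulating device heterogeneity.
Zero-inflation sets cells to exact 0 at rate π = 0.35 (matching the
sparsity level of final fused datasets in studies of this kind); cells are
masked missing at rate μ (default 0). Each participant contributes one
contiguous run of 9–14 observed weeks inside a 24-week study, giving
~11–12 weekly points per participant and ~500 rows at the default 45
participants — the scale this class of study actually produces.

What the generator deliberately does **not** emulate: raw sensor streams and
their feature-extraction pipelines (Lomb–Scargle circadian rhythms, location
entropy, significant-place clustering), non-stationary symptom dynamics,
informative missingness (dropout correlated with severity), and floor
effects of real instruments. Passing tests on synthetic cohorts therefore
demonstrates that the machinery is correct and that the ranking recovers
planted structure — not that any particular accuracy level transfers to a
real cohort.

Default modality informativeness (calls/location/screen/conversation
informative, fitbit/wifi noise) is a modeling choice that gives
sensor-selection tests a planted answer to find.

## Numerical choices and degenerate inputs

* Zero-variance features are dropped with a warning, not an error — constant
  columns are routine in zero-inflated folds.
* Folds too degenerate for a learner (no features left, < 2 rows, constant
  target) uniformly fall back to the training-mean predictor; an empty
  training fold leaves its slots unpredicted with a warning.
* OLS uses pivoted `lm.fit` with rank-deficient coefficients zeroed, so
  p > n folds (common in personalized strategies) are handled without
  error.
* KNN imputation donates from rows observed in the target column; if no
  pool row is, the column mean of the pool steps in; a column observed
  nowhere is an error naming the feature.
* All orderings (participants, fusion subsets, candidates, tie-breaks) are
  fixed, and every stochastic learner is seeded, making end-to-end runs
  byte-identical at a fixed seed.

## Problem sizes used in the bundled checks

The package's own experiment harness and acceptance checks run the full
63-fusion, four-strategy pipeline on the default 45-participant regime with
the suite reduced to OLS — on these panel sizes the linear model is
competitive, and one full run stays around a minute on a single core, which
keeps multi-seed comparisons practical. The seven-algorithm suite is
exercised end-to-end on smaller cohorts (8 participants, 3 modalities).
Property tests use 1000-instance random batches for the tensor operations
and 20 seeded replicates for the sensor-recovery check (12 participants,
3 modalities, σ = 0.05, no sparsity — low-noise conditions under which an
informative channel should essentially always out-rank noise channels).

## Known limitations

* The reference selection rule (labels inform per-participant model choice)
  inflates singular-strategy and framework metrics alike; use
  `honest_selection` when absolute performance matters.
* Per-user recall/F1 are defined as 0 for users with no positive truths, and
  such users are flagged rather than excluded; means over users therefore
  mix differently-defined quantities when positives are rare.
* The hamming ranking treats all slots equally; no temporal weighting or
  per-user normalization is applied before ranking.
* Binary change encoding discards magnitude; a multiclass or ordinal
  encoding is out of scope.
* With a single algorithm in the suite, stage-2 selection is trivial; the
  framework degrades gracefully but its best-model stage adds nothing.
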