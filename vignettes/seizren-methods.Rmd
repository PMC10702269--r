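---
title: "Methods: relative-entropy features for seizure cluster analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relative-entropy features for seizure cluster analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Many people with drug-resistant epilepsy experience seizure clusters: several
seizures within a short window, carrying a higher risk of progression to
prolonged seizures or status epilepticus. Two clinically useful questions can
be asked right after a seizure has occurred: *will another seizure follow
soon?* (next-seizure prediction) and *was this seizure the start of a
cluster?* (cluster-onset prediction). seizREN implements an individualized
analysis pipeline for both questions from chronic multichannel intracranial
EEG (iEEG): feature extraction, seizure-type statistics, and per-patient
classifiers, together with a synthetic-data generator that makes the whole
pipeline testable without access to clinical recordings.

## The feature: bivariate relative entropy

For a pair of channels $x$ and $y$, let $p$ and $q$ be the distributions of
their signal amplitudes over a short segment. Relative entropy (REN) is

$$\mathrm{REN}(x, y) = \max\{ D_{KL}(p \| q),\; D_{KL}(q \| p) \},$$

the maximum of the two directional Kullback–Leibler divergences (KL is
asymmetric; the maximum makes the feature symmetric). REN quantifies how
dissimilar the two channels' amplitude distributions are and has been used
for seizure detection and seizure-onset-zone localization; here it serves as
a network-level descriptor of the interactions underlying different seizure
types.

Estimation details are deliberately simple and surfaced in `ren_config()`:

* **Histogram estimator** on equal-width bins over *shared* edges spanning
  the pooled range of the two series. Shared edges are essential — with
  per-series edges the divergence of identical distributions would not be 0.
* **`n_bins = 10`** by default, sized so that segments of roughly a thousand
  samples put ~100 expected counts in each bin.
* **Smoothing** adds `smoothing_eps = 1e-10` pseudo-probability per bin
  before renormalizing, so empty bins cannot produce infinite KL.
* **Units are nats** (natural logarithm).

`relative_entropy()` is the readable R reference; `ren_all_pairs()` computes
the same arithmetic for all channel pairs, segments and bands in compiled
code (the test suite asserts agreement to 1e-12).

## From recording to feature table

1. **Bipolar montage** (`make_bipolar()`): consecutive contacts within each
   electrode array are subtracted, suppressing common-mode artifacts. The
   default layout (2 assemblies × 2 arrays × 4 contacts = 16 contacts)
   yields 12 bipolar channels. No further artifact rejection is applied.
2. **Analysis windows** (`extract_windows()`): per seizure, the *ictal*
   window `[onset, offset]` and the *near-seizure* window of up to 10
   minutes of pre-ictal signal ending at onset, truncated at the previous
   seizure's termination (possibly empty).
3. **Segmentation and filtering** (`segment_and_filter()`): windows are cut
   into non-overlapping 2.5 s segments aligned to seizure onset — tiling
   backward from onset for the near-seizure period and forward for the
   ictal period, the partial remainder at the far end being dropped. Each
   channel is filtered into delta (0.5–4 Hz), theta (4–8), alpha (8–12),
   beta (12–25) and gamma (25–45 Hz) with order-2 Butterworth band-passes,
   then every (segment, channel, band) series is z-normalized to zero mean
   and unit variance.
4. **Grand averages** (`grand_average()`, `compute_features()`): REN is
   averaged over all 66 channel pairs and all segments of a seizure,
   separately per band and period, giving 10 features per seizure
   (5 bands × 2 periods).

Numerical choices worth stating:

* Filters are applied **forward–backward** (zero phase). The alternative —
  a single causal pass — would delay band energy relative to onset and
  misalign segments; the zero-phase choice is verified by a test that
  pass-band tones keep their phase and stop-band tones are attenuated by at
  least 90 %. The forward–backward recursion runs in compiled code with
  edge-reflection padding (150 samples) to suppress start-up transients.
* Whether segments should tile backward or forward from onset in the
  near-seizure period is an open design point; backward tiling was chosen
  so that the segment boundary nearest the seizure coincides exactly with
  the onset sample, where the most informative pre-ictal signal lies.
* Time is continuous seconds internally; sample ranges are half-open
  `[start, end)` and onset maps to its floor sample.
* A segment in which any series is constant after filtering cannot yield an
  amplitude distribution; such segments are excluded and counted, never
  NaN-propagated. Seizures shorter than 2.5 s contribute no ictal segments;
  seizures with no usable segments in either period are dropped from the
  feature table (logged).

## Seizure taxonomy

`label_seizures()` groups seizures into clusters when the inter-seizure
interval (ISI) is at or below a cutoff — 24 h by default, 8 h for robustness
analyses — and assigns the categories *isolated*, *cluster-non-last* and
*cluster-last*, with the first seizure of each cluster flagged
*cluster-first* (the first member of a two-seizure cluster is both first and
non-last). Two points are configurable because the convention is genuinely
ambiguous:

* **ISI reference**: offset-to-onset by default (the clinical question is
  whether a new seizure occurs shortly after the current one *ends*);
  onset-to-onset is available.
* **Ties**: a gap exactly equal to the cutoff counts as *within* the
  cluster, fixed for determinism.

The linear-scan implementation is tested against an $O(n^2)$ union-find
oracle that applies the definition literally to all pairs.

## Group statistics

`compare_ren_groups()` compares grand-average REN between isolated seizures
and each cluster subcategory (cluster-first, cluster-non-last, cluster-last)
per band and period, using two-sided Wilcoxon rank-sum tests — exact
enumeration up to 20 observations per group, normal approximation with tie
correction above — and Benjamini–Hochberg FDR correction at q = 0.05 over
the pooled family of all patients × bands × periods × comparisons (a
per-patient family is available). Direction (cluster-higher vs
isolated-higher) is reported only for significant cells and tallied per
period by `direction_tally()`.

## Prediction

`run_task()` trains individualized classifiers — logistic regression (ridge,
glmnet), linear SVM (e1071), k-NN, decision tree (rpart) and random forest
(ranger) — with outer 5-fold stratified cross-validation and inner 5-fold
stratified selection of hyperparameters by mean validation AUC, using only
the outer-training portion. Training samples are weighted inversely
proportional to class size; features are standardized with outer-train
statistics only. Reported metrics (precision, recall, F1 of the positive
class, and AUC from continuous scores) are averaged across folds, and
across patients with equal weight. Patients with fewer than 10 seizures in
either class are excluded with a recorded reason.

Hyperparameter grids are small and standard, sized for tens to hundreds of
samples: ridge strength and SVM cost on log grids, k ∈ {3, 5, 7, 11, 15},
tree depth ∈ {2, 3, 5, 8, unbounded}, forest {100, 300} trees × depth
{3, 8, unbounded}.

One deliberate deviation from common practice: the linear SVM's scores are
its decision values mapped through a logistic link rather than Platt-scaled
probabilities. libsvm's Platt scaling runs an internal cross-validation on
process-global RNG state, which would break exact reproducibility under a
fixed seed; the logistic map preserves the ranking (hence AUC) and places
the 0.5 threshold exactly at the SVM's decision boundary.

Two closed-form baselines calibrate the metrics
(`baseline_performance()`): with positive-class prevalence $r$ and a
chance predictor emitting positives with probability $q$, both baselines
have precision $r$; recall is $q$ versus 1; F1 is $2rq/(r+q)$ versus
$2r/(r+1)$; AUC is 0.5 for the chance predictor and undefined for the
always-positive one. These formulas reproduce reference per-patient baseline
tables exactly from the class sizes.

`sample_size_sweep()` studies learning curves: a fixed stratified 20 % test
set, training subsets of the remaining pool (fractions 20–100 % or counts
$2^y$), five repetitions per size. The swept model trains with its default
hyperparameters (no inner selection), so repetition scatter reflects
sampling alone. `characteristic_association()` relates per-patient AUC to
patient characteristics with rank-based tests.

## The synthetic-data generator

No public recording accompanies the methodology, so `simulate_dataset()`
generates the study conditions with known ground truth.

**Schedules** follow an alternating-renewal process: blocks (one isolated
seizure, or a cluster of ≥ 2 seizures with geometric size, mean 3) separated
by gaps strictly above the ISI cutoff (cutoff + exponential excess, mean
36 h), with intra-cluster offset-to-onset gaps log-normal (mean 3 h)
truncated strictly below the cutoff. A renewal construction was chosen over
a self-exciting (Hawkes) process because it makes the true category of every
seizure auditable by construction — taxonomy recovery must be *exact*, and
is tested as such. Seizure durations are log-normal with mean 39 s and SD
63.6 s, truncated to [5 s, 600 s]; default rates give roughly equal numbers
of isolated-seizure and cluster blocks, and default recording length is 550
days at 400 Hz with 16 contacts, matching a chronic ambulatory implant
study.

**Signals** are materialized per seizure window (up to 10 min pre-ictal plus
the ictal period — nothing outside those windows is ever read downstream,
and multi-month continuous recordings would not fit in memory). Each contact
is a sum of independent band-limited Gaussian noise components, one per
physiologic band (white noise through the band's order-2 Butterworth filter)
with a 1/f-like amplitude profile across bands. Ictal samples additionally
ride an amplitude ramp (×3 background by default) so seizures are
morphologically distinguishable; no spike morphology is modeled because REN
does not require it.

**The type effect** is injected as multiplicative band gains drawn per
contact and per 0.5 s sub-block with log-normal spread. Two channels with
independently varying gains have amplitude distributions that are Gaussian
*scale mixtures*; a larger gain spread means heavier tails and hence larger
cross-channel REN. Crucially, the gain blocks (0.5 s) are shorter than the
analysis segments (2.5 s): a gain constant over a whole segment would be
removed exactly by the per-segment variance normalization, so the
heterogeneity must live *inside* the segment for any effect to survive
preprocessing. For cluster seizures the spread within the effect bands
(beta and gamma by default) is multiplied by `1 + effect_near` in the
near-seizure period and divided by `1 + effect_ictal` ictally, producing
the configured directionality: higher near-seizure REN and lower ictal REN
for cluster seizures. With both effects zero the two types are statistically
identical by construction, which is the basis of the null-calibration tests.

**Seizure-to-seizure variability** is injected as a per-seizure log-normal
multiplier on the gain spread (`seizure_spread_jitter`, log-SD 0.3 by
default, applied identically to both seizure types). This term matters more
than it may look: the grand average pools 66 pairs × hundreds of segments,
so without a seizure-level random effect the Monte-Carlo noise of the
features is tiny and the two classes separate almost perfectly at *any*
nonzero effect size — classifiers would reach their ceiling from a handful
of training samples, which no real recording exhibits. With the jitter,
within-class feature SD is comparable to moderate between-class shifts and
learning curves become informative.

Default effect sizes (`effect_near = 2`, i.e. a 3× spread ratio, and
`effect_ictal = 1`) were fixed by a pre-build Monte-Carlo as values at which
the group difference is unambiguous at ~50 seizures per group; a "moderate"
setting (`effect_near = 0.6`), fixed by the same Monte-Carlo, leaves visible
class overlap (test AUC rising from ~0.62 at 16 training samples to ~0.74 at
128) and is used for learning-curve experiments.

**What the generator does not emulate:** real ictal electrographic
morphology, spatially structured (lead-dependent) correlations, physiologic
nonstationarity across months, medication effects, and telemetry drop-outs
(the study this emulates excluded patients with significant data drops; the
generator does not model drops). Passing tests on synthetic data therefore
demonstrate that the *machinery* — windowing, estimation, testing,
cross-validation — is correct and calibrated, not that any particular
effect size holds in clinical recordings.

## Validation strategy and problem sizes

The test suite runs entirely on data generated in code, at sizes chosen to
balance statistical resolution against desk-scale runtimes:

* Signal-bearing fixtures use **fs = 100 Hz** (comfortably above twice the
  45 Hz gamma edge); the 400 Hz default is exercised by unit tests. One
  patient with ~200 seizures (≥ 50 per comparison group) carries the
  effect-recovery checks; an equally sized zero-effect patient carries the
  null checks; a ~120-seizure moderate-effect patient carries the
  learning-curve property.
* **Null calibration** of the Wilcoxon/BH stage uses 200 replicate families
  obtained by permuting the (exchangeable, zero-effect) seizure-type labels
  of the null patient's features; the features themselves come from the
  full signal pipeline. Fully independent signal replicates at this count
  would add nothing statistically — under the null the labels are
  exchangeable by construction — while costing hours.
* Oracle equivalences are exact-tolerance (1e-12) comparisons against
  independently coded brute-force implementations: histogram-KL REN,
  pairwise-definition taxonomy, BH step-up, and exhaustive rank-sum
  enumeration.

## Known limitations

* REN trajectories *within* a seizure are averaged away by design; temporal
  modeling is out of scope.
* The ISI taxonomy is threshold-based; rate-adaptive or change-point cluster
  definitions are cited alternatives, not implemented.
* Probability outputs of the classifiers are not calibrated; metrics that
  depend only on ranking (AUC) or on the 0.5 threshold are reported.
* The raw-binary + JSON signal container is the package's interchange
  format; EDF export is not provided.
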