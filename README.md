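# seizREN

Individualized analysis and prediction of **seizure clustering** from chronic
multichannel intracranial EEG (iEEG), built around a bivariate feature:
band-resolved **relative entropy (REN)** between channel pairs.

Seizure clusters — several seizures in rapid succession — carry a higher risk
of progression to prolonged seizures or status epilepticus. Right after a
seizure, two questions matter clinically: *will another seizure occur soon?*
and *was this the first seizure of a cluster?* seizREN implements a complete
pipeline for both, intended for researchers working with long-term iEEG and
seizure annotations:

* **Preprocessing** — bipolar montage over consecutive contacts (12 bipolar
  channels for the default 16-contact, two-assembly layout), ictal and
  near-seizure (≤ 10 min pre-ictal, truncated at the previous seizure's end)
  windows, 2.5 s non-overlapping segments aligned to onset, order-2
  Butterworth band-pass into delta/theta/alpha/beta/gamma, per-segment
  z-normalization.
* **REN features** — for channels *x*, *y* with segment amplitude
  distributions *p*, *q* (shared-edge histograms),
  `REN(x, y) = max(KL(p‖q), KL(q‖p))` in nats; averaged over all 66 channel
  pairs and all segments per seizure, band, and period → 10 features per
  seizure (5 bands × 2 periods).
* **Taxonomy** — inter-seizure-interval clustering (24 h cutoff, 8 h for
  robustness): isolated / cluster-first / cluster-non-last / cluster-last.
* **Statistics** — Wilcoxon rank-sum comparisons of grand-average REN between
  seizure types per band and period, Benjamini–Hochberg FDR correction,
  direction tallies.
* **Prediction** — individualized classifiers (logistic regression, linear
  SVM, k-NN, decision tree, random forest) under nested stratified 5-fold
  cross-validation with inverse-class-frequency sample weights; closed-form
  analytic baselines (chance-level: precision *r*, recall *q*,
  F1 = 2*rq*/(r+q), AUC 0.5; always-positive: precision *r*, recall 1,
  F1 = 2*r*/(r+1)); training-set-size sweeps; patient-characteristic
  association tests.
* **Synthetic data** — a generator producing seizure schedules and
  multichannel signals with known ground-truth type effects, so the entire
  pipeline is testable without clinical recordings.

## Worked example

```r
library(seizREN)

# one synthetic patient: 120 days, 100 Hz, strong near-seizure beta/gamma effect
cfg <- sim_config(n_patients = 1, recording_days = 120, fs = 100,
                  effect_near = 2, effect_ictal = 1, seed = 7)
ds <- simulate_dataset(cfg)
feats <- compute_features(ds)
lab <- label_seizures(ds$annotations, taxonomy_config(isi_threshold_h = 24))
fl <- merge(feats, lab[c("patient_id", "seizure_id", "category",
                         "is_cluster_first", "cluster_id")],
            by = c("patient_id", "seizure_id"))

aggregate(ga_ren_beta_near_seizure ~ category, fl, mean)
#>           category ga_ren_beta_near_seizure
#> 1     cluster_last                0.2183579
#> 2 cluster_non_last                0.2116662
#> 3         isolated                0.1200572
```

Near-seizure beta REN is roughly twice as high for cluster seizures as for
isolated ones — the planted effect. The rank-sum/FDR stage finds it:

```r
cells <- compare_ren_groups(fl)
direction_tally(cells)
#>         period cluster_higher isolated_higher
#> 1 near_seizure             11               0
#> 2        ictal              0               5
```

Eleven significant near-seizure cells, all with higher REN for cluster
seizures, and the reversed direction ictally. The analytic baselines for any class split
come from the closed forms, e.g. 28 negatives vs 648 positives:

```r
baseline_table(n_neg = 28, n_pos = 648)
#>     baseline precision recall   f1 auc n_neg n_pos         r
#> 1 baseline_1      95.9     50 65.7  50    28   648 0.9585799
#> 2 baseline_2      95.9    100 97.9  NA    28   648 0.9585799
```

Individualized prediction with nested CV (here random forest only):

```r
rep <- run_task(fl, "next_seizure", cv_config(families = "random_forest", seed = 1))
rep$across_patients[c("family", "auc_mean", "auc_sd")]
#>          family auc_mean auc_sd
#> 1 random_forest    0.694  0.166
```

(89 seizures; the fold scatter reflects the small per-fold test sets.)

The orchestrated pipeline (simulate → features → label → stats → predict)
with stage skipping and a manifest:

```r
run_pipeline(pipeline_config(sim = list(n_patients = 2, recording_days = 30,
                                        fs = 100), seed = 1),
             out_dir = "runs/demo")
```

or from a shell: `Rscript inst/scripts/seizren-pipeline.R --out runs/demo`.

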