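# Shared fixtures, built lazily once per test session. Signal-bearing
# datasets use fs = 100 Hz (well above twice the gamma upper edge) to keep
# run times reasonable; all other generator settings are the package
# defaults unless a test is explicitly about changing them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# features merged with taxonomy labels at the generator's own threshold
labeled_features <- function(ds, threshold_h = ds$config$isi_threshold_h) {
  feats <- compute_features(ds)
  lab <- label_seizures(ds$annotations, taxonomy_config(threshold_h))
  merge(feats,
        lab[c("patient_id", "seizure_id", "category", "is_cluster_first",
              "cluster_id")],
        by = c("patient_id", "seizure_id"))
}

# build a dataset, extract labeled features, and drop the raw signals
# (fixtures only consume annotations, truth, and features; keeping several
# hundred 16-contact windows alive would dominate memory)
build_fixture <- function(cfg) {
  ds <- simulate_dataset(cfg)
  feats <- labeled_features(ds)
  ds$signals <- NULL
  gc(verbose = FALSE)
  list(dataset = ds, features = feats)
}

# one patient, strong near-seizure/ictal beta-gamma effect (~220 seizures,
# at least 50 per comparison group)
fx_effect <- function() fixture("effect", function() {
  build_fixture(sim_config(n_patients = 1, recording_days = 300, fs = 100,
                           effect_near = 2, effect_ictal = 1, seed = 101))
})

# one patient, zero effect (~200 seizures): the null study
fx_null <- function() fixture("null", function() {
  build_fixture(sim_config(n_patients = 1, recording_days = 280, fs = 100,
                           effect_near = 0, effect_ictal = 0, seed = 202))
})

# one patient, moderate effect (~280 seizures): learning-curve material
# (effect size fixed by a pre-build Monte-Carlo so small training sets
# genuinely underfit while the full pool does not)
fx_moderate <- function() fixture("moderate", function() {
  build_fixture(sim_config(n_patients = 1, recording_days = 300, fs = 100,
                           effect_near = 0.6, effect_ictal = 0.3, seed = 303))
})

# synthetic feature table with a cleanly separable class structure
# (no signals involved; for exercising the CV machinery directly)
separable_features <- function(n_pos = 30, n_neg = 30, sd = 0.1, seed = 5,
                               patient = "px") {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- n_pos + n_neg
  cols <- feature_columns()
  df <- data.frame(patient_id = patient, seizure_id = seq_len(n),
                   onset_s = seq_len(n) * 1e5,
                   category = c(rep("cluster_non_last", n_pos),
                                rep("isolated", n_neg)),
                   is_cluster_first = FALSE, stringsAsFactors = FALSE)
  for (col in cols) df[[col]] <- rnorm(n, 0, 1)
  df$ga_ren_beta_near_seizure <- c(rnorm(n_pos, 3, sd), rnorm(n_neg, -3, sd))
  df
}
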