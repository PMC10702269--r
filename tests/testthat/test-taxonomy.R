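test_that("taxonomy labels match the pairwise-definition oracle on random schedules", {
  for (i in seq_len(200)) {
    ev <- random_schedule(n = sample(3:25, 1), seed = i)
    for (thr in c(24, 8)) {
      lab <- label_seizures(ev, taxonomy_config(thr))
      orc <- oracle_labels(ev$onset_s, ev$offset_s, thr * 3600)
      expect_identical(lab$category, orc$category)
      expect_identical(lab$is_cluster_first, orc$is_cluster_first)
    }
  }
})

test_that("worked examples: single seizure, 24 h chain, threshold ties", {
  one <- data.frame(patient_id = "a", onset_s = 100, offset_s = 160)
  expect_equal(label_seizures(one)$category, "isolated")

  # onsets at hours 0, 10, 20, 100 with short durations, 24 h cutoff:
  # first three chain into one cluster, the fourth stands alone
  ev <- data.frame(patient_id = "a", onset_s = c(0, 10, 20, 100) * 3600,
                   offset_s = c(0, 10, 20, 100) * 3600 + 60)
  lab <- label_seizures(ev, taxonomy_config(24))
  expect_equal(lab$category, c("cluster_non_last", "cluster_non_last",
                               "cluster_last", "isolated"))
  expect_equal(lab$is_cluster_first, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(lab$cluster_id, c(1L, 1L, 1L, NA_integer_))

  # a gap of exactly the threshold counts as within the cluster
  tie <- data.frame(patient_id = "a", onset_s = c(0, 24 * 3600 + 60),
                    offset_s = c(60, 24 * 3600 + 120))
  lab_tie <- label_seizures(tie, taxonomy_config(24))
  expect_equal(lab_tie$category, c("cluster_non_last", "cluster_last"))
  # the first member of a 2-seizure cluster is both first and non-last
  expect_true(lab_tie$is_cluster_first[1])

  # ISI reference matters for long seizures: 23 h offset-to-onset but 25 h
  # onset-to-onset straddles the 24 h cutoff
  long <- data.frame(patient_id = "a", onset_s = c(0, 25 * 3600),
                     offset_s = c(2 * 3600, 25 * 3600 + 60))
  expect_equal(label_seizures(long, taxonomy_config(24, "offset_to_onset"))$category,
               c("cluster_non_last", "cluster_last"))
  expect_equal(label_seizures(long, taxonomy_config(24, "onset_to_onset"))$category,
               c("isolated", "isolated"))
})

test_that("isolated set shrinks monotonically as the threshold grows", {
  for (i in 1:50) {
    ev <- random_schedule(n = 20, seed = 1000 + i)
    iso8 <- label_seizures(ev, taxonomy_config(8))$category == "isolated"
    iso24 <- label_seizures(ev, taxonomy_config(24))$category == "isolated"
    expect_true(all(which(iso24) %in% which(iso8)))
  }
})

test_that("generator truth is reproduced exactly at both cutoffs", {
  for (seed in 1:5) {
    for (thr in c(24, 8)) {
      cfg <- sim_config(n_patients = 1, recording_days = 120,
                        isi_threshold_h = thr, seed = seed)
      sch <- simulate_schedule(cfg, 1)
      lab <- label_seizures(sch[c("patient_id", "seizure_id", "onset_s", "offset_s")],
                            taxonomy_config(thr))
      expect_identical(lab$category, sch$true_category)
      expect_identical(lab$is_cluster_first, sch$is_cluster_first)
    }
  }
})

test_that("task classes follow the two task definitions", {
  ev <- data.frame(patient_id = "a", onset_s = c(0, 10, 20, 100) * 3600,
                   offset_s = c(0, 10, 20, 100) * 3600 + 60)
  lab <- label_seizures(ev)
  ns <- task_classes(lab, "next_seizure")
  expect_true(all(ns$included))
  expect_equal(as.character(ns$class), c("pos", "pos", "neg", "neg"))
  co <- task_classes(lab, "cluster_onset")
  expect_equal(sum(co$included), 2L)
  expect_equal(as.character(co$class[co$included]), c("pos", "neg"))

  all_iso <- label_seizures(data.frame(patient_id = "a",
                                       onset_s = c(0, 50, 100) * 86400,
                                       offset_s = c(0, 50, 100) * 86400 + 60))
  expect_true(all(task_classes(all_iso, "next_seizure")$class == "neg"))
})

test_that("patient eligibility needs 10 seizures in each class", {
  mk <- function(n_iso, n_first) {
    # isolated seizures spaced far apart, then 2-seizure clusters
    on_iso <- seq_len(n_iso) * 3 * 86400
    on_cl <- max(on_iso, 0) + seq_len(n_first) * 3 * 86400
    ev <- data.frame(
      patient_id = "a",
      onset_s = c(on_iso, as.vector(rbind(on_cl, on_cl + 3600))),
      offset_s = c(on_iso, as.vector(rbind(on_cl, on_cl + 3600))) + 60)
    label_seizures(ev)
  }
  expect_false(patient_eligible(mk(20, 4), "cluster_onset")$eligible)
  expect_true(patient_eligible(mk(10, 10), "cluster_onset")$eligible)
  expect_false(patient_eligible(mk(20, 0), "cluster_onset")$eligible)
  expect_match(patient_eligible(mk(20, 4), "cluster_onset")$reason, "below minimum")
})
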