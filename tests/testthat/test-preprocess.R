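test_that("default montage yields 12 bipolar pairs of consecutive contacts", {
  layout <- montage_layout()
  expect_equal(layout$n_contacts, 16L)
  expect_equal(nrow(layout$pairs), 12L)
  # consecutive within arrays, never across array boundaries
  expect_true(all(layout$pairs[, "j"] - layout$pairs[, "i"] == 1L))
  expect_false(any(layout$pairs[, "i"] %% layout$contacts_per_array == 0L))
})

test_that("make_bipolar subtracts consecutive contacts (impulse oracle)", {
  layout <- montage_layout()
  n <- 64L
  # unit impulses at distinct times per contact: differences verified sample-wise
  raw <- matrix(0, 16, n)
  for (ct in 1:16) raw[ct, ct * 3L] <- 1
  bp <- make_bipolar(raw, layout)
  expect_equal(dim(bp), c(12L, n))
  for (k in seq_len(12L)) {
    expect_equal(unname(bp[k, ]),
                 raw[layout$pairs[k, "i"], ] - raw[layout$pairs[k, "j"], ])
  }
  # identical contacts cancel exactly
  same <- matrix(rnorm(n), 16, n, byrow = TRUE)
  expect_true(all(make_bipolar(same, layout) == 0))
  expect_error(make_bipolar(raw[1:10, ], layout), "mismatch")
})

test_that("near-seizure windows honor the 10-minute cap and truncation", {
  ev <- seizure_events(data.frame(patient_id = "a", onset_s = 7200, offset_s = 7239))
  w <- extract_windows(ev)
  near <- w[w$period == "near_seizure", ]
  expect_equal(near$start_s, 6600)
  expect_equal(near$end_s, 7200)
  expect_equal(w[w$period == "ictal", c("start_s", "end_s")],
               data.frame(start_s = 7200, end_s = 7239), ignore_attr = TRUE)

  # previous seizure ends 120 s before onset -> truncated window of 120 s
  ev2 <- seizure_events(data.frame(patient_id = "a",
                                   onset_s = c(1000, 1220),
                                   offset_s = c(1100, 1260)))
  w2 <- extract_windows(ev2)
  n2 <- w2[w2$period == "near_seizure" & w2$seizure_id == 2, ]
  expect_equal(n2$end_s - n2$start_s, 120)

  # previous seizure ends exactly at onset -> empty window, zero segments
  ev3 <- seizure_events(data.frame(patient_id = "a",
                                   onset_s = c(1000, 1100),
                                   offset_s = c(1100, 1160)))
  w3 <- extract_windows(ev3)
  n3 <- w3[w3$period == "near_seizure" & w3$seizure_id == 2, ]
  expect_equal(n3$end_s - n3$start_s, 0)
  seg <- segment_and_filter(matrix(rnorm(2 * 100), 2), fs = 100, t0 = 1099,
                            n3, band_specs())
  expect_equal(dim(seg$data)[1], 0L)

  expect_error(seizure_events(data.frame(patient_id = "a",
                                         onset_s = c(0, 50),
                                         offset_s = c(60, 80))),
               "overlap")
})

test_that("segment counts follow floor(window / 2.5 s) and tile from onset", {
  fs <- 100
  bands <- band_specs()
  # 600 s near-seizure window -> 240 segments
  w_near <- data.frame(period = "near_seizure", start_s = 600, end_s = 1200)
  x <- matrix(rnorm(2 * (600 * fs + 10)), 2)
  seg <- segment_and_filter(x, fs, t0 = 600, w_near, bands)
  expect_equal(dim(seg$data)[1], 240L)
  expect_equal(dim(seg$data)[4], 250L)

  # 39 s ictal window -> 15 segments, partial tail dropped
  w_ict <- data.frame(period = "ictal", start_s = 1200, end_s = 1239)
  x2 <- matrix(rnorm(2 * round(39 * fs)), 2)
  seg2 <- segment_and_filter(x2, fs, t0 = 1200, w_ict, bands)
  expect_equal(dim(seg2$data)[1], 15L)

  # alignment: a marker at the onset sample lands at the start of the first
  # ictal segment and just after the last near-seizure segment
  w_near2 <- data.frame(period = "near_seizure", start_s = 0, end_s = 6.3)
  expect_equal(dim(segment_and_filter(matrix(rnorm(2 * 630), 2), fs, 0,
                                      w_near2, bands)$data)[1], 2L)
})

test_that("every retained series is z-normalized within 1e-6", {
  fs <- 100
  w <- data.frame(period = "ictal", start_s = 0, end_s = 10)
  x <- matrix(rnorm(3 * 1000), 3)
  seg <- segment_and_filter(x, fs, t0 = 0, w, band_specs())
  d <- dim(seg$data)
  for (s in seq_len(d[1])) for (ch in seq_len(d[2])) for (b in seq_len(d[3])) {
    v <- seg$data[s, ch, b, ]
    expect_lt(abs(mean(v)), 1e-6)
    expect_lt(abs(var(v) - 1), 1e-6)
  }
})

test_that("band filtering is zero-phase and attenuates stop-band tones", {
  fs <- 100
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  tone10 <- sin(2 * pi * 10 * t)   # alpha band (8-12 Hz)
  tone30 <- sin(2 * pi * 30 * t)   # gamma band (25-45 Hz)
  x <- rbind(tone10 + tone30, tone10 + tone30)
  w <- data.frame(period = "ictal", start_s = 5, end_s = 25)  # skip edges
  seg <- segment_and_filter(x, fs, t0 = 0, w, band_specs())
  alpha_idx <- which(seg$band_names == "alpha")
  n_samp <- dim(seg$data)[4]
  for (s in seq_len(dim(seg$data)[1])) {
    seg_t <- t[(round((5 + (s - 1) * 2.5) * fs) + 1):(round((5 + (s - 1) * 2.5) * fs) + n_samp)]
    basis <- cbind(sin(2 * pi * 10 * seg_t), cos(2 * pi * 10 * seg_t),
                   sin(2 * pi * 30 * seg_t), cos(2 * pi * 30 * seg_t))
    coef <- coef(lm(seg$data[s, 1, alpha_idx, ] ~ basis - 1))
    amp10 <- sqrt(sum(coef[1:2]^2)); amp30 <- sqrt(sum(coef[3:4]^2))
    # stop-band tone attenuated >= 90% relative to the pass-band tone
    expect_lt(amp30 / amp10, 0.1)
    # zero phase: the pass-band tone keeps its phase (sine, not quadrature)
    expect_gt(abs(coef[1]) / amp10, 0.99)
  }
})

test_that("degenerate (constant) segments are excluded, not NaN-propagated", {
  fs <- 100
  w <- data.frame(period = "ictal", start_s = 0, end_s = 5)
  x <- matrix(0, 2, 500)  # all-zero signal: constant after filtering
  expect_message(seg <- segment_and_filter(x, fs, 0, w, band_specs()),
                 "degenerate")
  expect_equal(dim(seg$data)[1], 0L)
  expect_equal(seg$dropped, 2L)
})
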