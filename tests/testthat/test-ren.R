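test_that("amplitude distributions match a direct tally", {
  set.seed(11)
  cfg <- ren_config(n_bins = 10, smoothing_eps = 1e-10)
  x <- rnorm(1000)
  edges <- seq(min(x), max(x), length.out = 11)
  p <- amplitude_distribution(x, cfg, edges)
  tally <- vapply(seq_len(10), function(b) {
    hi_ok <- if (b == 10) x <= edges[b + 1] else x < edges[b + 1]
    sum(x >= edges[b] & hi_ok)
  }, numeric(1))
  expect_equal(sum(p), 1)
  expect_equal(p, (tally / 1000 + 1e-10) / sum(tally / 1000 + 1e-10),
               tolerance = 1e-12)
  expect_true(all(p > 0))  # smoothing keeps every bin positive

  # constant series: all mass in one bin (pre-smoothing)
  pc <- amplitude_distribution(rep(0, 100), cfg, seq(-1, 1, length.out = 11))
  expect_equal(max(pc), (1 + 1e-10) / (1 + 10 * 1e-10), tolerance = 1e-9)
  expect_error(amplitude_distribution(rnorm(5), cfg, edges), "samples")
})

test_that("two-bin REN reproduces the closed-form KL values", {
  # p = (0.5, 0.5) vs q = (0.9, 0.1): KL(p||q) = 0.5108, KL(q||p) = 0.3680
  cfg <- ren_config(n_bins = 2, smoothing_eps = 1e-12)
  x <- c(rep(0.25, 500), rep(0.75, 500))
  y <- c(rep(0.25, 900), rep(0.75, 100))
  expect_equal(relative_entropy(x, y, cfg),
               0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1), tolerance = 1e-3)
  expect_equal(relative_entropy(x, y, cfg), 0.5108, tolerance = 1e-3)
  # the maximum of the two directions is returned (KL(q||p) = 0.3680 < REN)
  expect_gt(relative_entropy(x, y, cfg), 0.5)
})

test_that("REN is zero for identical series, symmetric, and nonnegative", {
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(500); y <- rnorm(500, sd = runif(1, 0.5, 2))
    expect_equal(relative_entropy(x, x), 0, tolerance = 1e-12)
    expect_identical(relative_entropy(x, y), relative_entropy(y, x))
    expect_gte(relative_entropy(x, y), 0)
  }
  expect_error(relative_entropy(rep(1, 100), rep(1, 100)), "degenerate")
})

test_that("R path, compiled kernel, and brute-force oracle agree to 1e-12", {
  set.seed(13)
  n_pairs <- 0L
  for (rep_i in 1:6) {
    # small segment tensors with varied shapes (heavy/light tails, scales)
    n_seg <- 3L; n_ch <- 4L; n_band <- 2L; n_samp <- 200L
    data <- array(rnorm(n_seg * n_ch * n_band * n_samp), c(n_seg, n_ch, n_band, n_samp))
    if (rep_i %% 2 == 0) data <- sign(data) * abs(data)^1.7  # heavy-tailed
    seg <- structure(list(data = data, fs = 100, period = "ictal",
                          band_names = c("b1", "b2"), segment_len_s = 2,
                          dropped = 0L), class = "segment_tensor")
    cfg <- ren_config()
    res <- ren_all_pairs(seg, cfg)
    pairs <- combn(n_ch, 2)
    for (s in seq_len(n_seg)) for (b in seq_len(n_band)) {
      for (pi in seq_len(ncol(pairs))) {
        x <- data[s, pairs[1, pi], b, ]; y <- data[s, pairs[2, pi], b, ]
        expect_equal(res$values[s, pi, b], relative_entropy(x, y, cfg),
                     tolerance = 1e-12)
        expect_equal(res$values[s, pi, b], oracle_ren(x, y), tolerance = 1e-12)
        n_pairs <- n_pairs + 1L
      }
    }
  }
  expect_gte(n_pairs, 100L)
})

test_that("12 channels give 66 pairs; identical channels give zero REN", {
  one <- rnorm(300)
  data <- array(rep(one, each = 2 * 12), c(2, 12, 1, 300))
  for (s in 1:2) for (ch in 1:12) data[s, ch, 1, ] <- one
  seg <- structure(list(data = data, fs = 100, period = "ictal",
                        band_names = "b", segment_len_s = 3, dropped = 0L),
                   class = "segment_tensor")
  res <- ren_all_pairs(seg)
  expect_equal(dim(res$values), c(2L, 66L, 1L))
  expect_true(all(res$values == 0))
})

test_that("normalization removes scale but not distribution shape", {
  set.seed(14)
  z <- function(v) (v - mean(v)) / sd(v)
  light <- z(runif(1000))                       # sub-Gaussian
  heavy <- z(sign(rnorm(1000)) * abs(rnorm(1000))^2)  # heavy-tailed
  expect_gt(relative_entropy(light, heavy), 0.1)
  # pure rescaling is invisible after z-normalization
  x <- rnorm(1000)
  expect_equal(relative_entropy(z(x), z(3 * x)), 0, tolerance = 1e-12)
})

test_that("grand averages and the feature table follow the arithmetic", {
  vals <- array(c(1, 2, 3, 4), c(2, 2, 1))
  ren <- structure(list(values = vals, pairs = combn(2, 2), band_names = "beta",
                        period = "ictal"), class = "ren_result")
  expect_equal(unname(grand_average(ren)), 2.5)

  const <- structure(list(values = array(0.7, c(3, 66, 5)), pairs = combn(12, 2),
                          band_names = band_specs()$name, period = "near_seizure"),
                     class = "ren_result")
  expect_equal(unname(grand_average(const)), rep(0.7, 5))

  bandn <- band_specs()$name
  ga <- stats::setNames(runif(5), bandn)
  rows <- list(list(patient_id = "a", seizure_id = 1, onset_s = 10,
                    near_seizure = ga, ictal = ga + 1),
               list(patient_id = "a", seizure_id = 2, onset_s = 5,
                    near_seizure = NULL, ictal = ga))
  ft <- assemble_features(rows)
  expect_equal(length(feature_columns()), 10L)
  expect_true(all(feature_columns() %in% names(ft)))
  expect_equal(ft$seizure_id, c(2, 1))  # ordered by onset
  # a seizure with both periods empty is excluded
  rows_bad <- c(rows, list(list(patient_id = "a", seizure_id = 3, onset_s = 99,
                                near_seizure = NULL, ictal = NULL)))
  expect_message(ft2 <- assemble_features(rows_bad), "excluded")
  expect_equal(nrow(ft2), 2L)
})
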