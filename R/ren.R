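#' REN estimation configuration
#'
#' Relative entropy between two channels is estimated from equal-width
#' histograms of the normalized signal amplitudes on bin edges shared by the
#' pair (spanning the pooled range of both series). A small pseudo-probability
#' is added to every bin before renormalization so that empty bins do not
#' produce infinite KL divergence. All values are in nats (natural log).
#'
#' @param n_bins number of histogram bins (>= 2); 10 is sized for segments of
#'   roughly a thousand samples (about 100 expected counts per bin).
#' @param smoothing_eps pseudo-probability added per bin (> 0).
#' @return object of class `ren_config`.
#' @export
ren_config <- function(n_bins = 10L, smoothing_eps = 1e-10) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (!is.numeric(smoothing_eps) || smoothing_eps <= 0)
    stop("smoothing_eps must be > 0")
  structure(list(n_bins = n_bins, smoothing_eps = smoothing_eps,
                 log_base = "nats"),
            class = "ren_config")
}

#' Amplitude distribution of a series on given bin edges
#'
#' @param x numeric series (finite values).
#' @param cfg a [ren_config()].
#' @param edges strictly increasing bin edges of length `n_bins + 1` covering
#'   the range of `x` (values outside are clamped into the end bins).
#' @return probability vector of length `n_bins`: `(count/n + eps)` per bin,
#'   renormalized to sum to 1.
#' @export
amplitude_distribution <- function(x, cfg = ren_config(), edges) {
  stopifnot(inherits(cfg, "ren_config"))
  if (any(!is.finite(x))) stop("x must be finite")
  if (length(x) < cfg$n_bins)
    stop(sprintf("cannot estimate a %d-bin distribution from %d samples",
                 cfg$n_bins, length(x)))
  if (length(edges) != cfg$n_bins + 1L || any(diff(edges) <= 0))
    stop("edges must be strictly increasing with length n_bins + 1")
  bin <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = cfg$n_bins)
  p <- counts / length(x) + cfg$smoothing_eps
  p / sum(p)
}

#' Relative entropy (REN) between two series
#'
#' The amplitude distributions of the two series are estimated on shared
#' equal-width bin edges spanning their pooled range and compared with
#' Kullback-Leibler divergence in both directions; since KL divergence is
#' non-symmetric, REN is the maximum of the two.
#'
#' @param x,y numeric series of equal length (typically normalized segments).
#' @param cfg a [ren_config()].
#' @return non-negative scalar in nats.
#' @examples
#' set.seed(1)
#' relative_entropy(rnorm(1000), rnorm(1000))
#' @export
relative_entropy <- function(x, y, cfg = ren_config()) {
  stopifnot(inherits(cfg, "ren_config"))
  if (length(x) != length(y)) stop("x and y must have equal length")
  rng <- range(c(x, y))
  if (!all(is.finite(rng))) stop("series must be finite")
  if (diff(rng) <= 0)
    stop("degenerate (constant) series: amplitude distribution has zero range")
  edges <- seq(rng[1], rng[2], length.out = cfg$n_bins + 1L)
  p <- amplitude_distribution(x, cfg, edges)
  q <- amplitude_distribution(y, cfg, edges)
  max(sum(p * log(p / q)), sum(q * log(q / p)))
}

#' REN for all channel pairs of a segment tensor
#'
#' Computes relative entropy for every unordered pair of bipolar channels,
#' separately per segment and band (compiled kernel; identical arithmetic to
#' [relative_entropy()]). For 12 channels this yields 66 pairs.
#'
#' @param seg a `segment_tensor` from [segment_and_filter()].
#' @param cfg a [ren_config()].
#' @return object of class `ren_result`: list with `values`, an array
#'   `[segment, pair, band]` of non-negative REN values (nats), `pairs` (2 x
#'   n_pairs matrix of channel indices, as [utils::combn()]), `band_names`,
#'   and `period`.
#' @export
ren_all_pairs <- function(seg, cfg = ren_config()) {
  stopifnot(inherits(seg, "segment_tensor"), inherits(cfg, "ren_config"))
  n_ch <- dim(seg$data)[2]
  pairs <- combn(n_ch, 2L)
  if (dim(seg$data)[1] == 0L) {
    values <- array(numeric(0), dim = c(0L, ncol(pairs), dim(seg$data)[3]))
  } else {
    values <- ren_pairs_kernel(seg$data, cfg$n_bins, cfg$smoothing_eps)
  }
  structure(list(values = values, pairs = pairs,
                 band_names = seg$band_names, period = seg$period),
            class = "ren_result")
}

#' Grand-average REN per band
#'
#' Averages REN over all channel pairs and all segments of one seizure period,
#' separately per band.
#'
#' @param ren a `ren_result` from [ren_all_pairs()].
#' @return named numeric vector (one mean per band); `NA` per band if the
#'   period contributed no segments.
#' @export
grand_average <- function(ren) {
  stopifnot(inherits(ren, "ren_result"))
  n_band <- dim(ren$values)[3]
  out <- vapply(seq_len(n_band), function(b) {
    v <- ren$values[, , b]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  names(out) <- ren$band_names
  out
}

#' Assemble the per-seizure feature table
#'
#' Builds one row per seizure with the 10 grand-average REN features
#' (5 bands x 2 periods, columns `ga_ren_<band>_<period>`). Seizures whose
#' periods both contributed no segments are excluded. Rows are ordered by
#' patient and onset time.
#'
#' @param rows list of per-seizure lists with elements `patient_id`,
#'   `seizure_id`, `onset_s`, `near_seizure` and `ictal` (named band vectors
#'   from [grand_average()], or NULL if the period is missing).
#' @param band_names band names in canonical order.
#' @return data.frame feature table.
#' @export
assemble_features <- function(rows, band_names = band_specs()$name) {
  feat_cols <- c(paste0("ga_ren_", band_names, "_near_seizure"),
                 paste0("ga_ren_", band_names, "_ictal"))
  recs <- lapply(rows, function(r) {
    near <- r$near_seizure
    ict <- r$ictal
    if (is.null(near)) near <- stats::setNames(rep(NA_real_, length(band_names)), band_names)
    if (is.null(ict)) ict <- stats::setNames(rep(NA_real_, length(band_names)), band_names)
    if (all(is.na(near)) && all(is.na(ict))) return(NULL)
    vals <- c(near[band_names], ict[band_names])
    df <- data.frame(patient_id = r$patient_id, seizure_id = r$seizure_id,
                     onset_s = r$onset_s, stringsAsFactors = FALSE)
    df[feat_cols] <- as.list(unname(vals))
    df
  })
  dropped <- sum(vapply(recs, is.null, logical(1)))
  if (dropped > 0L)
    message(sprintf("assemble_features: excluded %d seizure(s) with no usable segments", dropped))
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0L) stop("no seizures with usable segments")
  out <- do.call(rbind, recs)
  out <- out[order(out$patient_id, out$onset_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Feature-column names of a feature table
#' @param bands band table ([band_specs()]).
#' @return character vector of the 10 feature column names.
#' @export
feature_columns <- function(bands = band_specs()) {
  c(paste0("ga_ren_", bands$name, "_near_seizure"),
    paste0("ga_ren_", bands$name, "_ictal"))
}

#' Compute REN features for a synthetic dataset
#'
#' End-to-end feature extraction: bipolar montage, window extraction,
#' band-filtered 2.5 s segmentation, all-pairs REN, and per-seizure grand
#' averages for both periods.
#'
#' @param dataset a `synthetic_dataset` from [simulate_dataset()] (or any list
#'   with the same structure holding per-seizure window signals).
#' @param bands band table ([band_specs()]).
#' @param ren_cfg a [ren_config()].
#' @param layout a [montage_layout()].
#' @return feature table (see [assemble_features()]).
#' @export
compute_features <- function(dataset, bands = band_specs(),
                             ren_cfg = ren_config(), layout = montage_layout()) {
  ann <- seizure_events(dataset$annotations)
  windows <- extract_windows(ann)
  rows <- list()
  for (pid in names(dataset$signals)) {
    pat <- dataset$signals[[pid]]
    ann_p <- ann[ann$patient_id == pid, , drop = FALSE]
    win_p <- windows[windows$patient_id == pid, , drop = FALSE]
    for (k in seq_len(nrow(ann_p))) {
      sid <- ann_p$seizure_id[k]
      chunk <- pat$seizures[[k]]
      bp <- make_bipolar(chunk$signal, layout)
      per <- list(near_seizure = NULL, ictal = NULL)
      for (pd in c("near_seizure", "ictal")) {
        w <- win_p[win_p$seizure_id == sid & win_p$period == pd, , drop = FALSE]
        seg <- segment_and_filter(bp, pat$fs, chunk$t0, w, bands)
        if (dim(seg$data)[1] > 0L)
          per[[pd]] <- grand_average(ren_all_pairs(seg, ren_cfg))
      }
      rows[[length(rows) + 1L]] <- list(
        patient_id = pid, seizure_id = sid, onset_s = ann_p$onset_s[k],
        near_seizure = per$near_seizure, ictal = per$ictal
      )
    }
  }
  assemble_features(rows, band_names = bands$name)
}
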