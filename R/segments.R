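# zero-phase (forward-backward) application of an IIR filter with edge
# reflection padding to suppress start-up transients (compiled; at 60 filter
# runs per seizure the per-call cost of the ts-based wrappers dominates)
zero_phase_filter <- function(bf, x) {
  zero_phase_kernel(as.numeric(x), bf$b, bf$a, 150L)
}

#' Band-filter and segment a window of bipolar iEEG
#'
#' Slices one analysis window into non-overlapping 2.5 s segments aligned to
#' seizure onset, band-pass filters every channel into the physiologic bands
#' (order-2 Butterworth, applied forward-backward for zero phase), and
#' z-normalizes every (segment, channel, band) series to zero mean and unit
#' variance.
#'
#' Segments tile backward from onset for the near-seizure period (the window
#' end) and forward from onset for the ictal period (the window start), so a
#' segment boundary always coincides with the onset sample; the partial
#' remainder at the far end of the window is dropped. Segments in which any
#' (channel, band) series is constant after filtering are excluded and
#' counted in the `dropped` attribute.
#'
#' @param bipolar numeric matrix, channels x samples, covering the window.
#' @param fs sampling rate in Hz.
#' @param t0 absolute time (s) of the first column of `bipolar`.
#' @param window one row of [extract_windows()] output (needs `period`,
#'   `start_s`, `end_s`).
#' @param bands band table from [band_specs()].
#' @param segment_len_s segment length in seconds (2.5).
#' @return An object of class `segment_tensor`: list with `data`, a 4-d array
#'   `[segment, channel, band, sample]` in chronological segment order, plus
#'   `fs`, `period`, `band_names`, and `dropped` (count of excluded segments).
#'   Zero segments yield a zero-extent array.
#' @export
segment_and_filter <- function(bipolar, fs, t0, window, bands = band_specs(),
                               segment_len_s = 2.5) {
  stopifnot(is.matrix(bipolar), nrow(bipolar) >= 1L)
  validate_bands(bands, fs)
  period <- as.character(window$period)
  if (!period %in% c("near_seizure", "ictal")) stop("unknown period: ", period)
  w_len <- window$end_s - window$start_s
  if (w_len < 0) stop("window has negative length")
  n_samp_seg <- round(segment_len_s * fs)
  n_seg <- floor(w_len / segment_len_s + 1e-9)
  n_ch <- nrow(bipolar)
  n_band <- nrow(bands)

  empty <- function(dropped = 0L) {
    structure(list(
      data = array(numeric(0), dim = c(0L, n_ch, n_band, n_samp_seg)),
      fs = fs, period = period, band_names = bands$name,
      segment_len_s = segment_len_s, dropped = dropped
    ), class = "segment_tensor")
  }
  if (n_seg == 0L) return(empty())

  # segment boundaries anchored at onset: near-seizure tiles backward from the
  # window end (= onset), ictal tiles forward from the window start (= onset)
  if (period == "near_seizure") {
    seg_starts <- window$end_s - rev(seq_len(n_seg)) * segment_len_s
  } else {
    seg_starts <- window$start_s + (seq_len(n_seg) - 1L) * segment_len_s
  }
  # map continuous time to half-open sample ranges; onset maps to its floor sample
  idx0 <- floor((seg_starts - t0) * fs + 1e-9)  # 0-based first sample per segment
  if (any(idx0 < 0) || any(idx0 + n_samp_seg > ncol(bipolar)))
    stop("window extends outside the provided signal")

  filters <- lapply(seq_len(n_band), function(b)
    signal::butter(2, c(bands$lo[b], bands$hi[b]) / (fs / 2), type = "pass"))

  # segments are contiguous and equally spaced, so each (channel, band)
  # series slices into an n_samp x n_seg matrix for vectorized normalization
  data <- array(NA_real_, dim = c(n_seg, n_ch, n_band, n_samp_seg))
  keep <- rep(TRUE, n_seg)
  contiguous <- all(diff(idx0) == n_samp_seg)
  span <- (idx0[1L] + 1L):(idx0[n_seg] + n_samp_seg)
  for (ch in seq_len(n_ch)) {
    for (b in seq_len(n_band)) {
      y <- zero_phase_filter(filters[[b]], bipolar[ch, ])
      ymat <- if (contiguous) matrix(y[span], nrow = n_samp_seg) else
        vapply(seq_len(n_seg), function(s) y[(idx0[s] + 1L):(idx0[s] + n_samp_seg)],
               numeric(n_samp_seg))
      ymat <- sweep(ymat, 2L, colMeans(ymat))
      sds <- sqrt(colSums(ymat^2) / (n_samp_seg - 1L))
      bad <- !is.finite(sds) | sds < 1e-12
      keep[bad] <- FALSE
      sds[bad] <- 1
      data[, ch, b, ] <- t(sweep(ymat, 2L, sds, "/"))
    }
  }
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(sprintf("segment_and_filter: excluded %d degenerate segment(s) (%s)",
                    dropped, period))
    if (all(!keep)) return(empty(dropped))
    data <- data[keep, , , , drop = FALSE]
  }
  structure(list(
    data = data, fs = fs, period = period, band_names = bands$name,
    segment_len_s = segment_len_s, dropped = dropped
  ), class = "segment_tensor")
}

#' @export
print.segment_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<segment_tensor> %s: %d segments x %d channels x %d bands x %d samples (fs = %g Hz, %d dropped)\n",
              x$period, d[1], d[2], d[3], d[4], x$fs, x$dropped))
  invisible(x)
}
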