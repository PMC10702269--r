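#' Validate a seizure annotation table
#'
#' Annotations carry one row per seizure with absolute recording times in
#' seconds. Within each patient, events must be time-ordered and
#' non-overlapping.
#'
#' @param events data.frame with columns `patient_id`, `onset_s`, `offset_s`
#'   (a `seizure_id` column is added when absent, numbering events per patient
#'   in onset order).
#' @return the validated (and possibly reordered) data.frame.
#' @export
seizure_events <- function(events) {
  req <- c("patient_id", "onset_s", "offset_s")
  if (!is.data.frame(events) || !all(req %in% names(events)))
    stop("events must be a data.frame with columns patient_id, onset_s, offset_s")
  if (any(!is.finite(events$onset_s)) || any(!is.finite(events$offset_s)))
    stop("onset_s/offset_s must be finite")
  if (any(events$offset_s <= events$onset_s))
    stop("every seizure must have offset_s > onset_s")
  events <- events[order(events$patient_id, events$onset_s), , drop = FALSE]
  for (pid in unique(events$patient_id)) {
    e <- events[events$patient_id == pid, , drop = FALSE]
    if (nrow(e) > 1L && any(e$onset_s[-1L] < e$offset_s[-nrow(e)]))
      stop(sprintf("overlapping seizures for patient %s", pid))
  }
  if (!"seizure_id" %in% names(events)) {
    events$seizure_id <- stats::ave(seq_len(nrow(events)), events$patient_id,
                                    FUN = seq_along)
  }
  rownames(events) <- NULL
  events
}

#' Extract ictal and near-seizure analysis windows
#'
#' For every seizure, the ictal window is `[onset, offset]` and the
#' near-seizure window covers up to 10 minutes of pre-ictal signal ending at
#' onset. When the previous seizure of the same patient terminated within
#' those 10 minutes, the near-seizure window starts at that termination, so
#' its length is `min(600 s, onset - previous offset)`; a zero-length window
#' (previous seizure ends exactly at onset) is allowed and yields no segments.
#'
#' @param events a validated annotation table (see [seizure_events()]).
#' @param near_max_s maximum near-seizure window length in seconds (600).
#' @return data.frame with columns `patient_id`, `seizure_id`, `period`
#'   (`"near_seizure"` or `"ictal"`), `start_s`, `end_s`.
#' @examples
#' ev <- seizure_events(data.frame(patient_id = 1, onset_s = 7200, offset_s = 7239))
#' extract_windows(ev)  # near-seizure window [6600, 7200]
#' @export
extract_windows <- function(events, near_max_s = 600) {
  events <- seizure_events(events)
  out <- lapply(unique(events$patient_id), function(pid) {
    e <- events[events$patient_id == pid, , drop = FALSE]
    prev_off <- c(-Inf, e$offset_s[-nrow(e)])
    near_start <- pmax(e$onset_s - near_max_s, prev_off, 0)
    rbind(
      data.frame(patient_id = pid, seizure_id = e$seizure_id,
                 period = "near_seizure", start_s = near_start,
                 end_s = e$onset_s, stringsAsFactors = FALSE),
      data.frame(patient_id = pid, seizure_id = e$seizure_id,
                 period = "ictal", start_s = e$onset_s, end_s = e$offset_s,
                 stringsAsFactors = FALSE)
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
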