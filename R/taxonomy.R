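#' Cluster taxonomy configuration
#'
#' Seizures are grouped into clusters when the inter-seizure interval (ISI)
#' does not exceed a cutoff; 24 h is the widely used default and 8 h is
#' provided for robustness analyses. The ISI is measured from the termination
#' (offset) of one seizure to the onset of the next by default, because the
#' clinical question is whether another seizure occurs shortly after the
#' given seizure ends; onset-to-onset measurement is available as an option.
#' A gap exactly equal to the threshold counts as within the same cluster.
#'
#' @param isi_threshold_h ISI cutoff in hours (> 0).
#' @param isi_reference `"offset_to_onset"` (default) or `"onset_to_onset"`.
#' @return object of class `taxonomy_config`.
#' @export
taxonomy_config <- function(isi_threshold_h = 24,
                            isi_reference = c("offset_to_onset", "onset_to_onset")) {
  isi_reference <- match.arg(isi_reference)
  if (!is.numeric(isi_threshold_h) || length(isi_threshold_h) != 1L ||
      !is.finite(isi_threshold_h) || isi_threshold_h <= 0)
    stop("isi_threshold_h must be a single positive number")
  structure(list(isi_threshold_h = isi_threshold_h, isi_reference = isi_reference),
            class = "taxonomy_config")
}

#' Label seizures by the inter-seizure-interval taxonomy
#'
#' Assigns every seizure to one of three disjoint categories: `isolated` (no
#' seizure within the ISI cutoff before or after), `cluster_non_last`
#' (a cluster member followed by another seizure within the cutoff), and
#' `cluster_last` (the final seizure of a cluster). The first seizure of each
#' cluster is additionally flagged `is_cluster_first`; in a two-seizure
#' cluster the first member is both cluster-first and cluster-non-last.
#'
#' @param events annotation table (see [seizure_events()]).
#' @param cfg a [taxonomy_config()].
#' @return the events data.frame augmented with `category`,
#'   `is_cluster_first`, and `cluster_id` (NA for isolated seizures; ids are
#'   per patient in chronological order).
#' @export
label_seizures <- function(events, cfg = taxonomy_config()) {
  stopifnot(inherits(cfg, "taxonomy_config"))
  events <- seizure_events(events)
  thr_s <- cfg$isi_threshold_h * 3600
  out <- lapply(unique(events$patient_id), function(pid) {
    e <- events[events$patient_id == pid, , drop = FALSE]
    n <- nrow(e)
    ref <- if (cfg$isi_reference == "offset_to_onset") e$offset_s else e$onset_s
    gap_next <- if (n > 1L) e$onset_s[-1L] - ref[-n] else numeric(0)
    linked <- gap_next <= thr_s  # ties at the threshold count as clustered
    # cluster membership: maximal runs of linked consecutive seizures
    cluster_id <- rep(NA_integer_, n)
    category <- rep("isolated", n)
    is_first <- rep(FALSE, n)
    cid <- 0L
    i <- 1L
    while (i <= n) {
      j <- i
      while (j < n && linked[j]) j <- j + 1L
      if (j > i) {  # run i..j is a cluster
        cid <- cid + 1L
        cluster_id[i:j] <- cid
        category[i:(j - 1L)] <- "cluster_non_last"
        category[j] <- "cluster_last"
        is_first[i] <- TRUE
      }
      i <- j + 1L
    }
    e$category <- category
    e$is_cluster_first <- is_first
    e$cluster_id <- cluster_id
    e
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Binary classes for the two prediction tasks
#'
#' `next_seizure`: will another seizure occur within the ISI cutoff after the
#' given seizure? Positive class = cluster-non-last; negative = isolated and
#' cluster-last; every seizure is included. `cluster_onset`: is the given
#' seizure the first of a cluster? Positive = cluster-first; negative =
#' isolated; other cluster seizures are excluded.
#'
#' @param labels output of [label_seizures()].
#' @param task `"next_seizure"` or `"cluster_onset"`.
#' @return `labels` with logical `included` and factor `class`
#'   (levels `neg`, `pos`; NA when excluded).
#' @export
task_classes <- function(labels, task = c("next_seizure", "cluster_onset")) {
  task <- match.arg(task)
  stopifnot(is.data.frame(labels), "category" %in% names(labels))
  if (task == "next_seizure") {
    labels$included <- TRUE
    labels$class <- factor(ifelse(labels$category == "cluster_non_last", "pos", "neg"),
                           levels = c("neg", "pos"))
  } else {
    labels$included <- labels$category == "isolated" | labels$is_cluster_first
    cls <- rep(NA_character_, nrow(labels))
    cls[labels$included] <- ifelse(labels$is_cluster_first[labels$included], "pos", "neg")
    labels$class <- factor(cls, levels = c("neg", "pos"))
  }
  labels
}

#' Patient eligibility for a prediction task
#'
#' Patients with fewer than `min_per_class` seizures in either task class are
#' excluded from individualized prediction.
#'
#' @param labels labeled seizures of one patient ([label_seizures()]).
#' @param task prediction task (see [task_classes()]).
#' @param min_per_class minimum class size (10).
#' @return list with `eligible` (logical), `n_pos`, `n_neg`, and `reason`
#'   (NA when eligible).
#' @export
patient_eligible <- function(labels, task = c("next_seizure", "cluster_onset"),
                             min_per_class = 10L) {
  task <- match.arg(task)
  tc <- task_classes(labels, task)
  n_pos <- sum(tc$class == "pos", na.rm = TRUE)
  n_neg <- sum(tc$class == "neg", na.rm = TRUE)
  eligible <- n_pos >= min_per_class && n_neg >= min_per_class
  reason <- if (eligible) NA_character_ else
    sprintf("class sizes %d positive / %d negative below minimum %d per class",
            n_pos, n_neg, min_per_class)
  list(eligible = eligible, n_pos = n_pos, n_neg = n_neg, reason = reason)
}
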