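#' Wilcoxon rank-sum comparison of one cell
#'
#' Two-sided rank-sum test between two groups of grand-average REN values.
#' Exact enumeration is used for groups of up to 20 values each (without
#' ties); larger groups use the normal approximation with tie correction.
#' Direction is determined by comparing group medians.
#'
#' @param group_a,group_b numeric vectors (group A is the isolated group in
#'   the standard comparisons).
#' @return list with `p` (two-sided p-value, NA if untestable), `testable`,
#'   and `direction` (`"b_higher"`/`"a_higher"`/`"tied"`).
#' @export
wilcoxon_cell <- function(group_a, group_b) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L) {
    return(list(p = NA_real_, testable = FALSE, direction = NA_character_))
  }
  exact <- length(group_a) <= 20L && length(group_b) <= 20L
  p <- suppressWarnings(
    wilcox.test(group_a, group_b, alternative = "two.sided",
                exact = exact, correct = TRUE)$p.value
  )
  ma <- median(group_a); mb <- median(group_b)
  direction <- if (mb > ma) "b_higher" else if (ma > mb) "a_higher" else "tied"
  list(p = p, testable = TRUE, direction = direction)
}

#' Benjamini-Hochberg adjustment over a family of cells
#'
#' @param p vector of raw p-values (NA allowed for untestable cells).
#' @param q FDR level for the significance flags (0.05).
#' @return data.frame with `p_raw`, `p_adj`, `significant`.
#' @export
fdr_adjust <- function(p, q = 0.05) {
  p_adj <- p.adjust(p, method = "BH")
  data.frame(p_raw = p, p_adj = p_adj,
             significant = !is.na(p_adj) & p_adj < q)
}

#' Compare grand-average REN between seizure types
#'
#' For every patient, band, and period, runs the three comparisons of
#' isolated seizures against cluster-first, cluster-non-last, and
#' cluster-last seizures with Wilcoxon rank-sum tests, then applies
#' Benjamini-Hochberg FDR correction. The default correction family pools
#' all cells across patients, bands, periods, and comparisons; a per-patient
#' family is available.
#'
#' @param features feature table ([compute_features()]) merged with taxonomy
#'   labels ([label_seizures()]), i.e. containing `category` and
#'   `is_cluster_first` columns.
#' @param bands band table ([band_specs()]).
#' @param q FDR level (0.05).
#' @param family `"pooled"` (default) or `"per_patient"` BH family.
#' @return data.frame of comparison cells: `patient_id`, `band`, `period`,
#'   `comparison`, group sizes, `p_raw`, `p_adj`, `significant`, `direction`
#'   (`"cluster_higher"`/`"isolated_higher"`, NA unless significant).
#' @export
compare_ren_groups <- function(features, bands = band_specs(), q = 0.05,
                               family = c("pooled", "per_patient")) {
  family <- match.arg(family)
  stopifnot(all(c("category", "is_cluster_first") %in% names(features)))
  comparisons <- c(isolated_vs_first = "is_cluster_first",
                   isolated_vs_non_last = "cluster_non_last",
                   isolated_vs_last = "cluster_last")
  periods <- c("near_seizure", "ictal")
  cells <- list()
  for (pid in unique(features$patient_id)) {
    fp <- features[features$patient_id == pid, , drop = FALSE]
    iso <- fp[fp$category == "isolated", , drop = FALSE]
    groups <- list(
      isolated_vs_first = fp[fp$is_cluster_first, , drop = FALSE],
      isolated_vs_non_last = fp[fp$category == "cluster_non_last", , drop = FALSE],
      isolated_vs_last = fp[fp$category == "cluster_last", , drop = FALSE]
    )
    for (band in bands$name) {
      for (period in periods) {
        col <- paste0("ga_ren_", band, "_", period)
        for (cmp in names(comparisons)) {
          a <- iso[[col]]; b <- groups[[cmp]][[col]]
          w <- wilcoxon_cell(a, b)
          cells[[length(cells) + 1L]] <- data.frame(
            patient_id = pid, band = band, period = period, comparison = cmp,
            n_isolated = sum(is.finite(a)), n_cluster = sum(is.finite(b)),
            p_raw = w$p, testable = w$testable,
            raw_direction = if (is.na(w$direction)) NA_character_ else
              switch(w$direction, b_higher = "cluster_higher",
                     a_higher = "isolated_higher", tied = NA_character_),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- do.call(rbind, cells)
  if (family == "pooled") {
    adj <- fdr_adjust(out$p_raw, q)
    out$p_adj <- adj$p_adj
    out$significant <- adj$significant
  } else {
    out$p_adj <- NA_real_
    out$significant <- FALSE
    for (pid in unique(out$patient_id)) {
      idx <- out$patient_id == pid
      adj <- fdr_adjust(out$p_raw[idx], q)
      out$p_adj[idx] <- adj$p_adj
      out$significant[idx] <- adj$significant
    }
  }
  out$direction <- ifelse(out$significant, out$raw_direction, NA_character_)
  out$raw_direction <- NULL
  rownames(out) <- NULL
  out
}

#' Tally difference directions among significant cells
#'
#' Counts, per period, how many significant comparison cells had higher REN
#' for cluster seizures versus higher REN for isolated seizures.
#'
#' @param cells output of [compare_ren_groups()].
#' @return data.frame with `period`, `cluster_higher`, `isolated_higher`.
#' @export
direction_tally <- function(cells) {
  periods <- c("near_seizure", "ictal")
  out <- data.frame(
    period = periods,
    cluster_higher = vapply(periods, function(pd)
      sum(cells$period == pd & !is.na(cells$direction) &
            cells$direction == "cluster_higher"), integer(1)),
    isolated_higher = vapply(periods, function(pd)
      sum(cells$period == pd & !is.na(cells$direction) &
            cells$direction == "isolated_higher"), integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
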