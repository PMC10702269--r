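#' Write seizure annotations to CSV
#'
#' Standard annotation format: header `patient_id,seizure_id,onset_s,offset_s`
#' (plus any label columns present, e.g. from [label_seizures()]).
#'
#' @param events annotation (or labeled) data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(events, path) {
  write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Read seizure annotations from CSV
#' @param path CSV path with at least `patient_id,onset_s,offset_s`.
#' @return validated annotation data.frame (see [seizure_events()]).
#' @export
read_annotations <- function(path) {
  seizure_events(read.csv(path, stringsAsFactors = FALSE))
}

#' Write a synthetic dataset to a directory
#'
#' Signals are stored as raw little-endian float32 binaries (one file per
#' seizure window, contacts x samples in column-major sample order) with a
#' JSON sidecar `signals.json` describing `fs`, `n_contacts`, and each chunk's
#' patient, seizure, start time, and sample count. Annotations go to
#' `annotations.csv` and ground truth to `truth.csv`.
#'
#' @param dataset a `synthetic_dataset` ([simulate_dataset()]).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  chunks <- list()
  for (pid in names(dataset$signals)) {
    pat <- dataset$signals[[pid]]
    for (k in seq_along(pat$seizures)) {
      fname <- sprintf("%s_s%04d.bin", pid, k)
      con <- file(file.path(dir, fname), "wb")
      writeBin(as.vector(pat$seizures[[k]]$signal), con, size = 4L,
               endian = "little")
      close(con)
      chunks[[length(chunks) + 1L]] <- list(
        patient_id = pid, seizure_id = k, file = fname,
        t0 = pat$seizures[[k]]$t0,
        n_samples = ncol(pat$seizures[[k]]$signal))
    }
  }
  sidecar <- list(format = "float32_le_contacts_major",
                  fs = dataset$signals[[1L]]$fs,
                  n_contacts = dataset$signals[[1L]]$n_contacts,
                  chunks = chunks)
  jsonlite::write_json(sidecar, file.path(dir, "signals.json"),
                       auto_unbox = TRUE, digits = NA)
  write_annotations(dataset$annotations, file.path(dir, "annotations.csv"))
  write.csv(dataset$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return list shaped like a `synthetic_dataset` (without generator config):
#'   `signals`, `annotations`, and `truth` (NULL if absent).
#' @export
read_dataset <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "signals.json"),
                                 simplifyVector = FALSE)
  fs <- sidecar$fs
  n_contacts <- sidecar$n_contacts
  signals <- list()
  for (ch in sidecar$chunks) {
    con <- file(file.path(dir, ch$file), "rb")
    v <- readBin(con, what = "numeric", n = n_contacts * ch$n_samples,
                 size = 4L, endian = "little")
    close(con)
    if (is.null(signals[[ch$patient_id]]))
      signals[[ch$patient_id]] <- list(fs = fs, n_contacts = n_contacts,
                                       seizures = list())
    signals[[ch$patient_id]]$seizures[[ch$seizure_id]] <-
      list(signal = matrix(v, nrow = n_contacts), t0 = ch$t0)
  }
  truth_path <- file.path(dir, "truth.csv")
  structure(list(
    signals = signals,
    annotations = read_annotations(file.path(dir, "annotations.csv")),
    truth = if (file.exists(truth_path))
      read.csv(truth_path, stringsAsFactors = FALSE) else NULL
  ), class = "synthetic_dataset")
}

#' Write / read a feature table
#' @param features feature table ([compute_features()], possibly labeled).
#' @param path CSV path.
#' @return `path` (write) or the feature data.frame (read).
#' @export
write_features <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
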