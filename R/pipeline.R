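#' Pipeline configuration
#'
#' Bundles all stage configurations plus a global seed. Per-stage seeds are
#' derived deterministically from the global seed (stage code mixed in via a
#' fixed linear-congruential scheme), so stages are independently
#' reproducible. Unknown configuration keys are rejected.
#'
#' @param sim list of [sim_config()] arguments (or a `sim_config`).
#' @param taxonomy list of [taxonomy_config()] arguments (or a
#'   `taxonomy_config`).
#' @param ren list of [ren_config()] arguments (or a `ren_config`).
#' @param cv list of [cv_config()] arguments (or a `cv_config`).
#' @param tasks prediction tasks to run.
#' @param run_sweep run the sample-size sweep stage (default FALSE).
#' @param write_signals also write raw signal binaries in the run directory
#'   (default FALSE; they are bulky and downstream stages consume the
#'   in-memory dataset).
#' @param seed global integer seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = list(), taxonomy = list(), ren = list(),
                            cv = list(), tasks = c("next_seizure", "cluster_onset"),
                            run_sweep = FALSE, write_signals = FALSE, seed = 1L) {
  as_cfg <- function(x, ctor, cls) {
    if (inherits(x, cls)) return(x)
    if (!is.list(x)) stop("expected a list of arguments or a ", cls)
    known <- names(formals(ctor))
    unknown <- setdiff(names(x), known)
    if (length(unknown))
      stop("unknown ", cls, " key(s): ", paste(unknown, collapse = ", "))
    do.call(ctor, x)
  }
  tasks <- match.arg(tasks, c("next_seizure", "cluster_onset"), several.ok = TRUE)
  seed <- as.integer(seed)
  sim <- as_cfg(sim, sim_config, "sim_config")
  # the global seed drives the generator unless the sim section pins its own
  if (!("seed" %in% names(sim)) || identical(sim$seed, formals(sim_config)$seed))
    sim$seed <- derive_seed(seed, 101L)
  cvc <- as_cfg(cv, cv_config, "cv_config")
  cvc$seed <- derive_seed(seed, 103L)
  structure(list(
    sim = sim,
    taxonomy = as_cfg(taxonomy, taxonomy_config, "taxonomy_config"),
    ren = as_cfg(ren, ren_config, "ren_config"),
    cv = cvc,
    tasks = tasks, run_sweep = run_sweep, write_signals = write_signals,
    seed = seed
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file holds one section per stage (`sim`, `taxonomy`, `ren`, `cv`)
#' plus top-level `seed`, `tasks`, `run_sweep`, `write_signals`. Unknown keys
#' anywhere are rejected.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

file_md5 <- function(paths) {
  h <- tools::md5sum(paths)
  stats::setNames(as.character(h), basename(paths))
}

stage_current <- function(manifest, stage, inputs, outputs) {
  m <- manifest[[stage]]
  if (is.null(m)) return(FALSE)
  if (!all(file.exists(outputs))) return(FALSE)
  ok_out <- identical(file_md5(outputs), unlist(m$outputs))
  ok_in <- identical(if (length(inputs)) file_md5(inputs) else character(0),
                     if (length(m$inputs)) unlist(m$inputs) else character(0))
  isTRUE(ok_out) && isTRUE(ok_in)
}

#' Run the full analysis pipeline
#'
#' Stages: simulate -> features -> label -> stats -> predict (+ baselines)
#' -> optional sample-size sweep. Every stage writes its outputs under
#' `out_dir` and records them, with MD5 checksums of its inputs, in
#' `manifest.json`; on re-runs a stage is skipped when its recorded inputs
#' and outputs are unchanged. The resolved configuration is written next to
#' the outputs as `config_resolved.yaml`.
#'
#' @param config a [pipeline_config()] or path to a YAML config.
#' @param out_dir run directory (created if needed).
#' @param force rerun all stages even when outputs are current.
#' @return invisible list with the in-memory stage products (`dataset`,
#'   `features`, `labeled`, `cells`, `tally`, `reports`, `baselines`,
#'   `sweeps`).
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cfg_path <- file.path(out_dir, "config_resolved.yaml")
  yaml::write_yaml(serialize_config(config), cfg_path)
  man_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(man_path) && !force)
    jsonlite::read_json(man_path) else list()
  record <- function(stage, inputs, outputs) {
    manifest[[stage]] <<- list(
      inputs = as.list(if (length(inputs)) file_md5(inputs) else character(0)),
      outputs = as.list(file_md5(outputs)))
    jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  }
  paths <- list(
    ann = file.path(out_dir, "annotations.csv"),
    truth = file.path(out_dir, "truth.csv"),
    feat = file.path(out_dir, "features.csv"),
    labeled = file.path(out_dir, "labeled.csv"),
    feat_lab = file.path(out_dir, "features_labeled.csv"),
    cells = file.path(out_dir, "comparison_cells.csv"),
    tally = file.path(out_dir, "direction_tally.json")
  )

  # -- simulate ---------------------------------------------------------------
  dataset <- NULL
  sim_out <- c(paths$ann, paths$truth)
  if (force || !stage_current(manifest, "simulate", cfg_path, sim_out)) {
    message("[simulate] generating synthetic dataset")
    dataset <- simulate_dataset(config$sim)
    write_annotations(dataset$annotations, paths$ann)
    write.csv(dataset$truth, paths$truth, row.names = FALSE)
    if (config$write_signals) write_dataset(dataset, file.path(out_dir, "signals"))
    record("simulate", cfg_path, sim_out)
    message(sprintf("[simulate] %d seizures across %d patient(s)",
                    nrow(dataset$annotations), length(dataset$signals)))
  } else message("[simulate] outputs current, skipped")

  # -- features ---------------------------------------------------------------
  if (force || is.null(manifest$features) ||
      !stage_current(manifest, "features", c(cfg_path, sim_out), paths$feat)) {
    if (is.null(dataset)) dataset <- simulate_dataset(config$sim)
    message("[features] computing grand-average REN features")
    features <- compute_features(dataset, band_specs(), config$ren,
                                 config$sim$layout)
    write_features(features, paths$feat)
    record("features", c(cfg_path, sim_out), paths$feat)
    message(sprintf("[features] %d seizure rows x %d features",
                    nrow(features), length(feature_columns())))
  } else {
    features <- read_features(paths$feat)
    message("[features] outputs current, skipped")
  }

  # -- label ------------------------------------------------------------------
  if (force || !stage_current(manifest, "label",
                              c(cfg_path, paths$ann, paths$feat),
                              c(paths$labeled, paths$feat_lab))) {
    message(sprintf("[label] ISI taxonomy at %g h (%s)",
                    config$taxonomy$isi_threshold_h, config$taxonomy$isi_reference))
    labeled <- label_seizures(read_annotations(paths$ann), config$taxonomy)
    write_annotations(labeled, paths$labeled)
    feat_lab <- merge(features,
                      labeled[c("patient_id", "seizure_id", "category",
                                "is_cluster_first", "cluster_id")],
                      by = c("patient_id", "seizure_id"))
    feat_lab <- feat_lab[order(feat_lab$patient_id, feat_lab$onset_s), ]
    write_features(feat_lab, paths$feat_lab)
    record("label", c(cfg_path, paths$ann, paths$feat),
           c(paths$labeled, paths$feat_lab))
    message(sprintf("[label] categories: %s",
                    paste(names(table(labeled$category)), table(labeled$category),
                          sep = "=", collapse = ", ")))
  } else {
    labeled <- read_annotations(paths$labeled)
    feat_lab <- read_features(paths$feat_lab)
    message("[label] outputs current, skipped")
  }
  feat_lab$is_cluster_first <- as.logical(feat_lab$is_cluster_first)

  # -- stats ------------------------------------------------------------------
  if (force || !stage_current(manifest, "stats", c(cfg_path, paths$feat_lab),
                              c(paths$cells, paths$tally))) {
    message("[stats] rank-sum comparisons with BH-FDR correction")
    cells <- compare_ren_groups(feat_lab)
    tally <- direction_tally(cells)
    write.csv(cells, paths$cells, row.names = FALSE)
    jsonlite::write_json(tally, paths$tally, auto_unbox = TRUE, digits = NA)
    record("stats", c(cfg_path, paths$feat_lab), c(paths$cells, paths$tally))
    message(sprintf("[stats] %d cells tested, %d significant",
                    sum(cells$testable), sum(cells$significant)))
  } else {
    cells <- read.csv(paths$cells, stringsAsFactors = FALSE)
    tally <- direction_tally(cells)
    message("[stats] outputs current, skipped")
  }

  # -- predict ----------------------------------------------------------------
  reports <- list()
  baselines <- list()
  for (task in config$tasks) {
    rep_path <- file.path(out_dir, paste0("eval_", task, ".csv"))
    base_path <- file.path(out_dir, paste0("baselines_", task, ".csv"))
    if (force || !stage_current(manifest, paste0("predict_", task),
                                c(cfg_path, paths$feat_lab),
                                c(rep_path, base_path))) {
      message(sprintf("[predict] task %s: nested stratified CV", task))
      rep <- run_task(feat_lab, task, config$cv)
      write.csv(rep$per_patient, rep_path, row.names = FALSE)
      bl <- do.call(rbind, lapply(split(feat_lab, feat_lab$patient_id), function(fp) {
        tc <- task_classes(fp, task)
        n_pos <- sum(tc$class == "pos", na.rm = TRUE)
        n_neg <- sum(tc$class == "neg", na.rm = TRUE)
        if (n_pos == 0L || n_neg == 0L) return(NULL)
        cbind(patient_id = fp$patient_id[1], baseline_table(n_neg, n_pos))
      }))
      write.csv(bl, base_path, row.names = FALSE)
      record(paste0("predict_", task), c(cfg_path, paths$feat_lab),
             c(rep_path, base_path))
      if (nrow(rep$excluded))
        message(sprintf("[predict] excluded: %s",
                        paste(rep$excluded$patient_id, rep$excluded$reason,
                              sep = ": ", collapse = "; ")))
      reports[[task]] <- rep
      baselines[[task]] <- bl
    } else message(sprintf("[predict] task %s current, skipped", task))
  }

  # -- sweep ------------------------------------------------------------------
  sweeps <- NULL
  if (config$run_sweep) {
    sweep_path <- file.path(out_dir, "sweep_next_seizure.csv")
    if (force || !stage_current(manifest, "sweep", c(cfg_path, paths$feat_lab),
                                sweep_path)) {
      message("[sweep] sample-size experiments (next-seizure task)")
      sweeps <- list()
      for (pid in unique(feat_lab$patient_id)) {
        fp <- feat_lab[feat_lab$patient_id == pid, , drop = FALSE]
        if (!patient_eligible(fp, "next_seizure", config$cv$min_per_class)$eligible)
          next
        sw <- sample_size_sweep(fp, "next_seizure", config$cv)
        sw$summary$patient_id <- pid
        sweeps[[pid]] <- sw$summary
      }
      sweep_df <- do.call(rbind, sweeps)
      write.csv(sweep_df, sweep_path, row.names = FALSE)
      record("sweep", c(cfg_path, paths$feat_lab), sweep_path)
    } else message("[sweep] outputs current, skipped")
  }

  invisible(list(dataset = dataset, features = features, labeled = labeled,
                 features_labeled = feat_lab, cells = cells, tally = tally,
                 reports = reports, baselines = baselines, sweeps = sweeps,
                 out_dir = out_dir))
}

# YAML-safe view of the resolved configuration
serialize_config <- function(config) {
  list(
    seed = config$seed,
    tasks = config$tasks,
    run_sweep = config$run_sweep,
    write_signals = config$write_signals,
    sim = lapply(config$sim[setdiff(names(config$sim), "layout")], identity),
    layout = list(assemblies = config$sim$layout$assemblies,
                  arrays_per_assembly = config$sim$layout$arrays_per_assembly,
                  contacts_per_array = config$sim$layout$contacts_per_array),
    taxonomy = unclass(config$taxonomy),
    ren = unclass(config$ren),
    cv = list(outer_folds = config$cv$outer_folds,
              inner_folds = config$cv$inner_folds,
              families = config$cv$families,
              min_per_class = config$cv$min_per_class,
              seed = config$cv$seed)
  )
}
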