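# End-to-end orchestration: events -> cohort -> encoding -> model ->
# contributions -> ranked report, with a manifest capturing every seed and a
# checksum of every artifact so occlusion-mode runs can be verified
# bit-identical.

#' Checksum of an R object (for run manifests)
#'
#' Polynomial checksum over the serialized object; not cryptographic, only a
#' reproducibility fingerprint.
#' @param x any R object.
#' @return character scalar.
#' @export
rs_hash <- function(x) {
  r <- as.double(serialize(x, NULL, ascii = TRUE))
  w <- (seq_along(r) - 1) %% 97 + 1
  sprintf("%.0f", sum(r * w) %% 2147483647)
}

#' Run the full analysis pipeline on an event table
#'
#' Builds onsets and augmented samples, splits by patient, trains the chosen
#' architecture, evaluates, computes perturbation contributions on the test
#' fold and the relative-contribution screen with the full event/no-event
#' patient counts of that fold.
#'
#' @param events event table (see [generate_dataset()] / [read_events()]).
#' @param cohort_cfg an [cohort_config()] object.
#' @param model_cfg an [model_config()] object.
#' @param sdoh optional zip-level SDoH table.
#' @param seed master seed for this run (control sampling, splitting,
#'   training, noise perturbations).
#' @param include_sdoh include `SD:`/`NB:` tokens (`FALSE` = "-SDoH" arm).
#' @param fc_mode `"occlusion"` or `"noise"` (see [feature_contributions()]).
#' @param fc_scale `"logit"` or `"probability"` attribution scale.
#' @param fc_folds folds whose samples feed the contribution screen. The
#'   default `c("validation", "test")` attributes on data that never produced
#'   a gradient update (validation steered only early stopping), while
#'   roughly doubling the carrier counts behind each RC relative to the test
#'   fold alone; set to `"test"` for strictly-held-out attribution or include
#'   `"train"` for a descriptive screen over the whole cohort.
#' @param min_patient_count vocabulary retention threshold.
#' @param out_dir if non-`NULL`, write the samples manifest, metrics, FC
#'   table, ranked report and manifest JSON there.
#' @param ... passed to [encode_samples()].
#' @return list with `samples`, `fit` (see [fit_once()]), `fc`, `rc`,
#'   `report` and `manifest`.
#' @export
run_pipeline <- function(events, cohort_cfg, model_cfg, sdoh = NULL,
                         seed = 1L, include_sdoh = TRUE,
                         fc_mode = c("occlusion", "noise"),
                         fc_scale = c("logit", "probability"),
                         fc_folds = c("validation", "test"),
                         min_patient_count = 10L, out_dir = NULL, ...) {
  fc_mode <- match.arg(fc_mode)
  fc_scale <- match.arg(fc_scale)
  stopifnot(all(fc_folds %in% c("train", "validation", "test")))
  onsets <- find_onsets(events, cohort_cfg)
  samples <- build_samples(events, onsets, cohort_cfg, seed = seed)
  fit <- fit_once(samples, events, cohort_cfg, model_cfg, sdoh = sdoh,
                  seed = seed, min_patient_count = min_patient_count,
                  include_sdoh = include_sdoh, ...)
  fc_enc <- do.call(c, unname(fit$enc[fc_folds]))
  fc <- feature_contributions(fit$model, fc_enc, fit$vocab,
                              mode = fc_mode, scale = fc_scale, seed = seed)
  fc_pat <- unique(rbindlist(lapply(fc_enc, function(e)
    data.table(patient_id = e$patient_id, label = as.integer(e$label)))))
  n_event <- length(unique(fc_pat[label == 1L, patient_id]))
  n_noevent <- length(unique(fc_pat[label == 0L, patient_id]))
  rc <- analyze_contributions(fc, n_event = n_event, n_noevent = n_noevent)
  report <- rank_features(rc)
  manifest <- list(
    seed = seed, architecture = model_cfg$architecture,
    include_sdoh = include_sdoh, fc_mode = fc_mode, fc_scale = fc_scale,
    fc_folds = fc_folds,
    n_samples = nrow(samples), n_event_patients = n_event,
    n_noevent_patients = n_noevent,
    vocab_fingerprint = fit$model$vocab_fingerprint,
    config_hash = rs_hash(list(cohort_cfg, model_cfg, min_patient_count)),
    checksums = list(events = rs_hash(events), samples = rs_hash(samples),
                     model_par = rs_hash(fit$model$par), fc = rs_hash(fc),
                     rc = rs_hash(rc)),
    metrics = list(validation = as.list(fit$val_metrics),
                   test = as.list(fit$test_metrics))
  )
  res <- list(samples = fit$folds, fit = fit, fc = fc, rc = rc,
              report = report, manifest = manifest)
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

write_run <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fwrite(res$samples, file.path(out_dir, "samples.csv"))
  met <- rbind(
    data.frame(fold = "validation", t(res$fit$val_metrics)),
    data.frame(fold = "test", t(res$fit$test_metrics))
  )
  fwrite(met, file.path(out_dir, "metrics.csv"))
  write_rc_report(res$fc, file.path(out_dir, "fc.csv"))
  write_rc_report(res$report, file.path(out_dir, "rc_report.csv"))
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

.cfg_from_yaml <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

.sim_cfg_from_list <- function(x) {
  args <- x[intersect(names(x), names(formals(sim_config)))]
  if (!is.null(args$vocab_sizes)) args$vocab_sizes <- unlist(args$vocab_sizes)
  if (!is.null(args$planted_effects)) args$planted_effects <- unlist(args$planted_effects)
  if (!is.null(args$planted_types)) args$planted_types <- unlist(args$planted_types)
  if (!is.null(args$planted_prevalence)) args$planted_prevalence <- unlist(args$planted_prevalence)
  if (!is.null(args$encounters_per_patient)) {
    args$encounters_per_patient <- unlist(args$encounters_per_patient)
  }
  if (!is.null(args$lab_flag_probs)) args$lab_flag_probs <- unlist(args$lab_flag_probs)
  do.call(sim_config, args)
}

#' Simulate a dataset from a YAML config and write it to disk
#'
#' Writes `events.csv`, `sdoh.csv`, `truth_patients.csv` and
#' `truth_onsets.csv` under `out`.
#'
#' @param config path to a YAML file with a `sim:` section (fields of
#'   [sim_config()]), or a list.
#' @param out output directory.
#' @param seed optional master seed override.
#' @return the output directory, invisibly.
#' @export
rs_simulate <- function(config, out = ".", seed = NULL) {
  cfg <- if (is.character(config)) .cfg_from_yaml(config) else config
  sim <- .sim_cfg_from_list(cfg$sim %||% cfg)
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  ds <- generate_dataset(sim)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_events(ds$events, file.path(out, "events.csv"))
  write_sdoh(ds$sdoh, file.path(out, "sdoh.csv"))
  fwrite(ds$truth$patients, file.path(out, "truth_patients.csv"))
  fwrite(ds$truth$onsets, file.path(out, "truth_onsets.csv"))
  invisible(out)
}

#' Run the pipeline from a YAML config
#'
#' The config carries `cohort:` (fields of [cohort_config()]), `model:`
#' (fields of [model_config()]), optionally `sim:` (to simulate in place of
#' `events`/`sdoh` file paths) and `run:` (`seed`, `repeats`, `include_sdoh`,
#' `fc_mode`, `min_patient_count`, `out`).
#'
#' @param config path to YAML or a list.
#' @param out output directory (overrides `run$out`).
#' @param seed,arch,include_sdoh,repeats optional overrides.
#' @return the [run_pipeline()] result, with an `eval_report` element when
#'   `repeats >= 2`.
#' @export
rs_run <- function(config, out = NULL, seed = NULL, arch = NULL,
                   include_sdoh = NULL, repeats = NULL) {
  cfg <- if (is.character(config)) .cfg_from_yaml(config) else config
  run <- cfg$run %||% list()
  seed <- as.integer(seed %||% run$seed %||% 1L)
  out <- out %||% run$out
  include_sdoh <- include_sdoh %||% run$include_sdoh %||% TRUE
  repeats <- as.integer(repeats %||% run$repeats %||% 10L)

  if (!is.null(cfg$sim)) {
    ds <- generate_dataset(.sim_cfg_from_list(cfg$sim))
    events <- ds$events; sdoh <- ds$sdoh
  } else {
    if (is.null(cfg$events)) stop("config needs either a sim: section or an events: path")
    events <- read_events(cfg$events)
    sdoh <- if (!is.null(cfg$sdoh)) read_sdoh(cfg$sdoh) else NULL
  }
  cc_args <- cfg$cohort
  cc_args$qualifying_codes <- unlist(cc_args$qualifying_codes)
  cc_args$adverse_event_codes <- unlist(cc_args$adverse_event_codes)
  cohort_cfg <- do.call(cohort_config, cc_args)
  mc_args <- cfg$model %||% list()
  if (!is.null(arch)) mc_args$architecture <- arch
  model_cfg <- do.call(model_config, mc_args)

  res <- run_pipeline(events, cohort_cfg, model_cfg, sdoh = sdoh, seed = seed,
                      include_sdoh = isTRUE(include_sdoh),
                      fc_mode = run$fc_mode %||% "occlusion",
                      min_patient_count = run$min_patient_count %||% 10L,
                      out_dir = out)
  if (repeats >= 2L) {
    onsets <- find_onsets(events, cohort_cfg)
    samples <- build_samples(events, onsets, cohort_cfg, seed = seed)
    res$eval_report <- repeat_experiment(samples, events, cohort_cfg, model_cfg,
                                         sdoh = sdoh, n_repeats = repeats,
                                         seed = seed,
                                         min_patient_count = run$min_patient_count %||% 10L,
                                         include_sdoh = isTRUE(include_sdoh))
    if (!is.null(out)) {
      fwrite(cbind(metric = rownames(res$eval_report),
                   as.data.table(res$eval_report)),
             file.path(out, "eval_report.csv"))
    }
  }
  res
}

#' Summarise a completed run directory
#'
#' Reads the metrics and ranked report written by [rs_run()] and renders a
#' short markdown summary (also written to `summary.md`).
#'
#' @param results_dir directory written by [rs_run()].
#' @return the markdown lines, invisibly.
#' @export
rs_report <- function(results_dir) {
  missing <- setdiff(c("metrics.csv", "rc_report.csv"),
                     list.files(results_dir))
  if (length(missing)) {
    stop("missing inputs in ", results_dir, ": ", paste(missing, collapse = ", "))
  }
  met <- fread(file.path(results_dir, "metrics.csv"))
  rc <- fread(file.path(results_dir, "rc_report.csv"))
  lines <- c("# Run summary", "", "## Model performance", "")
  lines <- c(lines, paste0("| fold | AUROC | precision | recall | F1 |"),
             "|---|---|---|---|---|",
             sprintf("| %s | %.3f | %.3f | %.3f | %.3f |",
                     met$fold, met$auroc, met$precision, met$recall, met$f1))
  ev_path <- file.path(results_dir, "eval_report.csv")
  if (file.exists(ev_path)) {
    ev <- fread(ev_path)
    lines <- c(lines, "", "## Repeated runs",
               "", sprintf("- %s: %.3f (sd %.3f)", ev$metric,
                           ev$average, ev[["std.s"]]))
  }
  lines <- c(lines, "", "## Feature screen", "")
  if (nrow(rc) == 0L) {
    lines <- c(lines, "no features tested")
  } else {
    top <- head(rc, 15L)
    lines <- c(lines,
               "| Feature Name | RC | 95%CIup | 95%CIdown | FDR_Q | Bonferroni corrected p-value |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %.4g | %.4g | %.4g | %.4g | %.4g |",
                       top[["Feature Name"]], top$RC, top[["95%CIup"]],
                       top[["95%CIdown"]], top$FDR_Q,
                       top[["Bonferroni corrected p-value"]]))
  }
  writeLines(lines, file.path(results_dir, "summary.md"))
  cat(lines, sep = "\n")
  invisible(lines)
}
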