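# Case/control sample construction with encounter-level augmentation.
#
# A case patient contributes one sample per encounter between the first
# qualifying diagnosis and the first new-onset adverse event whose prediction
# window still captures that onset; control samples are drawn (seeded,
# without replacement) from encounters of event-free qualifying patients so
# the two groups are of nearly the same size. Splitting into train /
# validation / test is by patient, so augmented near-duplicate sequences can
# never straddle folds.

#' Cohort construction configuration
#'
#' @param qualifying_codes character vector of codes whose first occurrence
#'   defines cohort entry (the qualifying diagnosis).
#' @param adverse_event_codes character vector of adverse-event codes; each
#'   code is one event *type* for the new-onset rule.
#' @param prediction_window_days length of the prediction window (days).
#' @param control_sampling_ratio controls drawn per case sample.
#' @param split_ratios length-3 positive weights for train/validation/test;
#'   normalised to sum to 1.
#' @param allow_case_patients_as_controls if `TRUE`, encounters of case
#'   patients whose window misses every onset may serve as control samples;
#'   default `FALSE` keeps the two groups disjoint by patient.
#' @param seed integer seed for control sampling and splitting.
#' @return an object of class `rs_cohort_config`.
#' @export
cohort_config <- function(qualifying_codes,
                          adverse_event_codes,
                          prediction_window_days = 90L,
                          control_sampling_ratio = 1.0,
                          split_ratios = c(8, 1, 1),
                          allow_case_patients_as_controls = FALSE,
                          seed = 1L) {
  if (prediction_window_days <= 0) stop("prediction_window_days must be > 0")
  if (length(split_ratios) != 3 || any(split_ratios <= 0)) {
    stop("split_ratios must be three positive numbers")
  }
  if (control_sampling_ratio <= 0) stop("control_sampling_ratio must be > 0")
  structure(list(
    qualifying_codes = qualifying_codes,
    adverse_event_codes = adverse_event_codes,
    prediction_window_days = as.integer(prediction_window_days),
    control_sampling_ratio = control_sampling_ratio,
    split_ratios = split_ratios / sum(split_ratios),
    allow_case_patients_as_controls = isTRUE(allow_case_patients_as_controls),
    seed = as.integer(seed)
  ), class = "rs_cohort_config")
}

#' Locate qualifying dates and new-onset adverse events
#'
#' An adverse-event date is a *new onset* of a type only if the patient has no
#' record of that same code at or before the qualifying date, and the date
#' falls strictly after the qualifying date. Patients carrying adverse-event
#' codes but no qualifying code are excluded (and reported via a message);
#' patients with no qualifying code are excluded silently.
#'
#' @param events event table (`patient_id`, `date`, `code`, ... columns).
#' @param config an [cohort_config()] object.
#' @return list with `patients` (`patient_id`, `qualifying_day`), `onsets`
#'   (`patient_id`, `code`, `day`: first new onset per event type, in date
#'   order) and `excluded` (patient ids dropped for having adverse events but
#'   no qualifying diagnosis).
#' @export
find_onsets <- function(events, config) {
  ev <- as.data.table(events)
  qual <- ev[code %in% config$qualifying_codes,
             .(qualifying_day = min(date)), by = patient_id]
  ae <- ev[code %in% config$adverse_event_codes, .(patient_id, date, code)]
  no_qual_ae <- setdiff(unique(ae$patient_id), qual$patient_id)
  if (length(no_qual_ae)) {
    message(length(no_qual_ae),
            " patient(s) with adverse-event codes but no qualifying code excluded")
  }
  ae <- merge(ae, qual, by = "patient_id")
  # a type is pre-existing if recorded at or before the qualifying date
  pre <- unique(ae[date <= qualifying_day, .(patient_id, code)])
  pre[, pre_existing := TRUE]
  onsets <- ae[date > qualifying_day, .(day = min(date)), by = .(patient_id, code)]
  onsets <- merge(onsets, pre, by = c("patient_id", "code"), all.x = TRUE)
  onsets <- onsets[is.na(pre_existing), .(patient_id, code, day)]
  setorder(onsets, patient_id, day, code)
  list(patients = qual[order(patient_id)], onsets = onsets, excluded = no_qual_ae)
}

#' Build augmented case/control samples
#'
#' @param events event table.
#' @param onsets result of [find_onsets()].
#' @param config an [cohort_config()] object.
#' @param seed overrides `config$seed` for the control draw.
#' @return `data.table` of samples: `sample_id`, `patient_id`, `index_date`,
#'   `label` (1 = case), `target_event_code` (`NA` for controls).
#' @export
build_samples <- function(events, onsets, config, seed = config$seed) {
  ev <- as.data.table(events)
  win <- config$prediction_window_days
  qual <- onsets$patients
  ons <- onsets$onsets

  enc <- unique(ev[patient_id %in% qual$patient_id, .(patient_id, date)])
  enc <- merge(enc, qual, by = "patient_id")

  # first new onset per case patient (ties broken by code order)
  first_on <- ons[order(patient_id, day, code)][, .SD[1L], by = patient_id]
  setnames(first_on, c("day", "code"), c("onset_day", "onset_code"))

  case_enc <- merge(enc, first_on, by = "patient_id")
  case_enc <- case_enc[date >= qualifying_day & date < onset_day &
                         onset_day <= date + win]
  if (nrow(case_enc) == 0L) {
    stop("empty cohort: no encounter yields an eligible case sample")
  }
  cases <- case_enc[, .(patient_id, index_date = date, label = 1L,
                        target_event_code = onset_code)]

  # control-eligible encounters: qualifying patients, no adverse-event record
  # inside (index, index + window]
  ctrl_pool <- if (config$allow_case_patients_as_controls) enc else
    enc[!patient_id %in% first_on$patient_id]
  ctrl_pool <- ctrl_pool[date >= qualifying_day]
  ae <- ev[code %in% config$adverse_event_codes, .(patient_id, ae_day = date)]
  if (nrow(ae)) {
    hit <- merge(ctrl_pool, ae, by = "patient_id", allow.cartesian = TRUE)
    hit <- unique(hit[ae_day > date & ae_day <= date + win, .(patient_id, date)])
    ctrl_pool <- ctrl_pool[!hit, on = c("patient_id", "date")]
  }
  n_ctrl <- round(config$control_sampling_ratio * nrow(cases))
  if (nrow(ctrl_pool) < n_ctrl) {
    warning(sprintf("only %d eligible control encounters for %d requested",
                    nrow(ctrl_pool), n_ctrl))
    n_ctrl <- nrow(ctrl_pool)
  }
  setorder(ctrl_pool, patient_id, date)
  set.seed(seed)
  pick <- sort(sample.int(nrow(ctrl_pool), n_ctrl))
  controls <- ctrl_pool[pick, .(patient_id, index_date = date, label = 0L,
                                target_event_code = NA_character_)]

  samples <- rbindlist(list(cases, controls))
  setorder(samples, -label, patient_id, index_date)
  samples[, sample_id := sprintf("S%06d", .I)]
  data.table::setcolorder(samples, c("sample_id", "patient_id", "index_date",
                                     "label", "target_event_code"))
  samples[]
}

#' Split samples into train/validation/test by patient
#'
#' Patients are assigned whole to one fold (no sequence leakage across
#' folds). Assignment walks the patients in a seeded random order and greedily
#' gives each to the fold with the largest deficit relative to the target
#' sample proportions, so realised fold sizes track the ratios as closely as
#' patient granularity allows. Deterministic under the seed.
#'
#' @param samples sample table from [build_samples()].
#' @param config an [cohort_config()] object (uses `split_ratios`).
#' @param seed overrides `config$seed`.
#' @return the sample table with a `fold` column
#'   (`"train"`/`"validation"`/`"test"`).
#' @export
split_samples <- function(samples, config, seed = config$seed) {
  s <- as.data.table(samples)
  pats <- s[, .N, by = patient_id]
  if (nrow(pats) < 3L) stop("need at least 3 patients to split")
  set.seed(seed)
  pats <- pats[sample.int(nrow(pats))]
  p <- config$split_ratios
  fold_names <- c("train", "validation", "test")
  assigned <- integer(nrow(pats))
  cnt <- c(0, 0, 0)
  done <- 0
  for (i in seq_len(nrow(pats))) {
    done <- done + pats$N[i]
    deficit <- p * done - (cnt + 0)
    k <- which.max(deficit)
    assigned[i] <- k
    cnt[k] <- cnt[k] + pats$N[i]
  }
  map <- setNames(fold_names[assigned], pats$patient_id)
  s[, fold := unname(map[patient_id])]
  s[]
}
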