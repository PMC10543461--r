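# Synthetic longitudinal EHR generator with planted multiplicative effects.
#
# Outcome model: discrete time. Starting at the first qualifying diagnosis,
# follow-up is divided into consecutive windows of `window_days` (default 90,
# the prediction horizon). In each window the adverse-event probability is
#   min(1, baseline_hazard * prod(odds factors of planted codes present in
#                                 the patient's preceding `lookback_days`))
# Window Bernoulli draws, onset-day offsets and event types are pre-drawn per
# patient before any hazard is evaluated, so raising an odds factor can only
# turn non-events into events (monotonicity under a fixed seed), and each
# patient's random substream is derived from the master seed and the patient
# index, so earlier patients are unchanged when n_patients grows.

.rs_epoch <- as.Date("2010-01-01")
.rs_code_types <- c("DIAGNOSIS", "MEDICATION", "LAB", "SDOH_IND")
.rs_lab_flags <- c("ABNORMAL", "HIGH", "LOW")

#' Configuration for the synthetic EHR generator
#'
#' @param n_patients number of patients to simulate.
#' @param vocab_sizes named integer vector with elements `diagnosis`,
#'   `medication`, `lab`, `sdoh_individual` (count of binary individual-level
#'   social-determinant flags beyond age/sex/race) and `sdoh_neighborhood`
#'   (number of numeric zip-level features).
#' @param baseline_hazard probability of an adverse event per 90-day window in
#'   the absence of planted effects.
#' @param planted_effects named numeric vector mapping a code to its
#'   multiplicative odds factor (>1 risk, <1 protective). Carriers emit the
#'   code at every encounter (persistent exposure).
#' @param planted_types optional named character vector giving each planted
#'   code's record type (`MEDICATION`, `DIAGNOSIS` or `SDOH_IND`); defaults to
#'   `MEDICATION`.
#' @param planted_prevalence carrier prevalence per planted code (scalar or
#'   named vector). Carrier strata are disjoint: each patient carries at most
#'   one planted code, so effects are estimated without co-carriage
#'   confounding. Prevalences must sum to at most 1.
#' @param encounters_per_patient named numeric vector `c(mean=, dispersion=)`
#'   for the negative-binomial encounter count (at least one encounter is
#'   always generated).
#' @param followup_days length of each patient's observation period, in days.
#' @param lab_flag_probs named probabilities that a lab result is flagged
#'   `ABNORMAL`, `HIGH` or `LOW`; the remainder are normal results (no flag).
#' @param window_days hazard/prediction window length in days.
#' @param lookback_days how far before a window start a code counts as
#'   "recent history" for the hazard.
#' @param preexisting_ae_prob probability that a patient has an adverse-event
#'   record at or before the qualifying diagnosis (exercises the
#'   new-onset-by-type rule downstream).
#' @param n_zip number of distinct 5-digit zip codes.
#' @param qualifying_code diagnosis code marking cohort entry.
#' @param adverse_codes character vector of adverse-event diagnosis codes.
#' @param seed master integer seed.
#' @return an object of class `rs_sim_config`.
#' @export
sim_config <- function(n_patients = 1000,
                       vocab_sizes = c(diagnosis = 30, medication = 20, lab = 10,
                                       sdoh_individual = 3, sdoh_neighborhood = 4),
                       baseline_hazard = 0.08,
                       planted_effects = numeric(0),
                       planted_types = NULL,
                       planted_prevalence = 0.4,
                       encounters_per_patient = c(mean = 15, dispersion = 5),
                       followup_days = 900,
                       lab_flag_probs = c(ABNORMAL = 0.08, HIGH = 0.08, LOW = 0.08),
                       window_days = 90,
                       lookback_days = 365,
                       preexisting_ae_prob = 0.05,
                       n_zip = 40,
                       qualifying_code = "Q_INDEX",
                       adverse_codes = c("AE_A", "AE_B"),
                       seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients), vocab_sizes = vocab_sizes,
    baseline_hazard = baseline_hazard, planted_effects = planted_effects,
    planted_types = planted_types, planted_prevalence = planted_prevalence,
    encounters_per_patient = encounters_per_patient,
    followup_days = as.integer(followup_days), lab_flag_probs = lab_flag_probs,
    window_days = as.integer(window_days), lookback_days = as.integer(lookback_days),
    preexisting_ae_prob = preexisting_ae_prob, n_zip = as.integer(n_zip),
    qualifying_code = qualifying_code, adverse_codes = adverse_codes,
    seed = as.integer(seed)
  )
  class(cfg) <- "rs_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    stop(sprintf("invalid sim_config field '%s': %s", field, why), call. = FALSE)
  }
  if (!is.numeric(cfg$n_patients) || cfg$n_patients < 1) bad("n_patients", "must be >= 1")
  need <- c("diagnosis", "medication", "lab", "sdoh_individual", "sdoh_neighborhood")
  if (!all(need %in% names(cfg$vocab_sizes))) {
    bad("vocab_sizes", paste("must name", paste(need, collapse = ", ")))
  }
  if (any(cfg$vocab_sizes[c("diagnosis", "medication", "lab")] < 1)) {
    bad("vocab_sizes", "diagnosis/medication/lab sizes must be >= 1")
  }
  if (cfg$baseline_hazard < 0 || cfg$baseline_hazard > 1) {
    bad("baseline_hazard", "must lie in [0, 1]")
  }
  if (length(cfg$planted_effects)) {
    if (is.null(names(cfg$planted_effects)) || any(!nzchar(names(cfg$planted_effects)))) {
      bad("planted_effects", "must be a named numeric vector (code -> odds factor)")
    }
    if (any(cfg$planted_effects <= 0)) bad("planted_effects", "odds factors must be > 0")
    prev <- .planted_prevalence(cfg)
    if (any(prev < 0) || sum(prev) > 1) {
      bad("planted_prevalence", "prevalences must be >= 0 and sum to <= 1")
    }
    if (!is.null(cfg$planted_types)) {
      ok <- c("MEDICATION", "DIAGNOSIS", "SDOH_IND")
      if (!all(cfg$planted_types %in% ok)) {
        bad("planted_types", paste("values must be one of", paste(ok, collapse = "/")))
      }
    }
  }
  if (!all(c("mean", "dispersion") %in% names(cfg$encounters_per_patient)) ||
      cfg$encounters_per_patient[["mean"]] < 1) {
    bad("encounters_per_patient", "needs mean >= 1 and dispersion")
  }
  if (cfg$followup_days < cfg$window_days) bad("followup_days", "shorter than one window")
  if (any(cfg$lab_flag_probs < 0) || sum(cfg$lab_flag_probs) > 1) {
    bad("lab_flag_probs", "must be >= 0 and sum to <= 1")
  }
  if (!all(.rs_lab_flags %in% names(cfg$lab_flag_probs))) {
    bad("lab_flag_probs", "must name ABNORMAL, HIGH, LOW")
  }
  if (cfg$preexisting_ae_prob < 0 || cfg$preexisting_ae_prob > 1) {
    bad("preexisting_ae_prob", "must lie in [0, 1]")
  }
  if (cfg$window_days < 1) bad("window_days", "must be >= 1")
  if (cfg$lookback_days < 1) bad("lookback_days", "must be >= 1")
  if (length(cfg$adverse_codes) < 1) bad("adverse_codes", "at least one code required")
  invisible(cfg)
}

.planted_prevalence <- function(cfg) {
  k <- length(cfg$planted_effects)
  prev <- cfg$planted_prevalence
  if (length(prev) == 1L && is.null(names(prev))) prev <- rep(prev, k)
  if (is.null(names(prev))) names(prev) <- names(cfg$planted_effects)
  prev[names(cfg$planted_effects)]
}

.planted_type <- function(cfg) {
  codes <- names(cfg$planted_effects)
  tp <- setNames(rep("MEDICATION", length(codes)), codes)
  if (!is.null(cfg$planted_types)) tp[names(cfg$planted_types)] <- cfg$planted_types
  tp
}

.patient_seed <- function(master, i) {
  as.integer((as.double(master) * 48271 + i) %% 2147483629)
}

#' Generate a synthetic longitudinal EHR dataset
#'
#' Deterministic for a fixed configuration (including the seed). Every patient
#' has at least one encounter and a qualifying diagnosis at the first
#' encounter; adverse events arise from the discrete-time hazard model
#' described above.
#'
#' @param config an [sim_config()] object.
#' @return a list with `events` (a `data.table` of one row per dated clinical
#'   record: `patient_id`, `date` (integer day), `code_type`, `code`,
#'   `lab_flag`, `zip5`), `truth` (per-patient qualifying day, carrier stratum
#'   and window count, plus every simulated onset and the planted-effect
#'   echo), and `sdoh` (zip-level numeric feature table).
#' @export
generate_dataset <- function(config) {
  validate_sim_config(config)
  cfg <- config
  vs <- cfg$vocab_sizes
  diag_codes <- sprintf("D%03d", seq_len(vs[["diagnosis"]]))
  med_codes <- sprintf("M%03d", seq_len(vs[["medication"]]))
  lab_codes <- sprintf("L%03d", seq_len(vs[["lab"]]))
  sdi_codes <- if (vs[["sdoh_individual"]] > 0) sprintf("S%02d", seq_len(vs[["sdoh_individual"]])) else character(0)
  zips <- sprintf("%05d", 15000L + seq_len(cfg$n_zip))
  prev <- .planted_prevalence(cfg)
  ptype <- .planted_type(cfg)
  pcodes <- names(cfg$planted_effects)
  flag_p <- cfg$lab_flag_probs[.rs_lab_flags]
  W <- cfg$window_days

  n <- cfg$n_patients
  ev <- vector("list", n)
  qual_day <- integer(n); pat_zip <- character(n)
  carrier <- rep(NA_character_, n); n_windows <- integer(n)
  onset_list <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed(.patient_seed(cfg$seed, i))
    pid <- sprintf("P%06d", i)
    mu <- cfg$encounters_per_patient[["mean"]]
    disp <- cfg$encounters_per_patient[["dispersion"]]
    n_enc <- 1L + rnbinom(1L, size = disp, mu = max(mu - 1, 0.1))
    n_enc <- min(n_enc, cfg$followup_days)
    days <- sort(sample.int(cfg$followup_days, n_enc) - 1L)
    zip <- sample(zips, 1L)
    age <- sample(18:80, 1L)
    sex <- sample(c("F", "M"), 1L)
    race <- sample(1:5, 1L)
    sdi_mine <- sdi_codes[runif(length(sdi_codes)) < 0.3]
    my_code <- NA_character_
    if (length(pcodes)) {
      u <- runif(1L)
      hit <- which(u < cumsum(prev))
      if (length(hit)) my_code <- pcodes[hit[1L]]
    }
    has_pre <- runif(1L) < cfg$preexisting_ae_prob
    pre_type <- sample(cfg$adverse_codes, 1L)
    pre_off <- sample(10:60, 1L)

    # encounter content
    nd <- 1L + rpois(n_enc, 1)
    nm <- rpois(n_enc, 0.8)
    nl <- rpois(n_enc, 1)
    d_codes <- sample(diag_codes, sum(nd), replace = TRUE)
    m_codes <- if (sum(nm)) sample(med_codes, sum(nm), replace = TRUE) else character(0)
    l_codes <- if (sum(nl)) sample(lab_codes, sum(nl), replace = TRUE) else character(0)
    l_flags <- if (sum(nl)) {
      sample(c(.rs_lab_flags, ""), sum(nl), replace = TRUE,
             prob = c(flag_p, 1 - sum(flag_p)))
    } else character(0)

    q <- days[1L]
    starts <- seq.int(q, cfg$followup_days - 1L, by = W)
    nw <- length(starts)
    u_w <- runif(nw)
    off_w <- sample.int(W, nw, replace = TRUE)
    type_w <- sample(cfg$adverse_codes, nw, replace = TRUE)

    # assemble static record vectors
    r_date <- c(rep(days, nd), rep(days, nm), rep(days, nl))
    r_type <- c(rep("DIAGNOSIS", sum(nd)), rep("MEDICATION", sum(nm)), rep("LAB", sum(nl)))
    r_code <- c(d_codes, m_codes, l_codes)
    r_flag <- c(rep("", sum(nd) + sum(nm)), l_flags)
    # per-encounter demographic/SDoH records
    sd_codes <- c(sprintf("AGE:%d", age), sprintf("SEX:%s", sex), sprintf("RACE:%d", race), sdi_mine)
    r_date <- c(r_date, rep(days, each = length(sd_codes)))
    r_type <- c(r_type, rep("SDOH_IND", n_enc * length(sd_codes)))
    r_code <- c(r_code, rep(sd_codes, times = n_enc))
    r_flag <- c(r_flag, rep("", n_enc * length(sd_codes)))
    # qualifying diagnosis at first encounter
    r_date <- c(r_date, q); r_type <- c(r_type, "DIAGNOSIS")
    r_code <- c(r_code, cfg$qualifying_code); r_flag <- c(r_flag, "")
    # persistent planted exposure
    if (!is.na(my_code)) {
      r_date <- c(r_date, days); r_type <- c(r_type, rep(ptype[[my_code]], n_enc))
      r_code <- c(r_code, rep(my_code, n_enc)); r_flag <- c(r_flag, rep("", n_enc))
    }
    # pre-existing adverse event
    if (has_pre) {
      r_date <- c(r_date, max(0L, q - pre_off)); r_type <- c(r_type, "DIAGNOSIS")
      r_code <- c(r_code, pre_type); r_flag <- c(r_flag, "")
    }

    # outcome windows (hazard uses encounter history only, drawn above)
    onsets_d <- integer(0); onsets_c <- character(0)
    for (w in seq_len(nw)) {
      s <- starts[w]
      hz <- cfg$baseline_hazard
      if (!is.na(my_code) && any(days > s - cfg$lookback_days & days <= s)) {
        hz <- hz * cfg$planted_effects[[my_code]]
      }
      hz <- min(1, hz)
      if (u_w[w] < hz) {
        onsets_d <- c(onsets_d, s + off_w[w])
        onsets_c <- c(onsets_c, type_w[w])
      }
    }
    if (length(onsets_d)) {
      r_date <- c(r_date, onsets_d); r_type <- c(r_type, rep("DIAGNOSIS", length(onsets_d)))
      r_code <- c(r_code, onsets_c); r_flag <- c(r_flag, rep("", length(onsets_d)))
    }

    ev[[i]] <- list(patient_id = rep(pid, length(r_date)),
                    date = as.integer(r_date), code_type = r_type,
                    code = r_code, lab_flag = r_flag,
                    zip5 = rep(zip, length(r_date)))
    qual_day[i] <- q; pat_zip[i] <- zip; carrier[i] <- my_code; n_windows[i] <- nw
    onset_list[[i]] <- if (length(onsets_d)) {
      list(patient_id = rep(pid, length(onsets_d)), day = onsets_d, code = onsets_c)
    } else NULL
  }

  events <- data.table(
    patient_id = unlist(lapply(ev, `[[`, "patient_id")),
    date = unlist(lapply(ev, `[[`, "date")),
    code_type = unlist(lapply(ev, `[[`, "code_type")),
    code = unlist(lapply(ev, `[[`, "code")),
    lab_flag = unlist(lapply(ev, `[[`, "lab_flag")),
    zip5 = unlist(lapply(ev, `[[`, "zip5"))
  )
  events <- unique(events)
  setorder(events, patient_id, date, code_type, code, lab_flag)

  keep <- !vapply(onset_list, is.null, logical(1))
  onsets <- if (any(keep)) {
    data.table(
      patient_id = unlist(lapply(onset_list[keep], `[[`, "patient_id")),
      day = as.integer(unlist(lapply(onset_list[keep], `[[`, "day"))),
      code = unlist(lapply(onset_list[keep], `[[`, "code"))
    )
  } else {
    data.table(patient_id = character(0), day = integer(0), code = character(0))
  }
  setorder(onsets, patient_id, day, code)

  # zip-level neighborhood SDoH features from the master stream
  set.seed(cfg$seed)
  nf <- vs[["sdoh_neighborhood"]]
  sdoh <- data.table(zip5 = zips)
  for (j in seq_len(nf)) sdoh[[sprintf("nses%02d", j)]] <- round(rnorm(cfg$n_zip), 6)

  truth <- list(
    patients = data.table(patient_id = sprintf("P%06d", seq_len(n)),
                          qualifying_day = qual_day, zip5 = pat_zip,
                          carrier = carrier, n_windows = n_windows),
    onsets = onsets,
    planted_effects = cfg$planted_effects
  )
  list(events = events, truth = truth, sdoh = sdoh)
}

#' Write / read an event table as CSV
#'
#' The on-disk format is long CSV with header
#' `patient_id,date,code_type,code,lab_flag,zip5`; dates are written as
#' ISO-8601 calendar days and converted back to integer day offsets on read
#' (integer day columns are also accepted). `read_events(write_events(x))`
#' is the identity.
#'
#' @param events event `data.table` as produced by [generate_dataset()].
#' @param path file path.
#' @return `write_events` returns `path` invisibly; `read_events` returns the
#'   event `data.table`.
#' @export
write_events <- function(events, path) {
  out <- copy(as.data.table(events))
  out[, date := as.character(.rs_epoch + date)]
  fwrite(out, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  dt <- fread(path, colClasses = list(character = c("patient_id", "date", "code_type",
                                                    "code", "lab_flag", "zip5")))
  need <- c("patient_id", "date", "code_type", "code", "lab_flag", "zip5")
  if (!all(need %in% names(dt))) {
    stop("events file must have columns ", paste(need, collapse = ","))
  }
  bad_type <- which(!dt$code_type %in% .rs_code_types)
  if (length(bad_type)) {
    stop(sprintf("parse error at line %d: unknown code_type '%s'",
                 bad_type[1] + 1L, dt$code_type[bad_type[1]]))
  }
  bad_flag <- which(nzchar(dt$lab_flag) & dt$code_type != "LAB")
  if (length(bad_flag)) {
    stop(sprintf("parse error at line %d: lab_flag on a %s row",
                 bad_flag[1] + 1L, dt$code_type[bad_flag[1]]))
  }
  bad_lab <- which(nzchar(dt$lab_flag) & !dt$lab_flag %in% .rs_lab_flags)
  if (length(bad_lab)) {
    stop(sprintf("parse error at line %d: unknown lab_flag '%s'",
                 bad_lab[1] + 1L, dt$lab_flag[bad_lab[1]]))
  }
  if (nrow(dt) && all(grepl("^-?\\d+$", dt$date))) {
    dt[, date := as.integer(date)]
  } else {
    dt[, date := as.integer(as.Date(date) - .rs_epoch)]
  }
  dt[]
}

#' Write / read the zip-level neighborhood SDoH table
#'
#' CSV with a `zip5` column plus named numeric feature columns.
#'
#' @param sdoh table with `zip5` plus numeric columns.
#' @param path file path.
#' @export
write_sdoh <- function(sdoh, path) {
  out <- copy(as.data.table(sdoh))
  out[, zip5 := as.character(zip5)]
  fwrite(out, path)
  invisible(path)
}

#' @rdname write_sdoh
#' @export
read_sdoh <- function(path) {
  fread(path, colClasses = list(character = "zip5"))[]
}
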