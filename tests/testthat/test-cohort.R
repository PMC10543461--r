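cc_default <- function(...) {
  cohort_config(qualifying_codes = "QD", adverse_event_codes = c("A", "B"),
                seed = 7, ...)
}

test_that("first-occurrence and new-onset-by-type rules hold", {
  ev <- toy_events(list(
    p1 = list(enc = c(100, 120), qual = 100,
              ae = data.frame(day = c(150, 200), code = c("A", "A"))),
    p2 = list(enc = c(40, 100, 150), qual = 100,
              ae = data.frame(day = c(50, 180), code = c("A", "B"))),
    p3 = list(enc = c(10, 20))
  ))
  on <- find_onsets(ev, cc_default())
  # p1: two records of type A -> single onset at the first
  expect_equal(on$onsets[patient_id == "p1", .(code, day)],
               data.table::data.table(code = "A", day = 150))
  # p2: A pre-existing at day 50 (before qualifying), B is the only new onset
  expect_equal(on$onsets[patient_id == "p2", .(code, day)],
               data.table::data.table(code = "B", day = 180))
  # p3: no qualifying code anywhere -> absent entirely
  expect_false("p3" %in% on$patients$patient_id)
  expect_false("p3" %in% on$onsets$patient_id)
})

test_that("patients with adverse events but no qualifying code are excluded with a message", {
  ev <- toy_events(list(
    p1 = list(enc = 10, qual = 10, ae = data.frame(day = 50, code = "A")),
    p9 = list(enc = 5, ae = data.frame(day = 30, code = "B"))
  ))
  expect_message(on <- find_onsets(ev, cc_default()), "excluded")
  expect_identical(on$excluded, "p9")
})

test_that("augmentation emits one case sample per window-satisfying encounter", {
  ev <- toy_events(list(
    p1 = list(enc = c(0, 30, 60), qual = 0, ae = data.frame(day = 80, code = "A")),
    c1 = list(enc = c(0, 50, 100, 200), qual = 0),
    c2 = list(enc = c(10, 90, 300), qual = 10)
  ))
  cfg <- cc_default()
  on <- find_onsets(ev, cfg)
  s <- build_samples(ev, on, cfg)
  cases <- s[label == 1L]
  expect_equal(nrow(cases), 3L)                    # indices 0, 30, 60 all catch day 80
  expect_setequal(cases$index_date, c(0, 30, 60))
  expect_true(all(cases$patient_id == "p1"))
  expect_true(all(cases$target_event_code == "A"))
  expect_equal(nrow(s[label == 0L]), 3L)           # ratio 1.0 -> same count
})

test_that("an onset outside every window yields no case samples", {
  ev <- toy_events(list(
    p1 = list(enc = c(0, 30, 60), qual = 0, ae = data.frame(day = 200, code = "A")),
    p2 = list(enc = c(0, 40), qual = 0, ae = data.frame(day = 70, code = "B")),
    c1 = list(enc = c(0, 100, 250), qual = 0)
  ))
  cfg <- cc_default()
  on <- find_onsets(ev, cfg)
  s <- build_samples(ev, on, cfg)
  expect_false("p1" %in% s[label == 1L, patient_id])
  # p1's encounters can double as controls only when explicitly allowed
  expect_false("p1" %in% s[label == 0L, patient_id])
  cfg2 <- cc_default(allow_case_patients_as_controls = TRUE,
                     control_sampling_ratio = 5)
  s2 <- suppressWarnings(build_samples(ev, on, cfg2))
  # all of p1's pre-onset encounters have no event inside (d, d+90] and are
  # therefore control-eligible once case patients are allowed
  expect_true(all(c(0, 30, 60) %in%
                    s2[label == 0L & patient_id == "p1", index_date]))
})

test_that("an all-window-missing cohort raises the empty-cohort error", {
  ev <- toy_events(list(
    p1 = list(enc = 0, qual = 0, ae = data.frame(day = 500, code = "A")),
    c1 = list(enc = c(0, 10), qual = 0)
  ))
  cfg <- cc_default()
  expect_error(build_samples(ev, find_onsets(ev, cfg), cfg), "empty cohort")
})

test_that("control draw honours the sampling ratio exactly", {
  spec <- list(p1 = list(enc = seq(0, 270, by = 30), qual = 0,
                         ae = data.frame(day = 300, code = "A")))
  for (k in 1:10) {
    spec[[paste0("c", k)]] <- list(enc = seq(0, 900, by = 90), qual = 0)
  }
  ev <- toy_events(spec)
  cfg <- cc_default()
  s <- build_samples(ev, find_onsets(ev, cfg), cfg)
  n_case <- nrow(s[label == 1L])
  expect_gte(n_case, 3L)
  expect_equal(nrow(s[label == 0L]), round(1.0 * n_case))
  cfg2 <- cc_default(control_sampling_ratio = 2)
  s2 <- build_samples(ev, find_onsets(ev, cfg2), cfg2)
  expect_equal(nrow(s2[label == 0L]), round(2 * nrow(s2[label == 1L])))
})

test_that("splitting is by patient, deterministic, and near 8:1:1", {
  s <- data.table::data.table(
    sample_id = sprintf("S%02d", 1:10), patient_id = sprintf("p%02d", 1:10),
    index_date = 0L, label = rep(0:1, 5), target_event_code = NA_character_)
  cfg <- cc_default()
  f1 <- split_samples(s, cfg)
  expect_equal(sort(as.integer(table(f1$fold))), c(1, 1, 8))
  expect_identical(f1, split_samples(s, cfg))
  # augmented samples of one patient stay together
  s2 <- rbind(s, data.table::data.table(sample_id = sprintf("X%d", 1:5),
                                        patient_id = "p01", index_date = 1:5,
                                        label = 1L, target_event_code = "A"))
  f2 <- split_samples(s2, cfg)
  expect_equal(length(unique(f2[patient_id == "p01", fold])), 1L)
  expect_error(split_samples(s[1:2], cfg), "3 patients")
})

test_that("emitted samples satisfy the window/label invariants on random timelines", {
  win <- 90L
  for (rep in 1:8) {
    set.seed(100 + rep)
    spec <- list()
    for (i in 1:15) {
      enc <- sort(sample(0:400, sample(2:8, 1)))
      ae <- NULL
      if (runif(1) < 0.6) {
        k <- sample(1:3, 1)
        ae <- data.frame(day = sample(0:450, k),
                         code = sample(c("A", "B"), k, replace = TRUE))
      }
      spec[[paste0("p", i)]] <- list(enc = enc, qual = enc[1], ae = ae)
    }
    ev <- toy_events(spec)
    cfg <- cohort_config("QD", c("A", "B"), seed = rep)
    on <- find_onsets(ev, cfg)
    s <- tryCatch(suppressWarnings(build_samples(ev, on, cfg)),
                  error = function(e) NULL)
    if (is.null(s)) next  # no eligible case sample in this world

    ae_all <- ev[code %in% c("A", "B")]
    first_new <- on$onsets[order(patient_id, day, code)][, .SD[1L], by = patient_id]
    for (j in seq_len(nrow(s))) {
      pid <- s$patient_id[j]; idx <- s$index_date[j]
      qd <- on$patients[patient_id == pid, qualifying_day]
      expect_gte(idx, qd)
      if (s$label[j] == 1L) {
        od <- first_new[patient_id == pid, day]
        expect_true(od > idx && od <= idx + win)      # onset inside the window
        expect_lt(idx, od)                            # history excludes the onset
        expect_equal(s$target_event_code[j], first_new[patient_id == pid, code])
      } else {
        hits <- ae_all[patient_id == pid & date > idx & date <= idx + win]
        expect_equal(nrow(hits), 0L)
      }
    }
    # brute-force re-enumeration of the case-sample set
    expected_cases <- 0L
    for (pid in first_new$patient_id) {
      od <- first_new[patient_id == pid, day]
      qd <- on$patients[patient_id == pid, qualifying_day]
      encs <- unique(ev[patient_id == pid, date])
      expected_cases <- expected_cases +
        sum(encs >= qd & encs < od & od <= encs + win)
    }
    expect_equal(nrow(s[label == 1L]), expected_cases)
    # no patient in two folds
    if (length(unique(s$patient_id)) >= 3L) {
      f <- split_samples(s, cfg)
      expect_true(all(tapply(f$fold, f$patient_id,
                             function(x) length(unique(x))) == 1L))
    }
  }
})
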