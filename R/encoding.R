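# Tokenisation of multimodal clinical events and assembly of visit sequences.
#
# Token namespaces: DX: clustered diagnoses, RX: mapped medication ids,
# LAB:<code>:<flag> for flagged lab results only (normal results carry no
# signal and are dropped), SD: individual-level social determinants (age
# binned to decades), NB:<feature>:Q<k> quantile-binned neighborhood-level
# indices, NB:MISSING when a patient's zip is absent from the table.

.rs_pad <- "<PAD>"
.rs_unk <- "<UNK>"

.apply_map <- function(codes, map) {
  if (is.null(map)) return(codes)
  if (is.data.frame(map)) map <- setNames(as.character(map[[2L]]), as.character(map[[1L]]))
  hit <- map[codes]
  ifelse(is.na(hit), codes, unname(hit))
}

.sd_token <- function(codes) {
  age <- grepl("^AGE:", codes)
  out <- paste0("SD:", codes)
  if (any(age)) {
    yrs <- suppressWarnings(as.integer(sub("^AGE:", "", codes[age])))
    dec <- ifelse(is.na(yrs), "NA", as.character((yrs %/% 10L) * 10L))
    out[age] <- paste0("SD:AGE:", dec)
  }
  out
}

#' Tokenize clinical event records
#'
#' Maps each event row to zero or more tokens: diagnoses through the optional
#' cluster map (`DX:`), medications through the optional drug-id map (`RX:`),
#' lab results only when flagged `ABNORMAL`/`HIGH`/`LOW` (`LAB:<code>:<flag>`),
#' and individual SDoH codes (`SD:`, with continuous age binned to decades).
#' Unknown codes fall through the maps unchanged.
#'
#' @param events event table (`patient_id`, `date`, `code_type`, `code`,
#'   `lab_flag` columns).
#' @param cluster_map,drug_map optional named character vectors (or two-column
#'   data frames `raw,mapped`) translating raw codes.
#' @return `data.table` with `patient_id`, `date`, `token`, `static`
#'   (`TRUE` for SDoH tokens, which attach to the sample rather than a visit).
#' @export
tokenize_events <- function(events, cluster_map = NULL, drug_map = NULL) {
  ev <- as.data.table(events)
  out <- ev[, .(patient_id, date, code_type, code, lab_flag)]
  out[, token := NA_character_]
  out[code_type == "DIAGNOSIS", token := paste0("DX:", .apply_map(code, cluster_map))]
  out[code_type == "MEDICATION", token := paste0("RX:", .apply_map(code, drug_map))]
  out[code_type == "LAB" & lab_flag %in% .rs_lab_flags,
      token := paste0("LAB:", code, ":", lab_flag)]
  out[code_type == "SDOH_IND", token := .sd_token(code)]
  out <- out[!is.na(token), .(patient_id, date, token, static = code_type == "SDOH_IND")]
  unique(out)
}

#' @rdname tokenize_events
#' @param record a single-row event (list or one-row data frame).
#' @return `tokenize_record` returns a character vector of tokens (possibly
#'   empty, e.g. for an unflagged lab result).
#' @export
tokenize_record <- function(record, cluster_map = NULL, drug_map = NULL) {
  dt <- as.data.table(record[c("patient_id", "date", "code_type", "code", "lab_flag")])
  tokenize_events(dt, cluster_map, drug_map)$token
}

#' Quantile-bin a neighborhood SDoH table into tokens
#'
#' Each numeric feature is discretised by dataset-level quantile bins
#' (quintiles by default) into tokens `NB:<feature>:Q<k>`.
#'
#' @param sdoh table with `zip5` plus numeric feature columns.
#' @param n_bins number of quantile bins.
#' @return `data.table` mapping `zip5` to `token`.
#' @export
neighborhood_tokens <- function(sdoh, n_bins = 5L) {
  sd <- as.data.table(sdoh)
  feats <- setdiff(names(sd), "zip5")
  out <- lapply(feats, function(f) {
    x <- sd[[f]]
    br <- unique(quantile(x, probs = seq_len(n_bins - 1L) / n_bins, na.rm = TRUE))
    bin <- 1L + findInterval(x, br, left.open = TRUE)
    data.table(zip5 = sd$zip5, token = sprintf("NB:%s:Q%d", f, bin))
  })
  rbindlist(out)
}

#' Neighborhood SDoH tokens for one patient
#'
#' @param zip a 5-character zip code (or `NA`).
#' @param nb_tokens output of [neighborhood_tokens()].
#' @return character vector of `NB:` tokens; `"NB:MISSING"` when the zip is
#'   absent from the table.
#' @export
attach_neighborhood_sdoh <- function(zip, nb_tokens) {
  if (is.null(nb_tokens)) return(character(0))
  if (is.na(zip) || !zip %in% nb_tokens$zip5) return("NB:MISSING")
  nb_tokens[zip5 == zip, token]
}

#' Build a token vocabulary from training-fold samples
#'
#' Tokens carried by at least `min_patient_count` distinct training patients
#' are retained; all others map to the unknown token. Ids are contiguous with
#' `<PAD>` = 1 and `<UNK>` = 2; retained tokens are ordered by decreasing
#' patient count, ties broken lexicographically.
#'
#' @param token_dt `data.table` with `patient_id` and `token` columns
#'   (training fold only).
#' @param min_patient_count retention threshold in distinct patients.
#' @return an object of class `rs_vocab`.
#' @export
build_vocabulary <- function(token_dt, min_patient_count = 10L) {
  td <- as.data.table(token_dt)
  if (nrow(td) == 0L) stop("cannot build a vocabulary from an empty training fold")
  cnt <- unique(td[, .(patient_id, token)])[, .(n_pat = .N), by = token]
  keep <- cnt[n_pat >= min_patient_count]
  setorder(keep, -n_pat, token)
  tokens <- c(.rs_pad, .rs_unk, keep$token)
  vocab <- list(tokens = tokens,
                ids = setNames(seq_along(tokens), tokens),
                counts = setNames(c(NA_integer_, NA_integer_, keep$n_pat), tokens),
                min_patient_count = as.integer(min_patient_count))
  class(vocab) <- "rs_vocab"
  vocab
}

#' @export
print.rs_vocab <- function(x, ...) {
  cat(sprintf("<rs_vocab> %d tokens (+PAD/UNK), min patient count %d\n",
              length(x$tokens) - 2L, x$min_patient_count))
  invisible(x)
}

#' Map tokens to vocabulary ids
#'
#' @param vocab an `rs_vocab`.
#' @param tokens character vector.
#' @return integer ids; tokens outside the vocabulary map to the `<UNK>` id.
#' @export
vocab_id <- function(vocab, tokens) {
  id <- vocab$ids[tokens]
  id[is.na(id)] <- vocab$ids[[.rs_unk]]
  as.integer(unname(id))
}

#' Persist / load a vocabulary as TSV (token, id, patient_count)
#' @param vocab an `rs_vocab`.
#' @param path file path.
#' @export
write_vocabulary <- function(vocab, path) {
  fwrite(data.table(token = vocab$tokens, id = seq_along(vocab$tokens),
                    patient_count = unname(vocab$counts)),
         path, sep = "\t")
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  dt <- fread(path, sep = "\t")
  vocab <- list(tokens = dt$token,
                ids = setNames(dt$id, dt$token),
                counts = setNames(dt$patient_count, dt$token),
                min_patient_count = NA_integer_)
  class(vocab) <- "rs_vocab"
  vocab
}

#' A short fingerprint identifying a vocabulary
#' @param vocab an `rs_vocab`.
#' @return character scalar; changes whenever the token/id mapping changes.
#' @export
vocab_fingerprint <- function(vocab) {
  s <- paste(vocab$tokens, collapse = "|")
  h <- 5381
  for (v in utf8ToInt(s)) h <- (h * 33 + v) %% 2147483647
  sprintf("%d:%d", length(vocab$tokens), as.integer(h))
}

#' Encode cohort samples as visit sequences
#'
#' Events in each sample's history (records dated at or before the index
#' date) are grouped by calendar date into visits of unique token ids; static
#' SDoH tokens (individual `SD:` plus the patient's zip-linked `NB:` tokens)
#' are collected separately and, with `static_position = "prepend"`, injected
#' as a pseudo-visit at the start of the sequence. Histories longer than
#' `max_visits` keep the most recent visits.
#'
#' @param samples sample table from [build_samples()] (any subset).
#' @param events full event table.
#' @param vocab an `rs_vocab` built on the training fold.
#' @param sdoh optional zip-level SDoH table (see [neighborhood_tokens()]).
#' @param cluster_map,drug_map optional code maps (see [tokenize_events()]).
#' @param max_visits maximum number of visits retained per sample.
#' @param include_sdoh if `FALSE`, all `SD:`/`NB:` tokens are dropped (the
#'   "-SDoH" ablation arm).
#' @param static_position `"prepend"` (default) or `"none"` (drop static
#'   tokens from the model input while keeping them in the returned object).
#' @param n_bins quantile bins for neighborhood features.
#' @return list of encoded samples; each element has `visits` (list of
#'   integer id vectors), `days` (day offsets from the first retained visit),
#'   `static` (integer ids), `label`, `patient_id`, `sample_id`.
#' @export
encode_samples <- function(samples, events, vocab, sdoh = NULL,
                           cluster_map = NULL, drug_map = NULL,
                           max_visits = 200L, include_sdoh = TRUE,
                           static_position = c("prepend", "none"),
                           n_bins = 5L) {
  static_position <- match.arg(static_position)
  s <- as.data.table(samples)
  ev <- as.data.table(events)
  tok <- tokenize_events(ev[patient_id %in% unique(s$patient_id)],
                         cluster_map, drug_map)
  if (!include_sdoh) tok <- tok[static == FALSE]
  nb <- NULL
  if (include_sdoh && !is.null(sdoh)) nb <- neighborhood_tokens(sdoh, n_bins)
  pat_zip <- NULL
  if ("zip5" %in% names(ev)) {
    pat_zip <- ev[, .(zip5 = zip5[1L]), by = patient_id]
    pat_zip <- setNames(pat_zip$zip5, pat_zip$patient_id)
  }

  setorder(tok, patient_id, date, token)
  by_pat <- split(tok, by = "patient_id", keep.by = FALSE)
  unk <- vocab$ids[[.rs_unk]]

  out <- vector("list", nrow(s))
  for (i in seq_len(nrow(s))) {
    pid <- s$patient_id[i]
    pt <- by_pat[[pid]]
    hist <- if (is.null(pt)) pt else pt[date <= s$index_date[i]]
    vis_ids <- list(); vis_days <- integer(0); static_tok <- character(0)
    if (!is.null(hist) && nrow(hist)) {
      static_tok <- unique(hist[static == TRUE, token])
      dyn <- hist[static == FALSE]
      if (nrow(dyn)) {
        sp <- split(dyn$token, dyn$date)
        vis_days <- as.integer(names(sp))
        vis_ids <- lapply(sp, function(tt) sort(unique(vocab_id(vocab, tt))))
        keep <- lengths(vis_ids) > 0L
        vis_ids <- vis_ids[keep]; vis_days <- vis_days[keep]
        if (length(vis_ids) > max_visits) {
          sel <- tail(seq_along(vis_ids), max_visits)
          vis_ids <- vis_ids[sel]; vis_days <- vis_days[sel]
        }
      }
    }
    if (include_sdoh && !is.null(nb) && !is.null(pat_zip)) {
      static_tok <- c(static_tok,
                      attach_neighborhood_sdoh(pat_zip[[pid]] %||% NA_character_, nb))
    }
    static_ids <- sort(unique(vocab_id(vocab, static_tok)))
    visits <- vis_ids
    days <- if (length(vis_days)) vis_days - vis_days[1L] else integer(0)
    if (static_position == "prepend" && length(static_ids)) {
      visits <- c(list(static_ids), visits)
      days <- c(if (length(days)) days[1L] - 1L else 0L, days)
    }
    out[[i]] <- list(visits = visits, days = days, static = static_ids,
                     label = s$label[i], patient_id = pid,
                     sample_id = s$sample_id[i])
  }
  out
}

#' Persist / load encoded sequences as JSON
#'
#' Line-oriented JSON (one sample per line); `read_encoded(write_encoded(x))`
#' reproduces the sequences exactly.
#'
#' @param enc list of encoded samples (see [encode_samples()]).
#' @param path file path.
#' @export
write_encoded <- function(enc, path) {
  lines <- vapply(enc, function(e) {
    jsonlite::toJSON(list(sample_id = e$sample_id, patient_id = e$patient_id,
                          label = e$label, days = e$days, static = e$static,
                          visits = e$visits),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_encoded
#' @export
read_encoded <- function(path) {
  lapply(readLines(path), function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    list(visits = lapply(x$visits, function(v) as.integer(unlist(v))),
         days = as.integer(unlist(x$days)),
         static = as.integer(unlist(x$static)),
         label = as.integer(x$label),
         patient_id = x$patient_id, sample_id = x$sample_id)
  })
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
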