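# Perturbation-based feature contributions and the relative-contribution
# (RC) statistic.
#
# FC: for each sample and each token occurrence, the drop in predicted risk
# when that occurrence is removed (occlusion, deterministic) or perturbed
# with seeded Gaussian embedding noise; summed per patient over all of the
# patient's samples (a patient appearing in both label groups is aggregated
# per label group).
#
# RC for a feature = mean FC among event patients / mean FC among no-event
# patients. On the log scale the delta-method variance is the sum of squared
# coefficients of variation over their group sizes:
#   Var(ln RC) = (sd_e/mean_e)^2 / m + (sd_c/mean_c)^2 / n
# 95% CI = exp(ln RC +/- 1.96 sqrt(Var)), two-sided z-test on ln RC, then
# Bonferroni and Benjamini-Hochberg correction across features.

#' Per-patient perturbation feature contributions
#'
#' @param model a trained `rs_model`.
#' @param enc list of encoded samples (normally the test fold).
#' @param vocab the `rs_vocab` used for encoding.
#' @param mode `"occlusion"` (deterministic removal, default) or `"noise"`
#'   (mean score drop over `K` seeded Gaussian perturbations of the embedded
#'   input).
#' @param granularity `"token"` (default) perturbs *all* occurrences of a
#'   token in a sample at once — one drop per (sample, token) — and
#'   aggregates per patient by the mean over the patient's samples.
#'   `"occurrence"` perturbs one occurrence at a time and aggregates per
#'   patient by the sum over all occurrences. Token granularity is the
#'   default because single-occurrence removal of a persistently recorded
#'   exposure is diluted by redundancy (the other occurrences keep carrying
#'   the signal, leaving sign noise), and because occurrence *totals* scale
#'   with history length, which is label-associated in an augmented cohort
#'   and biases the RC of outcome-independent features.
#' @param scale `"logit"` (default) measures each drop on the log-odds scale,
#'   `"probability"` on the raw risk scale. The log-odds scale makes
#'   per-occurrence contributions comparable across patients: on the
#'   probability scale the sigmoid slope multiplies every drop, so patients
#'   whose scores sit mid-curve (predominantly cases) show uniformly larger
#'   drops for *every* feature, which biases the downstream RC of
#'   outcome-independent features away from 1.
#' @param normalize `"sample"` (default) centres every occurrence drop on
#'   the sample's median drop and divides by the mean absolute deviation
#'   from that median, so a token's contribution is its *excess* response
#'   over the sequence's typical occlusion response; `"none"` keeps raw
#'   drops. Raw drops are label-associated for *every* feature (short,
#'   recent, high-risk histories react far more — and more uniformly in one
#'   direction — to any occlusion than long saturated low-risk ones), so
#'   without within-sample centring the RC of outcome-independent features
#'   drifts away from 1 and the screen loses error control. The
#'   normalization is explicit and switchable.
#' @param K number of noise draws per occurrence.
#' @param noise_sd standard deviation of the embedding noise.
#' @param seed seed for `mode = "noise"`.
#' @return `data.table` with one row per (feature, patient, label-group):
#'   `feature` (token string), `patient_id`, `label`, `fc`. Tokens absent
#'   from a patient's samples yield no row. `<PAD>`/`<UNK>` are skipped.
#' @export
feature_contributions <- function(model, enc, vocab,
                                  mode = c("occlusion", "noise"),
                                  granularity = c("token", "occurrence"),
                                  scale = c("logit", "probability"),
                                  normalize = c("sample", "none"),
                                  K = 10L, noise_sd = 0.1, seed = 1L) {
  mode <- match.arg(mode)
  granularity <- match.arg(granularity)
  scale <- match.arg(scale)
  normalize <- match.arg(normalize)
  tr <- if (scale == "logit") {
    function(p) stats::qlogis(pmin(1 - 1e-12, pmax(1e-12, p)))
  } else {
    identity
  }
  if (!length(enc)) {
    return(data.table(feature = character(0), patient_id = character(0),
                      label = integer(0), fc = numeric(0)))
  }
  base <- score_samples(model, enc)
  skip_ids <- vocab_id(vocab, c(.rs_pad, .rs_unk))
  V <- model$cfg$V; D <- model$cfg$D
  if (mode == "noise") {
    E <- matrix(model$par[seq_len(V * D)], nrow = D, ncol = V)
    set.seed(seed)
  }
  acc <- vector("list", length(enc))
  for (i in seq_along(enc)) {
    visits <- enc[[i]]$visits
    if (!length(visits)) next
    if (granularity == "token") {
      # one perturbation per distinct token: all its occurrences at once
      occ_id <- setdiff(sort(unique(unlist(visits))), skip_ids)
      occ_t <- lapply(occ_id, function(id)
        which(vapply(visits, function(v) id %in% v, logical(1))))
    } else {
      occ_t <- list(); occ_id <- integer(0)
      for (t in seq_along(visits)) {
        ids <- setdiff(visits[[t]], skip_ids)
        occ_t <- c(occ_t, as.list(rep(t, length(ids))))
        occ_id <- c(occ_id, ids)
      }
    }
    if (!length(occ_id)) next
    if (mode == "occlusion") {
      mods <- vector("list", length(occ_id))
      for (k in seq_along(occ_id)) {
        mv <- visits
        for (t in occ_t[[k]]) mv[[t]] <- setdiff(mv[[t]], occ_id[k])
        mv <- mv[lengths(mv) > 0L]
        mods[[k]] <- mv
      }
      drops <- tr(base[i]) - tr(cpp_nn_forward(model$par, model$cfg, mods))
    } else {
      X <- vapply(visits, function(ids) {
        if (!length(ids)) return(numeric(D))
        v <- rowSums(E[, ids, drop = FALSE])
        if (model$cfg$agg == "mean" && length(ids) > 1) v / length(ids) else v
      }, numeric(D))
      X <- matrix(X, nrow = D)
      drops <- vapply(seq_along(occ_id), function(k) {
        pk <- vapply(seq_len(K), function(j) {
          Xk <- X
          for (t in occ_t[[k]]) Xk[, t] <- Xk[, t] + rnorm(D, 0, noise_sd)
          tr(cpp_nn_forward_x(model$par, model$cfg, Xk))
        }, numeric(1))
        tr(base[i]) - mean(pk)
      }, numeric(1))
    }
    if (normalize == "sample") {
      cen <- drops - stats::median(drops)
      denom <- mean(abs(cen))
      drops <- if (denom > 0) cen / denom else rep(0, length(cen))
    }
    acc[[i]] <- data.table(feature = vocab$tokens[occ_id],
                           patient_id = enc[[i]]$patient_id,
                           label = as.integer(enc[[i]]$label), fc = drops)
  }
  out <- rbindlist(acc)
  if (!nrow(out)) {
    return(data.table(feature = character(0), patient_id = character(0),
                      label = integer(0), fc = numeric(0)))
  }
  out <- if (granularity == "token") {
    out[, .(fc = mean(fc)), by = .(feature, patient_id, label)]
  } else {
    out[, .(fc = sum(fc)), by = .(feature, patient_id, label)]
  }
  setorder(out, feature, patient_id, label)
  out[]
}

#' Relative contribution of one feature with delta-method inference
#'
#' `rc = mean(FC | event) / mean(FC | no event)`, where the means divide by
#' `m` and `n`. By default `m`/`n` are the lengths of the supplied FC vectors
#' (patients carrying the feature); passing the full event/no-event patient
#' counts treats patients without the feature as contributing FC = 0, which
#' is how the pipeline-level screen is run. Inference is carried out whenever
#' both group means share a nonzero sign (ln RC is then defined and the
#' squared-CV variance is sign-invariant); with opposite signs or a zero
#' mean, the CI and p-value are suppressed and the feature is classified
#' `UNDEFINED`. With `conf = 0.95` the CI multiplier is the conventional
#' 1.96.
#'
#' @param fc_event FC values of event (case) patients carrying the feature.
#' @param fc_noevent FC values of no-event (control) patients carrying it.
#' @param m,n group sizes used for the means and the variance (>= the vector
#'   lengths; the difference is filled with zeros).
#' @param conf confidence level.
#' @return one-row `data.table`: `rc`, `ci_low`, `ci_high`, `var_ln_rc`, `z`,
#'   `p_raw`, `m`, `n`, `classification` (`RISK` iff rc > 1, `PROTECTIVE`
#'   iff rc < 1, else `UNDEFINED`).
#' @export
relative_contribution <- function(fc_event, fc_noevent,
                                  m = length(fc_event), n = length(fc_noevent),
                                  conf = 0.95) {
  if (m < length(fc_event) || n < length(fc_noevent)) {
    stop("group sizes m/n cannot be smaller than the number of FC values")
  }
  und <- function(rc = NA_real_) {
    data.table(rc = rc, ci_low = NA_real_, ci_high = NA_real_,
               var_ln_rc = NA_real_, z = NA_real_, p_raw = NA_real_,
               m = as.integer(m), n = as.integer(n),
               classification = "UNDEFINED")
  }
  if (m < 2L || n < 2L) return(und())
  if (length(fc_event) == 0L || length(fc_noevent) == 0L) return(und())
  e <- c(fc_event, rep(0, m - length(fc_event)))
  c_ <- c(fc_noevent, rep(0, n - length(fc_noevent)))
  me <- mean(e); mc <- mean(c_)
  if (me == 0 || mc == 0) return(und())
  rc <- me / mc
  if (rc <= 0) return(und(rc))
  v <- (sd(e) / me)^2 / m + (sd(c_) / mc)^2 / n
  zmult <- if (identical(conf, 0.95)) 1.96 else stats::qnorm(1 - (1 - conf) / 2)
  half <- zmult * sqrt(v)
  z <- if (v == 0) {
    if (log(rc) == 0) 0 else sign(log(rc)) * Inf
  } else {
    log(rc) / sqrt(v)
  }
  data.table(rc = rc, ci_low = exp(log(rc) - half), ci_high = exp(log(rc) + half),
             var_ln_rc = v, z = z, p_raw = 2 * pnorm(-abs(z)),
             m = as.integer(m), n = as.integer(n),
             classification = if (rc > 1) "RISK" else if (rc < 1) "PROTECTIVE" else "UNDEFINED")
}

#' Bonferroni and Benjamini-Hochberg adjustment
#'
#' Order-preserving with the input; Bonferroni is `min(1, M p)` with `M` the
#' number of tests, BH is the step-up procedure with monotonicity
#' enforcement (both via [stats::p.adjust()]).
#'
#' @param p vector of raw p-values in `[0, 1]` (no missing values).
#' @return list with `bonferroni` and `fdr` vectors aligned with `p`.
#' @export
adjust_pvalues <- function(p) {
  if (!length(p)) return(list(bonferroni = numeric(0), fdr = numeric(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  list(bonferroni = p.adjust(p, method = "bonferroni"),
       fdr = p.adjust(p, method = "BH"))
}

#' Relative contributions for every feature in an FC table
#'
#' @param fc_table output of [feature_contributions()].
#' @param n_event,n_noevent total numbers of event / no-event patients in the
#'   analysis set. If `NULL`, the per-feature carrier counts are used (the
#'   carrier-only statistic); the pipeline passes the full counts so that
#'   non-carriers contribute FC = 0.
#' @param conf confidence level.
#' @return `data.table` with one row per feature: the columns of
#'   [relative_contribution()] plus `feature`, `p_bonferroni` and `q_fdr`
#'   (adjusted across the features with a defined p; the Bonferroni
#'   multiplier is the number of features tested).
#' @export
analyze_contributions <- function(fc_table, n_event = NULL, n_noevent = NULL,
                                  conf = 0.95) {
  fc <- as.data.table(fc_table)
  feats <- sort(unique(fc$feature))
  rows <- lapply(feats, function(f) {
    fe <- fc[feature == f & label == 1L, fc]
    fn <- fc[feature == f & label == 0L, fc]
    r <- relative_contribution(fe, fn,
                               m = if (is.null(n_event)) length(fe) else n_event,
                               n = if (is.null(n_noevent)) length(fn) else n_noevent,
                               conf = conf)
    cbind(data.table(feature = f), r)
  })
  out <- rbindlist(rows)
  out[, p_bonferroni := NA_real_]
  out[, q_fdr := NA_real_]
  tested <- which(!is.na(out$p_raw))
  if (length(tested)) {
    adj <- adjust_pvalues(out$p_raw[tested])
    out[tested, p_bonferroni := adj$bonferroni]
    out[tested, q_fdr := adj$fdr]
  }
  out[]
}

#' Rank features into the report layout
#'
#' Orders by FDR q-value ascending (default); rows without inference
#' (`UNDEFINED` with no p-value) sink to the bottom. Columns follow the
#' conventional screen layout: `Feature Name`, `RC`, `95%CIup`, `95%CIdown`,
#' `FDR_Q`, `Bonferroni corrected p-value`.
#'
#' @param results output of [analyze_contributions()].
#' @param by `"q"` (FDR q-value) or `"rc"`.
#' @return ordered `data.table` in report layout.
#' @export
rank_features <- function(results, by = c("q", "rc")) {
  by <- match.arg(by)
  r <- as.data.table(results)
  key <- if (by == "q") r$q_fdr else -r$rc
  ord <- order(is.na(key), key, r$feature)
  r <- r[ord]
  data.table(`Feature Name` = r$feature, RC = r$rc,
             `95%CIup` = r$ci_high, `95%CIdown` = r$ci_low,
             FDR_Q = r$q_fdr, `Bonferroni corrected p-value` = r$p_bonferroni)
}

#' Write / read an FC table or report CSV
#' @param x table to write.
#' @param path file path.
#' @export
write_rc_report <- function(x, path) {
  fwrite(as.data.table(x), path)
  invisible(path)
}

#' @rdname write_rc_report
#' @export
read_rc_report <- function(path) {
  fread(path)[]
}
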