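# Independent straight-line oracles used to cross-check the package
# implementations. These deliberately share no code with the package.

# Relative contribution: direct transcription of the definition.
rc_oracle <- function(fc_e, fc_c, m = length(fc_e), n = length(fc_c)) {
  out <- list(rc = NA_real_, var = NA_real_, lo = NA_real_, hi = NA_real_,
              p = NA_real_, cls = "UNDEFINED")
  if (m < 2 || n < 2 || length(fc_e) == 0 || length(fc_c) == 0) return(out)
  e <- c(fc_e, rep(0, m - length(fc_e)))
  cc <- c(fc_c, rep(0, n - length(fc_c)))
  me <- sum(e) / m
  mc <- sum(cc) / n
  if (me == 0 || mc == 0) return(out)
  rc <- me / mc
  out$rc <- rc
  if (rc <= 0) return(out)
  sde <- sqrt(sum((e - me)^2) / (m - 1))
  sdc <- sqrt(sum((cc - mc)^2) / (n - 1))
  v <- (sde / me)^2 / m + (sdc / mc)^2 / n
  lo <- exp(log(rc) - 1.96 * sqrt(v))
  hi <- exp(log(rc) + 1.96 * sqrt(v))
  z <- if (v == 0) { if (log(rc) == 0) 0 else sign(log(rc)) * Inf } else log(rc) / sqrt(v)
  p <- 2 * stats::pnorm(-abs(z))
  cls <- if (rc > 1) "RISK" else if (rc < 1) "PROTECTIVE" else "UNDEFINED"
  list(rc = rc, var = v, lo = lo, hi = hi, p = p, cls = cls)
}

# Benjamini-Hochberg by the raw definition: q_i = min over j with
# p_(j) >= p_(i) of M * p_(j) / j, capped at 1.
bh_oracle <- function(p) {
  M <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(M)
  for (i in seq_len(M)) q[i] <- min(1, min(M * ps[i:M] / (i:M)))
  out <- numeric(M)
  out[o] <- q
  out
}

bonf_oracle <- function(p) pmin(1, length(p) * p)

# AUROC by exhaustive case/control pair comparison (ties count half).
auroc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Build a long event table from compact per-patient specs:
# list(pid = list(enc = days, qual = day or NULL, ae = data.frame(day, code)))
toy_events <- function(spec, qual_code = "QD", enc_code = "ENC") {
  rows <- list()
  for (pid in names(spec)) {
    s <- spec[[pid]]
    for (d in s$enc) {
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = pid, date = d, code_type = "DIAGNOSIS",
        code = enc_code, lab_flag = "", zip5 = "00000")
    }
    if (!is.null(s$qual)) {
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = pid, date = s$qual, code_type = "DIAGNOSIS",
        code = qual_code, lab_flag = "", zip5 = "00000")
    }
    if (!is.null(s$ae)) {
      for (k in seq_len(nrow(s$ae))) {
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = pid, date = s$ae$day[k], code_type = "DIAGNOSIS",
          code = s$ae$code[k], lab_flag = "", zip5 = "00000")
      }
    }
  }
  data.table::as.data.table(do.call(rbind, rows))
}

# Minimal encoded-sample constructor for model-level tests.
enc_sample <- function(visits, label, patient_id = "P1", sample_id = "S1") {
  list(visits = lapply(visits, as.integer), days = seq_along(visits) - 1L,
       static = integer(0), label = label, patient_id = patient_id,
       sample_id = sample_id)
}

# Separable toy task: token `signal_id` present iff label 1, plus noise
# tokens drawn from the rest of a vocabulary of size V.
toy_separable <- function(n, V = 10L, signal_id = 3L, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    lab <- i %% 2L
    ids1 <- sample(setdiff(3:V, signal_id), 2)
    ids2 <- sample(setdiff(3:V, signal_id), 2)
    v1 <- if (lab == 1L) c(signal_id, ids1[1]) else ids1
    enc_sample(list(v1, ids2), lab, patient_id = paste0("P", i),
               sample_id = paste0("S", i))
  })
}

tiny_nn_cfg <- function(arch = "tlstm", V = 8L, D = 4L, H = 3L, L = 2L,
                        gate = "tanh") {
  list(arch = arch, V = V, D = D, H = H, L = L, gate = gate,
       dropout = 0, agg = "sum")
}
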