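make_toy_model <- function(seed = 13, V = 10L, D = 4L, H = 4L) {
  cfg <- list(arch = "tlstm", V = V, D = D, H = H, L = 1L, gate = "tanh",
              dropout = 0, agg = "sum")
  set.seed(seed)
  structure(list(par = runif(riskseq:::cpp_par_count(cfg), -0.4, 0.4),
                 cfg = cfg, vocab_fingerprint = "toy", log = NULL),
            class = "rs_model")
}

toy_vocab <- function(V = 10L) {
  build_vocabulary(
    data.table::data.table(patient_id = paste0("p", seq_len(V - 2)),
                           token = paste0("T", seq_len(V - 2))), 1)
}

test_that("occlusion contributions are deterministic and sum per occurrence", {
  m <- make_toy_model()
  v <- toy_vocab()
  enc <- list(
    enc_sample(list(c(3L, 4L), c(5L), c(3L, 6L)), 1, "pa", "S1"),
    enc_sample(list(c(4L, 7L)), 0, "pb", "S2"))
  fc1 <- feature_contributions(m, enc, v, granularity = "occurrence",
                               scale = "probability", normalize = "none")
  fc2 <- feature_contributions(m, enc, v, granularity = "occurrence",
                               scale = "probability", normalize = "none")
  expect_identical(fc1, fc2)

  # oracle: recompute each occurrence drop by direct rescoring
  base <- riskseq:::cpp_nn_forward(m$par, m$cfg, list(enc[[1]]$visits))
  d1 <- base - riskseq:::cpp_nn_forward(m$par, m$cfg,
                                        list(list(c(4L), c(5L), c(3L, 6L))))
  d2 <- base - riskseq:::cpp_nn_forward(m$par, m$cfg,
                                        list(list(c(3L, 4L), c(5L), c(6L))))
  tok3 <- v$tokens[3]
  expect_equal(fc1[feature == tok3 & patient_id == "pa", fc], d1 + d2,
               tolerance = 1e-12)
})

test_that("a token with a zeroed embedding contributes exactly nothing", {
  m <- make_toy_model()
  v <- toy_vocab()
  id <- 5L
  m$par[((id - 1) * m$cfg$D + 1):(id * m$cfg$D)] <- 0  # embedding column
  enc <- list(enc_sample(list(c(3L, 5L), c(5L, 6L)), 1, "pa", "S1"))
  fc <- feature_contributions(m, enc, v, granularity = "occurrence",
                              scale = "probability", normalize = "none")
  expect_equal(fc[feature == v$tokens[id], fc], 0, tolerance = 1e-14)
})

test_that("contributions aggregate per patient across samples and label groups", {
  m <- make_toy_model()
  v <- toy_vocab()
  enc <- list(
    enc_sample(list(c(3L)), 1, "pa", "S1"),
    enc_sample(list(c(3L), c(4L)), 1, "pa", "S2"),
    enc_sample(list(c(3L)), 0, "pa", "S3"))  # same patient as a control
  fc <- feature_contributions(m, enc, v, granularity = "occurrence",
                              scale = "probability", normalize = "none")
  tok3 <- v$tokens[3]
  expect_equal(nrow(fc[feature == tok3]), 2L)  # one row per label group
  per_sample <- sapply(1:2, function(i) {
    b <- riskseq:::cpp_nn_forward(m$par, m$cfg, list(enc[[i]]$visits))
    mv <- enc[[i]]$visits
    mv[[1]] <- setdiff(mv[[1]], 3L)
    if (!length(mv[[1]])) mv[[1]] <- NULL
    b - riskseq:::cpp_nn_forward(m$par, m$cfg, list(mv))
  })
  expect_equal(fc[feature == tok3 & label == 1L, fc], sum(per_sample),
               tolerance = 1e-12)
})

test_that("noise-mode contributions are seeded and reproducible", {
  m <- make_toy_model()
  v <- toy_vocab()
  enc <- list(enc_sample(list(c(3L, 4L), c(5L)), 1, "pa", "S1"))
  a <- feature_contributions(m, enc, v, mode = "noise", K = 5, seed = 9)
  b <- feature_contributions(m, enc, v, mode = "noise", K = 5, seed = 9)
  d <- feature_contributions(m, enc, v, mode = "noise", K = 5, seed = 10)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$fc, d$fc)))
})

test_that("relative contribution reproduces hand-computed cases", {
  r <- relative_contribution(c(2, 4), c(1, 1, 1))
  expect_equal(r$rc, 3.0)
  expect_equal(r$classification, "RISK")

  r2 <- relative_contribution(c(1, 3), c(2, 2))
  expect_equal(r2$rc, 1.0)
  expect_equal(r2$var_ln_rc, 0.25)
  expect_equal(r2$ci_low, exp(-0.98), tolerance = 1e-12)
  expect_equal(r2$ci_high, exp(0.98), tolerance = 1e-12)
  expect_equal(r2$p_raw, 1.0)
  expect_equal(r2$classification, "UNDEFINED")  # rc exactly 1

  r3 <- relative_contribution(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r3$rc, 1.0)
  expect_equal(r3$classification, "UNDEFINED")

  # zero-padding to stated group sizes
  r4 <- relative_contribution(c(2, 4), c(1, 1, 1), m = 4, n = 6)
  expect_equal(r4$rc, (6 / 4) / (3 / 6))
  expect_error(relative_contribution(c(1, 2), c(1), m = 1), "smaller")

  # insufficient data and sign problems are flagged, not tested
  expect_equal(relative_contribution(c(1), c(1, 2))$classification, "UNDEFINED")
  expect_equal(relative_contribution(c(1, 2), c(-1, 1))$classification, "UNDEFINED")
  r5 <- relative_contribution(c(-1, -2), c(-3, -1))
  expect_equal(r5$rc, 0.75)
  expect_equal(r5$classification, "PROTECTIVE")
})

test_that("p-value adjustment matches the textbook definitions", {
  p <- rep(0.001, 50)
  expect_equal(adjust_pvalues(p)$bonferroni, rep(0.05, 50))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.04))$fdr, c(0.03, 0.03, 0.04))
  expect_equal(adjust_pvalues(0.2), list(bonferroni = 0.2, fdr = 0.2))
  expect_equal(adjust_pvalues(numeric(0)),
               list(bonferroni = numeric(0), fdr = numeric(0)))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
  # BH is monotone in sorted order and permutation-equivariant
  set.seed(12)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    q <- adjust_pvalues(p)$fdr
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    perm <- sample(length(p))
    expect_equal(adjust_pvalues(p[perm])$fdr[order(perm)], q)
  }
})

test_that("feature ranking orders by q with undefined rows last", {
  res <- data.table::data.table(
    feature = c("A", "B", "C"),
    rc = c(2, 0.5, NA), ci_low = c(1.5, 0.3, NA), ci_high = c(3, 0.9, NA),
    var_ln_rc = c(0.1, 0.1, NA), z = c(2, -2, NA),
    p_raw = c(0.04, 0.001, NA), m = 5L, n = 5L,
    classification = c("RISK", "PROTECTIVE", "UNDEFINED"),
    p_bonferroni = c(0.08, 0.002, NA), q_fdr = c(0.1, 0.001, NA))
  rep <- rank_features(res)
  expect_equal(rep[["Feature Name"]], c("B", "A", "C"))
  expect_equal(names(rep), c("Feature Name", "RC", "95%CIup", "95%CIdown",
                             "FDR_Q", "Bonferroni corrected p-value"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_rc_report(rep, f)
  back <- read_rc_report(f)
  expect_equal(back[["Feature Name"]], rep[["Feature Name"]])
  expect_equal(back$RC, rep$RC, tolerance = 1e-6)
})

test_that("the analysis table adjusts only the tested features", {
  fc <- data.table::data.table(
    feature = rep(c("A", "B", "C"), each = 4),
    patient_id = rep(paste0("p", 1:4), 3),
    label = rep(c(1L, 1L, 0L, 0L), 3),
    fc = c(2, 4, 1, 1, 1, 1, 1, 1, 1, -1, 1, -1))
  out <- analyze_contributions(fc)
  expect_equal(nrow(out), 3L)
  expect_true(is.na(out[feature == "C", q_fdr]))
  tested <- out[!is.na(p_raw)]
  expect_equal(tested$p_bonferroni,
               pmin(1, nrow(tested) * tested$p_raw), tolerance = 1e-12)
})
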