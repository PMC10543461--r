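test_that("analytic gradients match finite differences for both architectures", {
  for (case in list(c("tlstm", "tanh"), c("tlstm", "sigmoid"),
                    c("retain", "tanh"))) {
    cfg <- tiny_nn_cfg(arch = case[1], gate = case[2])
    n <- riskseq:::cpp_par_count(cfg)
    set.seed(42)
    par <- runif(n, -0.5, 0.5)
    samples <- list(list(c(1L, 3L), 2L, c(4L, 5L, 8L)), list(6L, c(2L, 3L)))
    y <- c(1, 0)
    g <- riskseq:::cpp_nn_loss_grad(par, cfg, samples, y, FALSE)$grad
    h <- 1e-6
    num <- vapply(seq_len(n), function(i) {
      p1 <- par; p1[i] <- p1[i] + h
      p2 <- par; p2[i] <- p2[i] - h
      (riskseq:::cpp_nn_loss_grad(p1, cfg, samples, y, FALSE)$loss -
         riskseq:::cpp_nn_loss_grad(p2, cfg, samples, y, FALSE)$loss) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(num - g)), 1e-6)
  }
})

test_that("scores are probabilities, deterministic, and attention normalises", {
  mc <- model_config("retain", embedding_dim = 6, hidden_size = 5,
                     num_layers = 1, max_epochs = 1, seed = 3)
  v <- build_vocabulary(
    data.table::data.table(patient_id = "p", token = paste0("T", 1:6)), 1)
  par <- init_params(mc, length(v$tokens))
  cfg <- riskseq:::.nn_cfg(mc, length(v$tokens), dropout = 0)
  samples <- toy_separable(10, V = 8)
  p1 <- riskseq:::cpp_nn_forward(par, cfg, lapply(samples, `[[`, "visits"))
  p2 <- riskseq:::cpp_nn_forward(par, cfg, lapply(samples, `[[`, "visits"))
  expect_true(all(p1 > 0 & p1 < 1))
  expect_identical(p1, p2)
  att <- riskseq:::cpp_retain_attention(par, cfg, samples[[1]]$visits)
  expect_equal(sum(att$alpha), 1, tolerance = 1e-6)
  expect_equal(length(att$alpha), length(samples[[1]]$visits))
})

test_that("rank AUROC equals exhaustive pairwise comparison", {
  expect_equal(auroc(c(1, 0), c(0.9, 0.1)), 1.0)
  expect_equal(auroc(c(1, 0, 1, 0), rep(0.8, 4)), 0.5)
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2)), 0.75)
  set.seed(99)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force ties sometimes
    expect_identical(auroc(labels, scores), auroc_oracle(labels, scores))
  }
  expect_error(auroc(rep(1, 4), runif(4)), "both classes")
})

test_that("label permutation drives AUROC to chance", {
  set.seed(7)
  scores <- runif(400)
  labels <- rep(0:1, 200)
  aucs <- replicate(200, auroc(sample(labels), scores))
  expect_lt(abs(mean(aucs) - 0.5), 3 * sd(aucs) / sqrt(200) + 0.01)
})

test_that("threshold metrics handle degenerate predictions", {
  m <- evaluate_scores(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2))
  expect_equal(unname(m["auroc"]), 0.75)
  expect_equal(unname(m["precision"]), 0.5)
  expect_equal(unname(m["recall"]), 0.5)
  expect_warning(m0 <- evaluate_scores(c(1, 0), c(0.1, 0.2)), "precision")
  expect_equal(unname(m0["precision"]), 0)
  expect_equal(unname(m0["f1"]), 0)
})

test_that("training is seeded, early-stops, and rejects one-class folds", {
  tr <- toy_separable(60, seed = 1)
  va <- toy_separable(30, seed = 2)
  mc <- model_config("tlstm", embedding_dim = 6, hidden_size = 5,
                     num_layers = 1, dropout = 0.2, max_epochs = 3,
                     batch_size = 16, seed = 11)
  v <- build_vocabulary(
    data.table::data.table(patient_id = letters[1:10],
                           token = rep(paste0("T", 1:10), length.out = 10)), 1)
  m1 <- train_model(tr, va, mc, v)
  m2 <- train_model(tr, va, mc, v)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$par, m2$par)

  # zero learning rate leaves validation flat: patience 1 stops after 2 epochs
  mc0 <- model_config("tlstm", embedding_dim = 6, hidden_size = 5,
                      num_layers = 1, patience = 1, learning_rate = 0,
                      max_epochs = 10, batch_size = 16, seed = 11)
  m0 <- train_model(tr, va, mc0, v)
  expect_equal(nrow(m0$log), 2L)
  expect_equal(m0$best_epoch, 1L)

  one_class <- toy_separable(20, seed = 3)
  for (e in seq_along(one_class)) one_class[[e]]$label <- 1
  expect_error(train_model(one_class, va, mc, v), "single class")
  expect_error(train_model(tr, one_class, mc, v), "single class")
})

test_that("both architectures learn a separable toy and share the input contract", {
  tr <- toy_separable(400, seed = 5)
  va <- toy_separable(120, seed = 6)
  v <- build_vocabulary(
    data.table::data.table(patient_id = letters[1:10],
                           token = rep(paste0("T", 1:10), length.out = 10)), 1)
  for (arch in c("tlstm", "retain")) {
    mc <- model_config(arch, embedding_dim = 8, hidden_size = 8,
                       num_layers = 2, dropout = 0, max_epochs = 40,
                       batch_size = 32, seed = 21)
    m <- train_model(tr, va, mc, v)
    p <- score_samples(m, va)
    expect_gte(auroc(vapply(va, `[[`, numeric(1), "label"), p), 0.95)
  }
})

test_that("scoring refuses a mismatched vocabulary", {
  tr <- toy_separable(40, seed = 1)
  va <- toy_separable(20, seed = 2)
  v <- build_vocabulary(
    data.table::data.table(patient_id = letters[1:10],
                           token = rep(paste0("T", 1:10), length.out = 10)), 1)
  mc <- model_config("tlstm", embedding_dim = 4, hidden_size = 4,
                     num_layers = 1, max_epochs = 1, batch_size = 16, seed = 2)
  m <- train_model(tr, va, mc, v)
  v2 <- build_vocabulary(
    data.table::data.table(patient_id = letters[1:9],
                           token = rep(paste0("T", 1:9), length.out = 9)), 1)
  expect_error(score_samples(m, va, v2), "fingerprint")
  expect_silent(score_samples(m, va, v))
})

test_that("model checkpoints round-trip with a readable sidecar", {
  tr <- toy_separable(60, seed = 1)
  va <- toy_separable(30, seed = 2)
  v <- build_vocabulary(
    data.table::data.table(patient_id = letters[1:10],
                           token = rep(paste0("T", 1:10), length.out = 10)), 1)
  mc <- model_config("tlstm", embedding_dim = 6, hidden_size = 5,
                     num_layers = 1, max_epochs = 2, batch_size = 16, seed = 4)
  m <- train_model(tr, va, mc, v)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  expect_true(file.exists(paste0(f, ".json")))
  m2 <- load_model(f)
  expect_identical(m2$par, m$par)
  expect_identical(m2$vocab_fingerprint, m$vocab_fingerprint)
  expect_identical(score_samples(m2, va), score_samples(m, va))
})

test_that("a strong planted exposure is recovered by both architectures", {
  ds <- generate_dataset(sim_config(
    n_patients = 2000, baseline_hazard = 0.05,
    planted_effects = c(RX_RISK = 8.0), planted_prevalence = 0.6, seed = 91))
  cc <- cohort_config("Q_INDEX", c("AE_A", "AE_B"), seed = 91)
  on <- find_onsets(ds$events, cc)
  s <- build_samples(ds$events, on, cc)
  for (arch in c("tlstm", "retain")) {
    mc <- model_config(arch, embedding_dim = 32, hidden_size = 32,
                       num_layers = 2, max_epochs = 15, batch_size = 64,
                       seed = 91)
    fit <- fit_once(s, ds$events, cc, mc, sdoh = ds$sdoh, seed = 91)
    expect_gte(fit$test_metrics[["auroc"]], 0.85)
  }
})

test_that("repeated evaluation reports the conventional metric layout", {
  ds <- generate_dataset(sim_config(n_patients = 120,
                                    planted_effects = c(RX_RISK = 6),
                                    planted_prevalence = 0.5, seed = 8))
  cc <- cohort_config("Q_INDEX", c("AE_A", "AE_B"), seed = 8)
  on <- find_onsets(ds$events, cc)
  s <- suppressWarnings(build_samples(ds$events, on, cc))
  mc <- model_config("tlstm", embedding_dim = 8, hidden_size = 8,
                     num_layers = 1, max_epochs = 2, batch_size = 32, seed = 8)
  rep1 <- repeat_experiment(s, ds$events, cc, mc, sdoh = ds$sdoh,
                            n_repeats = 2, seed = 8, min_patient_count = 2)
  expect_s3_class(rep1, "rs_eval_report")
  expect_equal(rownames(rep1),
               c("Validation AUC", "Test AUC", "Test Precision",
                 "Test Recall", "Test F1"))
  expect_equal(colnames(rep1), c("1", "2", "average", "std.s"))
  expect_true(all(rep1$average >= 0 & rep1$average <= 1))
  expect_true(all(rep1[["std.s"]] >= 0))
  rep2 <- repeat_experiment(s, ds$events, cc, mc, sdoh = ds$sdoh,
                            n_repeats = 2, seed = 8, min_patient_count = 2)
  expect_identical(rep1, rep2)
  expect_error(repeat_experiment(s, ds$events, cc, mc, n_repeats = 1), ">= 2")
})
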