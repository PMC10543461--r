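# Training and evaluation of the recurrent classifiers.
#
# Both architectures minimise binary cross-entropy with Adam and stop early
# when the validation AUROC has not improved for `patience` consecutive
# epochs, returning the best-validation parameters. All randomness
# (initialisation, epoch shuffling, dropout) flows through R's RNG from the
# config seed, so training logs are bit-reproducible.

#' Model configuration
#'
#' Defaults follow the reference setting for this model family: embedding and
#' hidden size 128, dropout 0.2, 8 stacked recurrent layers, early-stopping
#' patience 3, and tanh in place of sigmoid for the input/forget/output gates
#' of the LSTM (the probability head keeps sigmoid; sigmoid gates remain
#' available for ablation). The attention architecture uses one recurrent
#' layer per branch regardless of `num_layers`.
#'
#' @param architecture `"tlstm"` (stacked gated LSTM) or `"retain"`
#'   (two-RNN reverse-time attention).
#' @param embedding_dim,hidden_size,num_layers network dimensions.
#' @param dropout dropout rate in `[0, 1)` (between stacked layers, and on
#'   the attention context vector).
#' @param patience early-stopping patience (epochs without validation
#'   improvement), at least 1.
#' @param learning_rate,batch_size,max_epochs Adam optimiser settings.
#' @param gate_activation `"tanh"` or `"sigmoid"` gate activation.
#' @param early_stopping_metric `"loss"` (validation cross-entropy, default)
#'   or `"auroc"`. Ranking metrics can sit high before the network has
#'   learned anything (sequence-length artifacts alone separate the classes),
#'   which makes them a poor model-selection signal early in training; the
#'   validation loss only improves once the probabilities themselves do.
#' @param aggregation `"sum"` or `"mean"` pooling of token embeddings within
#'   a visit.
#' @param threshold classification threshold for precision/recall/F1.
#' @param seed integer seed.
#' @return an object of class `rs_model_config`.
#' @export
model_config <- function(architecture = c("tlstm", "retain"),
                         embedding_dim = 128L, hidden_size = 128L,
                         dropout = 0.2, num_layers = 8L, patience = 3L,
                         learning_rate = 1e-3, batch_size = 64L,
                         max_epochs = 50L,
                         gate_activation = c("tanh", "sigmoid"),
                         early_stopping_metric = c("loss", "auroc"),
                         aggregation = c("sum", "mean"),
                         threshold = 0.5, seed = 1L) {
  architecture <- match.arg(architecture)
  gate_activation <- match.arg(gate_activation)
  early_stopping_metric <- match.arg(early_stopping_metric)
  aggregation <- match.arg(aggregation)
  if (embedding_dim < 1 || hidden_size < 1 || num_layers < 1) {
    stop("network dimensions must be positive")
  }
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (patience < 1) stop("patience must be >= 1")
  structure(list(architecture = architecture,
                 embedding_dim = as.integer(embedding_dim),
                 hidden_size = as.integer(hidden_size), dropout = dropout,
                 num_layers = as.integer(num_layers), patience = as.integer(patience),
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 gate_activation = gate_activation,
                 early_stopping_metric = early_stopping_metric,
                 aggregation = aggregation,
                 threshold = threshold, seed = as.integer(seed)),
            class = "rs_model_config")
}

.nn_cfg <- function(config, vocab_size, dropout = NULL) {
  list(arch = config$architecture, V = as.integer(vocab_size),
       D = config$embedding_dim, H = config$hidden_size,
       L = if (config$architecture == "retain") 1L else config$num_layers,
       gate = config$gate_activation,
       dropout = if (is.null(dropout)) config$dropout else dropout,
       agg = config$aggregation)
}

.sample_visits <- function(enc) lapply(enc, `[[`, "visits")
.sample_labels <- function(enc) vapply(enc, `[[`, numeric(1), "label")

#' Initialise a parameter vector
#'
#' Weights are uniform in ±0.1; the input/forget/output gate biases start at
#' 1 so the gates open at initialisation (a tanh gate centred at zero
#' multiplies both the forward signal and the gradient by ~0, which stalls
#' training on short sequences).
#'
#' @param config an [model_config()] object.
#' @param vocab_size embedding rows (vocabulary length including PAD/UNK).
#' @param seed integer seed.
#' @return numeric parameter vector.
#' @export
init_params <- function(config, vocab_size, seed = config$seed) {
  cfg <- .nn_cfg(config, vocab_size)
  n <- cpp_par_count(cfg)
  set.seed(seed)
  par <- runif(n, -0.1, 0.1)
  par[cpp_gate_bias_idx(cfg)] <- 1.0
  par
}

#' Train a sequence classifier
#'
#' @param train,val lists of encoded samples (see [encode_samples()]);
#'   must be disjoint by patient and each contain both classes.
#' @param config an [model_config()] object.
#' @param vocab the `rs_vocab` the samples were encoded under.
#' @param verbose print per-epoch progress.
#' @return an object of class `rs_model`: best-validation parameters, the
#'   network configuration, the vocabulary fingerprint and the per-epoch
#'   training log.
#' @export
train_model <- function(train, val, config, vocab, verbose = FALSE) {
  if (length(unique(.sample_labels(train))) < 2L) {
    stop("training fold contains a single class")
  }
  if (length(unique(.sample_labels(val))) < 2L) {
    stop("validation fold contains a single class")
  }
  V <- length(vocab$tokens)
  cfg <- .nn_cfg(config, V)
  cfg_eval <- .nn_cfg(config, V, dropout = 0)
  tr_vis <- .sample_visits(train); tr_y <- .sample_labels(train)
  va_vis <- .sample_visits(val); va_y <- .sample_labels(val)

  set.seed(config$seed)
  par <- runif(cpp_par_count(cfg), -0.1, 0.1)
  par[cpp_gate_bias_idx(cfg)] <- 1.0
  m <- numeric(length(par)); v <- numeric(length(par))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; lr <- config$learning_rate
  step <- 0L

  metric <- config$early_stopping_metric %||% "loss"
  best_crit <- -Inf; best_auc <- NA_real_; best_par <- par
  best_epoch <- 0L; stall <- 0L
  log <- list()
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(length(tr_vis))
    starts <- seq(1L, length(ord), by = config$batch_size)
    ep_loss <- 0
    for (st in starts) {
      idx <- ord[st:min(st + config$batch_size - 1L, length(ord))]
      r <- cpp_nn_loss_grad(par, cfg, tr_vis[idx], tr_y[idx], TRUE)
      g <- r$grad
      step <- step + 1L
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g * g
      mhat <- m / (1 - b1^step); vhat <- v / (1 - b2^step)
      par <- par - lr * mhat / (sqrt(vhat) + eps)
      ep_loss <- ep_loss + r$loss * length(idx)
    }
    ep_loss <- ep_loss / length(tr_vis)
    va_p <- cpp_nn_forward(par, cfg_eval, va_vis)
    va_auc <- auroc(va_y, va_p)
    va_pc <- pmin(1 - 1e-12, pmax(1e-12, va_p))
    va_loss <- -mean(va_y * log(va_pc) + (1 - va_y) * log(1 - va_pc))
    log[[epoch]] <- data.table(epoch = epoch, train_loss = ep_loss,
                               val_loss = va_loss, val_auroc = va_auc)
    if (verbose) {
      message(sprintf("epoch %d loss %.4f val loss %.4f val AUROC %.4f",
                      epoch, ep_loss, va_loss, va_auc))
    }
    crit <- if (metric == "auroc") va_auc else -va_loss
    if (crit > best_crit) {
      best_crit <- crit; best_auc <- va_auc; best_par <- par
      best_epoch <- epoch; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  structure(list(par = best_par, cfg = cfg_eval, config = config,
                 vocab_fingerprint = vocab_fingerprint(vocab),
                 log = rbindlist(log), best_epoch = best_epoch,
                 best_val_auroc = best_auc),
            class = "rs_model")
}

#' @export
print.rs_model <- function(x, ...) {
  cat(sprintf("<rs_model> %s | V=%d D=%d H=%d L=%d | best epoch %d (val AUROC %.3f)\n",
              x$cfg$arch, x$cfg$V, x$cfg$D, x$cfg$H, x$cfg$L,
              x$best_epoch, x$best_val_auroc))
  invisible(x)
}

#' Score encoded samples with a trained model
#'
#' Deterministic in inference mode (dropout disabled).
#'
#' @param model an `rs_model`.
#' @param enc list of encoded samples.
#' @param vocab optional `rs_vocab`; if given, its fingerprint must match the
#'   one the model was trained under.
#' @return numeric vector of risk probabilities in (0, 1).
#' @export
score_samples <- function(model, enc, vocab = NULL) {
  if (!is.null(vocab) && vocab_fingerprint(vocab) != model$vocab_fingerprint) {
    stop("vocabulary fingerprint mismatch: samples were encoded under a different vocabulary")
  }
  cpp_nn_forward(model$par, model$cfg, .sample_visits(enc))
}

#' Visit-level attention weights of the attention architecture
#' @param model a trained `rs_model` with `architecture = "retain"`.
#' @param sample one encoded sample.
#' @return list with `alpha` (attention weights over visits, chronological
#'   order, summing to 1) and `prob`.
#' @export
retain_attention <- function(model, sample) {
  cpp_retain_attention(model$par, model$cfg, sample$visits)
}

#' Save / load a trained model checkpoint
#'
#' The learned parameters are written as an RDS blob at `path`; a JSON
#' sidecar (`<path>.json`) records the network configuration, the vocabulary
#' fingerprint, the best epoch and the training log, so a checkpoint can be
#' inspected without deserialising the weights. `load_model` verifies that
#' blob and sidecar agree.
#'
#' @param model an `rs_model`.
#' @param path checkpoint file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   `rs_model`.
#' @export
save_model <- function(model, path) {
  saveRDS(model$par, path)
  sidecar <- list(cfg = model$cfg, config = unclass(model$config),
                  vocab_fingerprint = model$vocab_fingerprint,
                  best_epoch = model$best_epoch,
                  best_val_auroc = model$best_val_auroc,
                  log = model$log, n_par = length(model$par))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  par <- readRDS(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (length(par) != side$n_par) {
    stop("checkpoint blob and sidecar disagree on parameter count")
  }
  cfg <- as.list(side$cfg)
  cfg[c("V", "D", "H", "L")] <- lapply(cfg[c("V", "D", "H", "L")], as.integer)
  config <- as.list(side$config)
  class(config) <- "rs_model_config"
  structure(list(par = as.numeric(par), cfg = cfg, config = config,
                 vocab_fingerprint = side$vocab_fingerprint,
                 log = as.data.table(side$log),
                 best_epoch = side$best_epoch,
                 best_val_auroc = side$best_val_auroc),
            class = "rs_model")
}

#' Area under the ROC curve by the rank (Mann-Whitney) statistic
#'
#' Midranks handle ties, so the value equals the exhaustive pairwise
#' probability that a random case outranks a random control (ties counted
#' half).
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUROC undefined: both classes required")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics at a threshold
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores.
#' @param threshold scores strictly above it predict the positive class.
#' @return named numeric vector `auroc`, `precision`, `recall`, `f1`.
#'   With zero predicted positives, precision is reported as 0 with a warning.
#' @export
evaluate_scores <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  if (tp + fp == 0L) {
    warning("no predicted positives; precision reported as 0")
    prec <- 0
  } else {
    prec <- tp / (tp + fp)
  }
  rec <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(auroc = auroc(labels, scores), precision = prec, recall = rec, f1 = f1)
}

#' Repeated train/evaluate runs with re-splitting
#'
#' Each repeat derives a fresh seed from the master seed, re-splits the
#' samples by patient, rebuilds the vocabulary on the new training fold,
#' retrains, and evaluates on validation and test. The report follows the
#' usual layout: one row per metric, one column per repeat plus the mean and
#' the sample standard deviation.
#'
#' @param samples sample table from [build_samples()].
#' @param events event table.
#' @param cohort_cfg an [cohort_config()] object (for the split ratios).
#' @param model_cfg an [model_config()] object.
#' @param sdoh optional zip-level SDoH table.
#' @param n_repeats number of repeats (>= 2).
#' @param seed master seed.
#' @param min_patient_count vocabulary retention threshold.
#' @param include_sdoh include `SD:`/`NB:` tokens (the "+SDoH" arm).
#' @param ... further arguments passed to [encode_samples()].
#' @return an object of class `rs_eval_report`: a data.frame with rows
#'   `Validation AUC`, `Test AUC`, `Test Precision`, `Test Recall`, `Test F1`
#'   and columns `1..N`, `average`, `std.s`.
#' @export
repeat_experiment <- function(samples, events, cohort_cfg, model_cfg,
                              sdoh = NULL, n_repeats = 10L, seed = 1L,
                              min_patient_count = 10L, include_sdoh = TRUE,
                              ...) {
  if (n_repeats < 2L) stop("n_repeats must be >= 2")
  rows <- c("Validation AUC", "Test AUC", "Test Precision", "Test Recall", "Test F1")
  res <- matrix(NA_real_, nrow = length(rows), ncol = n_repeats,
                dimnames = list(rows, as.character(seq_len(n_repeats))))
  for (r in seq_len(n_repeats)) {
    seed_r <- as.integer((seed + 10007 * r) %% 2147483629)
    run <- fit_once(samples, events, cohort_cfg, model_cfg, sdoh = sdoh,
                    seed = seed_r, min_patient_count = min_patient_count,
                    include_sdoh = include_sdoh, ...)
    res[, r] <- c(run$val_metrics[["auroc"]], run$test_metrics[["auroc"]],
                  run$test_metrics[["precision"]], run$test_metrics[["recall"]],
                  run$test_metrics[["f1"]])
  }
  out <- as.data.frame(res)
  out[["average"]] <- rowMeans(res)
  out[["std.s"]] <- apply(res, 1L, sd)
  class(out) <- c("rs_eval_report", "data.frame")
  out
}

#' One split/train/evaluate pass
#'
#' @inheritParams repeat_experiment
#' @param seed seed for this pass (splitting, training).
#' @return list with the fitted `model`, encoded folds, `val_metrics`,
#'   `test_metrics`, the `vocab`, and the fold-annotated samples.
#' @export
fit_once <- function(samples, events, cohort_cfg, model_cfg, sdoh = NULL,
                     seed = model_cfg$seed, min_patient_count = 10L,
                     include_sdoh = TRUE, ...) {
  sp <- split_samples(samples, cohort_cfg, seed = seed)
  folds <- split(sp, sp$fold)
  if (is.null(folds$train) || is.null(folds$validation) || is.null(folds$test)) {
    stop("splitting produced an empty fold; more patients are needed")
  }
  tok_train <- tokenize_events(
    as.data.table(events)[patient_id %in% unique(folds$train$patient_id)])
  nb_tok <- if (include_sdoh && !is.null(sdoh)) {
    nb <- neighborhood_tokens(sdoh)
    pz <- as.data.table(events)[, .(zip5 = zip5[1L]), by = patient_id]
    pz <- pz[patient_id %in% unique(folds$train$patient_id)]
    merge(pz, nb, by = "zip5", allow.cartesian = TRUE)[, .(patient_id, token)]
  } else NULL
  tok_all <- rbindlist(list(tok_train[, .(patient_id, token)], nb_tok))
  if (!include_sdoh) tok_all <- tok_all[!grepl("^(SD|NB):", token)]
  vocab <- build_vocabulary(tok_all, min_patient_count)

  mc <- model_cfg; mc$seed <- as.integer(seed)
  enc <- lapply(folds, encode_samples, events = events, vocab = vocab,
                sdoh = sdoh, include_sdoh = include_sdoh, ...)
  model <- train_model(enc$train, enc$validation, mc, vocab)
  val_p <- score_samples(model, enc$validation)
  test_p <- score_samples(model, enc$test)
  list(model = model, vocab = vocab, folds = sp, enc = enc,
       val_metrics = evaluate_scores(.sample_labels(enc$validation), val_p,
                                     model_cfg$threshold),
       test_metrics = evaluate_scores(.sample_labels(enc$test), test_p,
                                      model_cfg$threshold),
       test_scores = test_p, seed = seed)
}
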