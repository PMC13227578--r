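# Mini-batch training loop with Adam, early stopping, and the ablation /
# learning-rate / lambda sweep harnesses.

config_to_vit <- function(cfg) {
  vit_config(image_size = c(cfg$image_height, cfg$image_width),
             patch_size = cfg$patch_size, embed_dim = cfg$embed_dim,
             depth = cfg$depth, heads = cfg$heads, n_classes = cfg$n_classes,
             mlp_mult = cfg$mlp_mult, pos_encoding = cfg$pos_encoding,
             cross_attention = cfg$cross_attention,
             cross_source = cfg$cross_source, attention = cfg$attention)
}

# Early-stopping bookkeeping: training halts once the validation loss has
# failed to improve by more than `min_delta` for `patience` consecutive
# epochs; the best-validation epoch is retained.
es_new <- function(patience = 5L, min_delta = 1e-4) {
  list(patience = patience, min_delta = min_delta,
       best = Inf, best_epoch = 0L, wait = 0L, stop = FALSE)
}

es_update <- function(es, loss, epoch) {
  if (loss < es$best - es$min_delta) {
    es$best <- loss
    es$best_epoch <- epoch
    es$wait <- 0L
  } else {
    es$wait <- es$wait + 1L
    if (es$wait >= es$patience) es$stop <- TRUE
  }
  es
}

#' Evaluate a model on a sample set
#'
#' Runs the forward pass over every sample and computes the full metric set:
#' composite-loss components, accuracy, weighted precision/recall/F1, MAE and
#' RMSE of the severity predictions.
#'
#' @param params `vit_params`.
#' @param samples List of samples (`image`, `class` 0-based, `severity`).
#' @param config Run configuration (see [default_config()]).
#' @return List of metrics plus the raw predictions (`y_true`, `y_pred`,
#'   `severity_pred`, `severity_true`).
#' @export
evaluate_model <- function(params, samples, config) {
  vcfg <- config_to_vit(config)
  n <- length(samples)
  if (n == 0L) stop_invalid("samples must be non-empty")
  y_true <- integer(n); y_pred <- integer(n)
  sev_true <- numeric(n); sev_pred <- numeric(n)
  ce <- numeric(n)
  for (i in seq_len(n)) {
    s <- samples[[i]]
    out <- vit_forward(params, s$image, vcfg)
    y_true[i] <- s$class
    y_pred[i] <- which.max(out$class_probs) - 1L
    sev_true[i] <- s$severity
    sev_pred[i] <- out$severity
    ce[i] <- cross_entropy_loss(out$class_probs, s$class)
  }
  loss_class <- mean(ce)
  loss_severity <- severity_mse_loss(sev_pred, sev_true)
  rep <- classification_report(y_true, y_pred, n_classes = config$n_classes)
  reg <- regression_metrics(sev_pred, sev_true)
  list(loss_class = loss_class, loss_severity = loss_severity,
       loss_total = loss_class + config$lambda * loss_severity,
       accuracy = rep$accuracy,
       precision = rep$weighted$precision, recall = rep$weighted$recall,
       f1 = rep$weighted$f1, mae = reg[["mae"]], rmse = reg[["rmse"]],
       y_true = y_true, y_pred = y_pred,
       severity_pred = sev_pred, severity_true = sev_true)
}

#' Train the dual-head transformer
#'
#' Minimizes `L_class + lambda * L_severity` by mini-batch Adam with
#' decoupled weight decay, evaluating the validation loss each epoch and
#' stopping early when it fails to improve for `patience` consecutive
#' epochs.  The parameters from the best-validation epoch are returned.  The
#' run is fully deterministic given `config$seed`.
#'
#' @param train_samples,val_samples Non-empty lists of samples, each a list
#'   with `image` (matrix), `class` (0-based integer) and `severity`
#'   (numeric).
#' @param config Run configuration (see [default_config()]); the fields used
#'   here are the model geometry, `lambda`, `learning_rate`, `weight_decay`,
#'   `batch_size`, `max_epochs`, `patience`, `min_delta` and `seed`.
#' @return List (class `vit_fit`) with `params` (best epoch), `best_epoch`,
#'   `history` (one row per epoch with losses and the full metric set for
#'   both splits) and `config`.
#' @export
train_model <- function(train_samples, val_samples, config) {
  if (length(train_samples) == 0L || length(val_samples) == 0L)
    stop_invalid("train and validation sets must be non-empty")
  config <- validate_config(config)
  vcfg <- config_to_vit(config)
  params <- vit_init(vcfg, seed = config$seed)
  opt <- adam_init(params, learning_rate = config$learning_rate,
                   weight_decay = config$weight_decay)
  es <- es_new(config$patience, config$min_delta)
  n <- length(train_samples)
  hist_rows <- list()
  best_params <- params
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      order <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      for (st in starts) {
        idx <- order[st:min(st + config$batch_size - 1L, n)]
        grads <- NULL
        for (i in idx) {
          s <- train_samples[[i]]
          out <- vit_forward(opt$params, s$image, vcfg, keep_cache = TRUE)
          bk <- vit_backward(opt$params, out, vcfg, s$class, s$severity,
                             config$lambda)
          if (!is.finite(bk$loss_class) || !is.finite(bk$loss_severity))
            stop("training diverged: non-finite loss")
          grads <- if (is.null(grads)) bk$grads
                   else nl_map(`+`, grads, bk$grads)
        }
        grads <- nl_map(function(gr) gr / length(idx), grads)
        opt <- adam_step(opt, grads)
      }
      tr <- evaluate_model(opt$params, train_samples, config)
      va <- evaluate_model(opt$params, val_samples, config)
      hist_rows[[epoch]] <- data.frame(
        epoch = epoch,
        train_loss_total = tr$loss_total, train_loss_class = tr$loss_class,
        train_loss_severity = tr$loss_severity, train_accuracy = tr$accuracy,
        train_precision = tr$precision, train_recall = tr$recall,
        train_f1 = tr$f1, train_mae = tr$mae, train_rmse = tr$rmse,
        val_loss_total = va$loss_total, val_loss_class = va$loss_class,
        val_loss_severity = va$loss_severity, val_accuracy = va$accuracy,
        val_precision = va$precision, val_recall = va$recall,
        val_f1 = va$f1, val_mae = va$mae, val_rmse = va$rmse)
      es <- es_update(es, va$loss_total, epoch)
      if (es$best_epoch == epoch) best_params <- opt$params
      if (es$stop) break
    }
  })
  structure(list(params = best_params, best_epoch = es$best_epoch,
                 history = do.call(rbind, hist_rows), config = config),
            class = "vit_fit")
}

#' @export
print.vit_fit <- function(x, ...) {
  h <- x$history
  b <- h[h$epoch == x$best_epoch, ]
  cat(sprintf("<vit_fit> %d epochs (best %d): val accuracy %.3f, val MAE %.3f, val loss %.4f\n",
              nrow(h), x$best_epoch, b$val_accuracy, b$val_mae, b$val_loss_total))
  invisible(x)
}

#' Learning-rate sweep
#'
#' Trains one model per learning rate on identical data and seed and reports
#' the number of epochs to convergence, defined as the first epoch whose
#' validation loss is within 5% of the run's eventual minimum.
#'
#' @param train_samples,val_samples Sample lists as in [train_model()].
#' @param config Run configuration; `learning_rate` is overridden per run.
#' @param rates Positive learning rates to sweep.
#' @return `data.frame` with columns `learning_rate` and `epochs`.
#' @export
lr_sweep <- function(train_samples, val_samples, config, rates) {
  if (any(rates <= 0)) stop_invalid("all learning rates must be > 0")
  rows <- lapply(rates, function(r) {
    cfg <- config; cfg$learning_rate <- r
    fit <- train_model(train_samples, val_samples, cfg)
    v <- fit$history$val_loss_total
    conv <- which(v <= 1.05 * min(v))[1L]
    data.frame(learning_rate = r, epochs = conv)
  })
  do.call(rbind, rows)
}

severity_accuracy <- function(mae, config) {
  rng <- config$severity_max - config$severity_min
  max(0, min(100, 100 * (1 - mae / rng)))
}

#' Lambda trade-off sweep
#'
#' Trains one model per loss weight lambda on identical data and seed and
#' reports classification accuracy, severity-detection accuracy (defined as
#' `100 * (1 - MAE / severity range)`, a reporting convention only), and the
#' percent change of each relative to the first lambda.
#'
#' @param train_samples,val_samples Sample lists as in [train_model()].
#' @param config Run configuration; `lambda` is overridden per run.
#' @param lambdas Non-negative loss weights.
#' @return `data.frame` with columns `lambda`, `classification_accuracy`,
#'   `severity_accuracy`, `classification_change_pct`,
#'   `severity_change_pct`.
#' @export
lambda_sweep <- function(train_samples, val_samples, config, lambdas) {
  if (any(lambdas < 0)) stop_invalid("all lambdas must be >= 0")
  rows <- lapply(lambdas, function(lam) {
    cfg <- config; cfg$lambda <- lam
    fit <- train_model(train_samples, val_samples, cfg)
    ev <- evaluate_model(fit$params, val_samples, cfg)
    data.frame(lambda = lam,
               classification_accuracy = 100 * ev$accuracy,
               severity_accuracy = severity_accuracy(ev$mae, cfg))
  })
  out <- do.call(rbind, rows)
  out$classification_change_pct <-
    round2(percent_change(out$classification_accuracy[1L],
                          out$classification_accuracy), 2)
  out$severity_change_pct <-
    round2(percent_change(out$severity_accuracy[1L], out$severity_accuracy), 2)
  out
}

ablation_variants <- c("full", "no_positional", "no_self_attention", "single_head")

#' Ablation suite
#'
#' Re-trains the model with individual components removed, on identical data
#' and seed: `no_positional` skips the positional encoding,
#' `no_self_attention` replaces every attention mixer with an identity
#' pass-through, and `single_head` drops the severity head (lambda forced to
#' 0).
#'
#' @param train_samples,val_samples Sample lists as in [train_model()].
#' @param config Run configuration for the full model.
#' @param variants Subset of
#'   `c("full", "no_positional", "no_self_attention", "single_head")`.
#' @return `data.frame` with columns `variant`, `accuracy` and `total_loss`
#'   (validation split, best epoch).
#' @export
ablation_suite <- function(train_samples, val_samples, config,
                           variants = ablation_variants) {
  if (length(variants) == 0L) stop_invalid("variants must be non-empty")
  bad <- setdiff(variants, ablation_variants)
  if (length(bad)) stop_invalid("unknown ablation variant: ",
                                paste(bad, collapse = ", "))
  rows <- lapply(variants, function(v) {
    cfg <- config
    if (v == "no_positional") cfg$pos_encoding <- "none"
    if (v == "no_self_attention") cfg$attention <- "identity"
    if (v == "single_head") cfg$lambda <- 0
    fit <- train_model(train_samples, val_samples, cfg)
    ev <- evaluate_model(fit$params, val_samples, cfg)
    data.frame(variant = v, accuracy = ev$accuracy, total_loss = ev$loss_total)
  })
  do.call(rbind, rows)
}
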