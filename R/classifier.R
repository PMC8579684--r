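## Cost-sensitive sentence classifier: training configuration, triangular
## cyclical learning-rate schedule, class-weighted cross entropy, and the
## fitting function returning a `sentence_classifier` S3 model object.

#' Training configuration
#'
#' Defaults are the fine-tuning conditions the pipeline is designed around:
#' sequences padded to 256 tokens, head dropout 0.1, 10 epochs, a triangular
#' cyclical learning rate between 2e-5 and 5e-5 with step size 2500
#' initialized at 3e-5, about 12% of the training set held out for
#' validation, and distant-supervision cost weights \[0.52, 5.52\]
#' (absent, present) penalizing minority-class misclassification.  When
#' training a from-scratch encoder rather than fine-tuning a pretrained one,
#' raise the learning-rate bounds (see [train_classifier()] examples).
#'
#' @param max_sequence_length Padded token-sequence length (>= 1).
#' @param dropout_p Dropout probability on the pooled representation.
#' @param epochs Training epochs.
#' @param class_weights Length-2 positive numeric `c(absent, present)`;
#'   see [inverse_prevalence_weights()] for a data-driven alternative.
#' @param lr_lower,lr_upper,lr_init Learning-rate bounds and starting value;
#'   must satisfy `lr_lower <= lr_init <= lr_upper`.
#' @param lr_step_size Optimizer steps per half-cycle of the schedule.
#' @param canonical_start If `TRUE` the schedule starts at `lr_lower`
#'   (textbook triangle) instead of being phase-shifted to start at
#'   `lr_init`.
#' @param validation_fraction Fraction of the training data held out.
#' @param split_unit `"patient"` (no leakage) or `"sentence"`.
#' @param batch_size Minibatch size.
#' @param selection `"best"` keeps the epoch with the best validation F1,
#'   `"last"` keeps the final epoch.
#' @param weight_decay Decoupled weight decay applied to projection
#'   matrices.
#' @param seed Mandatory integer seed controlling initialization, shuffling
#'   and dropout; training is reproducible given the seed.
#' @return An object of class `training_config`.
#' @export
training_config <- function(max_sequence_length = 256L,
                            dropout_p = 0.1,
                            epochs = 10L,
                            class_weights = c(absent = 0.52, present = 5.52),
                            lr_lower = 2e-5,
                            lr_upper = 5e-5,
                            lr_init = 3e-5,
                            lr_step_size = 2500L,
                            canonical_start = FALSE,
                            validation_fraction = 0.12,
                            split_unit = c("patient", "sentence"),
                            batch_size = 32L,
                            selection = c("best", "last"),
                            weight_decay = 0.01,
                            seed) {
  split_unit <- match.arg(split_unit)
  selection <- match.arg(selection)
  if (missing(seed) || !is_count(seed)) stop_("'seed' is mandatory (integer)")
  if (!is_count(max_sequence_length) || max_sequence_length < 1) {
    stop_("'max_sequence_length' must be a positive integer")
  }
  if (!is_prob(dropout_p) || dropout_p >= 1) stop_("invalid 'dropout_p'")
  if (!is_count(epochs) || epochs < 1) stop_("'epochs' must be >= 1")
  if (length(class_weights) != 2L || any(!is.finite(class_weights)) ||
      any(class_weights <= 0)) {
    stop_("'class_weights' must be two strictly positive numbers")
  }
  if (!(lr_lower <= lr_init && lr_init <= lr_upper)) {
    stop_("learning rates must satisfy lr_lower <= lr_init <= lr_upper")
  }
  if (!is_count(lr_step_size) || lr_step_size < 1) {
    stop_("'lr_step_size' must be a positive integer")
  }
  if (!is.numeric(validation_fraction) || validation_fraction <= 0 ||
      validation_fraction >= 1) {
    stop_("'validation_fraction' must lie strictly between 0 and 1")
  }
  if (!is_count(batch_size) || batch_size < 1) stop_("invalid 'batch_size'")
  cw <- as.numeric(class_weights)
  names(cw) <- c("absent", "present")
  structure(list(
    max_sequence_length = as.integer(max_sequence_length),
    dropout_p = dropout_p, epochs = as.integer(epochs),
    class_weights = cw,
    lr_lower = lr_lower, lr_upper = lr_upper, lr_init = lr_init,
    lr_step_size = as.integer(lr_step_size),
    canonical_start = isTRUE(canonical_start),
    validation_fraction = validation_fraction, split_unit = split_unit,
    batch_size = as.integer(batch_size), selection = selection,
    weight_decay = weight_decay, seed = as.integer(seed)
  ), class = "training_config")
}

#' @export
print.training_config <- function(x, ...) {
  cat("<training_config>\n")
  cat(sprintf("  max_sequence_length %d  dropout %.2f  epochs %d  batch %d\n",
              x$max_sequence_length, x$dropout_p, x$epochs, x$batch_size))
  cat(sprintf("  class_weights [%.3g, %.3g]  (absent, present)\n",
              x$class_weights[1], x$class_weights[2]))
  cat(sprintf("  cyclical lr [%g, %g] init %g step %d%s\n",
              x$lr_lower, x$lr_upper, x$lr_init, x$lr_step_size,
              if (x$canonical_start) " (canonical start)" else ""))
  cat(sprintf("  validation %.0f%% by %s  selection %s  seed %d\n",
              100 * x$validation_fraction, x$split_unit, x$selection, x$seed))
  invisible(x)
}

#' Triangular cyclical learning rate
#'
#' The rate ramps linearly from `lr_lower` to `lr_upper` over
#' `lr_step_size` iterations and back down over the next `lr_step_size`
#' (period `2 * lr_step_size`).  By default the triangle wave is
#' phase-shifted so that the rate at iteration 0 equals `lr_init` on the
#' ascending limb; with `canonical_start = TRUE` it starts at `lr_lower`.
#' The exact bounds are attained at the wave's turning points (see
#' [lr_turning_points()]); `iteration` may be fractional so those points can
#' be evaluated exactly.
#'
#' @param iteration 0-based iteration (vectorized; non-negative, possibly
#'   fractional).
#' @param config A [training_config()].
#' @return Learning rate(s) in `[lr_lower, lr_upper]`.
#' @export
cyclical_lr <- function(iteration, config) {
  stopifnot(inherits(config, "training_config"))
  if (any(iteration < 0)) stop_("'iteration' must be non-negative")
  lo <- config$lr_lower; hi <- config$lr_upper; step <- config$lr_step_size
  if (hi == lo) return(rep(lo, length(iteration)))
  t0 <- if (config$canonical_start) 0 else
    step * (config$lr_init - lo) / (hi - lo)
  phase <- (iteration + t0) %% (2 * step)
  tri <- ifelse(phase <= step, phase / step, 2 - phase / step)
  lo + (hi - lo) * tri
}

#' @rdname cyclical_lr
#' @return For `lr_turning_points()`: list with `peak` and `trough`, the
#'   first non-negative (possibly fractional) iterations at which the rate
#'   equals `lr_upper` and `lr_lower` exactly.
#' @export
lr_turning_points <- function(config) {
  stopifnot(inherits(config, "training_config"))
  lo <- config$lr_lower; hi <- config$lr_upper; step <- config$lr_step_size
  t0 <- if (config$canonical_start || hi == lo) 0 else
    step * (config$lr_init - lo) / (hi - lo)
  list(peak = (step - t0) %% (2 * step),
       trough = (2 * step - t0) %% (2 * step))
}

#' Class-weighted cross-entropy loss
#'
#' Per-sentence loss `-w(label) * log softmax(logits)[label]`.  With unit
#' weights this is exactly the standard cross entropy.  Batch reduction
#' (`reduce = "batch"`) is the weight-normalized mean
#' `sum(w_i * ce_i) / sum(w_i)`.
#'
#' @param logits Numeric length-2 vector or an `n x 2` matrix of (absent,
#'   present) logits; must be finite.
#' @param label `"absent"`/`"present"` (length n).
#' @param class_weights Positive `c(absent, present)` weights.
#' @param reduce `"none"` (per-item losses) or `"batch"`.
#' @return Non-negative loss(es).
#' @examples
#' weighted_cross_entropy(c(0, 0), "present", c(1, 1))  # log(2)
#' @export
weighted_cross_entropy <- function(logits, label,
                                   class_weights = c(0.52, 5.52),
                                   reduce = c("none", "batch")) {
  reduce <- match.arg(reduce)
  if (is.vector(logits)) logits <- matrix(logits, ncol = 2, byrow = FALSE)
  if (ncol(logits) != 2L) stop_("'logits' must have two columns")
  if (any(!is.finite(logits))) stop_("non-finite logits")
  if (any(class_weights <= 0) || length(class_weights) != 2L) {
    stop_("'class_weights' must be two positive numbers")
  }
  yidx <- match(label, c("absent", "present"))
  if (anyNA(yidx)) stop_("labels must be 'absent' or 'present'")
  if (length(yidx) != nrow(logits)) stop_("label/logit length mismatch")
  p <- softmax_rows(logits)
  ce <- -log(p[cbind(seq_len(nrow(p)), yidx)])
  w <- class_weights[yidx]
  if (reduce == "batch") sum(w * ce) / sum(w) else w * ce
}

## Loss gradient w.r.t. logits under the weight-normalized batch mean.
wce_grad <- function(logits, yidx, class_weights) {
  p <- softmax_rows(logits)
  onehot <- matrix(0, nrow(p), 2)
  onehot[cbind(seq_len(nrow(p)), yidx)] <- 1
  w <- class_weights[yidx]
  (p - onehot) * (w / sum(w))
}

#' Inverse-prevalence class weights
#'
#' `w_c = n / (2 * n_c)`: each class contributes equal total weight, the
#' usual data-driven choice when cost weights have not been fixed
#' externally.
#'
#' @param labels Character vector of `"absent"`/`"present"` labels.
#' @return Named `c(absent, present)` weights.
#' @export
inverse_prevalence_weights <- function(labels) {
  n <- length(labels)
  n_abs <- sum(labels == "absent"); n_pres <- sum(labels == "present")
  if (n_abs == 0 || n_pres == 0) stop_("both classes must be present")
  c(absent = n / (2 * n_abs), present = n / (2 * n_pres))
}

#' Train the cost-sensitive sentence classifier
#'
#' Fits the encoder plus dropout/linear head by minibatch AdamW on the
#' class-weighted cross entropy under the triangular cyclical learning-rate
#' schedule, holding out `validation_fraction` of the data (patient-level by
#' default) and tracking per-epoch loss and validation metrics.  Training is
#' a deterministic function of `config$seed`.
#'
#' @param data Labeled sentence `data.frame` (columns `text`, `label`,
#'   `patient_id`; e.g. a [weak_label()] item table or gold sentences).
#'   Both classes must be present in the training split.
#' @param config A [training_config()].
#' @param spec An [encoder_spec()].
#' @param verbose Print per-epoch progress.
#' @return An object of class `sentence_classifier` with components
#'   `params` (encoder weights), `tokenizer`, `spec`, `config`, `history`
#'   (`$epochs` data.frame, `$lr` per-iteration learning rates) and
#'   `selected_epoch`.
#' @export
train_classifier <- function(data, config, spec = encoder_spec(),
                             verbose = FALSE) {
  stopifnot(inherits(config, "training_config"),
            inherits(spec, "encoder_spec"))
  if (inherits(data, "weak_dataset")) data <- data$items
  stopifnot(is.data.frame(data),
            all(c("text", "label", "patient_id") %in% names(data)))
  split <- stratify_split(data, config$validation_fraction,
                          unit = config$split_unit, seed = config$seed)
  train <- split$train; val <- split$validation
  if (nrow(val) == 0L) stop_("validation split is empty")
  if (length(unique(train$label)) < 2L) {
    stop_("training split contains a single class; ",
          "both 'present' and 'absent' are required")
  }
  with_seed(config$seed, {
    tokenizer <- word_tokenizer(train$text)
    params <- init_encoder(spec, vocab_size = length(tokenizer$vocab))
    state <- adamw_init(params)
    n <- nrow(train)
    yidx_all <- match(train$label, c("absent", "present"))
    # tokenize once; batches slice this cache
    ids_all <- encode_batch(train$text, tokenizer, config$max_sequence_length)
    nreal_all <- rowSums(ids_all != PAD_ID)
    val_ids <- encode_batch(val$text, tokenizer, config$max_sequence_length)
    val_nreal <- rowSums(val_ids != PAD_ID)
    cw <- config$class_weights
    lr_hist <- numeric(0)
    ep_rows <- vector("list", config$epochs)
    best <- list(f1 = -Inf, params = params, epoch = 0L)
    iter <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample(n)
      total_loss <- 0; total_w <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        nreal <- nreal_all[idx]
        Tmax <- max(2L, max(nreal))
        ids <- ids_all[idx, seq_len(Tmax), drop = FALSE]  # drop all-pad cols
        dmask <- if (config$dropout_p > 0) {
          matrix(stats::rbinom(length(idx) * spec$hidden, 1,
                               1 - config$dropout_p) / (1 - config$dropout_p),
                 length(idx), spec$hidden)
        } else NULL
        yidx <- yidx_all[idx]
        w <- cw[yidx]
        res <- encoder_train_step(params, spec, ids, nreal, dmask, yidx, cw)
        ce <- weighted_cross_entropy(res$logits,
                                     c("absent", "present")[yidx], cw)
        total_loss <- total_loss + sum(ce); total_w <- total_w + sum(w)
        grads <- res$grads
        lr <- cyclical_lr(iter, config)
        lr_hist <- c(lr_hist, lr)
        upd <- adamw_step(params, grads, state, lr,
                          weight_decay = config$weight_decay)
        params <- upd$params; state <- upd$state
        iter <- iter + 1L
      }
      vm <- sentence_metrics(
        predict_ids(params, spec, val_ids, val_nreal, config$batch_size),
        val$label)
      ep_rows[[ep]] <- data.frame(
        epoch = ep, train_loss = total_loss / total_w,
        val_precision = vm$precision, val_recall = vm$recall, val_f1 = vm$f1,
        val_accuracy = vm$accuracy)
      if (verbose) {
        message(sprintf("epoch %d  loss %.4f  val F1 %s", ep,
                        total_loss / total_w, format(vm$f1, digits = 3)))
      }
      f1 <- if (is.na(vm$f1)) -Inf else vm$f1
      if (config$selection == "best" && f1 > best$f1) {
        best <- list(f1 = f1, params = params, epoch = ep)
      }
    }
    if (config$selection == "best" && best$epoch > 0L) {
      params <- best$params
      selected <- best$epoch
    } else {
      selected <- config$epochs
    }
    structure(list(
      params = params, tokenizer = tokenizer, spec = spec, config = config,
      history = list(epochs = do.call(rbind, ep_rows), lr = lr_hist),
      selected_epoch = selected
    ), class = "sentence_classifier")
  })
}

## Sentence-level metrics against reference labels ("present" positive).
sentence_metrics <- function(pred, ref) {
  tp <- sum(pred == "present" & ref == "present")
  fp <- sum(pred == "present" & ref == "absent")
  fn <- sum(pred == "absent" & ref == "present")
  tn <- sum(pred == "absent" & ref == "absent")
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) ||
            (precision == 0 && recall == 0)) NA_real_
  else suppressWarnings(fbeta(precision, recall, 1))
  list(precision = precision, recall = recall, f1 = f1,
       accuracy = (tp + tn) / max(1L, length(ref)))
}

## Label pre-encoded sentences (no re-tokenization; used during training).
predict_ids <- function(params, spec, ids_all, nreal_all, batch_size) {
  n <- nrow(ids_all)
  if (n == 0L) return(character(0))
  out <- character(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    nreal <- nreal_all[idx]
    Tmax <- max(2L, max(nreal))
    ids <- ids_all[idx, seq_len(Tmax), drop = FALSE]
    logits <- encoder_logits(params, spec, ids, nreal)
    out[idx] <- c("absent", "present")[max.col(logits,
                                               ties.method = "first")]
  }
  out
}

predict_labels <- function(params, spec, tokenizer, texts,
                           max_sequence_length, batch_size,
                           return_logits = FALSE) {
  n <- length(texts)
  if (n == 0L) {
    return(if (return_logits) matrix(numeric(0), 0, 2) else character(0))
  }
  out <- vector("list", ceiling(n / batch_size))
  k <- 0L
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    ids <- encode_batch(texts[idx], tokenizer, max_sequence_length)
    nreal <- rowSums(ids != PAD_ID)
    Tmax <- max(2L, max(nreal))
    ids <- ids[, seq_len(Tmax), drop = FALSE]
    k <- k + 1L
    out[[k]] <- encoder_logits(params, spec, ids, nreal)
  }
  logits <- do.call(rbind, out)
  if (return_logits) logits else
    c("absent", "present")[max.col(logits, ties.method = "first")]
}

#' Predict sentence labels with a trained classifier
#'
#' Inference is deterministic (dropout off); the label is the argmax of the
#' two logits and input order is preserved.
#'
#' @param object A `sentence_classifier`.
#' @param newdata Either a character vector of sentences or a sentence
#'   `data.frame` with a `text` column.
#' @param type `"label"` (default), `"prob"` (probability of `present`) or
#'   `"logits"`.
#' @param ... Unused.
#' @return For `data.frame` input with `type = "label"`: the `data.frame`
#'   with `label` and `provenance = "model"` columns; otherwise a vector (or
#'   two-column matrix for `"logits"`).
#' @export
predict.sentence_classifier <- function(object, newdata,
                                        type = c("label", "prob", "logits"),
                                        ...) {
  type <- match.arg(type)
  is_df <- is.data.frame(newdata)
  texts <- if (is_df) newdata$text else as.character(newdata)
  logits <- predict_labels(object$params, object$spec, object$tokenizer,
                           texts, object$config$max_sequence_length,
                           object$config$batch_size, return_logits = TRUE)
  if (type == "logits") return(logits)
  if (type == "prob") {
    if (!length(texts)) return(numeric(0))
    return(softmax_rows(logits)[, 2])
  }
  labels <- if (length(texts)) {
    c("absent", "present")[max.col(logits, ties.method = "first")]
  } else character(0)
  if (is_df) {
    newdata$label <- labels
    newdata$provenance <- rep("model", nrow(newdata))
    newdata
  } else labels
}

#' @export
print.sentence_classifier <- function(x, ...) {
  cat("<sentence_classifier>\n")
  print(x$spec)
  cat(sprintf("  parameters %d  vocabulary %d  selected epoch %d/%d\n",
              n_parameters(x$params), length(x$tokenizer$vocab),
              x$selected_epoch, x$config$epochs))
  last <- x$history$epochs[x$selected_epoch, ]
  cat(sprintf("  validation: precision %s recall %s F1 %s\n",
              format(last$val_precision, digits = 3),
              format(last$val_recall, digits = 3),
              format(last$val_f1, digits = 3)))
  invisible(x)
}

#' @export
summary.sentence_classifier <- function(object, ...) {
  cat("Cost-sensitive transformer sentence classifier\n\n")
  print(object$spec)
  print(object$config)
  cat("\nTraining history:\n")
  print(object$history$epochs, row.names = FALSE, digits = 4)
  invisible(object$history$epochs)
}

#' @export
coef.sentence_classifier <- function(object, ...) {
  list(weights = object$params$Wc, bias = object$params$bc)
}

#' Plot training history
#'
#' Two base-graphics panels: weighted training loss and validation F1 per
#' epoch, and the per-iteration cyclical learning rate.
#'
#' @param x A `sentence_classifier`.
#' @param ... Passed to [plot()].
#' @export
plot.sentence_classifier <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  plot(h$epochs$epoch, h$epochs$train_loss, type = "b", pch = 16,
       xlab = "epoch", ylab = "weighted training loss",
       main = "Training", ...)
  graphics::par(new = TRUE)
  plot(h$epochs$epoch, h$epochs$val_f1, type = "b", col = "firebrick",
       pch = 17, axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
  graphics::axis(4, col.axis = "firebrick")
  graphics::mtext("validation F1", side = 4, line = 2.5, col = "firebrick")
  plot(seq_along(h$lr) - 1, h$lr, type = "l", xlab = "iteration",
       ylab = "learning rate", main = "Cyclical schedule")
  invisible(x)
}

#' Save or load a classifier checkpoint
#'
#' The weights go to an RDS file; a JSON sidecar (same path with
#' `.json` appended) records the architecture, training configuration and
#' history for auditability.
#'
#' @param object A `sentence_classifier`.
#' @param path Checkpoint path (`.rds`).
#' @return `save_classifier()` returns `path` invisibly; `load_classifier()`
#'   returns the restored `sentence_classifier`.
#' @export
save_classifier <- function(object, path) {
  stopifnot(inherits(object, "sentence_classifier"))
  saveRDS(object, path)
  sidecar <- list(
    spec = unclass(object$spec),
    config = unclass(object$config),
    selected_epoch = object$selected_epoch,
    history = object$history$epochs
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj, "sentence_classifier"))
  obj
}
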