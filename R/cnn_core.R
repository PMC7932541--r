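## Model construction, staged training with early stopping, prediction and
## evaluation.  The exact layer stack is a documented reconstruction:
## conv(n_filters, kernel, ReLU) -> max-pool(2) -> conv(n_filters, kernel,
## ReLU) -> global max-pool -> dense(64, ReLU) -> dropout(0.3) ->
## dense(1, sigmoid), binary cross-entropy loss, Adam (lr 1e-3).

#' Model configuration
#'
#' The tuning grid modulates two parameters, the number of convolution
#' filters (32, 64, 128) and the kernel size (3, 6, 12); training runs in
#' three blocks of at most 40/30/10 epochs, each block stopping early when
#' validation accuracy fails to improve for 15/10/5 epochs respectively,
#' with the best weights restored at every block boundary.
#'
#' @param n_filters filters per convolution layer; values off the
#'   `{32,64,128}` grid trigger a warning, not an error.
#' @param kernel_size convolution kernel width; grid `{3,6,12}`.
#' @param batch_size sequences per gradient step (512).
#' @param epoch_blocks maximum epochs per training block.
#' @param patience_per_block early-stopping patience per block (same
#'   length as `epoch_blocks`).
#' @param learning_rate Adam step size.
#' @param dropout dropout rate on the dense layer.
#' @param dense_units width of the penultimate dense layer.
#' @param decision_threshold probability cut-off for the positive class.
#' @param rng_seed integer seed for weight initialisation, shuffling and
#'   dropout; `NULL` uses the current RNG stream.
#' @return a list of class `model_config`.
#' @export
model_config <- function(n_filters = 64L, kernel_size = 6L, batch_size = 512L,
                         epoch_blocks = c(40L, 30L, 10L),
                         patience_per_block = c(15L, 10L, 5L),
                         learning_rate = 1e-3, dropout = 0.3,
                         dense_units = 64L, decision_threshold = 0.5,
                         rng_seed = NULL) {
  stopifnot(n_filters >= 1L, kernel_size >= 2L, batch_size >= 1L,
            length(epoch_blocks) == length(patience_per_block),
            all(epoch_blocks >= 1L), all(patience_per_block >= 1L),
            learning_rate >= 0, dropout >= 0, dropout < 1,
            decision_threshold > 0, decision_threshold < 1)
  if (!n_filters %in% c(32L, 64L, 128L)) {
    warning("n_filters = ", n_filters, " is off the {32,64,128} tuning grid")
  }
  if (!kernel_size %in% c(3L, 6L, 12L)) {
    warning("kernel_size = ", kernel_size, " is off the {3,6,12} tuning grid")
  }
  structure(list(n_filters = as.integer(n_filters),
                 kernel_size = as.integer(kernel_size),
                 batch_size = as.integer(batch_size),
                 epoch_blocks = as.integer(epoch_blocks),
                 patience_per_block = as.integer(patience_per_block),
                 learning_rate = learning_rate, dropout = dropout,
                 dense_units = as.integer(dense_units),
                 decision_threshold = decision_threshold,
                 rng_seed = rng_seed),
            class = "model_config")
}

glorot <- function(nin, nout, n_row, n_col) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(n_row * n_col, -lim, lim), n_row, n_col)
}

#' Build an untrained classifier
#'
#' Weights are Glorot-uniform initialised (reproducibly under
#' `config$rng_seed`).  The model maps a 200x5 one-hot matrix — equivalently
#' a 100-base window — to a probability in (0,1) that the window harbours an
#' SRE/NF-Y couple; the final layer is a single sigmoid unit.
#'
#' @param config a [model_config()].
#' @return object of class `sre_cnn`.
#' @export
build_model <- function(config = model_config()) {
  k <- config$kernel_size; nf <- config$n_filters; D <- config$dense_units
  L1 <- 200L - k + 1L
  L2 <- L1 %/% 2L
  L3 <- L2 - k + 1L
  if (L3 < 1L) stop("kernel_size too large for 200-row input")
  weights <- with_seed_opt(config$rng_seed, list(
    W1 = glorot(5 * k, nf, 5 * k, nf), b1 = numeric(nf),
    W2 = glorot(k * nf, nf, k * nf, nf), b2 = numeric(nf),
    W3 = glorot(nf, D, nf, D), b3 = numeric(D),
    W4 = as.numeric(glorot(D, 1, D, 1)), b4 = 0
  ))
  structure(list(weights = weights, config = config, history = NULL),
            class = "sre_cnn")
}

#' @export
print.sre_cnn <- function(x, ...) {
  cat("sre_cnn: conv(", x$config$n_filters, ", k=", x$config$kernel_size,
      ") -> pool(2) -> conv -> global max -> dense(", x$config$dense_units,
      ") -> sigmoid; ", n_params(x), " parameters; ",
      if (is.null(x$history)) "untrained" else
        sprintf("trained, best val accuracy %.3f", x$history$best_val_accuracy),
      "\n", sep = "")
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param model an `sre_cnn`.
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$weights, length, integer(1)))
}

as_code_matrix <- function(x) {
  if (is.character(x)) return(encode_codes(x))
  if (is.matrix(x) && ncol(x) == 200L) return(x)
  if (is.matrix(x) && identical(dim(x), c(200L, 5L))) x <- list(x)
  if (is.list(x)) {
    codes <- t(vapply(x, function(m) {
      stopifnot(identical(dim(m), c(200L, 5L)))
      as.integer(max.col(m, ties.method = "first") - 1L) * (rowSums(m) > 0) -
        (rowSums(m) == 0)
    }, numeric(200L)))
    storage.mode(codes) <- "integer"
    return(codes)
  }
  stop("cannot interpret input as encoded windows")
}

#' Predict SRE/NF-Y probabilities
#'
#' @param model an `sre_cnn`, or any function mapping a character vector of
#'   100-base windows to probabilities (useful for plugging surrogate
#'   classifiers into the scanner).
#' @param x character vector of 100-base windows, an integer code matrix
#'   from [encode_codes()], or a (list of) 200x5 one-hot matrices.
#' @param ... unused.
#' @return numeric vector of probabilities in (0,1), one per input window,
#'   in input order.
#' @export
predict_proba <- function(model, x, ...) UseMethod("predict_proba")

#' @export
predict_proba.sre_cnn <- function(model, x, ...) {
  cpp_cnn_predict(model$weights, as_code_matrix(x))
}

#' @export
predict_proba.function <- function(model, x, ...) model(x)

adam_init <- function(weights) {
  zeros <- function(w) if (is.matrix(w)) matrix(0, nrow(w), ncol(w)) else
    numeric(length(w))
  list(mW1 = zeros(weights$W1), vW1 = zeros(weights$W1),
       mb1 = zeros(weights$b1), vb1 = zeros(weights$b1),
       mW2 = zeros(weights$W2), vW2 = zeros(weights$W2),
       mb2 = zeros(weights$b2), vb2 = zeros(weights$b2),
       mW3 = zeros(weights$W3), vW3 = zeros(weights$W3),
       mb3 = zeros(weights$b3), vb3 = zeros(weights$b3),
       mW4 = zeros(weights$W4), vW4 = zeros(weights$W4),
       mb4 = 0, vb4 = 0, t = 0)
}

#' Train the classifier with staged early stopping
#'
#' Runs up to `length(epoch_blocks)` blocks of epochs.  Within each block,
#' training stops early when validation accuracy has not improved for the
#' block's patience; the best-validation weights seen so far are restored
#' at the end of each block (and at the very end), so later blocks continue
#' from the best model.  Sequences are held as integer codes and one-hot
#' expanded batch-wise inside the gradient code, never materialised as a
#' full matrix corpus.
#'
#' @param model an untrained (or previously trained) `sre_cnn`.
#' @param train_set,val_set disjoint data.frames with columns `sequence`
#'   (100-base windows) and `label` (0/1).
#' @param config optional [model_config()] overriding `model$config`.
#' @param verbose print per-epoch progress.
#' @return the trained `sre_cnn`, with `$history` holding a data.frame of
#'   per-epoch `block`, `epoch`, `loss`, `val_accuracy`, plus
#'   `best_val_accuracy` and `best_epoch`.
#' @export
train_cnn <- function(model, train_set, val_set, config = NULL,
                      verbose = FALSE) {
  config <- config %||% model$config
  stopifnot(is.data.frame(train_set), is.data.frame(val_set),
            nrow(train_set) > 0L, nrow(val_set) > 0L)
  if (length(unique(train_set$label)) < 2L) {
    stop("training set must contain both classes")
  }
  codes_tr <- encode_codes(train_set$sequence)
  y_tr <- as.numeric(train_set$label)
  codes_va <- encode_codes(val_set$sequence)
  y_va <- as.numeric(val_set$label)

  with_seed_opt(config$rng_seed, {
    weights <- model$weights
    adam <- adam_init(weights)
    best <- list(acc = -Inf, weights = weights, epoch = 0L)
    hist <- list()
    epoch_global <- 0L

    for (b in seq_along(config$epoch_blocks)) {
      patience <- config$patience_per_block[b]
      since_best <- 0L
      for (e in seq_len(config$epoch_blocks[b])) {
        perm <- sample.int(nrow(codes_tr)) - 1L
        drop_seed <- sample.int(.Machine$integer.max, 1L)
        res <- cpp_cnn_train_epoch(weights, adam, codes_tr, y_tr, perm,
                                   config$batch_size, config$learning_rate,
                                   config$dropout, drop_seed)
        weights <- res$weights
        adam <- res$adam
        epoch_global <- epoch_global + 1L
        pv <- cpp_cnn_predict(weights, codes_va)
        acc <- mean((pv >= config$decision_threshold) == (y_va == 1))
        hist[[epoch_global]] <- data.frame(block = b, epoch = epoch_global,
                                           loss = res$loss, val_accuracy = acc)
        if (verbose) {
          message(sprintf("block %d epoch %d: loss %.4f val_acc %.4f",
                          b, epoch_global, res$loss, acc))
        }
        if (acc > best$acc) {           # min-delta 0, strict improvement
          best <- list(acc = acc, weights = weights, epoch = epoch_global)
          since_best <- 0L
        } else {
          since_best <- since_best + 1L
          if (since_best >= patience) break
        }
      }
      weights <- best$weights           # restore best before next block
    }

    model$weights <- best$weights
    h <- do.call(rbind, hist)
    model$history <- list(epochs = h, best_val_accuracy = best$acc,
                          best_epoch = best$epoch,
                          block_boundaries = cumsum(config$epoch_blocks))
    model$config <- config
    model
  })
}

#' Confusion-table metrics at a probability threshold
#'
#' @param probabilities numeric vector in (0,1).
#' @param labels 0/1 vector of the same length.
#' @param threshold probabilities `>= threshold` are called positive.
#' @return list of class `classifier_metrics` with `tp`, `fp`, `fn`, `tn`,
#'   `accuracy`, `precision`, `recall`, `f1`.
#' @export
evaluate_classifier <- function(probabilities, labels, threshold = 0.5) {
  stopifnot(length(probabilities) == length(labels),
            length(probabilities) > 0L)
  call <- probabilities >= threshold
  pos <- labels == 1
  tp <- sum(call & pos); fp <- sum(call & !pos)
  fn <- sum(!call & pos); tn <- sum(!call & !pos)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 accuracy = (tp + tn) / length(labels),
                 precision = precision, recall = recall, f1 = f1),
            class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.3f  precision %.3f  recall %.3f  F1 %.3f  (TP %d FP %d FN %d TN %d)\n",
    x$accuracy, x$precision, x$recall, x$f1, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint with a versioned header; the on-disk object is a
#' plain list of weights plus configuration.
#'
#' @param model an `sre_cnn`.
#' @param path checkpoint path.
#' @return `path` (save) or the restored `sre_cnn` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sre_cnn"))
  saveRDS(list(format = "srescan-cnn", version = 1L,
               weights = model$weights, config = unclass(model$config),
               history = model$history),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "srescan-cnn")) {
    stop("not a srescan model checkpoint: ", path)
  }
  structure(list(weights = obj$weights,
                 config = structure(obj$config, class = "model_config"),
                 history = obj$history),
            class = "sre_cnn")
}
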