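#' Hyperparameter set for the gait phase classifier
#'
#' The eight design parameters of the model and training procedure, with the
#' level sets used in the orthogonal-array sensitivity study: activation
#' function (tanh / LeakyReLU), sliding-window overlap ratio (0.3 / 0.5 /
#' 0.7), number of stacked bidirectional layers (1-3), optimizer (Adam /
#' Nadam / AdamW), hidden units per direction (32 / 64 / 128), learning rate
#' (0.001 / 0.002 / 0.003), dropout rate (0.3 / 0.5 / 0.7) and batch size
#' (3000 / 5000 / 7000). Values outside the level sets require
#' `allow_custom = TRUE`.
#'
#' @param activation,overlap_ratio,layers,optimizer,hidden_units,learning_rate,dropout,batch_size
#'   design parameter values (see above for the admissible levels).
#' @param epochs training epochs (not part of the design space).
#' @param seed integer seed for initialisation, splitting, shuffling and
#'   dropout.
#' @param allow_custom allow values outside the listed levels.
#' @return An object of class `hyper_params`.
#' @export
hyper_params <- function(activation = "LeakyReLU", overlap_ratio = 0.3,
                         layers = 1L, optimizer = "Adam", hidden_units = 64L,
                         learning_rate = 0.003, dropout = 0.5,
                         batch_size = 7000L, epochs = 30L, seed = 1L,
                         allow_custom = FALSE) {
  h <- list(activation = activation, overlap_ratio = overlap_ratio,
            layers = as.integer(layers), optimizer = optimizer,
            hidden_units = as.integer(hidden_units),
            learning_rate = learning_rate, dropout = dropout,
            batch_size = as.integer(batch_size), epochs = as.integer(epochs),
            seed = as.integer(seed))
  if (!allow_custom) {
    levels <- design_levels()
    chk <- function(field, value) {
      if (!value %in% levels[[field]])
        stop(sprintf("%s = %s is not one of the design levels (%s); use allow_custom = TRUE to override",
                     field, format(value), paste(levels[[field]], collapse = ", ")),
             call. = FALSE)
    }
    chk("activation", h$activation); chk("overlap_ratio", h$overlap_ratio)
    chk("layers", h$layers); chk("optimizer", h$optimizer)
    chk("hidden_units", h$hidden_units); chk("learning_rate", h$learning_rate)
    chk("dropout", h$dropout); chk("batch_size", h$batch_size)
  }
  structure(h, class = "hyper_params")
}

#' The optimal design parameter combination
#'
#' The combination selected by the level-average analysis of the bundled
#' orthogonal-array study: LeakyReLU activation, 30% overlap, 1 layer, Adam,
#' 64 hidden units, learning rate 0.003, dropout 0.5, batch size 7000.
#'
#' @param ... overrides passed to [hyper_params()] (e.g. `epochs`, `seed`).
#' @return A [hyper_params()] object.
#' @export
optimal_hyper_params <- function(...) {
  hyper_params(activation = "LeakyReLU", overlap_ratio = 0.3, layers = 1L,
               optimizer = "Adam", hidden_units = 64L, learning_rate = 0.003,
               dropout = 0.5, batch_size = 7000L, ...)
}

# class order for reports and one-hot coding: SW, HS, FC, HO
class_labels <- function() unname(gait_phases())

#' Build an untrained bidirectional LSTM gait phase model
#'
#' Architecture: `layers` stacked bidirectional LSTM layers with
#' `hidden_units` units per direction (forward and backward outputs
#' concatenated, so the recurrent output has dimension `2 * hidden_units`),
#' inverted dropout on the recurrent output, a dense hidden layer with the
#' configured activation (LeakyReLU slope 0.01), and a 4-way softmax head.
#'
#' @param h a [hyper_params()] object.
#' @param n_features feature rows per window.
#' @param width window width in samples.
#' @param n_classes number of phases (default 4).
#' @return An object of class `bilstm_model` (untrained).
#' @export
build_model <- function(h, n_features, width, n_classes = 4L) {
  stopifnot(inherits(h, "hyper_params"))
  params <- with_seed(h$seed,
    init_params(n_features, h$hidden_units, h$layers, n_classes))
  structure(list(params = params, hyper = h, n_features = n_features,
                 width = width, n_classes = n_classes, trained = FALSE),
            class = "bilstm_model")
}

#' @export
print.bilstm_model <- function(x, ...) {
  h <- x$hyper
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf("Bidirectional LSTM gait phase model: %d layer(s) x %d units/direction, %s head, %d parameters%s\n",
              h$layers, h$hidden_units, h$activation, np,
              if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

onehot <- function(labels, n_classes) {
  idx <- match(labels, class_labels())
  if (anyNA(idx)) stop("unknown phase labels in windows", call. = FALSE)
  y <- matrix(0, length(idx), n_classes)
  y[cbind(seq_along(idx), idx)] <- 1
  y
}

#' Train the gait phase model
#'
#' Splits the windows randomly into training and validation sets (default
#' 6:4), then minimises categorical cross-entropy by mini-batch gradient
#' descent with the configured optimizer, with backpropagation through time.
#' All randomness (split, shuffling, dropout masks) derives from the
#' hyperparameter seed, so training is reproducible.
#'
#' @param model a [build_model()] result.
#' @param windows a `labeled_windows` object ([window_stream()]).
#' @param split training fraction (default 0.6).
#' @param epochs,batch_size optional overrides of the hyperparameters (batch
#'   sizes are typically scaled down in proportion for small synthetic runs).
#' @param verbose print per-epoch progress.
#' @return The trained model, with `$history` holding per-epoch training
#'   loss/accuracy and validation accuracy.
#' @export
train_model <- function(model, windows, split = 0.6,
                        epochs = NULL, batch_size = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "bilstm_model"), inherits(windows, "labeled_windows"))
  h <- model$hyper
  epochs <- if (is.null(epochs)) h$epochs else as.integer(epochs)
  batch_size <- if (is.null(batch_size)) h$batch_size else as.integer(batch_size)
  X <- windows$windows
  if (dim(X)[1] != model$n_features || dim(X)[2] != model$width)
    stop("window dimensions do not match the model", call. = FALSE)
  n <- dim(X)[3]
  with_seed(h$seed + 1L, {
    perm <- sample.int(n)
    n_train <- floor(split * n)
    tr <- perm[seq_len(n_train)]
    va <- perm[setdiff(seq_len(n), seq_len(n_train))]
    if (min(table(factor(windows$labels[tr], levels = class_labels()))) < 2L)
      stop("a gait phase is absent (or nearly absent) from the training split",
           call. = FALSE)
    y <- onehot(windows$labels, model$n_classes)
    params <- model$params
    state <- new_opt_state(params)
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       train_acc = numeric(0), val_acc = numeric(0))
    bs <- max(1L, min(batch_size, n_train))
    for (ep in seq_len(epochs)) {
      ord <- tr[sample.int(n_train)]
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1L, n_train, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n_train)]
        Xb <- X[, , idx, drop = FALSE]
        yb <- y[idx, , drop = FALSE]
        mask <- NULL
        if (h$dropout > 0) {
          keep <- 1 - h$dropout
          mask <- matrix(stats::rbinom(length(idx) * 2L * h$hidden_units, 1L, keep),
                         length(idx), 2L * h$hidden_units) / keep
        }
        fwd <- bilstm_forward(params, Xb, h$hidden_units, h$layers,
                              h$activation, dropout_mask = mask,
                              keep_cache = TRUE)
        lo <- softmax_xent(fwd$probs, yb)
        grads <- bilstm_backward(params, fwd, lo$dlogits, h$hidden_units,
                                 h$layers, h$activation)
        upd <- opt_step(params, grads, state, h$learning_rate, h$optimizer)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + lo$loss * length(idx)
        ep_correct <- ep_correct +
          sum(max.col(fwd$probs, ties.method = "first") == max.col(yb))
      }
      val_acc <- NA_real_
      if (length(va) > 0L) {
        pv <- predict_probs(params, X[, , va, drop = FALSE], h)
        val_acc <- mean(max.col(pv, ties.method = "first") ==
                          max.col(y[va, , drop = FALSE])) * 100
      }
      hist <- rbind(hist, data.frame(
        epoch = ep, train_loss = ep_loss / n_train,
        train_acc = ep_correct / n_train * 100, val_acc = val_acc))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  train %.2f%%  val %.2f%%",
                        ep, ep_loss / n_train, ep_correct / n_train * 100, val_acc))
    }
    model$params <- params
    model$trained <- TRUE
    model$history <- hist
    model$split <- list(train = tr, val = va)
  })
  model
}

# forward pass in evaluation mode, batched to bound memory
predict_probs <- function(params, X, h, batch = 2048L) {
  n <- dim(X)[3]
  out <- matrix(0, n, ncol(params$dense_W2))
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    fwd <- bilstm_forward(params, X[, , idx, drop = FALSE],
                          h$hidden_units, h$layers, h$activation)
    out[idx, ] <- fwd$probs
  }
  out
}

#' Predict gait phases for windows
#'
#' Argmax of the softmax output; ties break toward the lower class index in
#' the reporting order SW, HS, FC, HO.
#'
#' @param object a trained `bilstm_model`.
#' @param windows a `labeled_windows` object or a feature x width x n array.
#' @param ... unused.
#' @return Integer phase labels (codes 5/4/3/2).
#' @export
predict.bilstm_model <- function(object, windows, ...) {
  X <- if (inherits(windows, "labeled_windows")) windows$windows else windows
  if (dim(X)[1] != object$n_features || dim(X)[2] != object$width)
    stop("window dimensions do not match the model", call. = FALSE)
  probs <- predict_probs(object$params, X, object$hyper)
  class_labels()[max.col(probs, ties.method = "first")]
}

#' Confusion matrix and per-phase accuracy
#'
#' Rows are the true phases, columns the predictions, both in the order SW,
#' HS, FC, HO. Per-phase accuracy is the class recall
#' (diagonal / row sum x 100); total accuracy is trace / total x 100.
#'
#' @param pred,truth integer phase labels of equal length.
#' @return An object of class `gait_eval`: list with `confusion`,
#'   `per_phase_accuracy` (named, percent) and `total_accuracy` (percent).
#' @export
evaluate_predictions <- function(pred, truth) {
  if (length(pred) != length(truth) || length(truth) == 0L)
    stop("pred and truth must be non-empty and of equal length", call. = FALSE)
  if (!all(c(pred, truth) %in% class_labels()))
    stop("labels must be gait phase codes 2, 3, 4 or 5", call. = FALSE)
  lv <- class_labels()
  nm <- names(gait_phases())
  confusion <- table(factor(truth, levels = lv), factor(pred, levels = lv))
  confusion <- matrix(as.integer(confusion), 4, 4, dimnames = list(nm, nm))
  rs <- rowSums(confusion)
  per_phase <- ifelse(rs > 0, diag(confusion) / rs * 100, NA_real_)
  names(per_phase) <- nm
  structure(list(confusion = confusion,
                 per_phase_accuracy = per_phase,
                 total_accuracy = sum(diag(confusion)) / sum(confusion) * 100),
            class = "gait_eval")
}

#' @export
print.gait_eval <- function(x, ...) {
  cat("Gait phase evaluation (rows: truth, cols: prediction)\n")
  print(x$confusion)
  cat("Per-phase accuracy [%]:",
      paste(names(x$per_phase_accuracy),
            sprintf("%.2f", x$per_phase_accuracy), sep = "=", collapse = "  "), "\n")
  cat(sprintf("Total accuracy: %.2f%%\n", x$total_accuracy))
  invisible(x)
}
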