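# Trait predictors: unimodal LSTM, multi-stream feature fusion,
# additive soft-attention fusion, and decision-level score fusion with
# convex weights selected by grid search.

#' Model training configuration
#'
#' Defaults follow the working hyperparameters for the smaller
#' interview-style corpus: 20 recurrent neurons, batch size 32, dropout
#' 0.2, Adam at learning rate 0.01, early stopping with patience 4 on
#' validation loss.
#'
#' @param task `"regression"` (linear head, mean-absolute-error loss) or
#'   `"classification"` (sigmoid head, binary cross-entropy).
#' @param units hidden units per recurrent layer.
#' @param dropout dropout rate in [0, 1) on the representation entering
#'   the output head.
#' @param batch_size mini-batch size.
#' @param epochs maximum training epochs.
#' @param lr Adam learning rate.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param head_decay L2 penalty on the output head's weights. Besides
#'   mild regularization this makes attention-fusion scores
#'   identifiable: without it the head can absorb any rescaling of the
#'   softmax weights, so the learned attention need not reflect modality
#'   contributions.
#' @param seed master seed; fans out to initialization, shuffling and
#'   dropout.
#' @return object of class `model_config`.
#' @export
model_config <- function(task = c("regression", "classification"),
                         units = 20, dropout = 0.2, batch_size = 32,
                         epochs = 100, lr = 0.01, patience = 4,
                         head_decay = 0.01, seed = 1) {
  task <- match.arg(task)
  assert_that(is_count(units, 1), "units must be a positive integer")
  assert_that(is_number(dropout) && dropout >= 0 && dropout < 1,
              "dropout must be in [0, 1)")
  assert_that(is_count(batch_size, 1), "batch_size must be positive")
  assert_that(is_count(epochs, 1), "epochs must be positive")
  assert_that(is_number(lr) && lr > 0, "lr must be > 0")
  assert_that(is_count(patience, 1), "patience must be positive")
  assert_that(is_number(head_decay) && head_decay >= 0,
              "head_decay must be >= 0")
  structure(list(task = task, units = as.integer(units),
                 dropout = dropout, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr,
                 patience = as.integer(patience),
                 head_decay = head_decay, seed = as.integer(seed)),
            class = "model_config")
}

# Accepts a list of per-video L x D matrices or an N x L x D array and
# returns the array; errors on mixed sequence lengths.
as_block_array <- function(x, what = "block") {
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  if (is.matrix(x)) {
    return(array(x, c(1L, nrow(x), ncol(x))))
  }
  stopifnot(is.list(x), length(x) > 0)
  Ls <- vapply(x, nrow, integer(1))
  if (length(unique(Ls)) != 1L) {
    stop_kf("mixed sequence lengths in ", what, ": ",
            paste(sort(unique(Ls)), collapse = ", "),
            "; slice videos to a common window count first")
  }
  D <- ncol(x[[1]])
  arr <- array(0, c(length(x), Ls[1], D))
  for (i in seq_along(x)) arr[i, , ] <- as.matrix(x[[i]])
  arr
}

validate_labels <- function(y, task, n) {
  assert_that(is.numeric(y) && length(y) == n,
              "labels must be numeric, one per sequence")
  if (task == "classification") {
    assert_that(all(y %in% c(0, 1)), "classification labels must be 0/1")
    if (length(unique(y)) < 2L) {
      stop_kf("training labels contain a single class")
    }
  }
}

new_kf_model <- function(arch, fitted, config, dims, modalities) {
  structure(list(arch = arch, params = fitted$params, config = config,
                 dims = dims, modalities = modalities,
                 val_loss = fitted$val_loss, history = fitted$history,
                 best_epoch = fitted$best_epoch),
            class = "kf_model")
}

#' Train a unimodal recurrent predictor
#'
#' A single hidden LSTM layer followed by a one-neuron dense head
#' (sigmoid for classification, linear for regression).
#'
#' @param x list of per-video L x D matrices (or an N x L x D array) of
#'   one modality's window encodings.
#' @param y numeric labels, one per video: 0/1 for classification,
#'   [0, 1] scores for regression.
#' @param config a [model_config()].
#' @param x_val,y_val optional validation data for early stopping; when
#'   absent the training loss is monitored.
#' @return object of class `kf_model`.
#' @export
train_unimodal <- function(x, y, config, x_val = NULL, y_val = NULL) {
  stopifnot(inherits(config, "model_config"))
  blocks <- list(as_block_array(x))
  validate_labels(y, config$task, dim(blocks[[1]])[1])
  vb <- if (!is.null(x_val)) list(as_block_array(x_val)) else NULL
  fitted <- net_train("unimodal", blocks, y, config, vb, y_val)
  new_kf_model("unimodal", fitted, config,
               dims = dim(blocks[[1]])[3], modalities = "x")
}

#' Train a feature-fusion predictor
#'
#' One LSTM layer per modality; the final hidden states are concatenated
#' and passed to a single-neuron head. A single-modality call reduces to
#' the unimodal architecture.
#'
#' @param blocks named list of modalities, each a list of per-video
#'   L x D_m matrices (or an N x L x D_m array) sharing one window grid.
#' @inheritParams train_unimodal
#' @param blocks_val optional validation blocks (same structure).
#' @return object of class `kf_model`.
#' @export
train_feature_fusion <- function(blocks, y, config, blocks_val = NULL,
                                 y_val = NULL) {
  stopifnot(inherits(config, "model_config"))
  arrs <- lapply(blocks, as_block_array)
  Ls <- vapply(arrs, function(a) dim(a)[2], numeric(1))
  if (length(unique(Ls)) != 1L) {
    stop_kf("modalities disagree on the window count: ",
            paste(Ls, collapse = ", "))
  }
  validate_labels(y, config$task, dim(arrs[[1]])[1])
  vb <- if (!is.null(blocks_val)) lapply(blocks_val, as_block_array)
  fitted <- net_train("feature_fusion", arrs, y, config, vb, y_val)
  new_kf_model("feature_fusion", fitted, config,
               dims = vapply(arrs, function(a) dim(a)[3], numeric(1)),
               modalities = names(blocks) %||% paste0("m", seq_along(arrs)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train an additive soft-attention fusion predictor
#'
#' One LSTM layer per modality returns per-window representations. Per
#' window, the concatenated representations pass through a 12-unit fully
#' connected layer and a 3-way softmax whose outputs are the modality
#' attention weights; each modality representation is layer-normalized,
#' scaled by its weight and summed. The final window's fused state
#' drives a single-neuron head. The per-window weights form the
#' attention trace used for modality-contribution explanations.
#'
#' @param blocks named list of exactly three modalities (conventionally
#'   kineme, AU, speech), each a list of per-video L x D_m matrices or
#'   an N x L x D_m array.
#' @inheritParams train_feature_fusion
#' @return object of class `kf_model` (arch `"attention"`).
#' @export
train_attention_fusion <- function(blocks, y, config, blocks_val = NULL,
                                   y_val = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (length(blocks) != 3L) {
    stop_kf("attention fusion requires exactly 3 modalities, got ",
            length(blocks))
  }
  arrs <- lapply(blocks, as_block_array)
  Ls <- vapply(arrs, function(a) dim(a)[2], numeric(1))
  if (length(unique(Ls)) != 1L) {
    stop_kf("modalities disagree on the window count: ",
            paste(Ls, collapse = ", "))
  }
  validate_labels(y, config$task, dim(arrs[[1]])[1])
  vb <- if (!is.null(blocks_val)) lapply(blocks_val, as_block_array)
  fitted <- net_train("attention", arrs, y, config, vb, y_val)
  new_kf_model("attention", fitted, config,
               dims = vapply(arrs, function(a) dim(a)[3], numeric(1)),
               modalities = names(blocks) %||% c("kineme", "au", "speech"))
}

#' @export
print.kf_model <- function(x, ...) {
  cat("kf_model:", x$arch, "(", x$config$task, "),",
      length(x$dims), "modality stream(s), units =", x$config$units,
      "\n  best epoch", x$best_epoch, "monitored loss",
      signif(x$val_loss, 4), "\n")
  invisible(x)
}

#' Predict trait scores
#'
#' @param object a `kf_model`.
#' @param newdata for unimodal models a list of L x D matrices or an
#'   N x L x D array; for fusion models a list of modalities in
#'   training order.
#' @param ... unused.
#' @return numeric predictions (probabilities in [0, 1] for
#'   classification, scores for regression).
#' @export
predict.kf_model <- function(object, newdata, ...) {
  blocks <- if (object$arch == "unimodal") {
    list(as_block_array(newdata))
  } else {
    lapply(newdata, as_block_array)
  }
  fwd <- net_forward(object$arch, object$params, blocks)
  if (object$config$task == "classification") sigmoid(fwd$z) else fwd$z
}

#' Extract per-window attention traces
#'
#' @param model a `kf_model` trained by [train_attention_fusion()].
#' @param blocks modality blocks as for [predict.kf_model()].
#' @return N x L x 3 array of modality weights; each `[i, t, ]` row is
#'   non-negative and sums to 1.
#' @export
attention_trace <- function(model, blocks) {
  stopifnot(inherits(model, "kf_model"))
  if (model$arch != "attention") {
    stop_kf("attention traces require an attention-fusion model")
  }
  arrs <- lapply(blocks, as_block_array)
  fwd <- net_forward("attention", model$params, arrs, trace = TRUE)
  dimnames(fwd$A) <- list(NULL, NULL, model$modalities)
  fwd$A
}

# ---- decision fusion ---------------------------------------------------

#' Fuse unimodal score streams by convex combination
#'
#' @param streams list of equal-length numeric score vectors.
#' @param weights convex weights (non-negative, summing to 1 within
#'   1e-9), one per stream; a [fit_fusion_weights()] result is accepted.
#' @return element-wise convex combination.
#' @export
decision_fuse <- function(streams, weights) {
  if (inherits(weights, "fusion_weights")) weights <- weights$weights
  stopifnot(is.list(streams), length(streams) >= 2L)
  lens <- vapply(streams, length, integer(1))
  assert_that(length(unique(lens)) == 1L, "streams differ in length")
  assert_that(length(weights) == length(streams),
              "one weight per stream required")
  assert_that(all(weights >= 0), "weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9) {
    stop_kf("weights must sum to 1 (got ", sum(weights), ")")
  }
  out <- numeric(lens[1])
  for (i in seq_along(streams)) out <- out + weights[i] * streams[[i]]
  out
}

# All weight vectors of length m on the `step` lattice of the simplex.
simplex_grid <- function(m, step = 0.05) {
  n <- as.integer(round(1 / step))
  rec <- function(m, total) {
    if (m == 1L) return(matrix(total, 1, 1))
    out <- list()
    for (i in 0:total) {
      sub <- rec(m - 1L, total - i)
      out[[length(out) + 1L]] <- cbind(i, sub)
    }
    do.call(rbind, out)
  }
  g <- rec(m, n) * step
  dimnames(g) <- NULL
  g
}

#' Select decision-fusion weights by grid search
#'
#' Exhaustively searches the 0.05-step lattice on the weight simplex and
#' returns the weights maximizing validation macro F1 (classification;
#' fused scores thresholded at 0.5) or Pearson correlation (regression).
#' Ties are broken toward the most uniform weight vector, then
#' lexicographically.
#'
#' @param streams list of >= 2 validation score vectors.
#' @param labels validation labels (0/1 or continuous scores).
#' @param task `"regression"` or `"classification"`.
#' @param step grid step (default 0.05).
#' @return object of class `fusion_weights`: `weights`, `metric`,
#'   `value`.
#' @export
fit_fusion_weights <- function(streams, labels,
                               task = c("regression", "classification"),
                               step = 0.05) {
  task <- match.arg(task)
  stopifnot(is.list(streams), length(streams) >= 2L)
  n <- length(labels)
  assert_that(all(vapply(streams, length, integer(1)) == n),
              "streams and labels differ in length")
  if (length(unique(labels)) < 2L) {
    stop_kf("labels are constant; fusion weights are unidentifiable")
  }
  grid <- simplex_grid(length(streams), step)
  score_of <- function(w) {
    fused <- decision_fuse(streams, w)
    if (task == "classification") {
      macro_f1(as.integer(fused > 0.5), labels)
    } else {
      if (stats::sd(fused) == 0) return(-Inf)
      stats::cor(fused, labels)
    }
  }
  vals <- apply(grid, 1, score_of)
  best <- max(vals)
  cand <- which(vals >= best - 1e-12)
  if (length(cand) > 1L) {
    unif <- rowSums((grid[cand, , drop = FALSE] - 1 / length(streams))^2)
    cand <- cand[unif <= min(unif) + 1e-12]
    if (length(cand) > 1L) {
      ord <- do.call(order, as.data.frame(grid[cand, , drop = FALSE]))
      cand <- cand[ord[1]]
    }
  }
  best_idx <- cand[1]
  structure(list(weights = unname(drop(grid[best_idx, ])),
                 metric = if (task == "classification") "macro_f1"
                          else "pcc",
                 value = vals[best_idx]),
            class = "fusion_weights")
}

#' @export
print.fusion_weights <- function(x, ...) {
  cat("fusion_weights:", paste(format(x$weights), collapse = " "),
      "(", x$metric, "=", signif(x$value, 4), ")\n")
  invisible(x)
}
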