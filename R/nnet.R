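# Minimal recurrent neural engine.
#
# No deep-learning framework ships with the target image, so the three
# architectures the package needs (unimodal LSTM, multi-stream feature
# fusion, additive soft-attention fusion) are implemented directly:
# batched LSTM forward/backward through time, a layer-normalized
# attention block, sigmoid/linear heads with BCE/MAE losses, inverted
# dropout and an Adam optimizer. Gradients are analytic and verified
# against finite differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Glorot-uniform initialization, forget-gate bias set to 1.
lstm_init <- function(input_dim, hidden) {
  lim <- sqrt(6 / (input_dim + 4 * hidden))
  Wx <- matrix(stats::runif(input_dim * 4 * hidden, -lim, lim),
               input_dim, 4 * hidden)
  limh <- sqrt(6 / (hidden + 4 * hidden))
  Wh <- matrix(stats::runif(hidden * 4 * hidden, -limh, limh),
               hidden, 4 * hidden)
  b <- numeric(4 * hidden)
  b[(hidden + 1):(2 * hidden)] <- 1
  list(Wx = Wx, Wh = Wh, b = b)
}

dense_init <- function(input_dim, output_dim) {
  lim <- sqrt(6 / (input_dim + output_dim))
  list(W = matrix(stats::runif(input_dim * output_dim, -lim, lim),
                  input_dim, output_dim),
       b = numeric(output_dim))
}

# X: N x L x D array. Returns per-step hidden states (N x L x H) and the
# caches backpropagation needs.
lstm_forward <- function(par, X) {
  N <- dim(X)[1]; L <- dim(X)[2]; D <- dim(X)[3]
  H <- nrow(par$Wh)
  h <- matrix(0, N, H); c <- matrix(0, N, H)
  Hs <- array(0, c(N, L, H))
  cache <- vector("list", L)
  for (t in seq_len(L)) {
    xt <- matrix(X[, t, ], N, D)
    Z <- xt %*% par$Wx + h %*% par$Wh +
      matrix(par$b, N, 4 * H, byrow = TRUE)
    i <- sigmoid(Z[, 1:H, drop = FALSE])
    f <- sigmoid(Z[, (H + 1):(2 * H), drop = FALSE])
    o <- sigmoid(Z[, (2 * H + 1):(3 * H), drop = FALSE])
    g <- tanh(Z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f * c + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    cache[[t]] <- list(xt = xt, h_prev = h, c_prev = c, i = i, f = f,
                       o = o, g = g, c = c_new, tc = tc)
    h <- h_new; c <- c_new
    Hs[, t, ] <- h
  }
  list(Hs = Hs, h_last = h, cache = cache)
}

# dHs: N x L x H gradient on every hidden state (zeros where unused).
lstm_backward <- function(par, cache, dHs) {
  L <- length(cache)
  N <- nrow(cache[[1]]$xt); H <- ncol(cache[[1]]$i)
  dWx <- par$Wx * 0; dWh <- par$Wh * 0; db <- par$b * 0
  dh_next <- matrix(0, N, H); dc_next <- matrix(0, N, H)
  for (t in rev(seq_len(L))) {
    cc <- cache[[t]]
    dh <- matrix(dHs[, t, ], N, H) + dh_next
    do <- dh * cc$tc
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    df <- dc * cc$c_prev
    dg <- dc * cc$i
    dZ <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                do * cc$o * (1 - cc$o),
                dg * (1 - cc$g^2))
    dWx <- dWx + crossprod(cc$xt, dZ)
    dWh <- dWh + crossprod(cc$h_prev, dZ)
    db <- db + colSums(dZ)
    dh_next <- dZ %*% t(par$Wh)
    dc_next <- dc * cc$f
  }
  list(Wx = dWx, Wh = dWh, b = db)
}

# Row-wise layer normalization without learned affine parameters.
layernorm_forward <- function(Hm, eps = 1e-6) {
  mu <- rowMeans(Hm)
  centered <- Hm - mu
  v <- rowMeans(centered^2)
  inv <- 1 / sqrt(v + eps)
  list(out = centered * inv, centered = centered, inv = inv)
}

layernorm_backward <- function(cache, dout) {
  n <- cache$out
  inv <- cache$inv
  dn <- dout
  inv * (dn - rowMeans(dn) - n * rowMeans(dn * n))
}

softmax_rows <- function(Z) {
  m <- apply(Z, 1, max)
  e <- exp(Z - m)
  e / rowSums(e)
}

# ---- parameter trees, loss heads, Adam ---------------------------------

flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(p[[nm]])) {
      out <- c(out, flatten_params(p[[nm]], key))
    } else {
      out[[key]] <- p[[nm]]
    }
  }
  out
}

unflatten_params <- function(flat) {
  out <- list()
  for (key in names(flat)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    out <- assign_nested(out, parts, flat[[key]])
  }
  out
}

assign_nested <- function(lst, parts, value) {
  if (length(parts) == 1L) {
    lst[[parts]] <- value
    return(lst)
  }
  if (is.null(lst[[parts[1]]])) lst[[parts[1]]] <- list()
  lst[[parts[1]]] <- assign_nested(lst[[parts[1]]], parts[-1], value)
  lst
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0),
       t = 0L)
}

adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(flat)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    flat[[nm]] <- flat[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(flat = flat, state = state)
}

# Loss and gradient at the pre-activation of the single-neuron head.
# Classification: sigmoid + binary cross-entropy; regression: linear +
# mean absolute error (so Acc = 1 - MAE aligns with the training loss).
head_loss <- function(z, y, task) {
  n <- length(y)
  if (task == "classification") {
    p <- sigmoid(z)
    eps <- 1e-12
    loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
    list(loss = loss, dz = (p - y) / n, yhat = p)
  } else {
    loss <- mean(abs(z - y))
    list(loss = loss, dz = sign(z - y) / n, yhat = z)
  }
}

# ---- architecture forward/backward -------------------------------------
# `blocks` is always a list of N x L x D_m arrays (length 1 for the
# unimodal architecture). Dropout masks (inverted dropout on the
# representation entering the head) are supplied by the caller so
# evaluation passes can disable them.

net_forward <- function(arch, params, blocks, dropout_mask = NULL,
                        trace = FALSE) {
  if (arch %in% c("unimodal", "feature_fusion")) {
    outs <- lapply(seq_along(blocks), function(m) {
      lstm_forward(params$lstm[[m]], blocks[[m]])
    })
    rep_ <- do.call(cbind, lapply(outs, `[[`, "h_last"))
    if (!is.null(dropout_mask)) rep_ <- rep_ * dropout_mask
    z <- drop(rep_ %*% params$head$W) + params$head$b
    list(z = z, lstm = outs, rep = rep_)
  } else if (arch == "attention") {
    outs <- lapply(seq_along(blocks), function(m) {
      lstm_forward(params$lstm[[m]], blocks[[m]])
    })
    N <- dim(blocks[[1]])[1]; L <- dim(blocks[[1]])[2]
    H <- ncol(outs[[1]]$h_last)
    n12 <- ncol(params$att$W1)
    # per window: softmax attention over the three modality states,
    # layer-normalized states scaled by their weights and summed; the
    # head sees the fused state averaged over all windows, so every
    # window's weights face the loss
    A <- array(0, c(N, L, 3))
    att_cache <- vector("list", L)
    S <- matrix(0, N, H)
    for (t in seq_len(L)) {
      ht <- lapply(outs, function(o) matrix(o$Hs[, t, ], N, H))
      ln <- lapply(ht, layernorm_forward)
      # the scorer sees the layer-normalized states, so all three
      # modalities enter it on a common scale
      U <- do.call(cbind, lapply(ln, `[[`, "out"))
      pre <- tanh(U %*% params$att$W1 +
                    matrix(params$att$b1, N, n12, byrow = TRUE))
      logits <- pre %*% params$att$W2 +
        matrix(params$att$b2, N, 3, byrow = TRUE)
      a <- softmax_rows(logits)
      A[, t, ] <- a
      fused_t <- matrix(0, N, H)
      for (m in 1:3) fused_t <- fused_t + a[, m] * ln[[m]]$out
      S <- S + fused_t / L
      att_cache[[t]] <- list(U = U, pre = pre, a = a, ln = ln)
    }
    if (!is.null(dropout_mask)) S <- S * dropout_mask
    z <- drop(S %*% params$head$W) + params$head$b
    list(z = z, lstm = outs, rep = S, A = A, att_cache = att_cache)
  } else {
    stop_kf("unknown architecture: ", arch)
  }
}

net_backward <- function(arch, params, blocks, fwd, dz,
                         dropout_mask = NULL) {
  N <- dim(blocks[[1]])[1]; L <- dim(blocks[[1]])[2]
  grads <- list()
  drep <- outer(dz, drop(params$head$W))
  grads$head <- list(W = matrix(crossprod(fwd$rep, dz)), b = sum(dz))
  if (!is.null(dropout_mask)) drep <- drep * dropout_mask
  if (arch %in% c("unimodal", "feature_fusion")) {
    grads$lstm <- stats::setNames(vector("list", length(blocks)),
                                  paste0("m", seq_along(blocks)))
    off <- 0L
    for (m in seq_along(blocks)) {
      H <- ncol(fwd$lstm[[m]]$h_last)
      dHs <- array(0, c(N, L, H))
      dHs[, L, ] <- drep[, off + seq_len(H), drop = FALSE]
      grads$lstm[[m]] <- lstm_backward(params$lstm[[m]],
                                       fwd$lstm[[m]]$cache, dHs)
      off <- off + H
    }
  } else {
    H <- ncol(fwd$lstm[[1]]$h_last)
    dS <- drep
    grads$att <- list(W1 = params$att$W1 * 0, b1 = params$att$b1 * 0,
                      W2 = params$att$W2 * 0, b2 = params$att$b2 * 0)
    dHs_all <- lapply(1:3, function(m) array(0, c(N, L, H)))
    for (t in seq_len(L)) {
      cc <- fwd$att_cache[[t]]
      dfused_t <- dS / L
      da <- matrix(0, N, 3)
      for (m in 1:3) da[, m] <- rowSums(dfused_t * cc$ln[[m]]$out)
      dlogits <- cc$a * (da - rowSums(da * cc$a))
      dpre <- dlogits %*% t(params$att$W2)
      dpre_in <- dpre * (1 - cc$pre^2)
      grads$att$W1 <- grads$att$W1 + crossprod(cc$U, dpre_in)
      grads$att$b1 <- grads$att$b1 + colSums(dpre_in)
      grads$att$W2 <- grads$att$W2 + crossprod(cc$pre, dlogits)
      grads$att$b2 <- grads$att$b2 + colSums(dlogits)
      dU <- dpre_in %*% t(params$att$W1)
      for (m in 1:3) {
        # the normalized state feeds both the weighting and the scorer
        dln_total <- dfused_t * cc$a[, m] +
          dU[, (m - 1) * H + seq_len(H), drop = FALSE]
        dHs_all[[m]][, t, ] <- layernorm_backward(cc$ln[[m]], dln_total)
      }
    }
    grads$lstm <- stats::setNames(vector("list", 3), paste0("m", 1:3))
    for (m in 1:3) {
      grads$lstm[[m]] <- lstm_backward(params$lstm[[m]],
                                       fwd$lstm[[m]]$cache, dHs_all[[m]])
    }
  }
  grads
}

net_init <- function(arch, dims, units) {
  params <- list()
  params$lstm <- stats::setNames(lapply(dims, function(d)
    lstm_init(d, units)), paste0("m", seq_along(dims)))
  if (arch == "attention") {
    params$att <- c(
      stats::setNames(dense_init(3 * units, 12), c("W1", "b1")),
      stats::setNames(dense_init(12, 3), c("W2", "b2")))
    params$head <- dense_init(units, 1)
  } else {
    params$head <- dense_init(units * length(dims), 1)
  }
  params
}

# Full-batch loss without dropout (validation / scoring).
net_eval_loss <- function(arch, params, blocks, y, task) {
  fwd <- net_forward(arch, params, blocks)
  head_loss(fwd$z, y, task)$loss
}

# Core training loop shared by the three model constructors: mini-batch
# Adam with seeded shuffling and dropout, early stopping on validation
# loss, best-parameters restore. The head bias starts at the training
# label mean (logit of the base rate for classification) so the early
# epochs fit structure rather than the offset.
net_train <- function(arch, blocks, y, config, val_blocks = NULL,
                      val_y = NULL) {
  N <- dim(blocks[[1]])[1]
  dims <- vapply(blocks, function(b) dim(b)[3], numeric(1))
  has_val <- !is.null(val_blocks)
  with_seed(config$seed, {
    params <- net_init(arch, dims, config$units)
    params$head$b <- if (config$task == "classification") {
      stats::qlogis(min(max(mean(y), 0.05), 0.95))
    } else {
      mean(y)
    }
    flat <- flatten_params(params)
    state <- adam_init(flat)
    rep_dim <- if (arch == "attention") config$units else
      config$units * length(blocks)
    best <- list(loss = Inf, flat = flat, epoch = 0L)
    wait <- 0L
    history <- numeric(0)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(N)
      for (start in seq(1L, N, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, N)]
        bb <- lapply(blocks, function(b) b[idx, , , drop = FALSE])
        params <- unflatten_params(flat)
        # inverted dropout on the representation entering the head
        mask <- if (config$dropout > 0) {
          matrix(stats::rbinom(length(idx) * rep_dim, 1,
                               1 - config$dropout),
                 length(idx), rep_dim) / (1 - config$dropout)
        } else NULL
        fwd <- net_forward(arch, params, bb, mask)
        hl <- head_loss(fwd$z, y[idx], config$task)
        grads <- net_backward(arch, params, bb, fwd, hl$dz, mask)
        # L2 on the head weights: without it the head can absorb any
        # rescaling of the attention weights, leaving the softmax
        # unidentified; the penalty makes attention carry the signal
        if (config$head_decay > 0) {
          grads$head$W <- grads$head$W + config$head_decay * params$head$W
        }
        step <- adam_step(flat, flatten_params(grads), state,
                          config$lr)
        flat <- step$flat; state <- step$state
      }
      params <- unflatten_params(flat)
      monitor <- if (has_val) {
        net_eval_loss(arch, params, val_blocks, val_y, config$task)
      } else {
        net_eval_loss(arch, params, blocks, y, config$task)
      }
      history <- c(history, monitor)
      if (monitor < best$loss - 1e-9) {
        best <- list(loss = monitor, flat = flat, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    list(params = unflatten_params(best$flat), val_loss = best$loss,
         history = history, best_epoch = best$epoch)
  })
}
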