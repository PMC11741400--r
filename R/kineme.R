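# Kineme vocabulary learning and sequence assignment.
#
# Head motion is modeled as a sequence of elementary, interpretable
# units ("kinemes", by analogy with phonemes). Pooled l-frame windows of
# (pitch, yaw, roll), offset to non-negativity, form a characterization
# matrix H; non-negative matrix factorization H ~ B C yields a basis B
# and coefficients C; a Gaussian mixture over the coefficient vectors
# gives k component means C*, and H* = B C* holds the k kinemes as
# columns. New segments are projected onto B by non-negative least
# squares and assigned to the kineme maximizing the mixture posterior.

#' Solve a non-negative least-squares problem
#'
#' Lawson--Hanson active-set algorithm for
#' `min ||A x - b||^2  subject to  x >= 0`.
#'
#' @param A numeric matrix (m x n).
#' @param b numeric vector of length m.
#' @param tol tolerance on the dual feasibility test.
#' @return the non-negative solution vector of length n.
#' @export
nnls_solve <- function(A, b, tol = 1e-10) {
  stopifnot(is.matrix(A), length(b) == nrow(A))
  n <- ncol(A)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0L
  max_iter <- 30L * n
  scale <- max(abs(w), 1)
  while (any(!passive) && max(w[!passive]) > tol * scale) {
    iter <- iter + 1L
    if (iter > max_iter) break
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      Ap <- A[, passive, drop = FALSE]
      z <- numeric(n)
      z[passive] <- drop(qr.coef(qr(Ap), b))
      z[is.na(z)] <- 0
      if (all(z[passive] > tol)) { x <- z; break }
      viol <- passive & (z <= tol)
      alpha <- min(x[viol] / (x[viol] - z[viol]))
      x <- x + alpha * (z - x)
      passive <- passive & (x > tol)
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}

#' Build the pooled segment (characterization) matrix
#'
#' Cuts each angle series into overlapping `window_s`-second windows and
#' stacks the concatenated (pitch, yaw, roll) windows as columns, video
#' by video. A single global additive offset (`-min` over all entries, 0
#' if already non-negative) makes the matrix non-negative while
#' preserving motion shape exactly.
#'
#' @param series list of `pose_series` sharing one frame rate.
#' @param window_s window length in seconds (default 2).
#' @param overlap_fraction fractional window overlap (default 0.5, i.e.
#'   a 1 s hop at the 2 s default).
#' @return object of class `segment_matrix`: `H` (3l x S, non-negative),
#'   `len`, `hop` (frames), `offset`, `window_s`, `overlap_fraction`,
#'   `frame_rate`, and `video_of` mapping columns to source videos.
#' @export
build_segment_matrix <- function(series, window_s = 2,
                                 overlap_fraction = 0.5) {
  if (inherits(series, "pose_series")) series <- list(series)
  assert_that(length(series) > 0, "no pose series supplied")
  assert_that(is_number(window_s) && window_s > 0, "window_s must be > 0")
  assert_that(is_number(overlap_fraction) && overlap_fraction >= 0 &&
                overlap_fraction < 1,
              "overlap_fraction must be in [0, 1)")
  fr <- series[[1]]$frame_rate
  len <- as.integer(round(window_s * fr))
  hop <- max(1L, as.integer(round(len * (1 - overlap_fraction))))
  cols <- list()
  video_of <- character(0)
  for (s in series) {
    if (s$frame_rate != fr) stop_kf("all series must share one frame rate")
    Tn <- nrow(s$angles)
    if (Tn < len) {
      warning("video ", s$video_id, " shorter than one window (",
              Tn, " < ", len, " frames); skipped", call. = FALSE)
      next
    }
    for (st in window_starts(Tn, len, hop)) {
      idx <- st:(st + len - 1L)
      cols[[length(cols) + 1L]] <- c(s$angles[idx, 1], s$angles[idx, 2],
                                     s$angles[idx, 3])
      video_of <- c(video_of, s$video_id)
    }
  }
  if (length(cols) == 0L) stop_kf("all videos shorter than one window")
  H <- do.call(cbind, cols)
  offset <- max(0, -min(H))
  structure(list(H = H + offset, len = len, hop = hop, offset = offset,
                 window_s = window_s, overlap_fraction = overlap_fraction,
                 frame_rate = fr, video_of = video_of),
            class = "segment_matrix")
}

# Frobenius NMF by multiplicative updates (Lee--Seung), seeded uniform
# non-negative init, iteration cap with a relative-tolerance stop.
nmf_factorize <- function(V, r, seed, max_iter = 500, tol = 1e-4) {
  eps <- 1e-12
  with_seed(seed, {
    B <- matrix(stats::runif(nrow(V) * r, 0.1, 1), nrow(V), r)
    C <- matrix(stats::runif(r * ncol(V), 0.1, 1), r, ncol(V))
    res_prev <- Inf
    converged <- FALSE
    normV <- sqrt(sum(V^2))
    for (it in seq_len(max_iter)) {
      C <- C * (crossprod(B, V)) / (crossprod(B, B %*% C) + eps)
      B <- B * tcrossprod(V, C) / (B %*% tcrossprod(C) + eps)
      if (it %% 10L == 0L || it == max_iter) {
        res <- sqrt(sum((V - B %*% C)^2))
        # residual change measured against the data norm, so the stop
        # rule does not tighten as the fit improves
        if (is.finite(res_prev) &&
            abs(res_prev - res) <= tol * max(normV, eps)) {
          converged <- TRUE
          break
        }
        res_prev <- res
      }
    }
    if (!converged) {
      warning("NMF did not reach relative tolerance ", tol,
              " within ", max_iter, " iterations (final residual ",
              signif(sqrt(sum((V - B %*% C)^2)), 4), ")", call. = FALSE)
    }
    list(B = B, C = C)
  })
}

# Multivariate normal log-density via Cholesky; covariances carry a
# small ridge so near-degenerate coefficient clouds stay well-posed.
mvn_logdensity <- function(X, mean, cov) {
  d <- length(mean)
  ch <- chol(cov)
  centered <- sweep(X, 2, mean)
  z <- backsolve(ch, t(centered), transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

#' Fit a full-covariance Gaussian mixture by EM
#'
#' k-means initialization (seeded), expectation--maximization with a
#' ridge `reg` on covariance diagonals. `n_init` independent restarts
#' are run and the fit with the highest log-likelihood kept; a single
#' EM run can merge tight adjacent clusters under one inflated
#' covariance, which restarts reliably escape.
#'
#' @param X numeric matrix (n x d) of observations.
#' @param k number of components (2 <= k <= n).
#' @param seed integer seed for the k-means initializations.
#' @param max_iter,tol EM iteration cap and log-likelihood relative
#'   tolerance.
#' @param reg covariance ridge.
#' @param n_init number of EM restarts.
#' @return list with `weights`, `means` (k x d), `covs` (list of d x d),
#'   `loglik`.
#' @export
fit_gmm <- function(X, k, seed = 1, max_iter = 200, tol = 1e-8,
                    reg = 1e-6, n_init = 3) {
  best <- NULL
  for (init in seq_len(n_init)) {
    fit <- fit_gmm_once(X, k, derive_seed(seed, init), max_iter, tol,
                        reg)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best
}

fit_gmm_once <- function(X, k, seed, max_iter, tol, reg) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  assert_that(is_count(k, 1) && k <= n,
              paste0("k must be between 1 and the number of observations (",
                     n, ")"))
  km <- with_seed(seed, stats::kmeans(X, centers = k, nstart = 5,
                                      iter.max = 50))
  means <- km$centers
  weights <- as.numeric(table(factor(km$cluster, levels = seq_len(k)))) / n
  weights <- pmax(weights, 1e-8); weights <- weights / sum(weights)
  covs <- lapply(seq_len(k), function(j) {
    idx <- km$cluster == j
    S <- if (sum(idx) > d) stats::cov(X[idx, , drop = FALSE]) else
      stats::cov(X)
    S + diag(reg + 1e-8 * mean(diag(S)), d)
  })
  loglik_prev <- -Inf
  for (it in seq_len(max_iter)) {
    logd <- sapply(seq_len(k), function(j) {
      log(weights[j]) + mvn_logdensity(X, means[j, ], covs[[j]])
    })
    if (k == 1L) logd <- matrix(logd, ncol = 1)
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    resp <- exp(logd - lse)
    loglik <- sum(lse)
    if (is.finite(loglik_prev) &&
        abs(loglik - loglik_prev) <= tol * abs(loglik_prev)) break
    loglik_prev <- loglik
    nk <- colSums(resp)
    weights <- nk / n
    for (j in seq_len(k)) {
      means[j, ] <- colSums(resp[, j] * X) / nk[j]
      centered <- sweep(X, 2, means[j, ])
      S <- crossprod(centered * sqrt(resp[, j])) / nk[j]
      covs[[j]] <- S + diag(reg + 1e-8 * mean(diag(S)), d)
    }
  }
  list(weights = weights, means = means, covs = covs, loglik = loglik_prev)
}

# Mixture posterior responsibilities P(component | x) for rows of X.
gmm_posterior <- function(model, X) {
  X <- as.matrix(X)
  k <- length(model$weights)
  logd <- sapply(seq_len(k), function(j) {
    log(model$weights[j]) +
      mvn_logdensity(X, model$means[j, ], model$covs[[j]])
  })
  if (nrow(X) == 1L) logd <- matrix(logd, nrow = 1)
  m <- apply(logd, 1, max)
  post <- exp(logd - m)
  post / rowSums(post)
}

#' Learn a kineme vocabulary
#'
#' Factorizes the pooled segment matrix `H ~ B C` (rank `r` NMF,
#' multiplicative updates), fits a `k`-component full-covariance
#' Gaussian mixture to the coefficient columns of `C`, and forms the
#' kineme matrix `H* = B C*` whose columns are the `k` kinemes (`C*`
#' stacks the component means).
#'
#' @param segmat a [build_segment_matrix()] result.
#' @param r NMF rank (default 24; keep `r >= k`).
#' @param k number of kinemes (default 16).
#' @param seed integer seed for NMF init and mixture init.
#' @param nmf_iter,nmf_tol NMF iteration cap and relative tolerance.
#' @return object of class `kineme_vocabulary`: `B`, `mixture`, `Hstar`
#'   (3l x k), plus the window geometry (`len`, `hop`, `offset`,
#'   `window_s`, `frame_rate`), `r`, `k` and `seed`.
#' @export
learn_vocabulary <- function(segmat, r = 24, k = 16, seed = 1,
                             nmf_iter = 500, nmf_tol = 1e-4) {
  stopifnot(inherits(segmat, "segment_matrix"))
  S <- ncol(segmat$H)
  assert_that(is_count(k, 2), "k must be an integer >= 2")
  if (k > S) stop_kf("k = ", k, " exceeds the number of segments (", S, ")")
  if (r < k) warning("NMF rank r < k; r >= k is recommended",
                     call. = FALSE)
  fac <- nmf_factorize(segmat$H, r, seed = derive_seed(seed, 1),
                       max_iter = nmf_iter, tol = nmf_tol)
  mix <- fit_gmm(t(fac$C), k, seed = derive_seed(seed, 2))
  Cstar <- t(mix$means)                     # r x k
  Hstar <- fac$B %*% Cstar
  colnames(Hstar) <- paste0("K", seq_len(k))
  structure(list(B = fac$B, mixture = mix, Hstar = Hstar,
                 len = segmat$len, hop = segmat$hop,
                 offset = segmat$offset, window_s = segmat$window_s,
                 overlap_fraction = segmat$overlap_fraction,
                 frame_rate = segmat$frame_rate, r = r, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "kineme_vocabulary")
}

#' @export
print.kineme_vocabulary <- function(x, ...) {
  cat("kineme_vocabulary: k =", x$k, "kinemes, NMF rank r =", x$r,
      ", window", x$window_s, "s (", x$len, "frames, hop", x$hop, ")\n")
  invisible(x)
}

#' Project one segment onto the kineme basis
#'
#' Non-negative least-squares projection
#' `c-hat = argmin_{c >= 0} || h - B c ||^2` of a concatenated
#' (pitch, yaw, roll) window onto the learned basis. The segment must be
#' on the same non-negativity offset as at training; pass a raw
#' (un-offset) window with `apply_offset = TRUE`.
#'
#' @param h numeric vector of length `3 * len` (one segment column).
#' @param vocab a `kineme_vocabulary` (or a bare non-negative basis
#'   matrix `B`, in which case no offset is applied).
#' @param apply_offset add the vocabulary's stored training offset
#'   before projecting.
#' @return non-negative coefficient vector of length `r`.
#' @export
project_segment <- function(h, vocab, apply_offset = FALSE) {
  B <- if (inherits(vocab, "kineme_vocabulary")) vocab$B else vocab
  if (length(h) != nrow(B)) {
    stop_kf("segment length ", length(h), " does not match basis rows ",
            nrow(B))
  }
  if (apply_offset && inherits(vocab, "kineme_vocabulary")) {
    h <- h + vocab$offset
  }
  nnls_solve(B, h)
}

#' Map an angle series to a kineme sequence
#'
#' Cuts the series on the vocabulary's window grid, applies the stored
#' non-negativity offset, projects each window by NNLS and assigns it to
#' the kineme maximizing the mixture posterior `P(K_i | c-hat)` (ties
#' broken toward the lowest component index).
#'
#' @param series a `pose_series`.
#' @param vocab a `kineme_vocabulary`.
#' @return object of class `kineme_sequence`: `video_id`, integer
#'   `labels` in 1..k (one per window), `window_start_s`, and the
#'   posterior matrix `posterior` (L x k, rows summing to 1).
#' @export
assign_kinemes <- function(series, vocab) {
  stopifnot(inherits(series, "pose_series"),
            inherits(vocab, "kineme_vocabulary"))
  if (series$frame_rate != vocab$frame_rate) {
    stop_kf("series frame rate ", series$frame_rate,
            " differs from vocabulary frame rate ", vocab$frame_rate)
  }
  Tn <- nrow(series$angles)
  starts <- window_starts(Tn, vocab$len, vocab$hop)
  if (length(starts) == 0L) {
    stop_kf("video ", series$video_id, " shorter than one window (",
            Tn, " < ", vocab$len, " frames)")
  }
  Chat <- matrix(0, length(starts), vocab$r)
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + vocab$len - 1L)
    h <- c(series$angles[idx, 1], series$angles[idx, 2],
           series$angles[idx, 3]) + vocab$offset
    Chat[i, ] <- nnls_solve(vocab$B, h)
  }
  post <- gmm_posterior(vocab$mixture, Chat)
  labels <- apply(post, 1, which.max)   # which.max takes the lowest index
  structure(list(video_id = series$video_id, labels = as.integer(labels),
                 window_start_s = (starts - 1L) / vocab$frame_rate,
                 posterior = post, k = vocab$k),
            class = "kineme_sequence")
}

#' Adjusted Rand index between two label vectors
#'
#' Chance-corrected agreement between two partitions; 1 for identical
#' partitions (up to relabeling), ~0 for independent ones.
#'
#' @param a,b equal-length label vectors.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Write kineme sequences as CSV
#'
#' One row per window: `video_id`, `window_start_s`, `label`.
#'
#' @param seqs a `kineme_sequence` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_kineme_sequences <- function(seqs, path) {
  if (inherits(seqs, "kineme_sequence")) seqs <- list(seqs)
  rows <- do.call(rbind, lapply(seqs, function(s) {
    data.frame(video_id = s$video_id,
               window_start_s = s$window_start_s,
               label = s$labels)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

# ---- vocabulary serialization (plain JSON, text-only deliverable) ------

#' Write a kineme vocabulary to a JSON archive
#' @param vocab a `kineme_vocabulary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "kineme_vocabulary"))
  obj <- list(format_version = 1L,
              B = vocab$B, Hstar = vocab$Hstar,
              mixture = list(weights = vocab$mixture$weights,
                             means = vocab$mixture$means,
                             covs = vocab$mixture$covs),
              len = vocab$len, hop = vocab$hop, offset = vocab$offset,
              window_s = vocab$window_s,
              overlap_fraction = vocab$overlap_fraction,
              frame_rate = vocab$frame_rate,
              r = vocab$r, k = vocab$k, seed = vocab$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a kineme vocabulary from a JSON archive
#' @param path archive path written by [write_vocabulary()].
#' @return a `kineme_vocabulary`.
#' @export
read_vocabulary <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) || obj$format_version != 1L) {
    stop_kf("unsupported vocabulary archive version")
  }
  covs_raw <- obj$mixture$covs
  covs <- if (is.array(covs_raw) && length(dim(covs_raw)) == 3L) {
    # jsonlite simplifies a list of equal-size matrices to a k x r x r
    # array; restore the list-of-matrices layout
    lapply(seq_len(dim(covs_raw)[1]), function(j)
      matrix(covs_raw[j, , ], dim(covs_raw)[2], dim(covs_raw)[3]))
  } else {
    lapply(covs_raw, function(S) unname(as.matrix(S)))
  }
  mix <- list(weights = as.numeric(obj$mixture$weights),
              means = unname(as.matrix(obj$mixture$means)),
              covs = covs)
  Hstar <- unname(as.matrix(obj$Hstar))
  colnames(Hstar) <- paste0("K", seq_len(obj$k))
  structure(list(B = unname(as.matrix(obj$B)), mixture = mix,
                 Hstar = Hstar,
                 len = as.integer(obj$len), hop = as.integer(obj$hop),
                 offset = obj$offset, window_s = obj$window_s,
                 overlap_fraction = obj$overlap_fraction,
                 frame_rate = obj$frame_rate, r = obj$r,
                 k = as.integer(obj$k), seed = as.integer(obj$seed)),
            class = "kineme_vocabulary")
}
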