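# Per-window feature encodings consumed by the recurrent models.
#
# All three modalities are aligned on one shared grid of 2 s windows
# with a 1 s hop: a one-hot kineme block (L x k), a binary dominant-AU
# block (L x 17) and a z-scored speech block (L x 23).

#' One-hot encode a kineme sequence
#'
#' @param seq a `kineme_sequence` (or a bare integer label vector).
#' @param k vocabulary size; defaults to the sequence's own `k`.
#' @return L x k binary matrix, each row summing to 1.
#' @export
one_hot_kinemes <- function(seq, k = NULL) {
  labels <- if (inherits(seq, "kineme_sequence")) seq$labels else
    as.integer(seq)
  if (is.null(k)) {
    k <- if (inherits(seq, "kineme_sequence")) seq$k else max(labels)
  }
  if (any(labels < 1L | labels > k)) {
    stop_kf("kineme labels out of range 1..", k)
  }
  out <- matrix(0L, length(labels), k,
                dimnames = list(NULL, paste0("K", seq_len(k))))
  out[cbind(seq_along(labels), labels)] <- 1L
  out
}

#' Binarize dominant action units per window
#'
#' AU `a` is dominant in a window iff its mean intensity over the
#' window's frames strictly exceeds its mean intensity over the whole
#' video (a per-person adaptive baseline; constant channels are never
#' dominant). Strict inequality makes the all-constant case all-zero.
#'
#' @param aus an `au_series`.
#' @param window_s,hop_s window length and hop in seconds (defaults 2, 1).
#' @return L x 17 binary matrix with `window_start_s` attribute.
#' @export
dominant_aus <- function(aus, window_s = 2, hop_s = 1) {
  stopifnot(inherits(aus, "au_series"))
  len <- as.integer(round(window_s * aus$frame_rate))
  hop <- max(1L, as.integer(round(hop_s * aus$frame_rate)))
  Tn <- nrow(aus$intensities)
  starts <- window_starts(Tn, len, hop)
  if (length(starts) == 0L) {
    stop_kf("AU series shorter than one ", window_s, " s window")
  }
  video_mean <- colMeans(aus$intensities)
  out <- matrix(0L, length(starts), ncol(aus$intensities),
                dimnames = list(NULL, aus$channels))
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + len - 1L)
    wm <- colMeans(aus$intensities[idx, , drop = FALSE])
    out[i, ] <- as.integer(wm > video_mean)
  }
  attr(out, "window_start_s") <- (starts - 1L) / aus$frame_rate
  out
}

# Next power of two (FFT length for the MFCC spectrum).
next_pow2 <- function(n) 2L^ceiling(log2(n))

# Triangular mel filterbank (n_filters x n_fft/2+1) between 0 and sr/2.
mel_filterbank <- function(n_filters, n_fft, sample_rate) {
  hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
  mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)
  mel_pts <- seq(hz_to_mel(0), hz_to_mel(sample_rate / 2),
                 length.out = n_filters + 2L)
  bins <- floor((n_fft + 1) * mel_to_hz(mel_pts) / sample_rate)
  fb <- matrix(0, n_filters, n_fft %/% 2L + 1L)
  for (j in seq_len(n_filters)) {
    lo <- bins[j]; ce <- bins[j + 1]; hi <- bins[j + 2]
    if (ce > lo) {
      ks <- (lo + 1):ce
      fb[j, ks + 1L] <- (ks - lo) / (ce - lo)
    }
    if (hi > ce) {
      ks <- (ce + 1):hi
      fb[j, ks + 1L] <- (hi - ks) / (hi - ce)
    }
  }
  fb
}

# Orthonormal DCT-II matrix (n_out x n_in).
dct_matrix <- function(n_out, n_in) {
  M <- outer(0:(n_out - 1L), 0:(n_in - 1L), function(k, n) {
    cos(pi * k * (2 * n + 1) / (2 * n_in))
  })
  M <- M * sqrt(2 / n_in)
  M[1, ] <- M[1, ] / sqrt(2)
  M
}

#' Extract frame-level speech low-level descriptors
#'
#' Per analysis window of `window_s` (default 93 ms, hop 70 ms):
#' fundamental frequency F0 by normalized autocorrelation over a
#' 60--500 Hz search band (0 where unvoiced), a voicing probability (the
#' peak normalized autocorrelation, clipped to [0, 1]), the
#' zero-crossing rate (sign changes per sample pair, so a square wave
#' alternating every sample scores 1), and 20 MFCCs (Hamming window,
#' power spectrum, 26-filter mel bank, log, orthonormal DCT-II,
#' coefficients 1..20 including the energy coefficient).
#'
#' @param waveform numeric vector of mono samples in [-1, 1], or a list
#'   with `samples` and `sample_rate` as returned by [read_wav()].
#' @param sample_rate samples per second (>= 8000); ignored when
#'   `waveform` carries its own.
#' @param window_s,hop_s analysis window and hop in seconds.
#' @param voicing_threshold minimum voicing probability to report a
#'   nonzero F0.
#' @return data.frame with columns `f0`, `voicing`, `zcr`,
#'   `mfcc01`..`mfcc20`, one row per analysis frame, and a `time_s`
#'   attribute of frame-start times.
#' @export
extract_llds <- function(waveform, sample_rate = NULL, window_s = 0.093,
                         hop_s = 0.070, voicing_threshold = 0.3) {
  if (is.list(waveform)) {
    sample_rate <- waveform$sample_rate
    waveform <- waveform$samples
  }
  assert_that(length(waveform) > 0, "empty waveform")
  assert_that(is_number(sample_rate) && sample_rate >= 8000,
              "sample_rate must be >= 8000")
  len <- as.integer(round(window_s * sample_rate))
  hop <- max(1L, as.integer(round(hop_s * sample_rate)))
  starts <- window_starts(length(waveform), len, hop)
  if (length(starts) == 0L) {
    stop_kf("waveform shorter than one ", window_s, " s analysis window")
  }
  n_fft <- next_pow2(len)
  fb <- mel_filterbank(26L, n_fft, sample_rate)
  dct <- dct_matrix(20L, 26L)
  hamming <- 0.54 - 0.46 * cos(2 * pi * (seq_len(len) - 1) / (len - 1))
  lag_min <- max(2L, floor(sample_rate / 500))
  lag_max <- min(len - 1L, ceiling(sample_rate / 60))
  out <- matrix(0, length(starts), 23L,
                dimnames = list(NULL, lld_column_names()))
  for (i in seq_along(starts)) {
    x <- waveform[starts[i]:(starts[i] + len - 1L)]
    # zero-crossing rate over adjacent sample pairs
    s <- x >= 0
    zcr <- if (len > 1L) mean(s[-1] != s[-len]) else 0
    # autocorrelation pitch
    x0 <- x - mean(x)
    energy <- sum(x0^2)
    f0 <- 0; voicing <- 0
    if (energy > 1e-10 && lag_max > lag_min) {
      ac <- stats::fft(Mod(stats::fft(c(x0, numeric(len))))^2,
                       inverse = TRUE)
      ac <- Re(ac[seq_len(len)]) / length(ac)
      r <- ac[(lag_min:lag_max) + 1L] / ac[1]
      best <- which.max(r)
      voicing <- min(max(r[best], 0), 1)
      if (voicing > voicing_threshold) {
        f0 <- sample_rate / (lag_min + best - 1L)
      }
    }
    # MFCCs
    spec <- Mod(stats::fft(c(x * hamming, numeric(n_fft - len))))^2
    spec <- spec[seq_len(n_fft %/% 2L + 1L)]
    mel_energy <- log(drop(fb %*% spec) + 1e-10)
    out[i, ] <- c(f0, voicing, zcr, drop(dct %*% mel_energy))
  }
  res <- as.data.frame(out)
  attr(res, "time_s") <- (starts - 1L) / sample_rate
  res
}

#' Average speech descriptors over the shared window grid
#'
#' Per 2 s window (1 s hop), the mean of each LLD column over the
#' analysis frames whose centers fall inside the window, concatenated in
#' the fixed order (F0, voicing, ZCR, MFCC 1..20) to give a
#' 23-dimensional vector.
#'
#' @param lld data.frame from [extract_llds()] or [read_lld_table()].
#' @param duration_s video duration in seconds, which fixes the window
#'   count `L = floor((duration_s - window_s) / hop_s) + 1` shared with
#'   the other modalities.
#' @param window_s,hop_s grid window and hop in seconds (defaults 2, 1).
#' @param lld_window_s,lld_hop_s geometry of the descriptor frames
#'   (defaults 93 ms, 70 ms), used to place frame centers in time.
#' @return L x 23 matrix with a `window_start_s` attribute.
#' @export
speech_segment_features <- function(lld, duration_s, window_s = 2,
                                    hop_s = 1, lld_window_s = 0.093,
                                    lld_hop_s = 0.070) {
  lld <- as.data.frame(lld)[, lld_column_names()]
  L <- floor((duration_s - window_s) / hop_s) + 1
  if (L < 1) stop_kf("duration shorter than one ", window_s, " s window")
  centers <- (seq_len(nrow(lld)) - 1) * lld_hop_s + lld_window_s / 2
  out <- matrix(0, L, ncol(lld),
                dimnames = list(NULL, lld_column_names()))
  starts <- (seq_len(L) - 1) * hop_s
  for (t in seq_len(L)) {
    inside <- centers >= starts[t] & centers < starts[t] + window_s
    if (!any(inside)) {
      stop_kf("window starting at ", starts[t],
              " s contains no descriptor frames")
    }
    out[t, ] <- colMeans(lld[inside, , drop = FALSE])
  }
  attr(out, "window_start_s") <- starts
  out
}

#' Fit per-dimension z-scoring statistics
#'
#' Population mean and standard deviation per column, intended to be fit
#' on training windows only and then applied to all splits. Columns with
#' zero variance keep `sd = 1` with a warning so they pass through
#' centered but unscaled.
#'
#' @param X numeric matrix (training windows x dimensions).
#' @return list with `mean` and `sd` vectors.
#' @export
zscore_fit <- function(X) {
  X <- as.matrix(X)
  assert_that(nrow(X) >= 2, "need at least 2 rows to fit z-scoring")
  mu <- colMeans(X)
  sd <- sqrt(colMeans(sweep(X, 2, mu)^2))
  if (any(sd == 0)) {
    warning(sum(sd == 0), " zero-variance dimension(s); sd set to 1",
            call. = FALSE)
    sd[sd == 0] <- 1
  }
  list(mean = mu, sd = sd)
}

#' Apply fitted z-scoring statistics
#' @param X numeric matrix.
#' @param stats list from [zscore_fit()].
#' @return matrix of the same shape.
#' @export
zscore_apply <- function(X, stats) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, stats$mean), 2, stats$sd, "/")
}

#' Encode one video on the shared window grid
#'
#' Produces the three aligned per-window blocks: one-hot kinemes (from
#' [assign_kinemes()]), binary dominant AUs and raw speech window means
#' (z-scoring is applied corpus-wide by [encode_corpus()], never per
#' video). The vocabulary's window grid must equal the encoding grid.
#'
#' @param pose a `pose_series`.
#' @param aus an `au_series`.
#' @param lld an LLD data.frame for the same video.
#' @param vocab a `kineme_vocabulary`.
#' @param window_s,hop_s shared grid (defaults 2, 1).
#' @return object of class `segment_encoding` with blocks `kineme`
#'   (L x k), `au` (L x 17), `speech` (L x 23) and `window_start_s`.
#' @export
encode_video <- function(pose, aus, lld, vocab, window_s = 2, hop_s = 1) {
  if (abs(vocab$window_s - window_s) > 1e-9 ||
      abs(vocab$hop / vocab$frame_rate - hop_s) > 1e-9) {
    stop_kf("vocabulary window grid (", vocab$window_s, " s, hop ",
            vocab$hop / vocab$frame_rate, " s) differs from the encoding ",
            "grid (", window_s, " s, hop ", hop_s, " s)")
  }
  seq <- assign_kinemes(pose, vocab)
  kin <- one_hot_kinemes(seq)
  au_block <- dominant_aus(aus, window_s, hop_s)
  duration_s <- nrow(pose$angles) / pose$frame_rate
  sp <- speech_segment_features(lld, duration_s, window_s, hop_s)
  L <- min(nrow(kin), nrow(au_block), nrow(sp))
  structure(list(video_id = pose$video_id,
                 window_start_s = seq$window_start_s[seq_len(L)],
                 kineme = kin[seq_len(L), , drop = FALSE],
                 au = au_block[seq_len(L), , drop = FALSE],
                 speech = sp[seq_len(L), , drop = FALSE]),
            class = "segment_encoding")
}
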