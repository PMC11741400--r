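# Synthetic multimodal behavioral corpus generator.
#
# Emulates the statistical structure the pipeline assumes: head motion
# built from a small set of recurring sinusoidal prototypes on a fixed
# generation grid, 17-channel AU intensity streams on the 0--5 scale with
# per-video burst rates, frame-level speech descriptor streams with
# per-video channel means, and trait scores produced by a known
# logistic-linear model on behavioral summary statistics.

#' Configuration for the synthetic corpus generator
#'
#' @param n_videos number of videos (>= 2).
#' @param duration_s seconds per video (>= 4; must hold at least one
#'   generation window of `window_s` seconds).
#' @param frame_rate video frames per second (default 30, the working
#'   default for the supported corpora).
#' @param n_prototypes number of generating head-motion prototypes.
#' @param au_channels number of AU intensity channels (default 17).
#' @param trait_weights named list: one numeric coefficient vector per
#'   trait over the behavioral summary features, ordered as
#'   (prototype usage frequencies, AU channel means, LLD channel means).
#'   Each vector must have length `n_prototypes + au_channels + 23`.
#'   `NULL` selects defaults with three traits: `warmth` (signal in all
#'   three modalities), `dominance` (head-motion only) and `fluency`
#'   (speech only).
#' @param noise_sd named list of standard deviations: `angle` (radians,
#'   per-frame), `au` (intensity units, per-frame), `lld` (per-frame, in
#'   channel-specific spread units), `label` (additive trait-score
#'   noise). All must be >= 0.
#' @param window_s generation window length in seconds; each consecutive
#'   `window_s` block of frames realizes exactly one prototype.
#' @param audio `"lld"` emits frame-level descriptor tables directly
#'   (default; keeps the trait link exact); `"wav"` additionally
#'   synthesizes mono 16 kHz waveforms (tones plus noise bursts) so the
#'   LLD extractor can be exercised end to end.
#' @param seed integer master seed; generation is a pure function of
#'   (config, seed).
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_videos = 60, duration_s = 16, frame_rate = 30,
                         n_prototypes = 6, au_channels = 17,
                         trait_weights = NULL,
                         noise_sd = list(angle = 0.02, au = 0.3,
                                         lld = 1, label = 0.05),
                         window_s = 2, audio = c("lld", "wav"), seed = 1) {
  audio <- match.arg(audio)
  assert_that(is_count(n_videos, 2), "n_videos must be an integer >= 2")
  assert_that(is_number(duration_s) && duration_s >= 4,
              "duration_s must be >= 4")
  assert_that(is_number(frame_rate) && frame_rate > 0,
              "frame_rate must be > 0")
  assert_that(is_count(n_prototypes, 2), "n_prototypes must be >= 2")
  assert_that(is_count(au_channels, 1), "au_channels must be >= 1")
  for (nm in c("angle", "au", "lld", "label")) {
    assert_that(is_number(noise_sd[[nm]]) && noise_sd[[nm]] >= 0,
                paste0("noise_sd$", nm, " must be a number >= 0"))
  }
  n_lld <- 23L
  if (is.null(trait_weights)) {
    trait_weights <- default_trait_weights(n_prototypes, au_channels)
  }
  p <- n_prototypes + au_channels + n_lld
  for (tr in names(trait_weights)) {
    assert_that(is.numeric(trait_weights[[tr]]) &&
                  length(trait_weights[[tr]]) == p,
                paste0("trait_weights$", tr, " must have length ", p))
  }
  structure(list(n_videos = as.integer(n_videos), duration_s = duration_s,
                 frame_rate = frame_rate,
                 n_prototypes = as.integer(n_prototypes),
                 au_channels = as.integer(au_channels), n_lld = n_lld,
                 trait_weights = trait_weights, noise_sd = noise_sd,
                 window_s = window_s, audio = audio,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Default trait coefficient vectors
#'
#' Three traits over the summary features (prototype usage frequencies,
#' AU channel means, LLD channel means): `warmth` loads on all three
#' modalities, `dominance` on head motion only, `fluency` on speech only.
#' Magnitudes are matched to the natural spread of each feature family so
#' each loaded modality contributes comparably to the trait logit.
#'
#' @param n_prototypes,au_channels as in [synth_config()].
#' @return named list of coefficient vectors.
#' @export
default_trait_weights <- function(n_prototypes = 6, au_channels = 17) {
  n_lld <- 23L
  p <- n_prototypes + au_channels + n_lld
  nm <- summary_feature_names(n_prototypes, au_channels)
  zero <- stats::setNames(numeric(p), nm)
  warmth <- zero
  warmth["proto_freq_1"] <- 4
  warmth[n_prototypes + 9L] <- 1.5          # AU12_r mean (smiling)
  warmth["lld_mean_mfcc01"] <- 0.35
  warmth["lld_mean_voicing"] <- 1.5
  dominance <- zero
  dominance["proto_freq_1"] <- 5
  dominance["proto_freq_2"] <- -3
  fluency <- zero
  fluency["lld_mean_mfcc01"] <- 0.45
  fluency["lld_mean_mfcc02"] <- -0.35
  fluency["lld_mean_voicing"] <- 2
  list(warmth = warmth, dominance = dominance, fluency = fluency)
}

summary_feature_names <- function(n_prototypes, au_channels) {
  au_names <- if (au_channels == 17L) au_intensity_channels() else
    sprintf("AU%02d_r", seq_len(au_channels))
  c(paste0("proto_freq_", seq_len(n_prototypes)),
    paste0("au_mean_", au_names),
    paste0("lld_mean_", lld_column_names()))
}

# Per-channel base level and across-video spread of the synthetic LLD
# streams (f0 in Hz, voicing a probability, zcr a rate, MFCCs unitless).
lld_generation_params <- function() {
  nm <- lld_column_names()
  base <- stats::setNames(c(130, 0.6, 0.08, rep(0, 20)), nm)
  spread <- stats::setNames(c(20, 0.12, 0.03, rep(1.2, 20)), nm)
  list(base = base, spread = spread)
}

#' Generate a synthetic multimodal corpus
#'
#' Each video's angle series is a concatenation of `window_s`-second
#' prototype motions (a distinct sinusoid frequency and phase per
#' prototype and axis) plus Gaussian noise, so windows cut on the
#' generation grid contain exactly one prototype each. AU intensities
#' follow per-video, per-channel burst rates on the same grid; LLD
#' streams have per-video channel means. Trait scores are the logistic of
#' `trait_weights %*% (summary features, centered at the corpus mean)`
#' plus label noise, clipped to [0, 1].
#'
#' @param config a [synth_config()].
#' @return object of class `synth_corpus`: lists `pose`, `au`, `lld`
#'   (and `audio` when requested), per-video generation-grid prototype
#'   labels `proto_labels`, the summary feature matrix `summary`, the
#'   noiseless trait logits `logit`, trait scores `traits`, the
#'   prototype definitions `prototypes` and a train/val/test `split`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cf <- config
  len <- as.integer(round(cf$window_s * cf$frame_rate))
  n_blocks <- floor(cf$duration_s / cf$window_s)
  if (n_blocks < 1L) {
    stop_kf("duration_s = ", cf$duration_s, " too short: at least ",
            cf$window_s, " s (one generation window) is required")
  }
  with_seed(cf$seed, {
    P <- cf$n_prototypes
    ids <- sprintf("vid%03d", seq_len(cf$n_videos))
    # prototype bank: amplitude/phase per prototype and axis, frequency
    # (whole cycles per window) distinct per prototype
    protos <- lapply(seq_len(P), function(p) {
      amp <- stats::runif(3, 0.1, 0.3)
      phase <- stats::runif(3, 0, 2 * pi)
      t <- (seq_len(len) - 1) / len
      sapply(1:3, function(a) amp[a] * sin(2 * pi * p * t + phase[a]))
    })
    au_base <- stats::runif(cf$au_channels, 0.3, 1.2)
    au_amp <- stats::runif(cf$au_channels, 1.2, 2.5)
    llp <- lld_generation_params()
    n_lld_frames <- max(2L, n_windows(round(cf$duration_s * 1000),
                                      93, 70))

    pose <- vector("list", cf$n_videos)
    au <- vector("list", cf$n_videos)
    lld <- vector("list", cf$n_videos)
    audio <- if (cf$audio == "wav") vector("list", cf$n_videos) else NULL
    proto_labels <- vector("list", cf$n_videos)
    summary_mat <- matrix(0, cf$n_videos,
                          P + cf$au_channels + cf$n_lld,
                          dimnames = list(ids,
                            summary_feature_names(P, cf$au_channels)))
    for (v in seq_len(cf$n_videos)) {
      # head motion: per-video prototype usage ~ Dirichlet(2)
      g <- stats::rgamma(P, shape = 2)
      pi_v <- g / sum(g)
      z <- sample.int(P, n_blocks, replace = TRUE, prob = pi_v)
      ang <- do.call(rbind, protos[z])
      ang <- ang + matrix(stats::rnorm(length(ang), 0, cf$noise_sd$angle),
                          nrow(ang))
      colnames(ang) <- c("pitch", "yaw", "roll")
      pose[[v]] <- structure(list(video_id = ids[v],
                                  frame_rate = cf$frame_rate,
                                  angles = ang), class = "pose_series")
      proto_labels[[v]] <- z
      summary_mat[v, seq_len(P)] <- tabulate(z, P) / n_blocks

      # AUs: per-channel burst rate, bursts on the generation grid
      rate <- stats::rbeta(cf$au_channels, 2, 2)
      active <- matrix(stats::runif(n_blocks * cf$au_channels) <
                         rep(rate, each = n_blocks), n_blocks)
      ints <- matrix(rep(au_base, each = nrow(ang)), nrow(ang))
      ints <- ints + matrix(rep(au_amp, each = nrow(ang)), nrow(ang)) *
        active[rep(seq_len(n_blocks), each = len), , drop = FALSE]
      ints <- ints + matrix(stats::rnorm(length(ints), 0, cf$noise_sd$au),
                            nrow(ints))
      ints <- pmin(pmax(ints, 0), 5)
      chans <- if (cf$au_channels == 17L) au_intensity_channels() else
        sprintf("AU%02d_r", seq_len(cf$au_channels))
      colnames(ints) <- chans
      au[[v]] <- structure(list(video_id = ids[v],
                                frame_rate = cf$frame_rate,
                                intensities = ints, channels = chans),
                           class = "au_series")
      summary_mat[v, P + seq_len(cf$au_channels)] <- colMeans(ints)

      # speech LLDs: per-video channel means plus frame noise
      mu <- llp$base + llp$spread * stats::rnorm(cf$n_lld)
      fr <- matrix(rep(mu, each = n_lld_frames), n_lld_frames) +
        matrix(stats::rnorm(n_lld_frames * cf$n_lld, 0, cf$noise_sd$lld),
               n_lld_frames) *
        matrix(rep(llp$spread / 2, each = n_lld_frames), n_lld_frames)
      colnames(fr) <- lld_column_names()
      fr[, "f0"] <- pmax(fr[, "f0"], 0)
      fr[, "voicing"] <- pmin(pmax(fr[, "voicing"], 0), 1)
      fr[, "zcr"] <- pmax(fr[, "zcr"], 0)
      lld[[v]] <- as.data.frame(fr)
      summary_mat[v, P + cf$au_channels + seq_len(cf$n_lld)] <- colMeans(fr)

      if (cf$audio == "wav") {
        sr <- 16000
        tt <- seq_len(round(cf$duration_s * sr)) / sr
        f0v <- max(mu[1], 80)
        wave <- 0.4 * sin(2 * pi * f0v * tt) +
          0.05 * stats::rnorm(length(tt))
        audio[[v]] <- list(samples = pmin(pmax(wave, -1), 1),
                           sample_rate = sr)
      }
    }
    centered <- sweep(summary_mat, 2, colMeans(summary_mat))
    logits <- sapply(cf$trait_weights,
                     function(w) drop(centered %*% w))
    if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1)
    scores <- stats::plogis(logits) +
      matrix(stats::rnorm(length(logits), 0, cf$noise_sd$label),
             nrow(logits))
    scores <- pmin(pmax(scores, 0), 1)
    traits <- data.frame(video_id = ids, scores, check.names = FALSE)
    # 3:1:1 train/val/test, shuffled once per corpus
    split <- rep("train", cf$n_videos)
    ord <- sample.int(cf$n_videos)
    n_val <- max(1L, floor(cf$n_videos / 5))
    n_test <- max(1L, floor(cf$n_videos / 5))
    split[ord[seq_len(n_val)]] <- "val"
    split[ord[n_val + seq_len(n_test)]] <- "test"
    structure(list(config = cf, video_ids = ids, pose = pose, au = au,
                   lld = lld, audio = audio, proto_labels = proto_labels,
                   prototypes = protos, summary = summary_mat,
                   logit = logits, traits = traits, split = split),
              class = "synth_corpus")
  })
}

#' @export
print.synth_corpus <- function(x, ...) {
  cat("synth_corpus:", length(x$video_ids), "videos,",
      x$config$n_prototypes, "prototypes,",
      nrow(x$pose[[1]]$angles), "frames/video,",
      "traits:", paste(names(x$config$trait_weights), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a synthetic corpus to disk
#'
#' Emits OpenFace-dialect pose and AU tables, LLD tables (or WAV files
#' when the corpus carries audio), and a manifest CSV consumable by
#' [read_manifest()] unchanged.
#'
#' @param corpus a `synth_corpus`.
#' @param directory output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
write_corpus <- function(corpus, directory) {
  stopifnot(inherits(corpus, "synth_corpus"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop_kf("cannot create directory: ", directory)
  for (d in c("pose", "au", if (is.null(corpus$audio)) "lld" else "audio")) {
    dir.create(file.path(directory, d), showWarnings = FALSE)
  }
  ids <- corpus$video_ids
  rel <- function(...) file.path(...)
  pose_paths <- rel("pose", paste0(ids, ".csv"))
  au_paths <- rel("au", paste0(ids, ".csv"))
  for (v in seq_along(ids)) {
    write_pose_table(corpus$pose[[v]], file.path(directory, pose_paths[v]))
    write_au_table(corpus$au[[v]], file.path(directory, au_paths[v]))
  }
  man <- data.frame(video_id = ids, split = corpus$split,
                    frame_rate = corpus$config$frame_rate,
                    pose_path = pose_paths, au_path = au_paths)
  if (is.null(corpus$audio)) {
    lld_paths <- rel("lld", paste0(ids, ".csv"))
    for (v in seq_along(ids)) {
      write_lld_table(corpus$lld[[v]], file.path(directory, lld_paths[v]))
    }
    man$lld_path <- lld_paths
  } else {
    audio_paths <- rel("audio", paste0(ids, ".wav"))
    for (v in seq_along(ids)) {
      write_wav(corpus$audio[[v]]$samples, corpus$audio[[v]]$sample_rate,
                file.path(directory, audio_paths[v]))
    }
    man$audio_path <- audio_paths
  }
  man <- cbind(man, corpus$traits[, -1, drop = FALSE])
  manifest_path <- file.path(directory, "manifest.csv")
  utils::write.csv(man, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}
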