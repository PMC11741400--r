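# Shared fixtures, built once per test session. Everything is generated
# in code; nothing is read from disk.

# Small default corpus + vocabulary + encodings used across modules.
fixture_env <- new.env()

small_corpus <- function() {
  if (is.null(fixture_env$corpus)) {
    cfg <- synth_config(n_videos = 14, duration_s = 12, n_prototypes = 4,
                        seed = 42)
    fixture_env$corpus <- generate_corpus(cfg)
  }
  fixture_env$corpus
}

small_vocab <- function() {
  if (is.null(fixture_env$vocab)) {
    fixture_env$vocab <- suppressWarnings(
      corpus_vocabulary(small_corpus(), r = 8, k = 4, seed = 7))
  }
  fixture_env$vocab
}

small_encodings <- function() {
  if (is.null(fixture_env$enc)) {
    fixture_env$enc <- suppressWarnings(
      encode_corpus(small_corpus(), small_vocab()))
  }
  fixture_env$enc
}

# A tiny pose series with known values.
toy_pose <- function(angles, frame_rate = 30, id = "toy") {
  structure(list(video_id = id, frame_rate = frame_rate,
                 angles = matrix(angles, ncol = 3,
                                 dimnames = list(NULL,
                                   c("pitch", "yaw", "roll")))),
            class = "pose_series")
}

toy_au <- function(intensities, frame_rate = 30, id = "toy") {
  colnames(intensities) <- au_intensity_channels()[seq_len(ncol(intensities))]
  structure(list(video_id = id, frame_rate = frame_rate,
                 intensities = intensities,
                 channels = colnames(intensities)),
            class = "au_series")
}
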