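# Corpus-level glue: learn a vocabulary, encode every video on the
# shared grid, fit speech z-scoring on the training split, and expose
# model-ready blocks.

#' Learn a kineme vocabulary from a corpus's training videos
#'
#' @param corpus a `synth_corpus` (or any list with `pose` and `split`).
#' @param r,k NMF rank and kineme count (see [learn_vocabulary()]).
#' @param window_s,overlap_fraction window geometry (defaults 2 s, 50%).
#' @param seed integer seed.
#' @return a `kineme_vocabulary`.
#' @export
corpus_vocabulary <- function(corpus, r = 24, k = 16, window_s = 2,
                              overlap_fraction = 0.5, seed = 1) {
  train <- corpus$pose[corpus$split == "train"]
  if (length(train) == 0L) train <- corpus$pose
  segmat <- build_segment_matrix(train, window_s, overlap_fraction)
  learn_vocabulary(segmat, r = r, k = k, seed = seed)
}

#' Encode every video of a corpus on the shared window grid
#'
#' Runs [encode_video()] per video, then fits speech z-scoring on the
#' pooled *training* windows only and applies it to all splits.
#'
#' @param corpus a `synth_corpus`.
#' @param vocab a `kineme_vocabulary` whose grid matches
#'   `window_s`/`hop_s`.
#' @param window_s,hop_s shared grid (defaults 2, 1).
#' @return list with `encodings` (named by video id), `zstats` (the
#'   fitted speech normalization) and `video_ids`.
#' @export
encode_corpus <- function(corpus, vocab, window_s = 2, hop_s = 1) {
  encs <- vector("list", length(corpus$video_ids))
  names(encs) <- corpus$video_ids
  for (v in seq_along(corpus$video_ids)) {
    encs[[v]] <- encode_video(corpus$pose[[v]], corpus$au[[v]],
                              corpus$lld[[v]], vocab, window_s, hop_s)
  }
  train <- corpus$split == "train"
  if (!any(train)) train <- rep(TRUE, length(encs))
  pooled <- do.call(rbind, lapply(encs[train], `[[`, "speech"))
  zstats <- zscore_fit(pooled)
  for (v in seq_along(encs)) {
    encs[[v]]$speech <- zscore_apply(encs[[v]]$speech, zstats)
  }
  list(encodings = encs, zstats = zstats, video_ids = corpus$video_ids)
}

#' Extract one modality's block list from encodings
#'
#' @param encodings list of `segment_encoding` objects (or the result
#'   of [encode_corpus()]).
#' @param modality `"kineme"`, `"au"` or `"speech"`.
#' @param ids optional subset of video ids, in the order wanted.
#' @return list of per-video L x D matrices suitable for the trainers.
#' @export
modality_blocks <- function(encodings,
                            modality = c("kineme", "au", "speech"),
                            ids = NULL) {
  modality <- match.arg(modality)
  if (!is.null(encodings$encodings)) encodings <- encodings$encodings
  if (!is.null(ids)) encodings <- encodings[ids]
  lapply(encodings, `[[`, modality)
}

#' Extract all three modality block lists
#'
#' @inheritParams modality_blocks
#' @return named list `kineme`/`au`/`speech` of block lists.
#' @export
trimodal_blocks <- function(encodings, ids = NULL) {
  list(kineme = modality_blocks(encodings, "kineme", ids),
       au = modality_blocks(encodings, "au", ids),
       speech = modality_blocks(encodings, "speech", ids))
}
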