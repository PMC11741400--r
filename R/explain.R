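# Explanation surfaces: percentile-dominant behavioral patterns (which
# kinemes and AUs characterize the highest- and lowest-rated videos) and
# per-modality attention contributions averaged over runs.

#' Top and bottom percentile groups of videos by trait score
#'
#' Returns the `ceil(pct% * n)` highest- and lowest-scoring videos.
#' Boundary ties are resolved by a stable score-then-id ordering, so the
#' groups are deterministic.
#'
#' @param scores numeric trait scores.
#' @param ids video identifiers aligned with `scores`.
#' @param pct percentile in (0, 50].
#' @return list with `high` and `low` id vectors and `group_size`.
#' @export
percentile_groups <- function(scores, ids, pct = 10) {
  assert_that(is_number(pct) && pct > 0 && pct <= 50,
              "pct must be in (0, 50]")
  assert_that(length(scores) == length(ids), "scores/ids length mismatch")
  n <- length(scores)
  g <- ceiling(pct / 100 * n)
  ord_high <- order(-scores, ids)
  ord_low <- order(scores, ids)
  list(high = ids[ord_high[seq_len(g)]],
       low = ids[ord_low[seq_len(g)]],
       group_size = g)
}

#' Dominant behavioral patterns of a video group
#'
#' Pools all windows of the group's encodings and ranks kinemes by the
#' proportion of windows carrying each label, and AUs by the proportion
#' of windows in which each is dominant. Frequencies are per-group
#' window proportions so groups of unequal size stay comparable. Ties
#' rank the lower index first.
#'
#' @param encodings list of `segment_encoding` objects for the group.
#' @param trait trait name carried into the result.
#' @param group `"high"` or `"low"`, carried into the result.
#' @param n_kinemes,n_aus how many top entries to report (defaults 4
#'   and 5).
#' @return object of class `trait_explanation`: ranked `kinemes` and
#'   `aus` data frames (label, frequency) and the `group_size`.
#' @export
dominant_patterns <- function(encodings, trait = NA_character_,
                              group = NA_character_, n_kinemes = 4,
                              n_aus = 5) {
  assert_that(length(encodings) > 0, "empty group")
  kin <- do.call(rbind, lapply(encodings, `[[`, "kineme"))
  au <- do.call(rbind, lapply(encodings, `[[`, "au"))
  kin_freq <- colMeans(kin)
  au_freq <- colMeans(au)
  rank_top <- function(freq, top) {
    ord <- order(-freq, seq_along(freq))[seq_len(min(top, length(freq)))]
    data.frame(label = names(freq)[ord] %||% as.character(ord),
               index = ord, frequency = freq[ord], row.names = NULL)
  }
  structure(list(trait = trait, group = group,
                 kinemes = rank_top(kin_freq, n_kinemes),
                 aus = rank_top(au_freq, n_aus),
                 group_size = length(encodings),
                 n_windows = nrow(kin)),
            class = "trait_explanation")
}

#' @export
print.trait_explanation <- function(x, ...) {
  cat("trait_explanation:", x$trait, "(", x$group, "group,",
      x$group_size, "videos,", x$n_windows, "windows )\n")
  cat("  top kinemes:", paste0(x$kinemes$label, " (",
                               signif(x$kinemes$frequency, 3), ")",
                               collapse = ", "), "\n")
  cat("  top AUs:    ", paste0(x$aus$label, " (",
                               signif(x$aus$frequency, 3), ")",
                               collapse = ", "), "\n")
  invisible(x)
}

#' Summarize modality attention contributions
#'
#' Aggregates per-window attention weights bottom-up: windows within a
#' video (or chunk), then videos, then runs; the standard error is taken
#' over runs. Convexity is preserved at every level, so the reported
#' means are non-negative and sum to 1.
#'
#' @param traces list over runs; each element an N x L x 3 array from
#'   [attention_trace()] (or a list of per-video L x 3 matrices).
#' @param trait trait name carried into the result.
#' @return object of class `modality_contribution`: `mean` and `se`
#'   (length-3, named by modality), `n_runs`.
#' @export
summarize_attention <- function(traces, trait = NA_character_) {
  assert_that(length(traces) >= 2, "need >= 2 runs for a standard error")
  per_run <- lapply(traces, function(tr) {
    if (is.list(tr)) {
      mats <- lapply(tr, function(m) colMeans(as.matrix(m)))
      video_means <- do.call(rbind, mats)
    } else {
      stopifnot(length(dim(tr)) == 3L)
      video_means <- t(apply(tr, 1, colMeans))
      if (dim(tr)[3] == 1L) video_means <- t(video_means)
    }
    colMeans(video_means)
  })
  dims <- vapply(per_run, length, integer(1))
  if (length(unique(dims)) != 1L) {
    stop_kf("inconsistent trace shapes across runs")
  }
  M <- do.call(rbind, per_run)
  nm <- colnames(M) %||% c("kineme", "au", "speech")[seq_len(ncol(M))]
  means <- colMeans(M)
  se <- apply(M, 2, stats::sd) / sqrt(nrow(M))
  structure(list(trait = trait,
                 mean = stats::setNames(means, nm),
                 se = stats::setNames(se, nm),
                 n_runs = length(traces)),
            class = "modality_contribution")
}

#' @export
print.modality_contribution <- function(x, ...) {
  cat("modality_contribution:", x$trait, "over", x$n_runs, "runs\n")
  for (m in names(x$mean)) {
    cat(sprintf("  %-8s %.3f +/- %.3f (SE)\n", m, x$mean[m], x$se[m]))
  }
  invisible(x)
}

#' Write an explanation report as JSON
#'
#' @param explanations list of `trait_explanation` objects.
#' @param contributions optional list of `modality_contribution`
#'   objects.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_explanations <- function(explanations, path, contributions = NULL) {
  to_list <- function(e) {
    list(trait = e$trait, group = e$group, group_size = e$group_size,
         kinemes = e$kinemes, aus = e$aus)
  }
  obj <- list(patterns = lapply(explanations, to_list))
  if (!is.null(contributions)) {
    obj$contributions <- lapply(contributions, function(cc) {
      list(trait = cc$trait, mean = as.list(cc$mean),
           se = as.list(cc$se), n_runs = cc$n_runs)
    })
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
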