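# Prediction settings and metrics: median dichotomization, thin-slice
# chunking, chunk-to-video aggregation, Acc/F1/PCC, and the fixed-split
# and repeated-k-fold evaluation protocols.

#' Dichotomize continuous trait scores at the training median
#'
#' Label 1 iff the score strictly exceeds the median of the *training*
#' scores (computed on the training split only to avoid leakage); scores
#' exactly at the median go to the negative class, which reproduces the
#' mildly imbalanced class shares real corpora show.
#'
#' @param scores numeric scores to label.
#' @param train_scores scores used to compute the median; defaults to
#'   `scores`.
#' @return integer 0/1 labels.
#' @export
dichotomize_median <- function(scores, train_scores = scores) {
  assert_that(length(train_scores) >= 2, "need at least 2 scores")
  if (diff(range(train_scores)) == 0) {
    stop_kf("all training scores are equal; median split is degenerate")
  }
  as.integer(scores > stats::median(train_scores))
}

#' Cut a video encoding into thin slices
#'
#' Contiguous, non-overlapping chunks of `slice_s` seconds on the window
#' grid; windows straddling a chunk boundary and any trailing remainder
#' shorter than `slice_s` are dropped. Every chunk inherits the source
#' video's label downstream.
#'
#' @param encoding a `segment_encoding`.
#' @param slice_s slice length in seconds (>= the window span).
#' @param window_s window length of the grid (default 2 s).
#' @return list of `segment_encoding` chunks, each with a `chunk`
#'   field.
#' @export
make_slices <- function(encoding, slice_s, window_s = 2) {
  stopifnot(inherits(encoding, "segment_encoding"))
  if (slice_s < window_s) {
    stop_kf("slice_s = ", slice_s, " is shorter than one ", window_s,
            " s window")
  }
  starts <- encoding$window_start_s
  duration <- max(starts) + window_s
  n_chunks <- floor(duration / slice_s)
  if (n_chunks < 1L) {
    stop_kf("video spans ", duration, " s, shorter than one ", slice_s,
            " s slice")
  }
  out <- vector("list", n_chunks)
  for (j in seq_len(n_chunks)) {
    lo <- (j - 1) * slice_s
    hi <- j * slice_s
    keep <- which(starts >= lo - 1e-9 & starts + window_s <= hi + 1e-9)
    out[[j]] <- structure(
      list(video_id = encoding$video_id, chunk = j,
           window_start_s = starts[keep],
           kineme = encoding$kineme[keep, , drop = FALSE],
           au = encoding$au[keep, , drop = FALSE],
           speech = encoding$speech[keep, , drop = FALSE]),
      class = "segment_encoding")
  }
  out
}

#' Aggregate chunk predictions to a video prediction
#'
#' Majority vote for classification (ties go to the positive class, with
#' a message) and the arithmetic mean for regression.
#'
#' @param chunk_preds numeric predictions for one video's chunks.
#' @param task `"regression"` or `"classification"`.
#' @return scalar video-level prediction.
#' @export
aggregate_video <- function(chunk_preds,
                            task = c("regression", "classification")) {
  task <- match.arg(task)
  assert_that(length(chunk_preds) >= 1, "no chunk predictions")
  if (task == "regression") return(mean(chunk_preds))
  pos <- sum(chunk_preds == 1)
  neg <- sum(chunk_preds == 0)
  if (pos == neg) {
    message("majority-vote tie for video; assigning positive class")
    return(1L)
  }
  as.integer(pos > neg)
}

# Macro-averaged F1 over the two classes (0/0 per-class F1 counts as 0,
# keeping the score defined on degenerate confusion tables).
macro_f1 <- function(pred, truth) {
  f1s <- vapply(c(0, 1), function(cls) {
    tp <- sum(pred == cls & truth == cls)
    fp <- sum(pred == cls & truth != cls)
    fn <- sum(pred != cls & truth == cls)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1s)
}

#' Compute prediction metrics
#'
#' Classification: accuracy and macro-averaged F1. Regression:
#' `Acc = 1 - MAE` (on [0, 1]-standardized scores this lies in [0, 1])
#' and the Pearson correlation coefficient. A constant vector makes PCC
#' undefined; it is reported as `NA`, never coerced to 0.
#'
#' @param predictions,truths equal-length numeric vectors (length >= 2).
#' @param task `"regression"` or `"classification"`.
#' @return named list of metrics (`acc`, `f1` or `acc`, `mae`, `pcc`).
#' @export
compute_metrics <- function(predictions, truths,
                            task = c("regression", "classification")) {
  task <- match.arg(task)
  assert_that(length(predictions) == length(truths) &&
                length(truths) >= 2,
              "predictions and truths must have equal length >= 2")
  if (task == "classification") {
    list(acc = mean(predictions == truths),
         f1 = macro_f1(predictions, truths))
  } else {
    mae <- mean(abs(predictions - truths))
    pcc <- if (stats::sd(predictions) == 0 || stats::sd(truths) == 0) {
      NA_real_
    } else {
      stats::cor(predictions, truths)
    }
    list(acc = 1 - mae, mae = mae, pcc = pcc)
  }
}

#' Run an evaluation protocol
#'
#' Orchestrates either a fixed manifest split or repeated k-fold
#' cross-validation. Folds always partition *videos*; chunk-level work
#' stays inside `run_fn`, so no video's chunks ever span a train/test
#' boundary. Repeats use distinct derived seeds; the report carries one
#' row per run plus mean and sd per metric.
#'
#' @param video_ids character vector of video identifiers.
#' @param run_fn function `(train_ids, test_ids, seed)` returning a
#'   named numeric vector of metrics for one run.
#' @param protocol `"fixed-split"` or `"repeated-k-fold"`.
#' @param split for `"fixed-split"`: character vector aligned with
#'   `video_ids` holding `"train"`/`"val"`/`"test"` tags (val rows are
#'   passed to `run_fn` as part of the train side's complement, i.e.
#'   `train_ids` are the non-test rows).
#' @param folds,repeats fold count and repeat count for
#'   `"repeated-k-fold"` (defaults 10 and 5, i.e. 50 runs).
#' @param seed master seed; each repeat derives its own shuffling seed.
#' @return object of class `evaluation_report`: `runs` (one row per
#'   run) and `summary` (mean and sd per metric).
#' @export
run_protocol <- function(video_ids, run_fn,
                         protocol = c("fixed-split", "repeated-k-fold"),
                         split = NULL, folds = 10, repeats = 5,
                         seed = 1) {
  protocol <- match.arg(protocol)
  n <- length(video_ids)
  rows <- list()
  if (protocol == "fixed-split") {
    assert_that(!is.null(split) && length(split) == n,
                "fixed-split requires a split vector")
    test_ids <- video_ids[split == "test"]
    train_ids <- video_ids[split != "test"]
    assert_that(length(test_ids) > 0 && length(train_ids) > 0,
                "fixed split needs both train and test videos")
    met <- run_fn(train_ids, test_ids, derive_seed(seed, 1))
    rows[[1]] <- data.frame(run = 1L, rep = 1L, fold = 1L, t(met))
  } else {
    if (folds > n) {
      stop_kf("fold count ", folds, " exceeds video count ", n)
    }
    run <- 0L
    for (r in seq_len(repeats)) {
      rep_seed <- derive_seed(seed, r)
      perm <- with_seed(rep_seed, sample.int(n))
      fold_of <- rep(seq_len(folds), length.out = n)[order(perm)]
      for (f in seq_len(folds)) {
        run <- run + 1L
        test_ids <- video_ids[fold_of == f]
        train_ids <- video_ids[fold_of != f]
        met <- run_fn(train_ids, test_ids, derive_seed(rep_seed, f))
        rows[[run]] <- data.frame(run = run, rep = r, fold = f, t(met))
      }
    }
  }
  runs <- do.call(rbind, rows)
  metric_cols <- setdiff(names(runs), c("run", "rep", "fold"))
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(runs[[m]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(metric_cols, function(m) stats::sd(runs[[m]],
                                                   na.rm = TRUE),
                numeric(1)),
    row.names = NULL)
  structure(list(protocol = protocol, runs = runs, summary = summary),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report (", x$protocol, "), ", nrow(x$runs),
      " run(s)\n", sep = "")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %s: %.3f +/- %.3f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  }
  invisible(x)
}

#' Write an evaluation report
#'
#' One CSV row per run plus a JSON summary.
#'
#' @param report an `evaluation_report`.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return `report`, invisibly.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  if (!is.null(csv_path)) {
    utils::write.csv(report$runs, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(protocol = report$protocol,
                              summary = report$summary),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
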