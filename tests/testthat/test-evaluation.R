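test_that("median dichotomization follows the training median", {
  expect_equal(dichotomize_median(c(0.1, 0.4, 0.6, 0.9)),
               c(0L, 0L, 1L, 1L))
  # a score exactly at the median goes to the negative class
  expect_equal(dichotomize_median(c(0.5), train_scores = c(0, 0.5, 1)),
               0L)
  expect_error(dichotomize_median(rep(0.3, 5)), "degenerate")
  # class shares may be unequal, mirroring real corpora
  set.seed(4)
  s <- c(stats::rbeta(60, 2, 1), stats::rbeta(40, 1, 3))
  lab <- dichotomize_median(s)
  expect_true(all(lab %in% 0:1))
  expect_equal(sum(lab == 1) + sum(lab == 0), 100)
})

test_that("thin slices partition the window grid", {
  enc <- small_encodings()$encodings[[1]]   # 12 s video -> 11 windows
  chunks <- make_slices(enc, slice_s = 4)
  expect_length(chunks, 3)                  # floor(12 / 4)
  for (ch in chunks) {
    expect_s3_class(ch, "segment_encoding")
    expect_equal(nrow(ch$kineme), 3)        # starts 0..2 within 4 s
    expect_equal(ch$video_id, enc$video_id)
  }
  # slice equal to the video span returns the whole video
  whole <- make_slices(enc, slice_s = 12)
  expect_length(whole, 1)
  expect_equal(whole[[1]]$kineme, enc$kineme)
  expect_error(make_slices(enc, slice_s = 1), "shorter")
  # 15 s video at 30 fps, 5 s slices -> 3 chunks
  ps <- toy_pose(matrix(stats::rnorm(450 * 3), ncol = 3))
  vocab <- small_vocab()
  au <- toy_au(matrix(stats::runif(450 * 17, 0, 3), ncol = 17))
  lld <- as.data.frame(matrix(1, 210, 23))
  names(lld) <- c("f0", "voicing", "zcr", sprintf("mfcc%02d", 1:20))
  enc15 <- encode_video(ps, au, lld, vocab)
  expect_length(make_slices(enc15, 5), 3)
})

test_that("video aggregation is majority vote / mean", {
  expect_equal(aggregate_video(c(1, 1, 0), "classification"), 1L)
  expect_equal(aggregate_video(c(0.2, 0.4), "regression"), 0.3)
  expect_equal(aggregate_video(0.7, "regression"), 0.7)
  expect_message(tie <- aggregate_video(c(0, 1), "classification"),
                 "tie")
  expect_equal(tie, 1L)
})

test_that("metrics match closed forms", {
  m <- compute_metrics(c(0.1, 0.4, 0.7), c(0.2, 0.5, 0.6), "regression")
  expect_equal(m$mae, 0.1)
  expect_equal(m$acc, 0.9)
  # hand product-moment computation
  pcc_hand <- stats::cov(c(0.1, 0.4, 0.7), c(0.2, 0.5, 0.6)) /
    (stats::sd(c(0.1, 0.4, 0.7)) * stats::sd(c(0.2, 0.5, 0.6)))
  expect_equal(m$pcc, pcc_hand)
  ident <- compute_metrics(c(0.2, 0.8), c(0.2, 0.8), "regression")
  expect_equal(ident$acc, 1)
  expect_equal(ident$pcc, 1)
  anti <- compute_metrics(1 - c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9),
                          "regression")
  expect_equal(anti$pcc, -1)
  # undefined PCC is NA, never 0
  expect_true(is.na(compute_metrics(c(0.5, 0.5), c(0.1, 0.9),
                                    "regression")$pcc))
  cls <- compute_metrics(c(1, 0, 1, 1), c(1, 0, 0, 1),
                         "classification")
  expect_equal(cls$acc, 0.75)
  expect_equal(cls$f1, mean(c(2 * 1 / (2 * 1 + 1 + 0),
                              2 * 2 / (2 * 2 + 1 + 0))))
})

test_that("repeated k-fold partitions videos and is deterministic", {
  ids <- sprintf("v%02d", 1:17)
  calls <- list()
  run_fn <- function(train_ids, test_ids, seed) {
    calls[[length(calls) + 1L]] <<- list(train = train_ids,
                                         test = test_ids)
    c(acc = length(test_ids) / 17)
  }
  rep_count <- 3; fold_count <- 5
  rp <- run_protocol(ids, run_fn, "repeated-k-fold",
                     folds = fold_count, repeats = rep_count, seed = 2)
  expect_equal(nrow(rp$runs), rep_count * fold_count)
  # each repeat's folds partition the ids exactly
  for (r in seq_len(rep_count)) {
    tests <- unlist(lapply(calls[(r - 1) * fold_count + 1:fold_count],
                           `[[`, "test"))
    expect_setequal(tests, ids)
    expect_equal(length(tests), 17)
  }
  for (cl in calls) {
    expect_length(intersect(cl$train, cl$test), 0)
  }
  rp2 <- run_protocol(ids, function(a, b, s) c(acc = s %% 7),
                      "repeated-k-fold", folds = fold_count,
                      repeats = rep_count, seed = 2)
  rp3 <- run_protocol(ids, function(a, b, s) c(acc = s %% 7),
                      "repeated-k-fold", folds = fold_count,
                      repeats = rep_count, seed = 2)
  expect_identical(rp2$runs, rp3$runs)
  expect_error(run_protocol(ids, run_fn, "repeated-k-fold", folds = 30),
               "exceeds")
})

test_that("fixed-split protocol respects the manifest split", {
  ids <- sprintf("v%02d", 1:10)
  split <- rep(c("train", "val", "test"), c(6, 2, 2))
  rp <- run_protocol(ids, function(train_ids, test_ids, seed) {
    expect_setequal(test_ids, ids[9:10])
    expect_setequal(train_ids, ids[1:8])
    c(acc = 1)
  }, "fixed-split", split = split)
  expect_equal(nrow(rp$runs), 1)
})

test_that("video-level regression aggregation does not hurt accuracy on
           chunked synthetic predictions", {
  # unbiased chunk noise: averaging chunks reduces MAE in expectation
  set.seed(11)
  gains <- replicate(20, {
    truth <- stats::runif(15)
    chunk_preds <- lapply(truth, function(t) t + stats::rnorm(4, 0, 0.15))
    video_pred <- vapply(chunk_preds, mean, numeric(1))
    chunk_acc <- 1 - mean(abs(unlist(chunk_preds) - rep(truth, each = 4)))
    video_acc <- 1 - mean(abs(video_pred - truth))
    video_acc - chunk_acc
  })
  expect_gt(mean(gains), 0)
})

test_that("evaluation report writes CSV and JSON", {
  rp <- run_protocol(letters[1:6], function(a, b, s) c(acc = 0.5,
                                                       pcc = 0.1),
                     "repeated-k-fold", folds = 3, repeats = 2,
                     seed = 1)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_report(rp, csv, js)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), 6)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$summary$mean[1], 0.5)
})
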