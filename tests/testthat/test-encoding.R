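test_that("one-hot kineme encoding is exact", {
  expect_equal(unname(one_hot_kinemes(c(2L, 1L), k = 3)),
               rbind(c(0L, 1L, 0L), c(1L, 0L, 0L)))
  set.seed(2)
  labels <- sample.int(16, 40, replace = TRUE)
  oh <- one_hot_kinemes(labels, k = 16)
  expect_equal(ncol(oh), 16)
  expect_equal(rowSums(oh), rep(1, 40))
  expect_error(one_hot_kinemes(c(1L, 5L), k = 4), "out of range")
})

test_that("dominant AUs compare window means to the video mean", {
  # 4-frame toy table at 1 fps, 2 s windows with 1 s hop -> 3 windows
  ints <- matrix(1, 4, 2)
  ints[, 1] <- c(3, 3, 0.5, 0.5)   # video mean 1.75
  ints[, 2] <- c(0.5, 0.5, 0.5, 0.5)
  au <- toy_au(ints, frame_rate = 1)
  dom <- dominant_aus(au, window_s = 2, hop_s = 1)
  # AU channel 1: window means 3, 1.75, 0.5 vs video mean 1.75
  expect_equal(unname(dom[, 1]), c(1L, 0L, 0L))
  # constant channel is never dominant (strict inequality)
  expect_equal(unname(dom[, 2]), c(0L, 0L, 0L))
})

test_that("dominant AUs: all-constant input gives an all-zero block and
           scaling one AU uniformly changes nothing", {
  corp <- small_corpus()
  au <- corp$au[[1]]
  const <- toy_au(matrix(2.5, 120, 17))
  expect_true(all(dominant_aus(const) == 0))
  dom <- dominant_aus(au)
  expect_equal(ncol(dom), 17)
  # mean-relative threshold: scaling one AU uniformly (within scale)
  # leaves the dominance pattern unchanged
  base <- au
  base$intensities <- au$intensities / 2
  scaled <- base
  scaled$intensities[, 5] <- base$intensities[, 5] * 1.7
  expect_equal(dominant_aus(scaled), dominant_aus(base))
})

test_that("LLD extraction behaves on canonical signals", {
  sr <- 16000
  # digital silence
  sil <- extract_llds(numeric(sr), sr)
  expect_true(all(sil$zcr == 0))
  expect_true(all(sil$f0 == 0))
  expect_true(all(sil$voicing < 0.3))
  # 440 Hz pure tone: median F0 within 5%
  tone <- sin(2 * pi * 440 * seq_len(sr) / sr)
  lt <- extract_llds(tone, sr)
  expect_lt(abs(stats::median(lt$f0) - 440) / 440, 0.05)
  expect_true(all(lt$voicing > 0.9))
  # square wave alternating every sample: maximal ZCR
  sq <- rep(c(1, -1), sr / 2)
  ls <- extract_llds(sq, sr)
  expect_true(all(ls$zcr > 0.99))
  # frame geometry: 93 ms window, 70 ms hop
  expect_equal(nrow(lt), floor((sr - round(0.093 * sr)) /
                                 round(0.070 * sr)) + 1)
  expect_equal(ncol(lt), 23)
  expect_error(extract_llds(numeric(0), sr), "empty")
})

test_that("speech segment features average LLDs on the shared grid", {
  # constant stream -> window means equal the constants
  lld <- as.data.frame(matrix(rep(c(100, 0.5, 0.1, rep(1, 20)),
                                  each = 60), nrow = 60))
  names(lld) <- c("f0", "voicing", "zcr", sprintf("mfcc%02d", 1:20))
  sp <- speech_segment_features(lld, duration_s = 4)
  expect_equal(dim(sp), c(3L, 23L))
  expect_equal(unname(sp[2, ]), c(100, 0.5, 0.1, rep(1, 20)))
  # two-frame window: mean of {100, 200} is 150
  lld2 <- lld[1:28, ]
  lld2$f0 <- rep(c(100, 200), 14)
  sp2 <- speech_segment_features(lld2, duration_s = 2)
  expect_equal(unname(sp2[1, "f0"]), 150)
})

test_that("z-scoring uses population statistics fit once", {
  X <- cbind(a = c(1, 3), b = c(2, 2))
  expect_warning(st <- zscore_fit(X), "zero-variance")
  Z <- zscore_apply(X, st)
  expect_equal(unname(Z[, 1]), c(-1, 1))
  expect_equal(unname(Z[, 2]), c(0, 0))
  # applying the fitted stats to the training block is idempotent in
  # the fitted sense: mean 0, sd 1 (population)
  set.seed(3)
  Y <- matrix(rnorm(200, 5, 2), 50)
  sty <- zscore_fit(Y)
  Zy <- zscore_apply(Y, sty)
  expect_equal(colMeans(Zy), rep(0, 4), tolerance = 1e-9)
  expect_equal(sqrt(colMeans(Zy^2)), rep(1, 4), tolerance = 1e-6)
})

test_that("the three blocks share one grid per video", {
  enc <- small_encodings()
  for (e in enc$encodings) {
    L <- nrow(e$kineme)
    expect_equal(nrow(e$au), L)
    expect_equal(nrow(e$speech), L)
    expect_length(e$window_start_s, L)
    expect_equal(rowSums(e$kineme), rep(1, L))
    expect_true(all(e$au %in% c(0L, 1L)))
  }
  # speech z-scoring was fit on the training split only
  tr <- small_corpus()$split == "train"
  pooled <- do.call(rbind, lapply(enc$encodings[tr], `[[`, "speech"))
  expect_equal(colMeans(pooled), rep(0, 23), tolerance = 1e-9,
               ignore_attr = TRUE)
})
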