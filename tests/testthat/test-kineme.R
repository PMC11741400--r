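test_that("segment matrix geometry follows the window grid", {
  # T = 6 frames, 2 s windows at 2 fps -> l = 4, hop = 2 -> 2 columns
  ps <- toy_pose(cbind(1:6 / 10, 0, 0), frame_rate = 2)
  sm <- build_segment_matrix(list(ps), window_s = 2,
                             overlap_fraction = 0.5)
  expect_equal(sm$len, 4L)
  expect_equal(sm$hop, 2L)
  expect_equal(dim(sm$H), c(12L, 2L))
  # columns are concatenated (pitch, yaw, roll) windows plus the offset
  expect_equal(sm$H[1:4, 1] - sm$offset, (1:4) / 10)
  expect_equal(sm$H[1:4, 2] - sm$offset, (3:6) / 10)
  # 2 s windows with 50% overlap at 30 fps -> l = 60, hop = 30
  ps30 <- toy_pose(cbind(rnorm(120), rnorm(120), rnorm(120)))
  sm30 <- build_segment_matrix(list(ps30))
  expect_equal(sm30$len, 60L)
  expect_equal(sm30$hop, 30L)
  expect_equal(ncol(sm30$H), 3L)   # floor((120 - 60) / 30) + 1
})

test_that("constant zero series yields an all-zero matrix, offset 0", {
  ps <- toy_pose(matrix(0, 8, 3), frame_rate = 2)
  sm <- build_segment_matrix(list(ps), window_s = 2,
                             overlap_fraction = 0.5)
  expect_equal(sm$offset, 0)
  expect_true(all(sm$H == 0))
})

test_that("short videos are skipped with a warning; all short errors", {
  long <- toy_pose(cbind(rnorm(70), 0, 0))
  short <- toy_pose(matrix(0, 10, 3), id = "short")
  expect_warning(sm <- build_segment_matrix(list(long, short)),
                 "skipped")
  expect_equal(ncol(sm$H), 1L)
  expect_error(suppressWarnings(build_segment_matrix(list(short))),
               "shorter")
})

test_that("NNLS matches a brute-force grid oracle", {
  set.seed(31)
  for (i in 1:10) {
    B <- matrix(runif(12 * 2), 12, 2)
    h <- runif(12, 0, 2)
    chat <- nnls_solve(B, h)
    expect_true(all(chat >= 0))
    obj <- function(c1, c2) sum((h - B %*% c(c1, c2))^2)
    grid <- seq(0, 10, by = 1e-3)
    # profile the 2-D grid search one axis at a time around the solution
    best_grid <- min(outer(seq(max(0, chat[1] - 0.05), chat[1] + 0.05,
                               by = 1e-3),
                           seq(max(0, chat[2] - 0.05), chat[2] + 0.05,
                               by = 1e-3),
                           Vectorize(obj)))
    expect_lte(obj(chat[1], chat[2]), best_grid + 1e-3)
    # never worse than the zero vector
    expect_lte(obj(chat[1], chat[2]), sum(h^2))
  }
})

test_that("NNLS recovers exact non-negative combinations and zero", {
  set.seed(7)
  B <- matrix(runif(30 * 4), 30, 4)   # full column rank w.h.p.
  c0 <- c(0.5, 0, 1.2, 0.3)
  expect_equal(nnls_solve(B, drop(B %*% c0)), c0, tolerance = 1e-6)
  expect_equal(nnls_solve(B, numeric(30)), numeric(4))
})

test_that("learn_vocabulary recovers planted prototypes", {
  set.seed(13)
  protos <- matrix(runif(18 * 3, 0, 1), 18, 3)
  H <- protos[, rep(1:3, each = 20)]
  sm <- structure(list(H = H, len = 6L, hop = 3L, offset = 0,
                       window_s = 2, overlap_fraction = 0.5,
                       frame_rate = 3, video_of = rep("v", 60)),
                  class = "segment_matrix")
  vocab <- suppressWarnings(learn_vocabulary(sm, r = 5, k = 3, seed = 2))
  expect_equal(ncol(vocab$Hstar), 3L)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  sim <- outer(1:3, 1:3, Vectorize(function(i, j)
    cosine(vocab$Hstar[, i], protos[, j])))
  # best permutation assignment (k = 3: enumerate all 6)
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  best <- max(vapply(perms, function(p)
    min(sim[cbind(1:3, p)]), numeric(1)))
  expect_gte(best, 0.99)
})

test_that("vocabulary learning is deterministic and validates k", {
  corp <- small_corpus()
  sm <- build_segment_matrix(corp$pose[1:4])
  v1 <- suppressWarnings(learn_vocabulary(sm, r = 6, k = 3, seed = 5))
  v2 <- suppressWarnings(learn_vocabulary(sm, r = 6, k = 3, seed = 5))
  expect_equal(v1$Hstar, v2$Hstar, tolerance = 1e-9)
  expect_error(suppressWarnings(learn_vocabulary(sm, r = 6, k = 1e5)),
               "exceeds")
  expect_equal(sum(v1$mixture$weights), 1, tolerance = 1e-9)
})

test_that("a window equal to a kineme column maps to its label", {
  vocab <- small_vocab()
  for (j in seq_len(vocab$k)) {
    col <- vocab$Hstar[, j] - vocab$offset
    len <- vocab$len
    ang <- cbind(col[1:len], col[len + 1:len], col[2 * len + 1:len])
    ps <- toy_pose(ang, frame_rate = vocab$frame_rate)
    seq_j <- assign_kinemes(ps, vocab)
    expect_equal(seq_j$labels[1], j)
  }
})

test_that("posteriors are normalized and equal-weight isotropic mixtures
           reduce to nearest-mean assignment", {
  vocab <- small_vocab()
  corp <- small_corpus()
  ks <- assign_kinemes(corp$pose[[1]], vocab)
  expect_equal(rowSums(ks$posterior), rep(1, length(ks$labels)),
               tolerance = 1e-9)
  expect_equal(length(ks$labels),
               floor((nrow(corp$pose[[1]]$angles) - vocab$len) /
                       vocab$hop) + 1)
  # shared isotropic covariance + equal weights => nearest mean
  iso <- vocab
  k <- vocab$k; r <- vocab$r
  iso$mixture$weights <- rep(1 / k, k)
  iso$mixture$covs <- rep(list(diag(0.05, r)), k)
  ks_iso <- assign_kinemes(corp$pose[[2]], iso)
  # independent oracle: project windows, pick the closest mean
  sm <- build_segment_matrix(corp$pose[2], vocab$window_s,
                             vocab$overlap_fraction)
  for (i in seq_along(ks_iso$labels)) {
    h <- sm$H[, i] - sm$offset + vocab$offset
    chat <- project_segment(h, vocab)
    d <- apply(iso$mixture$means, 1, function(mu) sum((chat - mu)^2))
    expect_equal(ks_iso$labels[i], unname(which.min(d)))
  }
})

test_that("assignment recovers generating prototypes on a clean corpus", {
  cfg <- synth_config(n_videos = 16, duration_s = 12, n_prototypes = 4,
                      noise_sd = list(angle = 0.01, au = 0.3, lld = 1,
                                      label = 0.05),
                      seed = 19)
  corp <- generate_corpus(cfg)
  sm <- build_segment_matrix(corp$pose, window_s = 2,
                             overlap_fraction = 0)
  vocab <- suppressWarnings(learn_vocabulary(sm, r = 10, k = 4, seed = 3))
  assigned <- unlist(lapply(corp$pose,
                            function(p) assign_kinemes(p, vocab)$labels))
  truth <- unlist(corp$proto_labels)
  expect_gte(adjusted_rand_index(assigned, truth), 0.8)
})

test_that("kineme sequences export as tidy CSV", {
  corp <- small_corpus()
  vocab <- small_vocab()
  seqs <- lapply(corp$pose[1:2], assign_kinemes, vocab = vocab)
  path <- withr::local_tempfile(fileext = ".csv")
  write_kineme_sequences(seqs, path)
  back <- utils::read.csv(path)
  expect_equal(names(back), c("video_id", "window_start_s", "label"))
  expect_equal(nrow(back), sum(vapply(seqs, function(s)
    length(s$labels), integer(1))))
  expect_equal(back$label[seq_along(seqs[[1]]$labels)],
               seqs[[1]]$labels)
})

test_that("vocabulary JSON archive round-trips", {
  vocab <- small_vocab()
  path <- withr::local_tempfile(fileext = ".json")
  write_vocabulary(vocab, path)
  back <- read_vocabulary(path)
  expect_equal(back$Hstar, vocab$Hstar, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$mixture$means, vocab$mixture$means,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$len, vocab$len)
  # an assignment computed with the restored vocabulary agrees
  corp <- small_corpus()
  expect_equal(assign_kinemes(corp$pose[[1]], back)$labels,
               assign_kinemes(corp$pose[[1]], vocab)$labels)
})
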