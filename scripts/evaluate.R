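#!/usr/bin/env Rscript
# Evaluate trait predictors on a corpus described by a manifest CSV.
#
# Usage:
#   Rscript scripts/evaluate.R --manifest <dir>/manifest.csv
#       [--trait <name>] [--task regression|classification]
#       [--protocol fixed-split|repeated-k-fold] [--folds 10]
#       [--repeats 5] [--slice-seconds <s>] [--level chunk|video]
#       [--seeds 1] [--kinemes 16] [--rank 24] [--units 20]
#       [--epochs 150] [--patience 10] [--config <file>] [--verbose]
#       [--out <prefix>]
#
# Trains the three unimodal recurrent models (kineme, AU, speech) plus
# decision fusion, under the requested protocol, and writes
# <prefix>.csv (one row per run) and <prefix>.json (summary).
# --config points at a YAML-style "key: value" file whose entries are
# read before the command line (flags win).

suppressPackageStartupMessages(library(kinfuse))

args <- commandArgs(trailingOnly = TRUE)
read_config_file <- function(path) {
  out <- list()
  for (line in readLines(path, warn = FALSE)) {
    line <- sub("#.*$", "", line)
    if (!grepl(":", line)) next
    key <- trimws(sub(":.*$", "", line))
    val <- trimws(sub("^[^:]*:", "", line))
    if (nzchar(key) && nzchar(val)) out[[key]] <- val
  }
  out
}
get_arg <- function(flag, default = NULL) {
  i <- which(args == paste0("--", flag))
  if (length(i) == 1L && i < length(args)) return(args[i + 1L])
  if (!is.null(cfg_file_opts[[flag]])) return(cfg_file_opts[[flag]])
  default
}
has_flag <- function(flag) any(args == paste0("--", flag))

cfg_file_opts <- list()
ci <- which(args == "--config")
if (length(ci) == 1L && ci < length(args)) {
  cfg_file_opts <- read_config_file(args[ci + 1L])
}

manifest_path <- get_arg("manifest")
if (is.null(manifest_path)) stop("--manifest is required", call. = FALSE)
task <- match.arg(get_arg("task", "regression"),
                  c("regression", "classification"))
protocol <- match.arg(get_arg("protocol", "fixed-split"),
                      c("fixed-split", "repeated-k-fold"))
level <- match.arg(get_arg("level", "video"), c("chunk", "video"))
slice_s <- as.numeric(get_arg("slice-seconds", "0"))
folds <- as.integer(get_arg("folds", "10"))
repeats <- as.integer(get_arg("repeats", "5"))
seed <- as.integer(get_arg("seeds", "1"))
k_kin <- as.integer(get_arg("kinemes", "16"))
r_rank <- as.integer(get_arg("rank", "24"))
units <- as.integer(get_arg("units", "20"))
epochs <- as.integer(get_arg("epochs", "150"))
patience <- as.integer(get_arg("patience", "10"))
out_prefix <- get_arg("out", "evaluation")
verbose <- has_flag("verbose")
say <- function(...) if (verbose) message(sprintf(...))

man <- read_manifest(manifest_path)
root <- dirname(manifest_path)
tab <- man$table
trait <- get_arg("trait", man$traits[1])
if (!trait %in% man$traits) {
  stop("trait '", trait, "' not in manifest (have: ",
       paste(man$traits, collapse = ", "), ")", call. = FALSE)
}
say("manifest: %d videos, trait '%s', task %s", nrow(tab), trait, task)

corpus <- list(video_ids = tab$video_id,
               split = tab$split,
               pose = lapply(seq_len(nrow(tab)), function(i)
                 read_pose_table(file.path(root, tab$pose_path[i]),
                                 frame_rate = man$frame_rate,
                                 video_id = tab$video_id[i])),
               au = lapply(seq_len(nrow(tab)), function(i)
                 read_au_table(file.path(root, tab$au_path[i]),
                               frame_rate = man$frame_rate,
                               video_id = tab$video_id[i])),
               lld = if ("lld_path" %in% names(tab)) {
                 lapply(tab$lld_path,
                        function(p) read_lld_table(file.path(root, p)))
               } else {
                 lapply(tab$audio_path, function(p)
                   extract_llds(read_wav(file.path(root, p))))
               })

say("learning %d-kineme vocabulary (rank %d)", k_kin, r_rank)
vocab <- suppressWarnings(corpus_vocabulary(corpus, r = r_rank,
                                            k = k_kin, seed = seed))
enc <- suppressWarnings(encode_corpus(corpus, vocab))
blocks <- trimodal_blocks(enc)
scores <- tab[[trait]]
names(scores) <- tab$video_id
y <- if (task == "classification") {
  dichotomize_median(scores,
                     train_scores = scores[tab$split == "train"])
} else {
  scores
}
names(y) <- tab$video_id

# one run: train three unimodal models + decision fusion, score at the
# requested level
run_fn <- function(train_ids, test_ids, run_seed) {
  val_ids <- if (protocol == "fixed-split" &&
                 any(tab$split[match(train_ids, tab$video_id)] == "val")) {
    train_ids[tab$split[match(train_ids, tab$video_id)] == "val"]
  } else if (task == "classification") {
    # stratified quarter so both classes appear in train and validation
    unlist(lapply(split(train_ids, y[train_ids]), function(ids)
      ids[seq_len(max(1L, floor(length(ids) / 4)))]))
  } else {
    train_ids[seq_len(max(2L, floor(length(train_ids) / 4)))]
  }
  fit_ids <- setdiff(train_ids, val_ids)
  pick <- function(block, ids) block[match(ids, tab$video_id)]
  slice_blocks <- function(ids) {
    if (slice_s <= 0) {
      list(blocks = lapply(blocks, pick, ids = ids),
           labels = y[ids], video = ids)
    } else {
      kin <- list(); au <- list(); sp <- list()
      lab <- numeric(0); vid <- character(0)
      for (id in ids) {
        for (ch in make_slices(enc$encodings[[id]], slice_s)) {
          kin[[length(kin) + 1L]] <- ch$kineme
          au[[length(au) + 1L]] <- ch$au
          sp[[length(sp) + 1L]] <- ch$speech
          lab <- c(lab, y[id]); vid <- c(vid, id)
        }
      }
      list(blocks = list(kineme = kin, au = au, speech = sp),
           labels = lab, video = vid)
    }
  }
  trd <- slice_blocks(fit_ids); vad <- slice_blocks(val_ids)
  ted <- slice_blocks(test_ids)
  pv <- list(); pt <- list()
  for (m in c("kineme", "au", "speech")) {
    cfg_m <- model_config(task, units = units, epochs = epochs,
                          patience = patience, seed = run_seed)
    mod <- train_unimodal(trd$blocks[[m]], trd$labels, cfg_m,
                          vad$blocks[[m]], vad$labels)
    pv[[m]] <- predict(mod, vad$blocks[[m]])
    pt[[m]] <- predict(mod, ted$blocks[[m]])
  }
  fw <- fit_fusion_weights(pv, vad$labels, task)
  fused <- decision_fuse(pt, fw)
  finalize <- function(p) {
    if (task == "classification") p <- as.integer(p > 0.5)
    if (level == "video") {
      vapply(split(p, ted$video)[unique(ted$video)],
             aggregate_video, numeric(1), task = task)
    } else {
      p
    }
  }
  truth <- if (level == "video") y[unique(ted$video)] else ted$labels
  out <- numeric(0)
  for (m in names(pt)) {
    met <- compute_metrics(finalize(pt[[m]]), truth, task)
    out[paste0(m, "_acc")] <- met$acc
    out[paste0(m, "_", if (task == "regression") "pcc" else "f1")] <-
      if (task == "regression") met$pcc else met$f1
  }
  met <- compute_metrics(finalize(fused), truth, task)
  out["df_acc"] <- met$acc
  out[paste0("df_", if (task == "regression") "pcc" else "f1")] <-
    if (task == "regression") met$pcc else met$f1
  say("run seed %d done (test n = %d)", run_seed, length(truth))
  out
}

report <- run_protocol(tab$video_id, run_fn, protocol,
                       split = tab$split, folds = folds,
                       repeats = repeats, seed = seed)
print(report)
write_report(report, paste0(out_prefix, ".csv"),
             paste0(out_prefix, ".json"))
say("wrote %s.csv and %s.json", out_prefix, out_prefix)
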