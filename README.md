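# kinfuse

Explainable multimodal prediction of human-centered traits (personality
impressions, interview attributes) from thin slices of nonverbal
behavior: head motion, facial action units and speech.

Who this is for: behavioral-signal-processing and computational
psychometrics researchers who have per-frame head-pose and action-unit
tables (the OpenFace output dialect), audio, and per-video trait
annotations, and who want interpretable predictors rather than black
boxes.

## What it does

All three channels are encoded on a shared grid of 2 s windows with a
1 s hop:

* **Kinemes** — elementary head-motion units, learned from data.
  Windows of (pitch, yaw, roll) angles, offset to non-negativity, form a
  matrix `H`; NMF `H ≈ BC` plus a k-component Gaussian mixture over the
  coefficient columns give the kineme matrix `H* = BC*`. New windows are
  projected by non-negative least squares,
  `ĉ = argmin_{c≥0} ‖h − Bc‖²`, and assigned by maximum mixture
  posterior, yielding one-hot vectors (default k = 16).
* **Dominant AUs** — a binary 17-vector per window: an AU is dominant
  iff its window-mean intensity strictly exceeds its whole-video mean.
* **Speech** — 23 low-level descriptors (F0, voicing, zero-crossing
  rate, 20 MFCCs) over 93 ms frames, averaged per window and z-scored
  with training-split statistics.

Predictors: unimodal LSTM, multi-stream feature fusion, additive
soft-attention fusion (which also emits per-window modality weights),
and decision fusion with convex weights grid-searched on a 0.05 simplex
lattice. Regression uses a linear head with MAE loss (so
`Acc = 1 − MAE`); classification a sigmoid head with cross-entropy,
labels from a training-median split. Explanations: per-trait top/bottom
10-percentile groups summarized by their 4 most frequent kinemes and 5
dominant AUs, and attention-trace contribution summaries with standard
errors over runs. A synthetic-corpus generator with known ground truth
(sinusoidal motion prototypes, bursty AU channels, trait scores from a
logistic-linear link) makes the whole pipeline testable offline.

The recurrent engine (LSTM, attention, layer norm, Adam, BPTT) is
implemented in plain R and gradient-checked against finite differences —
no external deep-learning framework is required.

## Worked example

```r
library(kinfuse)

cfg    <- synth_config(n_videos = 120, duration_s = 16, seed = 7)
corpus <- generate_corpus(cfg)
vocab  <- corpus_vocabulary(corpus, r = 12, k = 6, seed = 2)
enc    <- encode_corpus(corpus, vocab)

tr <- corpus$split == "train"; va <- corpus$split == "val"
te <- corpus$split == "test"
y  <- corpus$traits$warmth
blocks <- trimodal_blocks(enc)

cfg_m <- model_config("regression", units = 20, epochs = 150,
                      patience = 10, seed = 3)
fit <- lapply(c(kineme = "kineme", au = "au", speech = "speech"),
              function(m) train_unimodal(blocks[[m]][tr], y[tr], cfg_m,
                                         blocks[[m]][va], y[va]))
pv <- lapply(names(fit), function(m) predict(fit[[m]], blocks[[m]][va]))
pt <- lapply(names(fit), function(m) predict(fit[[m]], blocks[[m]][te]))
names(pv) <- names(pt) <- names(fit)

for (m in names(fit)) {
  met <- compute_metrics(pt[[m]], y[te], "regression")
  cat(sprintf("%-7s Acc = %.3f  PCC = %.3f\n", m, met$acc, met$pcc))
}
fw <- fit_fusion_weights(pv, y[va], "regression")
print(fw)
met <- compute_metrics(decision_fuse(pt, fw), y[te], "regression")
cat(sprintf("fused   Acc = %.3f  PCC = %.3f\n", met$acc, met$pcc))

groups <- percentile_groups(corpus$traits$dominance, corpus$video_ids,
                            pct = 10)
print(dominant_patterns(enc$encodings[groups$high],
                        trait = "dominance", group = "high"))
```

Output (exactly as printed by this code):

```
kineme  Acc = 0.827  PCC = 0.217
au      Acc = 0.834  PCC = -0.059
speech  Acc = 0.797  PCC = -0.142
fusion_weights: 0.45 0.35 0.20 ( pcc = 0.4852 )
fused   Acc = 0.843  PCC = 0.122
trait_explanation: dominance ( high group, 12 videos, 180 windows )
  top kinemes: K4 (0.378), K1 (0.356), K3 (0.106), K5 (0.1)
  top AUs:     AU02_r (0.561), AU14_r (0.544), AU07_r (0.517), AU05_r (0.511), AU25_r (0.506)
```

Reading it: `Acc = 1 − MAE` on [0, 1]-standardized scores, so ~0.83
means mean absolute error ≈ 0.17. The `warmth` trait is deliberately
hard (ridge ceiling ≈ 0.3–0.5 PCC at this size), and a single 24-video
test split makes PCC noisy — the fused Acc is the best here while its
split PCC is not; the acceptance script runs the stabler cross-validated
comparison, where trimodal decision fusion beats the best unimodal
stream on average over 5 seeds. The explanation block recovers the
mechanism planted in the generator: the `dominance` trait loads
positively on prototype 1 usage, and the high group's top kinemes (K4,
K1 here) are the learned counterparts of the favored prototypes.

## Command line

```sh
Rscript scripts/evaluate.R --manifest corpus/manifest.csv \
    --trait warmth --task regression --protocol repeated-k-fold \
    --folds 10 --repeats 5 --slice-seconds 4 --level video \
    --seeds 1 --out results/warmth
```

reads a manifest (per-video OpenFace-dialect pose/AU tables, LLD tables
or WAV audio, trait columns, split tags), learns the kineme vocabulary
on the training videos, trains the three unimodal models plus decision
fusion under the chosen protocol, and writes one CSV row per run plus a
JSON summary. `--config file` supplies `key: value` defaults;
`--verbose` enables progress logs.

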