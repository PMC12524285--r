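# satsn

Automated detection of daily behaviors — **licking, standing, walking,
eating** — of giraffes in fixed-camera zoo video. Changes in these
behaviors (in particular oral licking of non-food objects, a candidate
stereotypy) are welfare indicators, and scoring them by hand over hours
of footage is slow and observer-dependent. `satsn` implements the full
analysis pipeline downstream of any pose detector: multi-object tracking,
keypoint-guided input routing, a spatial-adaptive two-stream classifier,
frame-level evaluation metrics, and ethogram statistics, together with a
seeded synthetic scene generator so that every stage is testable without
any video download.

## The model

**SATSN (spatial-adaptive two-stream network).** A slow pathway takes
*T* frames at temporal stride *τ*, embeds non-overlapping *t×h×w*
tubelets as tokens and encodes them with a pre-norm ViT using joint
space–time self-attention. A fast pathway takes *αT* frames (α > 1)
through 3×3×3 convolution stages with *βC* channels (β < 1); after each
stage a temporal-attention block computes per-frame weights

&nbsp;&nbsp;&nbsp;&nbsp;M = σ( W_m ReLU(W_n avg) + W_m ReLU(W_n max) ) ∈ (0,1)^T

from average/max pooled frame descriptors and rescales the frames. Fast
stages fuse laterally into the slow tokens (stride-α temporal
subsampling, spatial pooling to the token grid, learned linear
projection, addition). The *spatial-adaptive* part is the input routing:
a 128×128 patch centered on the detected mouth keypoint replaces the
full-body crop in the fast pathway (scheme **B**; scheme **A** = full
body in both, scheme **C** = mouth crop in the slow pathway), applied
during training only to licking samples.

**Tracking.** An observation-centric SORT-style tracker: constant-velocity
Kalman filter over `[cx, cy, s, r]` and velocities, association cost
`C = (1 − IoU) + λ·θ/π` (θ = angle between the observation-derived track
direction and the track-to-candidate direction), a GIoU recovery pass
over unmatched tracks' last observations, and on reactivation a Kalman
re-update along the virtual trajectory `Z̃_t = z_{t1} + (t−t1)/(t2−t1)·(z_{t2}−z_{t1})`.

**Evaluation.** Precision = TP/(TP+FP), Recall = TP/(TP+FN),
F1 = 2PR/(P+R), AP = ∫₀¹ P(R) dR (all-point interpolation at 1 Hz
keyframes, IoU ≥ 0.5), mAP = (1/k)Σ AP_i, confusion matrices, and
per-window behavior durations / event counts.

Because no deep-learning framework is assumed, the network is implemented
directly in matrix algebra (im2col convolutions over BLAS, hand-written
backward passes verified against finite differences) and trains the
desk-scale "tiny" profile on a CPU in minutes.

## Worked example

```r
library(satsn)

# Adversarial tracking scenario: two giraffes cross while one is hidden
# and stops walking; plain IoU tracking loses its identity, the
# observation-centric mechanisms keep it.
fx <- make_crossing_fixture(seed = 1)
tracks <- track_video(fx$dets[setdiff(names(fx$dets), "agent_id")],
                      tracker_config())
cat("tracks:", length(unique(tracks$track_id)),
    "| identity switches:", id_switch_count(tracks, fx$gt), "\n")
#> tracks: 2 | identity switches: 0

# Metrics layer
pr <- precision_recall_f1(tp = 913, fp = 76, fn = 87)
sprintf("precision %.4f  recall %.4f  F1 %.4f",
        pr$precision, pr$recall, pr$f1)
#> "precision 0.9232  recall 0.9130  F1 0.9180"
f1_measure(92.33, 91.29)   # percent scale in, percent scale out
#> 91.81
mean_ap(c(91.69, 92.30, 95.90, 96.08))
#> 93.99
```

The two tracks with zero identity switches mean both animals kept one id
through the occlusion; the F1/mAP values show the metric formulas applied
to a published operating point. An end-to-end training run on synthetic
scenes is one call:

```r
ex <- run_synthetic_experiment(n_train = 200, n_test = 60,
                               scheme = "B", seed = 1, epochs = 15)
ex$mAP          # held-out 4-class mAP, ~1.0 on the clean synthetic task
ex$ap           # per-class AP (licking, standing, walking, eating)
```

## Command line

A thin dispatcher over the same functions lives at `inst/cli/satsn.R`:

```sh
Rscript inst/cli/satsn.R simulate --out data/demo --n-clips 40 --seed 1 --frames
Rscript inst/cli/satsn.R track --detections data/demo/clip0001/detections.jsonl --out mot.csv
Rscript inst/cli/satsn.R train --data data/demo --checkpoint model.json --epochs 15
Rscript inst/cli/satsn.R infer --data data/demo --checkpoint model.json --out pred.csv
Rscript inst/cli/satsn.R evaluate --pred pred.csv --gt data/demo/test.csv --out report.json
Rscript inst/cli/satsn.R stats --pred pred.csv --out ethogram.csv
```

## File formats

* **AVA-style annotations** — 8 comma-separated fields, no header:
  `video_id, timestamp_s, x1, y1, x2, y2, action_id, entity_id`; boxes
  normalized to [0,1] by frame width/height; timestamps are 1 Hz
  keyframes; `action_id`: 1 = licking, 2 = standing, 3 = walking,
  4 = eating. Predictions CSVs append a ninth `score` column.
* **Detection streams** — JSON lines with `frame`, `box{x1,y1,x2,y2}`,
  `score`, `mouth{x,y,visible}` (visible: 0 absent / 1 occluded /
  2 visible).
* **Tracks** — MOT-style CSV `frame,id,x,y,w,h,score`.
* **Checkpoints** — versioned single-file JSON with the architecture
  header and all parameters.

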