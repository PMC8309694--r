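---
title: "Automated C. elegans lifespan counting: models, simulator, and design choices"
author: "wormlifespan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated C. elegans lifespan counting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A lifespan assay counts the live *Caenorhabditis elegans* on each plate
every day, from the start of adulthood until the last death, and reports
the survival percentage

$$\%\,\mathrm{live}(d) = 100 \cdot \frac{N_\mathrm{live}(d)}{N_\mathrm{initial}}.$$

Counting by eye is laborious, and the hard part is the end of life: worms
barely move during their last days, so "did this animal move since
yesterday?" cannot be answered from a single day's images. The criterion
implemented here is that a worm is dead once it holds the same position
*and posture* for more than one day.

`wormlifespan` automates the count from low-resolution plate image
sequences (nominally 1944 px square, 30 frames per plate per day at 1 fps,
worms projecting roughly 55 x 3 px). Because a real labelled plate corpus
of this kind is not publicly available, the package ships a plate simulator
that generates labelled imagery under the same acquisition geometry, and
every claim the test suite makes is made against that simulator's ground
truth.

## Pipeline

1. **Zones.** A plate image has a homogeneously lit central disk and a
   darker wall annulus with irregular illumination; they are processed
   independently (`partition_zones()`, central radius defaulting to
   0.72 x outer).
2. **Segmentation and centroids.** Dark foreground is segmented by
   background difference: a large-kernel median filter estimates the
   background, the difference is thresholded, and 8-connected components of
   at least 20 px (the minimum worm projection) become candidate worms. The
   day's centroids are taken from the last of the 30 frames
   (`track_daily_centroids()`).
3. **Triplets.** For each current-day centroid, 80 x 80 crops are taken at
   identical image coordinates from the previous, current, and next day's
   images (`crop_triplet()`). No alignment is performed; the window size
   covers the worm length (55 px), the measured maximum plate placement
   displacement (15 px), and a 10 px safety margin.
4. **Stage 1 - motion rules** (`stage1_classify()`). The blob nearest the
   crop centre of the current frame is the anchored worm. If the previous
   or the next frame contains no blob of at least 20 px within 20 px of the
   anchor (15 px displacement + 5 px margin), the worm has assuredly moved:
   verdict ALIVE. Everything else - stationary worms, noisy crops - is
   UNDETERMINED and goes to the network. The wall annulus is handled by
   temporal change analysis instead (`wall_motion_detect()`): pixels whose
   intensity changes more than 0.15 between consecutive frames, with a
   per-stack change count in [2, 10] (low frequency - a body passing, not
   flicker), grouped into regions of at least 20 px.
5. **Stage 2 - CNN-LSTM** (`build_model()`, `train()`, `predict()`). Each
   of the three frames passes independently through a convolutional
   backbone producing one feature vector per frame; a single-layer
   unidirectional LSTM (hidden size 256 at full scale) consumes the 3-step
   sequence; its final hidden state feeds a linear layer to two classes
   with softmax output.
6. **Curves and postprocessing** (`build_curve()`, `monotone_correct()`).
   Daily live counts become a survival curve, forced monotone in two
   periods around the strain's mean life (14 days for N2): upward
   corrections before the split (early errors are missed worms), downward
   after it (late errors are dirt-driven false positives), each run to a
   fixed point.
7. **Validation** (`true_dead_rate()`, `plate_error()`,
   `condition_error()`). Per-class hit rates from the TD/FA/FD/TA confusion
   matrix; curve error as the mean absolute daily difference in survival
   percentage, per plate and pooled per condition.

## The simulator

`sim_config()` fixes the study conditions; `simulate_plate()` and
`generate_dataset()` derive everything from one seed.

* **Worms** are smooth sinusoidal polylines (13 skeleton points, arc length
  45-58 px, width 2-4 px, intensity 0.1-0.35 against a ~0.85 background),
  rendered with anti-aliased edges.
* **Backgrounds** are rendered, not photographed: a bright central disk
  with a mild vignette, a dark wall annulus crossed by bright illumination
  ring arcs, plus a static low-frequency texture field (Gaussian-smoothed
  noise, sd 0.035, scale 6 px) standing in for agar granularity and uneven
  backlight. The texture is a plate property: it moves with the plate's
  daily placement transform. Without it, a globally pooled feature vector
  could not see worm motion at all - motion is observable exactly because
  the worm occludes different background from day to day.
* **Motion.** `perturb_pose()` moves a pose by a target mean per-point
  displacement ("speed", px/day): a dominant rigid translation, a body
  re-orientation of up to ~0.5 rad, and a perpendicular bend, rescaled so
  the mean displacement matches the target within a few percent and arc
  length is preserved. Worms move at `speed` (default 30 px/day) in mid
  life and decelerate linearly over their last five days to 20% of it -
  the slow near-death movers are the cases the network exists for. Death
  days are drawn uniformly on `[3, days + 4]`; dead worms freeze.
* **Within-day motion** interpolates each live worm from yesterday's pose
  to today's across the 30 frames, so wall-zone motion detection has
  something to detect; the last frame of the day is exactly the daily pose.
* **Plate placement**: one rigid transform per day (translation up to
  15 px, rotation up to 2 degrees - the translation bound is the measured
  value, the rotation is our conservative choice), applied to the whole
  frame and recorded so truth centroids map through it.
* **Triplet sets** for training mirror the plate conditions crop-locally:
  live triplets perturb the previous day's pose and keep the next day equal
  to the current one; dead triplets are identical up to the placement
  transforms; a configurable fraction carries a static opaque blob, a
  bystander worm near the crop edge (`neighbor_frac`), or a blob *as* the
  anchored object (`anchor_noise_frac` - the segmentation-error case).
  `replicate_dead_from_live()` builds dead sequences by copying one live
  frame three times with small independent rigid jitters.

What the simulator does **not** model: bacterial lawn and condensation
appearance, egg and larva rendering, worm aggregation contact dynamics
(worms may overlap, but no attempt is made to render realistic clumps), and
real tracker trajectory statistics - the pose dynamics are a synthetic
stand-in. Passing tests on this imagery therefore demonstrate the
pipeline's logic and the classifier's ability to learn the motion/stasis
distinction at the stated scale, not performance on real plates.

## Desk-scale network choices

The full-scale configuration (18-layer residual backbone, 512-dim
features, 224 px inputs, 120 + 10 epochs at learning rates 1e-4 / 1e-5,
batch 64, rotation augmentation by 0/90/180/270 degrees) is expressed in
`net_config()` / `train_config()` defaults and the `"residual18"` backbone,
which this package implements structurally (projection shortcuts, global
average pooling) but without batch normalisation and without bundled
pretrained weights. Training it to convergence is a GPU-scale undertaking;
the package's tests and demos use the `"small_cnn"` backbone (four conv
blocks, global average pool, 64-512-dim features, 32 px inputs) with a
shorter, larger-step schedule (about 25 epochs at 3e-3 / 3e-4, batch 32).

Three design choices were needed to make the sequence task learnable at
this scale, all config-exposed:

* **Feature standardisation** after the global pool (a parameter-free
  layer norm), plus forget-gate bias 1 and small random biases on the
  other LSTM gates. The alive/dead signal is the *magnitude* of the
  across-frame feature difference, whose direction is random from scene to
  scene; a zero-bias LSTM is an odd function of its input around the zero
  state and cannot expose a magnitude to the linear head.
* **Per-sequence feature centering** (`seq_center`): the three frame
  feature vectors are centred on their mean before the LSTM, removing
  scene-specific appearance. Dead sequences become near-zero inputs;
  between-scene variance no longer swamps the temporal signal.
* **A soft radial crop mask** (`center_mask`, fading over 26-38 px from
  the crop centre) applied before resizing. Globally pooled features have
  no locality: a bystander worm wandering fully into the 80 px window of a
  dead worm's crop is otherwise indistinguishable from anchor motion. The
  mask suppresses content far from the anchored object; the training
  generator's `neighbor_frac` distractors cover the residual leakage.

These leave the module contract intact (per-frame feature vector, 3-step
LSTM, linear head on the final hidden state) and default off for the
residual backbone.

Boundary days have no previous (day 1) or next (final day) neighbour; the
cascade reuses the current day's image in the missing slot, which never
fabricates motion. Because the training distribution puts live motion in
the *previous* slot, day-1 UNDETERMINED triplets are time-reversed before
prediction.

## Numerical and procedural choices

* Coordinates are 1-based `(row, col)` with floating-point centroids, the
  native R convention.
* Blob connectivity is 8-connected (3 px diagonal bodies fragment under
  4-connectivity); components are labelled over foreground pixels via
  graph connectivity.
* Segmentation default: median radius 9, threshold 0.15, no morphological
  opening. An opening element at 2-4 px body widths fragments worms into
  multiple blobs (double-counting live worms); the minimum blob area
  already rejects speckle. `opening_size` remains available for speckly
  imagery.
* Stage-1 ties (several equally near blobs) break by larger area, then
  lexicographic centroid; any single qualifying neighbour blob suffices to
  route a triplet to the network.
* Monotone correction runs each period to a fixed point, making the
  operation idempotent and insensitive to scan order; equal counts at the
  split are left untouched (strict inequality triggers corrections).
* The demo assay is 10 days, so its correction split defaults to the mean
  of the simulated death distribution, `floor((days + 7) / 2)` = 8, rather
  than the 14-day N2 value used at full scale.
* `percent_live()` flags but never clamps counts above the initial
  population; the raw overcount is visible to the caller.

## Problem sizes

The shipped demo and the reproduction script use: 1200 training + 200
validation simulator triplets, 24 + 3 training epochs, and five simulated
plates of 6 worms over 10 days at 600 px. Plates are rendered at 600 px
rather than 1944 px with proportionally fewer worms, keeping the worm
density per area within a factor of ~4 of the full-scale plates; worm size
in pixels is unchanged, so crops, area thresholds, and distance rules carry
over exactly. On one CPU core the whole demo runs in roughly ten minutes.
At these sizes the end-to-end mean plate error against simulator truth
comes out around 10% (the training run's draw moves it a few points either
way); the dominant residual errors are slow near-death live worms
read as dead, occasional bystander-motion false alives, and merged blobs
when worms touch.

## Known limitations

* The stage-2 classifier is trained per run at desk scale; no pretrained
  checkpoint is shipped, and the residual18 path is structural fidelity,
  not a performance claim.
* Aggregates (several worms in one blob) anchor a single triplet: the
  count loses the extra worms until they separate. Identity tracking
  across days is out of scope by design.
* The wall-zone detector counts low-frequency motion regions, not worms;
  two worms moving through one region read as one.
* Real-plate phenomena - condensation, lawn texture, decomposition - are
  absent from the simulator, so error rates here do not transfer to real
  imagery.
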