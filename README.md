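# finpose

Markerless pose tracking and swim kinematics for embryonic and larval
zebrafish, as an R package with no deep-learning framework dependency.

High-throughput behavioral assays — touch-evoked escape responses recorded at
1000 Hz, visuomotor (light/dark) responses in 24-well plates at 100 Hz — need
software that tracks body landmarks robustly even with probes in the field of
view, works on multiwell layouts, and runs without GPUs. finpose provides the
whole desk-scale pipeline for researchers running such assays:

* **Heatmap keypoint regression.** Up to 10 keypoints along the
  rostral–caudal axis are regressed as 2D Gaussian heatmaps
  `t_k(p) = exp(-||p - mu_k||^2 / (2 sigma^2))` at half the input resolution,
  decoded back to subpixel coordinates with a baseline-subtracted 3×3
  centroid. Accuracy is scored as PCK (fraction of keypoints within a radius)
  and as relative accuracy between ablated and full training data.
* **A compact isotropic CNN.** An 8×8 pixel unshuffle patchifies the frame;
  N inverted-bottleneck residual blocks (slimmed to one instance
  normalization and one hard swish each, with squeeze-and-excitation) run at
  a single internal resolution; the outro restores resolution with a pixel
  shuffle. A hierarchical encoder–decoder is included for comparison, plus
  exact parameter counting and theoretical-minimum training-memory
  accounting. The network core (forward, backward, AdamW) is implemented in
  the package itself -- BLAS matrix products plus two compiled depthwise
  kernels -- and is finite-difference-checked in the tests.
* **The full training recipe.** MSE heatmap loss; AdamW (β₁ = 0.9,
  β₂ = 0.95, ε = 1e-6, decoupled weight decay 1e-5 on convolution weights
  only); batch 16 with exact gradient accumulation; Xavier initialization
  with a zeroed final layer (so the untrained network outputs exactly zero);
  label-consistent on-the-fly augmentation (gamma, brightness, one composed
  affine, standardization, noise); 75/25 train/validation splits; a
  data-ablation experiment driver.
* **Kinematics.** Per-frame speed, the signed rostral–caudal bend angle
  (turning-angle sum; 150° for 7 points on a semicircle), high-amplitude bend
  events (|peak| ≥ 110°), swim bouts (speed > 2 mm/s), post-stimulus windows
  (5 s), 1 s mean-filter presentation smoothing, and tidy CSV exports that
  feed external statistics software.
* **A seeded synthetic-fish generator** — curved, tapered dark larvae on
  bright well backgrounds with optional well rims, probe occluders,
  illumination gradients and noise, with exact ground-truth keypoints and
  scripted bout/bend movies — so the entire pipeline is testable without any
  recordings.

## Worked example

```r
library(finpose)

# 1. synthesize a labeled dataset (128 frames, 1 keypoint, 64 px wells)
ds <- generate_dataset(128, n_keypoints = 1,
                       ranges = scene_ranges(frame_size = 64), seed = 1)
sp <- split_dataset(ds, 0.75, seed = 1)

# 2. train a tiny isotropic network (64x64 input, M = 8, N = 4, 4x4 patches)
cfg <- network_config(H = 64, M = 8, O = 1, N = 4, patch = 4)
res <- train(build_network(cfg), sp$train, sp$val,
             tcfg = train_config(learning_rate = 6e-3, n_updates = 600),
             ccfg = codec_config(correctness_radius = 2))
tail(res$history, 1)
#>   update  train_loss    val_loss wall_time_s
#> 6    600 0.001996483 0.001038935      60.208

evaluate_network(res$net, sp$val, res$stats,
                 codec_config(correctness_radius = 2))[c("loss", "pck")]
#> $loss
#> [1] 0.001038935
#> $pck
#> [1] 0.9375
```

The validation loss falls from the zero-output initial value (the mean squared
target, ≈ 0.01 here) by an order of magnitude, and 93.75% of validation
keypoints land within 2 px of the ground truth.

```r
# 3. kinematics on a scripted movie (ground truth, no network in the loop)
script <- trajectory_script(
  framerate = 100, duration = 4, mm_per_px = 0.1,
  bout_schedule = data.frame(start = c(0.5, 2.0), duration = c(0.3, 0.4),
                             peak_speed = c(6, 3.5)),
  bend_schedule = data.frame(peak_time = 1.2, peak_angle = 130),
  body_length = 40)
mv <- generate_trajectory_movie(script, scene_spec(frame_size = 512),
                                render = FALSE)
detect_bouts(compute_speed(mv$truth), 100, kinematic_config())
#>   start_time end_time duration peak_speed
#> 1       0.53     0.77     0.24   5.991777
#> 2       2.08     2.32     0.24   3.497302
```

Both scripted bouts are recovered: a bout spans the frames with speed above
the 2 mm/s threshold, so the detected intervals are the supra-threshold cores
of the scheduled half-sine pulses, and the peak speeds match the scheduled 6
and 3.5 mm/s within one-frame discretization. The scheduled 130° bend is
classified as one high-amplitude body bend.

A thin command-line wrapper covers the same pipeline
(`inst/cli/finpose.R synth|train|eval|ablate|track|analyze|bench`).

## Documentation

The methods vignette (`vignettes/finpose-methods.Rmd`) describes the model
and its assumptions, every tunable parameter with units and defaults, the
numerical choices (coordinate conventions, decoder baseline subtraction,
footprint accounting rules), what the synthetic generator emulates and what
it deliberately does not, and known limitations.
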