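---
title: "Heatmap pose tracking and swim kinematics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heatmap pose tracking and swim kinematics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

finpose is a desk-scale toolkit for markerless pose tracking of embryonic and
larval zebrafish and for the kinematic analysis of their escape and visuomotor
behavior. This vignette is the package's own account of the underlying models,
the tunable parameters and their defaults, the numerical choices, and what the
synthetic test bed does and does not establish about real recordings.

## The regression model

Up to 10 anatomical keypoints along the rostral-caudal body axis are tracked
per frame. Rather than regressing coordinates directly, the network regresses
one probability heatmap per keypoint: the training target for keypoint $k$ at
heatmap pixel $p$ is

$$ t_k(p) = \exp\left(-\frac{\lVert p - \mu_k \rVert^2}{2\sigma^2}\right), $$

a two-dimensional Gaussian centered on the label $\mu_k$ mapped to heatmap
coordinates. Heatmaps live at half the input resolution; with 0-based
pixel-center coordinates the input coordinate $x$ maps to heatmap coordinate
$x/2 - 0.25$, which keeps the round-trip bias of the scale change below a
quarter input pixel. Training minimizes mean squared error between predicted
and target heatmaps.

**Decoding.** The predicted keypoint is the channel's global maximum (ties
broken at the lowest row-major index), refined to subpixel precision by an
intensity-weighted centroid over the 3x3 neighborhood after subtracting the
neighborhood minimum. The baseline subtraction matters: wide Gaussians
($\sigma \gtrsim 1.5$ heatmap px) have flat shoulders, and a plain centroid is
biased toward the peak pixel by up to $\approx 0.5$ heatmap pixels, violating
the half-input-pixel round-trip bound this package guarantees (and tests) for
$\sigma \in [1, 4]$. With baseline removal the worst-case round-trip error is
0.49 input px across that range. The channel peak value is reported as a
confidence; an all-zero channel is flagged undetected with confidence 0.

**Codec parameters.** $\sigma$ defaults to 2 heatmap pixels: small enough that
subpixel decoding resolves ~1.5 input px, large enough for smooth gradients
early in training. Label "wiggle" -- isotropic Gaussian jitter of the target
center, SD 0.5 input px, applied during training-target generation only (the
image is untouched) -- is a mild regularizer against label overconfidence.
Accuracy is scored as PCK: the fraction of keypoints with Euclidean error
*strictly* below a radius (3 px for the 7-keypoint escape-response setting,
1.5 px for single-keypoint multiwell tracking; both interpreted as input-image
pixels). The strict inequality is a convention; real-valued errors make the
boundary a measure-zero event.

## Network architectures

The default macro-architecture is *isotropic*: an 8x8 pixel unshuffle folds
the grayscale input into $64$ channels at $1/8$ resolution, a pointwise
convolution projects to $M$ middle channels, and $N$ residual blocks process
this single internal resolution. The outro expands channels by the ratio
$E = 2$, applies hard swish and spatial dropout (probability 0.05), projects
to $16\,O$ channels and restores resolution with a 4x4 pixel shuffle, yielding
$O$ heatmaps at half the input resolution. Two reference configurations are
built in:

| preset | input | M | O | N | output |
|---|---|---|---|---|---|
| `preset_touch()` | 512x512 | 32 | 7 | 10 | 256x256 |
| `preset_visuomotor()` | 256x256 | 16 | 1 | 10 | 128x128 |

A *hierarchical* encoder-decoder is included for comparison: a 4x4/stride-2
intro convolution and two 2x2/stride-2 downsampling stages reach $1/8$
resolution (where the $N$ blocks run with $M$ channels), mirrored by two
2x2/stride-2 transposed convolutions; channel widths halve per 2x resolution
step. No skip connections bridge the down and up paths: the reference design
is a pure encoder-decoder, and adding U-Net-style skips would change the
memory accounting this comparison is about; this was a genuinely open design
point and is noted as such. The isotropic network carries *more* parameters
than the hierarchical one at the touch configuration (82,416 vs 76,631) yet a
considerably *smaller* theoretical minimum training footprint, because no
activations are retained at 1/2 or 1/4 resolution.

**The residual block.** The baseline block is the MobileNetV3 inverted
bottleneck: 1x1 expansion ($M \to EM$), depthwise 3x3, squeeze-and-excitation
(4x reduction on the expanded channels, ReLU then hard sigmoid), 1x1
projection, with a normalization after each convolution and hard swish after
the first two. The *slim* variant keeps exactly one normalization and one
hard swish. Which ones to keep is consequential; the default keeps the
normalization after the depthwise convolution and the hard swish after the
expansion. The reference description does not pin the winning placement, so
all six keep-combinations remain constructible (`slim_norm`, `slim_act`) and
the default is documented as a choice, not a certainty.

**Normalization.** Instance normalization is the default: it is
batch-size-independent, so gradient accumulation over single-sample
micro-batches reproduces large-batch gradients *exactly* (a property the test
suite asserts to 1e-5 relative norm, and asserts to *fail* for batch
normalization, whose statistics couple samples). Batch, layer and group
normalization (8 groups) are available. All normalizations use
$\varepsilon = 10^{-3}$; batch normalization keeps running statistics with
momentum 0.9.

**Initialization.** Xavier normal for all convolution weights, gain
$\sqrt{2}$ when a nonlinearity follows (directly or through a normalization),
gain 1 otherwise; the projection convolution of each residual block is scaled
by $1/\sqrt{N}$; the final convolution and all biases are zeros. The zeroed
final layer makes the freshly initialized network output identically zero, so
the initial loss equals the mean squared target -- a property the tests pin to
1e-6 against an independent codec-side computation.

## Training recipe

AdamW with $\beta_1 = 0.9$, $\beta_2 = 0.95$, $\varepsilon = 10^{-6}$;
decoupled weight decay $10^{-5}$ applied to convolution weights only (never
biases or normalization parameters); batch size 16 with gradient accumulation
to the configured effective batch; 6000 parameter updates at the reference
scale; learning rate $5 \times 10^{-4}$ (touch preset) or $1 \times 10^{-4}$
(visuomotor preset); no learning-rate schedule. Batches are sampled uniformly
with replacement per update -- update-centric bookkeeping matches a recipe
stated in parameter updates rather than epochs; this is a documented choice,
as the reference does not state the epoch structure. Reductions run in a
fixed order on one thread, so a run is bit-reproducible given (seed, config).
Validation is evaluated in evaluation mode (no augmentation, no dropout,
running statistics for batch normalization) every `eval_interval` updates.

Augmentation is applied on the fly to the training split only, in a fixed
order: photometric (gamma, brightness) -> one composed geometric affine
(resize, flips, rotation, pad/crop translation) -> standardization (mean/SD
pooled over the training split's pixels) -> Gaussian noise. Composing the
geometric operations into a single affine avoids compounding interpolation
loss and makes the keypoint transform exact; images are bilinearly resampled
with the image median as border fill, keypoints are transformed by the exact
affine. The magnitudes are package choices (the reference lists the
operations but not their strengths): gamma log-uniform in [0.75, 1.33],
brightness +/-0.1, resize +/-10%, rotation uniform over the full circle (fish
orientation in a well is unconstrained), translation up to +/-5% of the side,
flip probability 0.5 per axis, post-standardization noise SD 0.05. A
transform that pushes every keypoint out of frame is resampled (20 tries)
before erroring.

## Memory-footprint accounting

`theoretical_min_footprint()` charges 4 bytes per scalar for: parameters,
gradients, two AdamW moment buffers, the activations each layer must retain
for its backward pass (one micro-batch), the input/target buffers, and one
workspace buffer the size of the largest layer output. The accounting rules:
buffers are allocated up front and never repurposed; depthwise convolutions
use implicit padding (no padded copies charged); and gradient accumulation is
used to the fullest extent that does not change results -- so the retained
activations are charged for a *single sample* unless batch normalization
forces the whole micro-batch through jointly. Consequently the footprint is
independent of the effective batch size for batch-independent normalizations,
and strictly larger for batch normalization at the same dimensions.

## The synthetic test bed

Because no public labeled dataset accompanies the reference recordings, the
package carries a seeded generator that every other module is tested against.
A larva is rendered as a constant-curvature arc midline with a linearly
interpolated taper of half-widths (defaults from ~5% of body length at the
head to ~1% at the tail tip), drawn as an anti-aliased union of disks, dark
on a bright background, then optically blurred and corrupted with seeded
Gaussian noise. Scenes add optional well rims, probe-like bar occluders (which
may overlap the fish without invalidating labels), and corner-to-corner
illumination gradients. Keypoints are exact closed-form points on the midline
at arc-length fractions $i/(K-1)$; a single keypoint sits at the head end
(the between-the-eyes point of a real larva). One root seed is split into
per-frame seeds through a fixed counter scheme, so datasets are byte-identical
across runs.

Scripted movies drive the *head* keypoint along half-sine speed pulses (swim
bouts) and superimpose triangular pulses of the chord-based bend angle (body
bends), with event times snapped to the frame grid. Anchoring translation at
the head means bends do not displace the reference keypoint, so the scripted
speed equals the measured frame-to-frame speed exactly and the kinematics
stack can be validated against exact ground truth. Bend amplitudes are
specified in measured (chord) angle units; the generator sets the underlying
arc curvature to $\kappa = \theta\,(K-1)/(K-2)$ so the angle read off $K$
keypoints reproduces the scheduled peak exactly.

What passing synthetic tests shows: the codec, augmentation, optimization,
decoding and kinematics pipelines are internally consistent and the network
can learn real localization structure from realistic-looking frames. What it
does not show: robustness to the full variability of real recordings --
defocus beyond mild blur, shadows, water-surface artifacts, multiple animals,
or body shapes far from a constant-curvature arc. Dataset sizes in tests
(dozens to low hundreds of frames) are chosen for test speed, not fidelity.

## Kinematic readouts

All readouts operate on per-frame keypoints with a uniform time base and an
explicit `mm_per_px` calibration (never guessed; typically derived from the
known well diameter).

- **Speed**: $\lVert p_t - p_{t-1} \rVert \cdot \text{mm/px} \cdot f$ at the
  reference keypoint (default: the most rostral), first frame 0. Speeds are
  always computed from raw positions; the 1 s centered mean filter
  (`smooth_series()`) is for presentation traces only.
- **Rostral-caudal angle**: the sum of signed turning angles between
  consecutive inter-keypoint segments, counterclockwise positive in image
  coordinates. It is invariant under rotation/translation, negates under
  reflection, and reads 150 degrees for 7 points on a semicircle (6 chords,
  5 turns of 30 degrees). A head-to-tail vector angle was the alternative
  construction; the turning-angle sum was chosen because it accumulates
  curvature along the whole body rather than only its endpoints.
- **Bends**: the angle series is segmented at zero crossings; each
  constant-sign segment contributes one peak (maximum magnitude, earliest
  frame on ties). Requiring zero-crossing separation between events -- rather
  than counting every local extremum -- was a documented choice: it makes
  "one bend" robust to small ripples near a peak. Peaks with magnitude at or
  above 110 degrees are high-amplitude body bends.
- **Bouts**: maximal runs with speed strictly above 2 mm/s (exit at or below
  the threshold); single-frame bouts are allowed, and a run open at the end
  of the series closes at the last frame. Duration is run length over
  framerate. Raising the threshold can only drop whole bouts when each bout's
  speed profile is unimodal; on noisy, multi-peaked speed traces it can split
  a run, so bout *counts* should be compared at a fixed threshold.
- **Stimulus summaries**: over `[mark, mark + 5 s)` after a light or dark
  transition -- maximum raw speed, bout count, mean bout duration and mean
  bout peak speed (missing when no bout); windows exceeding the recording
  truncate with a warning. Escape-response summaries report duration
  ($n/f$), path length of the reference keypoint in mm, bend summaries, and
  response progress $t/\text{duration} \in [0, 1]$.

Reference framerates are 1000 Hz for touch-evoked escape recordings and
100 Hz for multiwell visuomotor recordings; a 24-well plate maps to a 4x6 ROI
grid with one animal per ROI. ROIs are letterboxed (aspect-preserving resize
plus median-fill padding) to the network input, and decoded keypoints are
mapped back through the exact inverse to plate coordinates.

## Numerical choices and problem sizes

All computation is double precision; pointwise convolutions and the
squeeze-excitation algebra are BLAS matrix products, the depthwise
convolution forward/backward are small compiled kernels (checked against a
plain R loop oracle in the tests), and the footprint accounting assumes the
4-byte scalars of the reference 32-bit training arithmetic. Normalization uses the biased (1/n) variance. The test
suite and the acceptance checks run scaled-down experiments chosen as a
package decision: a tiny isotropic configuration (64x64 input, M = 8, N = 4,
K = 1, 4x4 patches -- the patch scales with the input so the internal grid
keeps 16x16 sites) trained for 600 updates at learning rate 6e-3 on 128
synthetic frames, where it reaches validation PCK@2 px around 0.85-0.9; and a
two-point data-ablation (25% vs 100% of the training split, 3 seeds, constant
validation split, the same 600 updates -- the overfitting gap between the
ablated and full splits only emerges with enough training) reproducing the
expected ordering of final validation losses. The learning rate for the tiny
configuration was selected from a small sweep (3e-3, 6e-3, 1e-2) by mean
final validation loss across seeds; the reference learning rates (5e-4 /
1e-4) remain the defaults for the full-size presets.

## Known limitations

Single animal per ROI; no multi-peak decoding; 2D only. Training at the full
touch preset (512x512, 6000 updates) is possible but slow -- the numerical
core favors auditability and exact reproducibility over throughput, and
wall-clock speed is explicitly not a claim this package makes. Video files are not decoded; recordings enter as PNG/TIFF
frame sequences. Dataset frames are written as 16-bit TIFF (no installed R
writer produces 16-bit PNG).
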