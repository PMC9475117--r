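---
title: "Smoke removal, self-supervised disparity and anaglyph 3D for binocular endoscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smoke removal, self-supervised disparity and anaglyph 3D for binocular endoscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endostereo)
```

## The problem

A binocular (stereo) endoscope delivers rectified left/right image pairs of
internal tissue.  Two things stand between those frames and a useful 3D
display in surgery: electrocautery smoke, which veils the scene with a
semi-transparent white plume, and the absence of ground-truth depth, which
rules out supervised disparity training.  This package implements a
desk-scale version of a three-stage pipeline:

1. **Desmoking** — a U-Net restores the clean frame from a fogged one,
   trained supervised on synthetically fogged images (clean frame = label).
2. **Disparity estimation** — a convolutional network predicts left and
   right horizontal disparity maps from the left image alone, trained
   *self*-supervised: the right view reconstructed by warping the left view
   through the predicted disparity must match the real right view.
3. **Anaglyph rendering** — the red channel is resampled through the
   disparity and fused with the untouched blue–green channels, giving a
   red/cyan 3D frame with minimal color loss.

Because no deep-learning framework is available to R, the package carries
its own small reverse-mode automatic-differentiation engine (`R/autograd.R`,
`R/ops.R`) with C++ kernels for convolution (im2col + BLAS), transposed
convolution, bilinear resizing, horizontal STN warping and box filtering.
Every kernel's vector–Jacobian product is tested against central finite
differences.

## Sign convention

All modules share one convention: for a rectified pair with the right
camera displaced to the right,

\[ \mathrm{right}(x) = \mathrm{left}(x + d), \qquad d \ge 0 . \]

A left pixel at column \(j\) therefore corresponds to the right image at
column \(j - d^l(j)\): the left view is reconstructed by sampling the right
image at \(x - d^l\), the right view by sampling the left image at
\(x + d^r\), and the left–right consistency term compares \(d^l(j)\) with
\(d^r(j - d^l(j))\).  Warping is backward (gather) with edge clamping, so
rendered views have no holes; this is a deliberate simplification relative
to true occlusion handling.

## Smoke model

Surgical smoke is modeled as an additive, depth-independent, near-grayscale
field: multi-octave value noise shaped by a Gaussian falloff around a random
center, scaled by a density parameter \(d_{rand}\in(0,1]\):

\[ I_{fogged} = \mathrm{clip}_{[0,1]}(I_{clean} + I_{smoke}). \]

Plain clipped addition keeps two properties testable: zero smoke is an exact
identity, and compositing is monotone.  A scalar smoke mask
\(0.30R + 0.59G + 0.11B\) (weights summing to 1) is computed and stored with
each dataset; the baseline desmoking loss uses only images, so the mask is
exposed for extensions rather than consumed.  "Light" fog is one
render+composite pass; "dense" fog applies a second independent pass to the
light result, so dense frames are never darker than light ones.

## Desmoking network

The encoder has seven convolution groups (kernels 7, 5, 3, 3, 3, 3, 3; each
group two convolutions with strides 1 and 2; widths 32–512).  The seventh
group uses stride 1 so the total down-sampling factor is 64 — with seven
stride-2 groups the factor would be 128, which contradicts the stated factor
of 64, and a 256×128 input could not support a 128× reduction.  Before each
group the matching level of a Laplacian pyramid of the input (band-pass
image, 3 channels) is concatenated to the features, re-injecting the fine
detail that down-sampling discards.  The decoder mirrors the encoder with
kernel-3 groups (widths 512–16), bilinear ×2 up-sampling, skip connections
from the matching encoder scale (the full-resolution group takes the input
frame itself as its skip), CBAM attention in the last five groups, and a
1×1 convolution + sigmoid head so the \([0,1]\) range is structural.  The
training loss is the per-pixel L1 deviation between the network output and
the clean label.

Two points were genuinely open and resolved as follows: skip/fusion
concatenation happens *before* the first convolution of each group, and the
decoder up-samples bilinearly (the source describes "up-sampling layers with
steps 1 and 2" without naming the operator; bilinear + stride-1
convolutions avoid checkerboard artifacts and reuse the differentiable
resize kernel).  CBAM placement follows the majority reading ("last five"
decoder groups) and is a configuration switch (`cbam_position = "first5"`)
so the alternative is one flag away.

### Laplacian pyramid

Levels obey \(L_i = G_i - \mathrm{up}(\mathrm{down}(G_i))\) with a separable
binomial \([1,4,6,4,1]/16\) blur (reflective padding, exactly normalized so
constants are preserved) and bilinear (four-neighbor) up-sampling.
Decimation samples through the same half-pixel-center bilinear convention as
the up-sampler — for even sizes, a 2×2 block average of the blurred image.
With strided decimation instead, the down/up round trip is displaced by half
a pixel and the "band-pass" residuals are dominated by that shift; with the
aligned convention a smooth blob concentrates >90 % of its Laplacian energy
in the coarse levels, and collapsing the stack reconstructs the input
exactly by construction.

### CBAM

Channel attention: global average- and max-pooled channel vectors pass
through a shared two-layer bottleneck MLP (ReLU after the first layer,
reduction ratio \(r = 16\), the module's published default, clamped to the
channel count for narrow desk-scale layers), are summed and sigmoid-squashed.
Spatial attention: channel-wise mean and max maps are stacked and convolved
with a single 7×7 kernel, then sigmoid-squashed.  Both are broadcast
multiplied into the features, channel first.

## Disparity network

A 7×7 stride-2 convolution (batch-normalized) preprocesses the left image;
four encoder stages (widths 32–256, each a stride-2 entry convolution +
batch norm + one hierarchical split block in a residual wrapper) reach 1/32
resolution.  The decoder uses 3×3 stride-2 transposed convolutions with
encoder skips; the last four scales (1/8, 1/4, 1/2, 1/1) each emit a
two-channel head mapped through a sigmoid and scaled by
`max_disparity_fraction` (default 0.3) times the width at that scale,
giving bounded nonnegative left and right disparities.  Both eyes are
emitted at every scale because the per-scale losses need both.

**Hierarchical split block (HSB).**  A 1×1 convolution maps the input to the
block width, split into \(s\) groups (default \(s = 5\)).  Group 1 passes
through; each later group's 3×3 convolution sees its split concatenated
with the carried half of the previous group's output; outputs are halved
into carry/emit (carry gets \(\lceil c/2\rceil\) on odd widths, so no
channel is lost), the last group is emitted whole, and a trailing 1×1
convolution restores the designed width inside a residual connection.
Counted against a standard convolution of the same input/output width
(\(k^2 s^2 w^2\) weights), the constructed block is strictly cheaper for
every \(s \in \{2,\dots,6\}\) at \(k = 3\), \(w = 4\) — the package verifies
this by building the block and counting, rather than trusting a printed
formula whose typography is ambiguous.  One HSB per stage is used; the
stage count per encoder level is not pinned down by the source.

**Head initialization.**  Disparity heads start with down-scaled weights and
a bias of −3, so the initial prediction sits near 5 % of the disparity
range (≈1.8 px at width 128) rather than at the sigmoid midpoint (≈19 px).
Photometric losses are only informative within roughly a texture correlation
length of the true offset; starting near the identity warp and growing
outward keeps the search inside that basin.  This is an initialization
choice of the implementation, not a data-dependent calibration.

## Self-supervised loss

Per scale, with images resized to that scale:

* **Photometric reprojection**: per pixel,
  \(pe = \frac{\alpha}{2}(1-\mathrm{SSIM}) + (1-\alpha)\,\mathrm{L1}\) with
  \(\alpha = 0.85\), channel-averaged.  SSIM uses 3×3 box-window local
  statistics (window configurable), constants \(c_1 = (0.01L)^2\),
  \(c_2 = (0.03L)^2\), \(c_3 = c_2/2\) — the standard simplification that
  collapses the luminance·contrast·structure product to the two-term form.
* **Minimum reprojection & auto-mask**: with several source views the
  per-pixel minimum of their errors is used; the binary mask
  \(\mu = [\,\min pe(\text{warped}) < \min pe(\text{unwarped source})\,]\)
  (strict inequality; ties give 0) excludes static/textureless pixels and
  weights only the photometric terms.  In stereo-pair mode the source set
  has one element, and the code is written over lists so nothing changes
  for multi-view extensions.
* **Left–right consistency**: mean \(|d^l(j) - d^r(j - d^l(j))|\) (and
  symmetrically for the right), sampling the other eye's disparity with the
  same bilinear edge-clamped sampler as image warping.
* **Edge-aware smoothness**: mean of \(|\partial_x d|e^{-|\partial_x I|} +
  |\partial_y d|e^{-|\partial_y I|}\), image gradients reduced over channels
  by mean absolute value.

The total per scale is \(\mu\)-masked photometric (both eyes) plus
\(\lambda\) times the consistency and smoothness terms; scales are
*averaged* (summing versus averaging is not specified by the source;
averaging keeps \(\lambda\) meaningful independently of the scale count).
\(\lambda\) is never given a value in the source; the default 0.1 keeps the
photometric term dominant, the usual regime in self-supervised stereo, and
is exposed in `loss_weights()`.

A training-free cross-check, `disparity_search_oracle()`, minimizes the same
photometric error over a finite set of candidate constant shifts per pixel
(box-aggregated).  On synthetic pairs it recovers a constant disparity of 4
exactly at the mode, which validates the loss landscape independently of
any network.

## Synthetic data

`make_stereo_dataset()` fabricates what the pipeline needs and nothing
more: multi-octave value-noise tissue textures (reddish base color, mild
per-channel decorrelation so color carries information, dark Bézier "vessel"
strokes), an analytic disparity field (constant / ramp / smooth blob), the
right view rendered by the shared warp, and optional smoke on both eyes
(same field for both, as a plume between scene and lens would appear).  All
generators are pure functions of their seeds; per-sample seeds derive from
one master seed and are recorded in the dataset manifest.

What this emulates: textured tissue, known horizontal-only disparity,
additive semi-transparent smoke.  What it does not: specular highlights,
occlusion (backward warping fills from edge clamp), instrument motion,
calibration error, photometric differences between the two cameras, depth-
dependent smoke.  Tests passing on these fixtures therefore demonstrate
that the algorithms are implemented correctly and that the training
objectives optimize what they claim — not that the trained weights transfer
to real endoscopy, which requires the full-scale data regime of the
original study.

## Desk-scale study conditions

The published configuration (256×128 inputs, full widths, Adam, learning
rate 1e-4, batch 16, tens of thousands of real stereo-endoscopy pairs, GPU hours) is the
package default (`train_config()`, `desmoke_net_spec()`, `disp_net_spec()`).
The test suite and the acceptance script run the same topologies at
`width_multiplier = 1/8` (widths floored at 4 channels so attention and
split blocks stay non-degenerate):

* desmoking: 64×64 frames, 200 light-fog pairs, batch 16, learning rate
  3e-3, 20 epochs — a few CPU-minutes; judged by held-out PSNR improvement
  over the fogged input (≥ 2 dB expected, ~5 dB typical);
* disparity: 64×128 frames, 200 constant-disparity pairs, batch 8,
  learning rate 1e-2, 15 epochs — judged by median interior error against
  ground truth (≤ 1 px), averaged over three seeds.

The higher desk-scale learning rates compensate for the small problem; they
are configuration, not defaults.

## Numerical choices and degenerate inputs

* Bilinear resizing uses the half-pixel-center (align-corners-false)
  convention everywhere, and the warp is exact at integer coordinates.
* The warp gradient w.r.t. disparity is the analytic two-neighbor
  difference; it is zeroed where the sample clamps at the frame edge.
* SSIM local variances are clamped at 0 before any square root; the
  training path uses the sqrt-free two-term form.
* Box-filter SSIM windows are truncated and renormalized at borders (the
  test oracle mirrors this convention, so equivalence is well defined).
* `gaussian_down` refuses 1-pixel axes; `fusion_stack` emits a zero
  band-pass image where a scale has collapsed to a single pixel.
* Disparity magnitudes are validated against `W/4` before warping;
  `predict_disparity` resizes non-multiple-of-32 inputs internally and
  rescales the disparity values with the width ratio.
* Training aborts with a diagnostic on a non-finite loss rather than
  continuing silently.
* PSNR of identical images is reported as `Inf` (zero MSE), and disparity
  errors refuse an empty valid mask.

## Known limitations

* Backward warping cannot represent occlusion; disoccluded regions take
  edge-clamped values both in data synthesis and rendering (the anaglyph
  renderer offers nearest-valid row inpainting as an alternative).
* The desk-scale trainings demonstrate optimization correctness, not
  clinical performance; headline metrics from the original study's
  full-scale data are out of reach by design.
* Batch statistics (not running averages) are used during training;
  inference uses the running estimates, so tiny batch sizes give noisier
  normalization than a framework-grade implementation.
* The disparity network sees the left eye only; temporal (multi-frame)
  self-supervision is out of scope.
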