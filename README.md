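# endostereo

Smoke removal, self-supervised disparity estimation and red/cyan anaglyph
3D rendering for binocular (stereo) endoscopy — as a self-contained,
desk-scale R package.

## The problem

Electrocautery smoke degrades laparoscopic video exactly when the surgeon
needs it most, and stereo endoscopes deliver rectified left/right pairs
with no ground-truth depth, so depth must be learned without labels.  The
pipeline implemented here:

1. **Desmoking** — a 7-scale U-Net restores the clean frame from a fogged
   one.  Training pairs are manufactured by compositing procedural smoke
   onto clean frames (`I_fogged = clip(I_clean + I_smoke)`), so the clean
   frame is its own label and the loss is the per-pixel L1 deviation
   `L = Σ |I_clean − I_desmoked|`.  Two additions sharpen the restoration:
   each encoder scale receives the matching level of a Laplacian pyramid of
   the input (`L_i = G_i − up(down(G_i))`, binomial blur, bilinear
   up-sampling), and the last five decoder groups carry CBAM attention
   (`F″ = M_s(M_c(F)⊗F) ⊗ (M_c(F)⊗F)` with sigmoid-gated channel and 7×7
   spatial attention maps).
2. **Disparity** — an encoder of hierarchical split blocks (HSB: grouped
   3×3 convolutions whose outputs are halved into carry/emit, strictly
   cheaper than a standard convolution of the same width) feeds a decoder
   that emits left/right disparity at four scales,
   `d = sigmoid(head) · 0.3 · W`.  Training is self-supervised under the
   convention `right(x) = left(x + d)`: per scale, a photometric error
   `pe = (α/2)(1−SSIM) + (1−α)·L1` (α = 0.85) between each eye and its
   reconstruction warped from the other eye, an auto-mask
   `μ = [pe(warped) < pe(source)]` that drops static/textureless pixels,
   left–right disparity consistency `|d^l(j) − d^r(j − d^l(j))|`, and
   edge-aware smoothness `|∂d| e^{−|∂I|}`, combined as
   `L = μ(L_p^r + L_p^l) + λ(L_lr^l + L_lr^r + L_ds^l + L_ds^r)`.
3. **Anaglyph** — the red channel is resampled through the (optionally
   amplified) disparity and fused with the untouched blue–green channels.

There is no deep-learning framework in the dependency set: the package
ships a small reverse-mode autograd engine with Rcpp/Armadillo kernels
(im2col convolution, transposed convolution, bilinear resize, horizontal
STN warp, box filter), each gradient verified against finite differences in
the test suite.  A synthetic stereo-endoscopy generator (value-noise tissue
textures, analytic disparity fields, rendered right views, procedural
smoke) makes every stage testable without external data.

## Worked example

```r
library(endostereo)

# a synthetic stereo dataset with known constant disparity of 4 px
samples <- make_stereo_dataset(200, texture_spec(shape = c(64, 128)),
                               disparity_spec("constant", 4), "none", seed = 21)

# train the disparity network at desk scale (about 4 CPU-minutes)
net <- train_disparity(samples, disp_net_spec(width_multiplier = 1/8),
                       train_config(input_size = c(64, 128), epochs = 18,
                                    batch_size = 8, learning_rate = 1e-2, seed = 1))
print(net)
#> Self-supervised disparity network (HSB encoder, 4-scale decoder)
#>   width multiplier: 0.125  groups s: 5  parameters: 49624
#>   trained 18 epochs; final loss: 0.02558

held <- make_stereo_dataset(1, texture_spec(shape = c(64, 128)),
                            disparity_spec("constant", 4), "none", seed = 99)[[1]]
d <- predict_disparity(net, held$left)
median(d[5:60, 9:120])          # interior median of the predicted map
#> [1] 3.795759                  # true value: 4 px; error ~0.2 px

# no-training cross-check: exhaustive photometric search over candidates
oracle <- disparity_search_oracle(held$left, held$right, 0:8)
table(oracle[5:60, 9:120])[["4"]] / (56 * 112)
#> [1] 1                         # every interior pixel lands on 4 px

# 3D display
ana <- make_anaglyph(held$left, d)
write_image_rgb(ana, "anaglyph.png")
```

The printed numbers mean: the self-supervised objective alone (no labels
anywhere in training) pins the constant disparity to within a fifth of a
pixel, and the exhaustive photometric minimizer — a pure, training-free
implementation of the same error — confirms the loss landscape has its
minimum at the true offset.

For desmoking, `fog_dataset()` + `train_desmoke()` at the same desk scale
(64×64, 200 light-fog pairs, 20 epochs) raises held-out PSNR of fogged
frames by about 5 dB; see `vignettes/endostereo-methods.Rmd` for the model
and its assumptions, and `inst/cli/endostereo.R` for shell entry points
(`synth-data`, `fog`, `train-desmoke`, `desmoke`, `train-disparity`,
`predict-disparity`, `anaglyph`, `evaluate`, `pyramid`).

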