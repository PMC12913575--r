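---
title: "dualseg: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dualseg: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

`dualseg` segments two nested structures from a 2-D slice: an organ (e.g. a
kidney) and a mass protruding from it. The two structures have very
different statistics — the organ is a large region with strong contrast
against the background, the mass a small local protrusion whose contrast is
mostly against the *organ* — so the package uses two specialised tracks and
a deterministic fusion.

**Track 1 (organ).** A U-Net whose encoder alternates a vision-transformer
block with a multi-scale convolution block at each of four resolutions.
The transformer block is pre-norm:

    v = x + MHSA(LN(x));    y = v + FFN(LN(v))

and captures long-range context; the multi-scale block sums parallel
same-padding convolutions with kernel sizes 1, 3 and 5, then applies batch
normalisation and ReLU, preserving local high-resolution detail. A patch
embedding (stride-2 2×2 convolution plus a learned additive positional
table) performs the first spatial halving; the remaining three halvings are
stride-2 max pools. With 224×224×3 inputs the encoder ladder is
112²×64 → 56²×128 → 28²×256 → 14²×512, the bridge widens to 14²×1024 with a
3×3 convolution and ReLU, and the decoder's four stages each apply a 2×2
stride-2 transposed convolution, add a 1×1-projected encoder skip at the
matching resolution (the first three stages), and finish with a 3×3
convolution and ReLU, ending at 224²×64. A 1×1 convolution and sigmoid give
the organ probability map.

**Track 2 (mass).** The protuberance detection network receives the
organ-masked image — the preprocessed image multiplied by Track 1's
*predicted* organ mask. Ground-truth masks never enter this input at
inference; the no-leakage contract is asserted by a test that corrupts all
ground-truth masks and verifies that predictions are unchanged. The stem is
a 3×3 convolution + batch norm + ReLU; each of the following stages applies
stride-2 max pooling, the centre-surround contrast operator
`Δ(x) = x − boxavg₃(x)`, and a widening 3×3 convolution with ReLU. The final
contrast features are refined by a depthwise-separable 3×3 convolution,
batch norm and LeakyReLU (slope 0.01); contrast and border branches are
concatenated, reduced to one channel by a 1×1 convolution, passed through a
sigmoid, bilinearly upsampled to the input size and thresholded strictly at
τ (default 0.5 — a tie at exactly τ is background, so an all-0.5 map yields
an empty mask).

**Fusion.** `fuse_masks()` overlays the two binary masks into labels
{0 background, 1 organ, 2 mass}; a mass pixel outside the predicted organ is
suppressed to background. Fusion is deterministic and pixelwise: it can only
remove out-of-organ false positives from the mass mask, so the fused mass
score can drop below the raw mass-track score only where the organ mask
erases true mass pixels.

**Training.** Both tracks minimise the soft Dice loss
`1 − (2|P∩G|+ε)/(|P|+|G|+ε)` (ε = 1e-6) with Adam. The published recipe —
learning rate 0.001, batch 32, 35 epochs — is the default; the alternative
published rate 0.0001 is available as `lr_preset = "slow"`. Training is
sequential: Track 1 first, then Track 2 on masked images built from the
trained Track 1 (the only ordering consistent with the masked-input
definition). The best epoch by validation Dice is restored at the end.

## Implementation

No deep-learning framework is used: convolutions (im2col + GEMM), transposed
convolutions, pooling, layer/batch normalisation, multi-head attention, the
depthwise-separable convolution, all backward passes, the Dice-loss gradient
and Adam are implemented in the package. Feature maps are `(H, W, N, C)`
arrays, so channel mixing is one BLAS product per layer. The hot kernels
(convolution, attention core, pooling, box filter, bilinear resampling) are
compiled (Rcpp/RcppArmadillo) and run in single precision — the networks'
working precision — while plain-R double-precision reference implementations
of every kernel are kept and compared against the compiled path in the test
suite; the reference backward passes are checked against finite differences.

Attention over large token grids is quadratic, so each transformer block
average-pools its (layer-normalised) token grid by the smallest power-of-two
factor that brings the count under `attn_token_limit`, attends on the pooled
grid and broadcasts the output back before the residual add. The default
limit of 4096 tokens leaves grids of 64×64 and smaller untouched (the
224-px configuration pools its first stage by 4); the desk preset lowers
the limit to 256 tokens as a CPU-budget choice.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `patch_size` | 2 | embedding stride; realises the first halving of the printed resolution ladder |
| `stage_widths` | 64–512 | encoder widths (published feature-map shapes); Table-style 16–128 alternative via the `gray-256` preset |
| `bridge_width` | 1024 | bottleneck channels |
| `attn_heads`, `ffn_expansion` | 4, 2 | transformer block size (unpublished; chosen small, configurable) |
| `hrnet_kernels` | 1, 3, 5 | parallel convolution scales (S = 3) |
| `contrast_width`, `border_width` | 1024, 512 | PDN branch widths; their sum is the published 1536-channel fused tensor |
| `threshold` τ | 0.5 | mass-mask threshold, strict `>` |
| `clahe_clip_limit`, `clahe_tile_grid` | 2.0, 8×8 | contrast-limited adaptive histogram equalization |
| rotation limit | ±20° | the value stated repeatedly in the methodology; the alternative published 15° is reachable via `augment_config()` |
| learning rate | 0.001 | published table value; 0.0001 preset kept |
| `width_divisor` | 1 | divides all widths for desk-scale runs |

Units: all boundary metrics are in pixels unless `pixel_spacing` is set, in
which case distances are in the spacing's physical units.

## The phantom generator

`phantom_spec()` draws an elliptical "organ" (semi-axes 12–20 px in a 64-px
frame, random centre jitter and rotation) with a disc "mass" (radius 4–9 px)
centred on the organ contour so that it protrudes; the organ mask is the
ellipse united with the mass, which guarantees mass ⊆ organ. Intensities are
piecewise constant (background 30, organ 110, mass 190 on [0, 255]) plus a
smooth Gaussian texture field (sd 5) and i.i.d. Gaussian noise (sd 8),
clipped to [0, 255]. Everything is a deterministic function of
`(seed, index)`.

The phantoms emulate the *geometry* of organ-with-mass slices — a bright
protuberance on a brighter-than-background organ — and the intensity
ordering is enforced so the contrast-driven mass track has a learnable
signal. They do not emulate CT physics, anatomical texture, neighbouring
organs, partial-volume boundaries, or slices without masses. Passing the
scaled-down experiment therefore demonstrates that the architecture, losses,
gradients and orchestration work end to end — not that clinical performance
transfers.

## The desk-scale experiment

The scaled configuration used by the tests and the acceptance script:
250 phantoms at 64×64×1, split 200/10/40 (`r_val = 0.04`, `r_test = 0.16` —
the published 80/10/10 rule applied so that 200 train and 40 test samples
result, with a small validation set for best-checkpoint selection);
`width_divisor = 4` (widths 16–128, bridge 256); batch 16; Adam 0.001;
10 epochs per track; flip and ±20° rotation augmentation only (the published
elastic-transform parameters are calibrated for 224-px clinical slices and
are nearly a no-op at 64 px, and intensity jitter adds nothing to
piecewise-constant phantoms). The PDN desk preset uses three pooling stages
instead of four, keeping its probability grid at 1/8 of the input
resolution: the published 256-px/4-stage configuration has a 1/16 grid,
which at 64 px would be coarser than the phantom masses themselves.

## Numerical choices and degenerate inputs

- Dice/IoU are ε-smoothed; two empty masks score 1. Boundary metrics refuse
  empty masks (opt-in zero sentinel for an identical empty pair). Boundaries
  are 4-connectivity erosion residues; HD95 uses the default quantile
  estimator over the pooled directed distances.
- `Δ` uses a count-normalised 3×3 window average (borders divide by the
  actual window size), so a spatially constant map maps to exactly zero
  everywhere — the property the contrast operator is defined by.
- The split rule is floor on the train share, then floor on the validation
  share of the remainder; the floor is guarded against floating-point droop
  (10,015 × 0.8 is 8,011.999… in IEEE doubles). This is the unique simple
  rule reproducing the published partition tables.
- Masks binarise at value > 0 on load; 8-bit exports commonly store
  foreground as 255.
- Initialisation: He-normal convolutions, Glorot attention/linear weights,
  zero biases and positional table, batch-norm γ = 1. Max-pool ties break
  to the first window element scanned (deterministic).
- CI aggregation uses the population SD (a single value has SD 0) and a
  fixed 1.96 multiplier, matching the published interval arithmetic.
- A constant image passes through contrast enhancement unchanged (degenerate
  histogram); the global equalization step is a monotone 256-bin cdf map.

## Open design points, resolved

- The mass-track fusion's printed 1536 channels equal 1024 + 512, so the
  concatenation joins the contrast branch with the border-refined branch
  (the equation's repetition of one symbol is read as a typo).
- The fusion operator between the two tracks is the minimal deterministic
  overlay; no learned fusion network is described, so none is built. The
  "boundary refinement" mentioned alongside fusion names no operator and is
  left out.
- Dice loss is `1 − DSC`: every published (loss, dice) pair satisfies it
  exactly, while the printed sign convention would make the loss negative.
- Dataset masks are ambiguous between organ and tumor semantics, so a sample
  carries an organ mask and an optional mass mask and both evaluations are
  reported.
- Whether the SD aggregates over seeds or samples is ambiguous; the report
  aggregates per-sample values, and multi-seed runs can be aggregated with
  the same helper.

## Known limitations

- Parameter counts of the published models are not reproducible from the
  text (two different architectures are printed with the same count); the
  package reports its own counts and the exact fp32 size arithmetic.
- Training at the full 224/256-px geometry is functional but slow on a
  single CPU (the package is tuned for the desk scale); no GPU path exists.
- The attention-pooling approximation changes the attention operator
  whenever a grid exceeds the token limit; it is a documented contract-level
  approximation, reported via `options(dualseg.verbose = TRUE)`.
- Only 2-D slices are supported; the NIfTI adapter flattens volumes to
  axial PNGs.
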