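# dualseg

Dual-track segmentation of an organ and a protuberant mass from 2-D image
slices, implemented entirely in R (with small compiled kernels for the hot
numerical paths).

Automatic delineation of a kidney and of a tumor bulging from its surface is
a two-part problem: the organ is large and high-contrast against the
surrounding tissue, while the mass is a local, low-contrast protrusion inside
(and on the boundary of) the organ. `dualseg` addresses the two parts with
two cooperating networks:

- **Track 1 — transformer-enhanced U-Net.** A U-shaped encoder–decoder whose
  encoder interleaves vision-transformer attention blocks
  (`LN → MHSA → +residual`, then `LN → FFN → +residual`) with multi-scale
  convolution blocks (parallel 1/3/5 kernels summed, batch-normalised,
  ReLU). A stride-2 patch embedding plus three stride-2 max pools give the
  resolution ladder 224 → 112 → 56 → 28 → 14 with widths 64 → 512, a
  1024-channel bridge, and an additive-skip decoder back to full resolution.
  A 1×1 sigmoid head yields the per-pixel organ probability `S_k`.
- **Track 2 — contrast-driven protuberance detection network (PDN).** The
  organ-masked image `I ⊙ Ŝ_k` (built from Track 1's *prediction*, never
  from ground truth) passes through a convolutional stem and repeated
  [max-pool → centre-surround contrast Δ(x) = x − boxavg₃(x) → widening
  convolution] stages, then a depthwise-separable convolution with batch
  normalisation and LeakyReLU refines boundaries; the contrast (1024-ch) and
  border (512-ch) branches are concatenated (1536 channels at 16×16 for a
  256-px input), reduced by a 1×1 convolution, passed through a sigmoid,
  bilinearly upsampled and thresholded at τ to the mass mask `S_m`.
- **Fusion.** `S_final = Φ(S_k, S_m)` is the deterministic overlay: label 2
  (mass) where both masks agree, label 1 (organ) where only the organ mask
  fires, 0 elsewhere; mass pixels outside the organ are suppressed, so
  mass ⊆ organ always holds.

Both tracks are trained with the soft Dice loss `1 − (2|P∩G|+ε)/(|P|+|G|+ε)`
and Adam (learning rate 0.001, batch 32, 35 epochs at the published scale);
evaluation reports Dice, IoU (`D = 2J/(1+J)`), the 95th-percentile Hausdorff
distance and the average symmetric surface distance, aggregated as
mean ± SD with a 1.96·SD normal-approximation 95% CI.

Every layer, every backward pass, the Dice-loss gradient and the Adam
optimizer are implemented in this package (R plus a few Rcpp/RcppArmadillo
kernels for convolution, pooling and attention); no deep-learning framework
is used. A synthetic phantom generator (bright elliptical organ with a
brighter disc mass attached to its contour, plus texture and noise) provides
paired images and masks so the whole pipeline trains and evaluates on one
CPU core in minutes.

## Worked example

```r
library(dualseg)
spec <- phantom_spec(seed = 777)          # 64 x 64 organ-with-mass phantoms
samples <- generate_samples(250, spec)
cfg <- train_config(seed = 1)             # desk preset: Adam 1e-3, batch 16, 10 epochs
res <- run_dual_track(samples, cfg, quiet = TRUE)
print(res$report)        # organ segmentation on the 40 held-out phantoms
print(res$mass_report)   # fused mass segmentation (label == 2)
n <- count_parameters(res$vhu)
cat("organ-track parameters:", n, "->", model_size_mib(n), "MiB fp32\n")
```

```
metrics_report: 40 samples
  dice  0.9808 +/- 0.0039  [0.9731-0.9885]
  iou   0.9623 +/- 0.0076  [0.9475-0.9772]
  hd95  1.0000 +/- 0.0000  [1.0000-1.0000]
  assd  0.3445 +/- 0.0746  [0.1982-0.4907]
  confusion: TP 35456 FP 149 FN 1219 TN 127016
metrics_report: 40 samples
  dice  0.7012 +/- 0.1887  [0.3313-1.0711]
  iou   0.5689 +/- 0.2034  [0.1701-0.9676]
  confusion: TP 3780 FP 261 FN 2197 TN 157602
organ-track parameters: 877345 -> 3.35 MiB fp32
```

The first block is Track 1 + fusion on the held-out phantoms: the organ is
recovered with Dice 0.98 and sub-pixel mean surface error (distances are in
pixels). The second block is the fused mass layer: Dice 0.70 against masses
that are only a few pixels across, predicted from an 8×8 probability grid.
The mass track alone scores slightly lower (`res$pdn_mass_report`); fusion
removes its out-of-organ false positives.

A command-line front end with `generate | split | train | predict | evaluate`
subcommands is installed at `inst/cli/dualseg.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/dualseg.R", package="dualseg"))')" \
  generate --n 50 --size 64 --seed 1 --out data/
```

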