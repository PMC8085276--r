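---
title: "Model-blind spatiotemporal denoising of two-photon calcium imaging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-blind spatiotemporal denoising: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Two-photon Ca²⁺ imaging records neuronal activity as a movie of a fixed
field of view; photon-limited excitation makes individual frames heavily
corrupted by signal-dependent shot noise plus sensor read noise. Averaging
many frames gives a clean image but destroys the temporal signal — the
Ca²⁺ transients — that the experiment exists to measure. `caldenoise`
implements a per-frame denoiser that exploits the redundancy between
*consecutive* frames instead: a residual convolutional network sees a stack
of three consecutive frames and predicts the noise of the central one.

## Noise model

A corrupted frame is modeled as

$$ m \;=\; t \;+\; n_{sp}(t) \;+\; n_{sg}, $$

where $t$ is the noise-free frame (intensities in $[0,1]$), $n_{sp}$ is
signal-dependent shot noise and $n_{sg}$ is i.i.d. zero-mean Gaussian read
noise. Shot noise is parameterized by a *photon budget* $B$ — the expected
photon count at intensity 1.0 — and a dimensionless magnitude $\alpha$:

$$ n_{sp}(t) = \alpha\,\left(\mathrm{Poisson}(B\,t)/B - t\right). $$

This separates the *shape* of the shot noise (set by $B$) from its
*strength* ($\alpha$): $\alpha = 1$ is physical shot noise at budget $B$,
and $\alpha = 0$ is an exact identity. The default $B = 1000$ puts the
shot-noise standard deviation at intensity 0.5 near 0.022, comparable to
the read-noise levels used in training ($\sigma$ drawn uniformly from
$(0, 0.05)$), so neither term trivially dominates. The corruption is
mean-preserving with per-pixel variance $\alpha^2 t/B + \sigma^2$, and
`corrupt()` deliberately does **not** clip its output: clipping would bias
the moments that both the training target and the test suite rely on.
`clip_unit()` is the explicit export-time clamp.

## The network

The denoiser is a plain 20-layer convolutional stack: 3×3×c kernels
(c = 3, the temporal stack depth), 128 filters in the first layer, 64 in
every hidden layer, 3 in the last; leaky-ReLU activations (negative slope
0.1) after every layer except the last; same (zero) padding everywhere; no
normalization layers. That is 706,883 trainable parameters. The network
predicts the *residual* (the noise), and the clean estimate of the central
frame is the channel mean of `stack − residual`, clipped to $[0,1]$.

Two choices here were genuinely open:

* **Final frame from 3 output channels.** The training target replicates
  one frame into three channels, so the network has a 3-channel output; we
  average the three channel estimates (rather than taking the center
  channel), which uses all outputs symmetrically and slightly reduces
  output variance.
* **Initialization.** Hidden layers use fan-in variance scaling adapted to
  the leaky ReLU, $\mathrm{sd} = \sqrt{2/((1+a^2)\,\mathrm{fan_{in}})}$.
  The final layer starts at **zero**, the standard residual-branch
  initialization: the untrained network then predicts a zero residual (so
  denoising degenerates gracefully to a 3-frame temporal average), and the
  loss starts at the data floor and decreases monotonically instead of
  first having to un-learn a large random residual. This matters at a
  constant learning rate of 1e-4, where early training cannot take large
  corrective steps.

Inference is single precision on top of BLAS matrix products (im2col), so
repeated runs on the same machine are bit-identical.

## Two-stage training

**Stage 1 (supervised).** A clean reference of the field of view is built
by averaging 100 corrupted frames (residual noise falls as $1/\sqrt{N}$).
Each training pair draws one read-noise SD from $(0, 0.05)$, corrupts the
reference three times with it (shot noise magnitude 1), stacks the three
corruptions as the input, and replicates the reference as the target. The
loss is the L2 distance between the predicted residual and the desired
residual `input − target`, averaged over pixels and channels.

**Stage 2 (noise-to-noise fine-tuning).** The raw movie is partitioned
into *non-overlapping* windows of four consecutive frames; frames 1–3 form
the input, frame 4 (replicated) the target. No clean data enters this
stage: because the corruption is zero-mean, a denoiser that predicts the
true signal minimizes the expected loss even against a noisy target. The
whole network is retrained (no freezing, fresh optimizer state) from the
supervised weights. The converged fine-tune loss is *floored* near the
target-noise variance — observing it plateau well above the supervised
loss is expected behavior, not a failure.

Windows are non-overlapping by design: partitioning avoids duplicated
targets and keeps the pairs statistically independent.

Optimization is Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8) at a constant
learning rate of 1e-4 — no schedule — for 50 supervised and 10 fine-tune
epochs at full scale. Per-stage validation pairs (a seeded 90/10 split by
pair index) drive best-checkpoint selection; the returned weights are
those of the epoch with the lowest validation loss.

## The simulator

The synthetic generator emulates what those recordings look like at the
scale the package can exercise on one CPU:

* somata are isotropic Gaussian-profile blobs (σ = `cell_radius_px`,
  masks at the 2σ contour), placed by rejection sampling so masks do not
  overlap;
* each cell's brightness is a resting level plus Ca²⁺ transients — a
  unit-peak double-exponential kernel
  $(1-e^{-u/\tau_r})\,e^{-u/\tau_d}$ with defaults $\tau_r = 50$ ms,
  $\tau_d = 0.5$ s, Poisson-process onsets (default 0.2 events/cell/s)
  and uniform peak amplitudes;
* motion artifacts are per-frame rigid shifts or smooth elastic fields
  (bilinearly upsampled coarse grids of normal node displacements),
  applied by backward bilinear warping.

What it does **not** model: optical point-spread blur, scanning artifacts,
photobleaching, axial drift, neuropil contamination, or dendritic
morphology. Passing tests on this generator therefore demonstrate that the
*method* — architecture, two losses, two-stage procedure — removes mixed
Poisson-Gaussian noise from temporally redundant movies; they do not
certify performance on any particular microscope's artifacts.

## Desk-scale study conditions

`run_config()` pins the configuration every end-to-end run and the
acceptance script use: a 128×128, 40 Hz movie of 480 frames with 10 cells;
frames 1–100 build the reference, the last 24 frames are held out for
evaluation, the frames between supply the 4-frame fine-tuning windows.
Supervised training uses 400 random 32×32 patch pairs (100 sequences ×
4 crops) for 15 epochs, fine-tuning 2 crops per window for 5 epochs, batch
size 4. These sizes are the package's own desk-scale choice: a 20-layer
network costs ≈4.3 GFLOP per 32×32 patch per optimization visit, and at a
constant learning rate of 1e-4 what limits convergence is the *number of
Adam updates*, so small batches (many updates per unit compute) are the
efficient operating point on a single CPU. The epoch counts (15 + 5) keep
the full-scale 50:10 ratio's spirit at reduced cost.

## Numerical and metric conventions

* **PSNR** is $10\log_{10}(R^2/\mathrm{MSE})$; identical images return
  `+Inf` (no silent cap).
* **SSIM** is single-scale with an 11×11 Gaussian window (σ = 1.5),
  $K_1 = 0.01$, $K_2 = 0.03$, Gaussian-weighted local moments without the
  sample-covariance correction, averaged over the valid region (5-pixel
  border excluded). This matches the common reference implementation to
  better than 1e-6.
* **ΔF/F** uses $f_0$ = 25th percentile of the ROI-mean trace, with
  linear interpolation between order statistics (R quantile type 7) —
  stated explicitly so tests can be exact. $f_0 \le 0$ raises a typed
  degenerate-baseline error.
* **Transient SNR** is (peak-window mean − baseline mean)/baseline SD of
  ΔF/F; windows are `round(seconds × rate)` frames with a floor of one
  (75 ms → 3 frames and 2 s → 80 frames at 40 Hz); the peak window is
  centered on the caller-supplied peak index and the baseline window ends
  immediately before it — the placement is not dictated by the metric's
  definition, so adjacency was chosen as the simplest consistent rule.
  SD uses denominator N−1. Peak indices are caller-supplied
  (`find_peak()` is a convenience argmax).
* Degenerate inputs raise typed conditions
  (`caldenoise_invalid_argument`, `caldenoise_degenerate_baseline`,
  `caldenoise_format`) rather than producing NaNs.

## Known limitations

* Training throughput is bounded by single-threaded GEMM; full-scale
  (500×500, 1,200-pair, 50-epoch) training is possible but slow on one
  CPU.
* Only 3×3 kernels and a temporal stack of 3 are implemented — the
  contract of this architecture, not a general conv-net library.
* The noise-to-noise stage assumes the underlying signal is nearly static
  across 4 consecutive frames; very fast transients (≪ 100 ms at 40 Hz)
  violate this and will be smoothed.
* The simulator's photon budget is a free parameter of the synthetic
  conditions; real recordings should estimate their own gain before any
  quantitative comparison of noise variances.

```{r}
library(caldenoise)
res <- run_pipeline(run_config(seed = 1), out_dir = "run1", verbose = TRUE)
res$summary
```
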