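---
title: "Weakly supervised vegetation segmentation by spectral reconstruction: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vegsr methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the method

Pixel-accurate vegetation masks are expensive to annotate, but vegetation
betrays itself spectrally: healthy canopies reflect strongly in the
red-edge (~735 nm) and near-infrared (~790 nm) while absorbing visible
light, so a normalized-difference index of two well-chosen bands separates
plants from soil with a simple threshold. Multispectral cameras that
capture those bands are, however, far less common than RGB cameras, and
multi-lens UAV sensors deliver bands that are never perfectly co-registered.

`vegsr` therefore learns the *spectral reconstruction* (SR) map from RGB to
a 4-band multispectral image (green 550, red 660, red-edge 735, NIR 790 nm)
and applies classical index thresholding to the reconstruction. The only
supervision is paired RGB/multispectral imagery — no segmentation labels
anywhere. The pipeline is:

    RGB --SR model--> 4-band image --fusion--> index map --threshold--> mask

**Fusion** is either the generic vegetation-index (VI) form
`(C_i − C_j)/(C_i + C_j + ε)` — by default NIR against green, so vegetation
is positive — or a weighted band sum `Σ W_i C_i` computed on the byte scale
(default weights `(−1, 0, 1, 1)`).

**Thresholding** is fixed for VI maps (default `t = 0.2`) and adaptive for
weighted maps: with `a = Avg(I_fw)` over the whole image, the threshold is
`0.9·a` when `a > 150`, `1.15·a` when `a < 145`, and `a` itself in between.
The two printed branches only cover the outside of the band `[S_l, S_h]`;
the identity was chosen for the middle as the unique continuous completion
of their intent (pull bright scenes' threshold down, dark scenes' up).
Equality at the threshold goes to background: the defining inequalities are
strict on both sides, and background is the conservative class. The mean is
global, not tile-wise, because the rule is explicitly about the global
scene brightness.

## The two reconstruction models

Both models are spatial-size-agnostic image-to-image operators
(H×W×3 → H×W×4, unit scale, output clamped to [0,1] at inference only so
training gradients stay clean).

**SRCNet** (convolutional, default width 32, depth 6, ≈0.19 M parameters).
Stem 3×3 convolution to `width` channels, then `depth` blocks: a 3×3
convolution expands to `3·width` channels (ReLU), the block input is
concatenated back on, and a 1×1 convolution fuses down to `width`; a 3×3
head maps to the 4 bands. The concatenations carry early features forward
intact, which also buffers the model against per-band spatial
misregistration. There is no global residual path. The growth factor 3 was
chosen so the default lands inside the ~0.30 M ± 50 % parameter budget of
the reference design; exact layer counts are not dictated by the science,
so they live in the model config and are trivially changeable.

**SRANet** (spectral self-attention, default width 16, depth 3, 1 head,
≈0.03 M parameters). Stem convolution, then transformer-style blocks:
channel-wise self-attention (the tokens are the feature *channels*, the
spatial positions act as the feature axis, so the attention matrix is
width×width and the cost of attention is independent of spatial ordering)
with a residual connection, followed by a convolutional feed-forward
sublayer (3×3 → GELU → 3×3, expansion 2×) with a second residual. Scores
are scaled by `1/sqrt(H·W)`; rows of the attention matrix are softmax
distributions over channels. Multiple heads partition the channel set.
Residual-branch output projections are initialised at 0.1× He scale
(near-identity start); without this the stacked residuals make the
untrained output two orders of magnitude too large and Adam stalls — this
was the single most important optimisation fix in the package.

All padding is `same` with edge replication, making the convolutional
model exactly translation-equivariant away from borders (a property the
tests check); attention pools globally, so SRANet is only approximately so.

## Training

The loss is the unweighted composite `MRAE + (1 − SSIM)`:

* `MRAE = mean(|X − Y| / max(Y, 1/255))` — the reference goes in the
  denominator; the floor of one 8-bit quantisation step guards the dark
  pixels (vegetation red reflectance is ~0.06, so an unfloored MRAE
  explodes there).
* `SSIM` uses the standard 11×11 Gaussian window (σ = 1.5),
  `c1 = (0.01·MAX)²`, `c2 = (0.03·MAX)²`, valid-region averaging, averaged
  over the 4 bands. Both terms are differentiable; the SSIM gradient is
  the analytic chain rule through the windowed moments, checked against
  finite differences in the test suite.

The optimiser is Adam with cosine-decayed learning rate (default 2e-3),
random square crops (default 32 px; 16 px in the canned desk-scale
experiments — the synthetic scenes are spatially homogeneous, so small
crops lose nothing and cut the per-step cost by 4×), random horizontal
flips, batch 16. The per-epoch evaluation recomputes loss, MRAE, SSIM and
PSNR on a capped subset of held-out images, plus — when masks exist — the
downstream segmentation MIoU of that epoch under the uniform setting (VI
fusion NIR/green, fixed t = 0.2). `loss == mrae + (1 − ssim)` is an exact
identity per history row. Everything is derived from one integer seed, so
a rerun reproduces the history bitwise.

Checkpoint selection reflects the package's central observation: with
misregistered training targets, *better reconstruction is not better
segmentation*. As training fits the misaligned bands ever more faithfully,
the reconstruction inherits their spatial shifts and the index map smears
across class boundaries; early checkpoints, which have learned the
inter-band mapping but not the misalignment, segment best.
`select_checkpoint(history, "segmentation")` picks the MIoU-argmax epoch
(ties to the earliest); the `epoch_effect` experiment quantifies the
phenomenon with a misaligned arm against an aligned control arm.

## The synthetic scene generator

The generator emulates paired UAV field imagery with three classes —
vegetation, bare soil, plastic mulch film — rendered from per-class mean
reflectances with per-channel multiplicative jitter (sd 0.03) and additive
pixel noise (default sd 0.05 on the unit scale), under a global
illumination gain. Layouts: `dense` (closed canopy) thresholds a smoothed
Gaussian random field; `row_crop` adds a strong periodic row pattern;
`mixed` a weak one. The threshold is the field's empirical quantile, so the
realised vegetation fraction matches the target per scene.

The signatures are synthetic and calibrated to the package's own
contracts, not to a radiometric library: vegetation
(0.10, 0.06, 0.45, 0.55) shows the red-edge/NIR rise, soil
(0.31, 0.35, 0.33, 0.25) is slightly *negative* in the NIR-green index
(≈ −0.11) so that the index thresholded at zero recovers the generator
mask on quiet scenes, and film (0.60, 0.60, 0.62, 0.62) is bright and
flat — nearly index-neutral but with a weighted-sum value (≈163) that sits
above the adaptive threshold of typical mixed scenes, which is exactly why
the weight strategy degrades on film-bearing fields while the VI strategy
does not. Real soils are usually slightly index-positive; that realism was
traded away deliberately, because the generator's role is to make the
zero-threshold oracle contract and the strategy-ordering experiments
well-posed, not to emulate a particular site.

"Strong noise" — the residual per-band misregistration of multi-lens
sensors after calibration and manual alignment — is modelled as an
independent rigid translation of each spectral band with continuous
offsets `|dx|,|dy| ≤ magnitude` (bilinear resampling, edge replication),
with RGB and mask untouched. Translation is the minimal model that
reproduces the training pathology; rotation/scale residuals are not
simulated. The default magnitude in the experiments is 3 px, a parameter,
not a claim about any particular sensor.

What passing tests on this generator do **not** show: robustness to real
within-class spectral variation (species, phenology, moisture), shadows,
specular film highlights, mixed pixels at real sensor PSFs, or
illumination fields that vary across a scene. The generator's classes are
spectrally compact by construction; real-data performance must be
established on real data.

## Numerical choices and degenerate inputs

* VI denominator stabiliser ε = 1e-6 (unit scale) — avoids 0/0 on black
  pixels without visibly biasing the index.
* PSNR of identical images is capped at 100 dB.
* A class absent from both prediction and truth contributes IoU 1
  (vacuous agreement keeps all-background scenes well-defined); dataset
  scores are means of per-image scores (one term per test image), with
  pooled-count variants reported alongside.
* Patches tile from the top-left corner on a regular grid, row-major;
  residual borders are discarded (`floor(H/p)·floor(W/p)` patches — the
  1280×960 sensor geometry at 340 px gives exactly 6).
* The train/test split draws `round(ratio·n)` training rows from a seeded
  RNG; ratios that would empty either side are rejected.
* Multispectral rasters travel as 4-page grayscale TIFFs (page order =
  band order); masks as {0,255} PNGs; 8-bit round-trips are lossless.

## Problem sizes in the shipped experiments

The canned experiments run at desk scale, chosen so the whole suite stays
comfortably interactive on one CPU: the end-to-end ablation trains the
default SRCNet on 180 synthetic 64×64 pairs for 8 epochs (16 px crops) and
evaluates on 20 held-out scenes; the epoch-effect study trains SRANet on
24 48×48 scenes for 15 epochs per arm and seed; the fusion comparison uses
20 mixed scenes with 10–20 % film; the oracle contract uses 50 quiet
scenes (pixel noise 0.01). At these sizes the convolutional model reaches
segmentation MIoU well above the direct RGB-pair baselines, which is the
ordering the method exists to demonstrate; pushing reconstruction metrics
further (more epochs, larger crops) does not change the orderings the
package reports.

## Known limitations

* The NN engine is CPU-only base R; it is meant for small models at patch
  scale, not for full-resolution orthomosaics.
* JPEG input is not supported (PNG/TIFF readers only).
* `heads` must divide `width`; attention heads partition channels.
* The adaptive threshold's middle branch (identity) is a documented
  completion, not an empirical finding.
* Reported accuracies are on the synthetic generator; see the caveats
  above about what that does and does not establish.
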