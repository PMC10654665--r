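---
title: "cephmark: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cephmark: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cephalometric analysis quantifies maxillofacial morphology from 23
anatomically defined landmarks (sella, nasion, A-point, B-point, menton,
gonion, ...). Clinically these are traced on lateral cephalograms, which
exposes patients to X-rays. `cephmark` implements a two-stage detector that
works on ordinary lateral *profile photographs*: landmarks annotated by
superimposing the cephalometric tracing on the photograph can be learned, and
then predicted, from the photograph alone.

Stage 1 is heatmap regression. Each landmark $L_i$ is encoded as a 2D
Gaussian at quarter resolution,

$$h_i(\mathbf{x}) = \frac{1}{2\pi\sigma^2}
  \exp\left(-\frac{\lVert \mathbf{x}-L_i\rVert^2}{2\sigma^2}\right),$$

and a high-resolution multi-branch convolutional network is trained to
predict the 23-channel stack under a summed $L_2$ loss. Predicted heatmaps
are decoded by argmax with a quarter-pixel shift toward the larger
axis-neighbour, then mapped back to image coordinates.

Stage 2 is coordinate regression. The 23 decoded x-coordinates (and,
separately, the 23 y-coordinates) enter a three-layer perceptron with 500
hidden units that outputs 23 refined coordinates. Because the two axis
networks see *all* landmarks at once, they can exploit the strong
inter-landmark correlation structure that heatmap regression ignores — the
heatmap stage treats each landmark channel independently, so a per-landmark
localisation error (an occluder near the ear, say) is invisible to it but
recoverable from the other 22 landmarks.

Training alternates: one backbone epoch, then 100 refiner epochs on pairs
(decoded stage-1 prediction, ground truth) freshly decoded from the current
backbone. Refiner parameters persist across cycles; they are initialised
once.

## Architecture

The backbone follows the high-resolution topology: a stem of two stride-2
3×3 convolutions (resolution 1/4), a first stage of bottleneck residual
units, then parallel branches added one per stage (stage 2 has two branches,
stage 4 has four) at widths $C, 2C, 4C, 8C$ and resolutions $1/4 \dots
1/32$. Exchange units fuse every branch pair: stride-2 3×3 convolutions
downward, nearest-neighbour upsampling followed by a 1×1 convolution upward.
The head upsamples all branches to 1/4 resolution, concatenates, and applies
two 1×1 convolutions to emit 23 channels.

Two instances matter:

* **full scale** (`fullscale_backbone_config()`): $C = 18$, blocks 1/4/3, four
  residual units per block, bottleneck width 64 — the published
  configuration, far too expensive to train on one CPU;
* **desk scale** (`backbone_config()` defaults): $C = 8$, one block per
  stage, two units per block, 64-px inputs. Same topology, same contracts,
  trainable in minutes.

The final 1×1 convolution is zero-initialised so the untrained network
predicts the zero heatmap; without this the early epochs are spent shrinking
a large random output instead of shaping peaks. No normalisation layers are
used: at desk scale He initialisation plus Adam is sufficient, and the
original description mentions none.

Everything is implemented in base R (vectorised index-gather im2col, one
BLAS matrix product per convolution, hand-written backprop, Adam). No deep
learning framework exists in the supported dependency set; at these sizes
the pure-R engine trains the desk configuration comfortably.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `mm_per_px` | 0.35 | mm/px | device pixel spacing; converts px errors to mm |
| `sigma` | 1.5 | heatmap px | Gaussian width; unstated in the source, 1.5 is the quarter-resolution facial-landmark convention |
| `r` | 4 | — | heatmap reduction factor (fixed by the stem) |
| decode offset | 0.25 | heatmap px | sub-pixel shift toward the larger axis-neighbour |
| backbone lr | 1e-4 (full), 1e-3 (desk) | — | full-scale schedule drops ×0.1 at cycles 30 and 50 of 60 |
| refiner | 500 hidden, lr 1e-5, wd 1e-4, 100 epochs/cycle, batch 16 | — | published stage-2 settings |
| SDR thresholds | 2, 2.5, 3, 4 | mm | standard cephalometric detection thresholds |

## Numerical and interpretation choices

* **Coordinates** are real-valued pixels, origin at the *center* of the
  top-left pixel, x right, y down. All I/O formats state this.
* **Argmax ties** break by row-major first occurrence; an all-constant
  channel is an error naming the channel, never a silent NaN.
* **"Second largest value" decoding**: interpreted as the larger per-axis
  neighbour (0.25 px shift), not the global second maximum, which is
  unstable for near-symmetric Gaussians. No shift on border peaks or exact
  ties.
* **"Within 2 mm"** is inclusive: $R \le t$.
* **SD** uses the $n-1$ denominator over pooled radial errors; the SD of a
  single value is reported as `NA`, not 0.
* **Angles**: for "the angle between A, B, C" the middle point is the
  vertex. Line-line angles are unsigned acute angles in $[0, 90]$ except
  inside the ODI/APDI sums, which need *signed* angles in $(-90, 90]$
  (unsigned sums cannot reach the published normal ranges for all
  anatomies); the sign is the rotation from the first to the second line,
  counterclockwise in the (x right, y down) frame.
* **Classification bands**: normal intervals are inclusive at both ends.
  Three printed bands are internally inconsistent and corrected here (all
  configurable): SNB (printed directions contradict each other; retrognathic
  is taken below 74.6°, prognathic above 78.7°), ODI (open tendency below
  the normal lower bound 78.4°, the printed 68.4° leaves a gap), MW
  (edge-to-edge below 2 mm; the printed band is the single value 0 mm).
* **Refiner normalisation and initialisation**: coordinates are divided by
  the image side and centered per coordinate (centers estimated from the
  first training batch and frozen in the model metadata), and each axis
  network starts as the exact identity map (`relu(x) - relu(-x) = x` across
  paired hidden units; the remaining units have random first-layer columns
  and zero second-layer rows). Both address the same fact: with a randomly
  initialised network on raw [0, 1] coordinates, the design matrix of
  hidden features has a dominant shared constant and a variance spectrum
  spanning four orders of magnitude, and gradient training provably needs
  step budgets on the order of the published schedule (hundreds of
  thousands of steps) to cross that plateau. Identity initialisation makes
  training learn only the *correction* to the stage-1 coordinates, which
  converges in hundreds of full-batch steps; an exact ridge-regression
  oracle on the hidden features confirms the converged solutions match
  what the architecture can express. Random initialisation remains
  available via config.
* **Refiner activation** is a rectifier (unstated in the source; `tanh`
  available via config). The refiner regresses absolute coordinates; a
  residual mode exists behind a flag for experimentation.
* **Desk training steps**: backbone overfit runs use lr 1e-3 with batch
  size 1–5; refiner ablation runs use full-batch steps at lr 1e-4. These
  adapt the published step budgets (60 epochs on 1600 images; 6000 refiner
  epochs, i.e. hundreds of thousands of optimiser steps) to minutes-scale
  runs; the published rates remain the config defaults.

## The synthetic world

The private clinical dataset (2000 annotated profile photographs,
1200×1200 px, 0.35 mm/px) cannot be shipped. The generator replaces it with
a *stated world*, chosen once:

* a 23-point template in 1200×1200 px arranged as a lateral profile — 18
  points along the soft-tissue/dental profile curve, 5 displaced off-curve
  (the sella/porion/menton/gonion/basion analogues, the points hardest to
  place from a profile tracing), with larger y-spread than x-spread (long
  faces scatter landmarks vertically);
* three unit-RMS deformation modes — vertical elongation, anteroposterior
  shear, linearised rotation — with sds 60/40/25 px (21/14/9 mm): facial
  heights and jaw positions vary on the centimetre scale across adults;
  plus 2 px independent jitter (annotator-scale disagreement);
* rendered toy images: a smooth seeded background plus one distinct local
  texture per landmark (radial blobs / oriented ripples, unique
  orientation and frequency), pattern maxima exactly on the landmark, and
  amplitudes kept below saturation so the maxima cannot shift;
* structured stage-1 noise: a rank-2 correlated component (global shift
  weighted toward y, global expansion — the error modes of
  tracing-superimposition) with 6 px per-mode sd, plus 1.5 px independent
  noise inflated ×2 on the five deep landmarks.

What a green test establishes: the architecture is wired correctly (it can
overfit its own renderings), the codec and metrics are exact, and the
refiner removes correlated stage-1 error on held-out data. What it does not
establish: photographic performance, robustness to occlusion/illumination,
or the published error tables — those require the clinical data and GPU
budgets and are explicitly out of scope.

## Known limitations

* The pure-R engine is single-threaded apart from BLAS; the full-scale
  configuration is present for contract checks, not training.
* Nearest-neighbour image resizing only; at desk scale images are rendered
  directly at the network input side.
* Images are ASCII PGM: no PNG/JPEG codec exists in the supported stack.
* The anatomical identities of L3, L4, L7, L9, L11, L12, L17, L18 are not
  fixed by the measure table; recipes are index-literal and the template's
  choices for those points are geometric conveniences.
* FMA here is the index-literal recipe (line L1–L2 vs line L10–L9), which
  differs from the conventional Frankfort-mandibular definition.
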