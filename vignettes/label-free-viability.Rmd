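---
title: "Label-free viability assay from quantitative phase imaging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free viability assay from quantitative phase imaging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(phaseviab)
```

## The problem

Classical live/dead assays stain cells with membrane-permeability reagents
(a NucBlue-like channel marking all nuclei, a NucGreen-like channel marking
nuclei with compromised membranes). Staining takes time, bleaches, and is
itself toxic, which rules out long-term observation. Quantitative phase
imaging (QPI) measures the optical path-length delay through a specimen
without any label, and spatial light interference microscopy (SLIM) is a
common-path QPI variant that reconstructs phase from four phase-shifted
interferograms. `phaseviab` implements a computational-specificity pipeline
on top of SLIM: a convolutional segmenter is trained to predict, from the
phase image alone, the three-class map (live nucleus, dead nucleus,
background) that the fluorescence assay would have produced. Once trained,
viability is read out label-free, frame by frame, and nuclear area and dry
mass can be tracked over time without perturbing the cells.

## Phase reconstruction

With interferogram frames $I_k$ recorded at modulator shifts
$\theta_k \in \{0, \pi/2, \pi, 3\pi/2\}$, the two-beam model is

$$I_k = I_0\left(1 + b^2 + 2b\cos(\phi + \theta_k)\right),$$

where $b$ is the scattered-to-incident amplitude ratio. The standard
four-step estimator

$$\Delta\phi = \operatorname{atan2}(I_{3\pi/2} - I_{\pi/2},\, I_0 - I_\pi)$$

recovers $\phi$ exactly in the noise-free case. The composition step
$\phi = \arctan[b\sin\Delta\phi/(1 + b\cos\Delta\phi)]$ is available when a
calibrated $b$ is supplied, but the default mode returns $\Delta\phi$
directly: halo/amplitude calibration is out of scope here, and the bundled
simulator uses the matching forward model, so reconstruction-plus-forward
is the identity by construction (the tests verify $10^{-6}$ rad round
trips). Pixels where both atan2 arguments fall below $10^{-12}$ carry no
fringe contrast; they are zeroed and counted, and reconstruction aborts if
they exceed half the image.

Dry mass follows from the linear relation between phase and non-aqueous
content:

$$m = \frac{\lambda}{2\pi\alpha} \sum_{x\in\text{mask}} \phi(x)\,\Delta^2,$$

with refractive increment $\alpha = 0.2\ \mu\text{m}^3/\text{pg}$ (the
standard QPI value, configurable), wavelength $\lambda = 0.55\ \mu$m (a
representative broadband-LED center, configurable) and pixel pitch
$\Delta$ (default $0.1625\ \mu$m, a 6.5 µm camera pixel behind a 40×
objective; phase maps are typically downsampled by 2 before training,
doubling the pitch).

## Ground truth from fluorescence

The training targets come from the paired stain channels: Gaussian
smoothing (σ = 2 px) and a global Otsu threshold on the all-nuclei channel,
8-connected components, and a 50 px minimum area give the nucleus masks;
each nucleus is then classified by its relative intensity
$r = \overline{\text{green}}/\overline{\text{blue}}$ with a threshold of
0.5 (ties to dead). The exact statistic used in the original assay is not
published; the per-nucleus mean ratio is monotone in relative intensity,
invariant to a common gain, and has a single interpretable parameter.
Nuclei are labeled wholly live or wholly dead; everything else is
background (class encoding 0/1/2). Border-touching nuclei are kept by
default (a `drop` policy exists for ablations).

## The segmenter and its loss

The model is a U-Net-style encoder–decoder with skip connections and a
softmax head. Two encoder families are built:

* `tiny` — four stride-2 stages of plain conv+ReLU blocks (~0.1 M
  parameters). This is the desk-scale profile used by the tests, the
  acceptance experiments and the examples; it trains in minutes on one CPU.
* `b0`–`b7` — EfficientNet-style encoders assembled from
  inverted-bottleneck MBConv blocks (expansion 1 with ReLU, expansion 6
  with ReLU6, residual connections within stages), five downsampling stages
  and five decoder stages, with compound width/depth scaling. They
  reproduce the architecture family structurally at reduced width; full
  ImageNet-pretrained capacity is not reproduced, and encoder weights can
  be injected through `load_weights()` instead.

Because no deep-learning framework is available to this package's target
environment, the forward/backward passes, Adam, and the convolution kernels
are implemented in the package (R with small C++ kernels). Batch
normalization is omitted; with per-image z-score input standardization and
He initialization the desk-scale network trains stably, and the tests
verify every analytic gradient against numerical differentiation.

Training minimizes the indicator-weighted compound loss
$L = \alpha L_{focal} + \beta L_{dice}$:

$$L_{focal} = -\frac{1}{B}\sum_i \frac{1}{MN} \sum_{x}
  \left[1 - y_i(x)^T p_i(x)\right]^{\gamma} y_i(x)^T \log_2 p_i(x),$$

with $\gamma = 2$ and the base-2 logarithm kept exactly as specified (a
constant factor $1/\ln 2$ away from natural-log conventions), and

$$L_{dice} = 1 - \frac{1}{3}\sum_{c=0}^{2}
  \frac{2TP_c + \epsilon}{2TP_c + FP_c + FN_c + \epsilon},$$

with TP/FP/FN micro-accumulated over all pixels of the batch. A class with
no ground-truth pixels in the batch scores 1 — it cannot be missed, and
spurious predictions against it are already penalized through the other
classes' counts — so a perfect prediction always has zero dice loss. In
the training gradient the dice term uses soft probability masses (hard
argmax counts are not differentiable); hard-label dice is used for
reporting. Probabilities are clipped at $10^{-7}$ before the logarithm.

The optimizer is Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-7}$), initial learning rate $5\times10^{-4}$, multiplied
by 0.8 whenever the validation loss (computed on the whole validation
partition each epoch) has not decreased for 10 epochs; the weights with the
lowest validation loss are kept. The full-scale recipe (512×512 patches,
batches of 14 or 4, 100 epochs, EfficientNet-B3/B7 encoders) is expressible
through `train_config()`, while the defaults are the desk profile: 128 px
patches, batch 8, ≤ 30 epochs, `tiny` encoder. On-the-fly augmentation
applies random crop, flips, ±10% integer shifts with reflect padding,
Gaussian noise (1% of range) and brightness offsets (±5%); geometric
transforms are applied to labels by pure copying (nearest neighbour), so
label values stay in {0,1,2}. Note that the per-image z-score at the
network input makes a constant brightness offset a no-op; the augmentation
is retained for fidelity to the recipe and for the noise term.

Data are split by *sequence* (time-lapse recording), never by frame, in
proportions 6:1:1 with largest-remainder rounding and at least one sequence
per partition, so that temporally correlated frames never straddle
partitions.

## Object-based evaluation

Pixel-wise scores under-weight biologically meaningful errors, so the
primary metric is object-based: every ground-truth nucleus is assigned the
dominant (majority) predicted label inside its own pixel set. If background
dominates (> 50%), the nucleus is "missed" and reported separately rather
than forced into the 2×2 live/dead confusion matrix — how such nuclei
entered the published tables is not stated, and keeping them out of the
matrix keeps precision/recall interpretable. Live/dead ties go to dead
(deterministic, and conservative for viability). The confusion matrix is
column-normalized by ground-truth class totals (columns sum to 100%), which
makes each class's recall equal to its diagonal entry. Per-class precision,
recall and $F_1 = 2PR/(P+R)$ plus the macro (unweighted mean) $F_1$ mirror
the published table layout; table-style values are rounded half-up to one
decimal. An exhaustive brute-force tally over small scenes serves as the
oracle for this machinery in the tests, and pixel-wise per-class
precision/recall/F1/IoU are provided alongside.

## Tracking and group statistics

Nuclei are linked across frames with a deterministic greedy
nearest-neighbour assignment (candidate pairs sorted by ascending centroid
distance, one-to-one, gated at 30 px, tracks shorter than 5 frames
dropped). The published analysis used an interactive ImageJ tracker with
unreported parameters; for slow-moving adherent cells a greedy linker is
adequate and reproducible. A cell keeps one identity through its live→dead
transition, with the class recorded per timepoint. Per-timepoint area
(pixel count × pitch²) and dry mass (phase integral over the object mask)
are normalized per track to the value at the first timepoint, and two
groups are compared at each timepoint with a two-sided Welch t-test
(unequal variances; "two-sample t-test" is underspecified, and Welch is the
safe default — it reduces to Student's t when variances and sizes agree,
which the tests check to $10^{-9}$).

On the Welch power check used in the acceptance suite: with the group
difference set to 3 standard errors of the difference, the analytic power
of a two-sided 5% test is $\Phi(3 - 1.96) \approx 85\%$ (slightly less with
estimated variances), independent of sample size. The Monte-Carlo in the
acceptance suite measures exactly this quantity; a detection rate near 85%
is therefore the expected outcome of a correct implementation, not a
defect of the test statistic.

## The simulator

`simulate_experiment()` generates the full acquisition: cells are placed
without nucleus overlap as rotated elliptical flat-top profiles
($e^{-\rho^4}$ in the elliptical radius; semi-axes 6–9 px) with a fainter
cytoplasm (1.8× axes, 12% amplitude); nuclear peak phase is 1.5 rad ± 5%
per cell. Each live cell dies independently with a configurable per-frame
hazard (geometric death times, so the final dead fraction follows
$1-(1-h)^n$). From its death frame, over `fluor_dead_ramp_frames` frames, a
dying cell swells to 1.3× area, then shrinks to 0.7×, while its nuclear
phase density rises to a 1.3× peak before settling at 1.2× (condensed,
denser chromatin) — a piecewise-linear emulation of the swell-then-shrink
morphology of necrotic death, not a calibrated biophysical model. The
"dead" fluorescence channel ramps from 0 to the "live"-channel level over
the same window. Interferograms come from the two-beam forward model
($I_0 = 0.25$, $b = 0.3$) with optional Gaussian camera noise (default
0.5% of full scale) and 16-bit quantization; fluorescence channels are
quantized the same way. Per-nucleus truth (class, footprint area, dry
mass) is carried alongside; a truth mass is the cell's *own* rendered
phase summed over its footprint, so agreement with `compute_dry_mass()`
on that footprint (within 1%) cross-checks the mask bookkeeping, the
unit conversions and the smallness of neighbouring cytoplasm tails.

The default ramp is 3 frames (staining develops with a lag, as it does in
practice). The ground-truth-recovery and learning experiments use a ramp
of 1 so that the truth label, the morphology change and the dead-reagent
signal all switch at the death frame: with a multi-frame ramp a
just-died nucleus is intentionally ambiguous (its stain ratio is still
below threshold), which measures the staining lag rather than the
pipeline. This choice was fixed at design time.

What the simulator does *not* emulate: optical halo and diffraction,
realistic phase texture, apoptotic fragmentation, cell motility, touching
or overlapping nuclei, focus drift. Passing tests on simulated data
therefore demonstrate the internal consistency and learnability of the
pipeline, not performance on real microscope data.

## Desk-scale experiment sizes

The acceptance experiments run on one CPU inside a test session, with
sizes chosen as the package's own desk profile: 100 random phase maps for
the reconstruction round trip; ≥ 500 nucleus decisions across seeds for
ground-truth recovery; 25 simulated sequences × 8 frames of 128² px
(200 frames, 5 cells each, hazard 0.15) for the learning experiment, with
the `tiny` encoder, batch 8 and ≤ 30 epochs, evaluated by object-based
macro-F1 on the held-out test sequences; 200 replicates for the Welch
power Monte-Carlo. The compound loss for the learning experiment uses
$[\alpha, \beta] = [1, 1]$: dead nuclei are a small fraction of pixels,
and the dice term weights each class equally, which is exactly the
class-imbalance situation that motivated the dice indicator in the
published recipe. The learning experiment runs with mini-batches of 2
rather than the full-scale batch sizes: at 150 training frames the number
of optimizer steps, not the number of epochs, is what limits convergence
(the learning rate schedule is per-step via Adam), and batch 2 gives the
recipe ~1900 steps within 25 epochs, after which it converges; with batch
8 the identical recipe plateaus before the dead class is ever predicted.

## Known limitations

* No batch normalization; very deep B-like variants would likely need it
  (or careful initialization) to train from scratch at full scale.
* The greedy linker has no gap closing or division handling.
* The nucleus-boundary accuracy of predictions is limited by the low
  nucleus/cytoplasm contrast the segmenter sees in injured cells; dry-mass
  tracking inherits any segmentation bias.
* Table-scale accuracies from the original study (GPU-trained B3/B7 on
  real data) are out of scope; only the evaluation arithmetic on those
  published values is reproduced exactly.
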