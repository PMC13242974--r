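---
title: "Methods: phantom-based skin-stiffness quantification with octstiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom-based skin-stiffness quantification with octstiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The measurement model

`octstiff` quantifies skin stiffness from optical coherence tomography
(OCT) B-scan time series acquired under non-contact air-jet indentation.
A controlled air pulse dents the skin surface while the OCT probe records
cross-sections at 10 frames per second; the acquisition follows a
three-window protocol — a baseline window before pressure, a pressure-on
window, and a recovery window (5 s each by default). The biomechanical
summary is the *structural stiffness coefficient*

$$K = \frac{F}{\Delta d},$$

where the applied force is gauge pressure times the nozzle bore area,
$F = p\,\pi (d/2)^2$ (a 2 mm bore at 100 kPa gives 0.3142 N), and
$\Delta d$ is the depth by which the tracked stratum-corneum (SC)
landmark moves between the baseline and the deepest indentation. $K$ is
deliberately a structure-level quantity — it folds in layer geometry and
surface state — rather than a material constant such as Young's modulus,
which would require homogeneity and semi-infinite-medium assumptions that
wounded skin does not satisfy.

Two design points in the displacement stage deserve justification:

* **Baseline is the pre-window mean, not a single frame.** Averaging the
  ~50 baseline frames suppresses tracking noise at no cost, since the
  phantom (and a resting arm) is stationary before loading.
* **Maximum indentation is the raw per-frame maximum over the on-window.**
  A maximum over ~50 noisy frames is upward-biased (extreme-value bias of
  roughly $2.2\sigma$ for Gaussian noise); the test suite quantifies this
  with 1000 simulated traces (bias well under 3 px at 1 px noise), and an
  optional 3-frame running median (`smooth = "median3"`) is available
  when predicted masks are noisy. We keep the raw maximum as the default
  because it is the plain reading of "depth at maximum indentation".

The depth-axis convention, used everywhere: row 1 of a frame is the
shallowest pixel, depth grows with the row index, and indentation
increases depth.

## The speckle phantom

No deposited OCT dataset accompanies this kind of study, so the package
ships a phantom generator that *is* the study's synthetic ground truth,
not a test fixture. A phantom frame stacks, from the top: a dark air gap;
a bright thin SC band (the segmentation target); and deeper layers of
decreasing mean intensity. On top of this piecewise-constant profile the
generator applies exponential depth attenuation below the tissue surface
and unit-mean multiplicative gamma speckle — the standard first-order
phenomenology of coherent imaging. The speckle contrast (SD/mean,
default 0.3) sets the gamma shape $1/c^2$; attenuation defaults to
0.8/mm.

Deformation is modelled as a rigid downward translation of the whole
layer stack, scaled laterally by a Gaussian envelope (default
$\sigma = 1$ mm) centred on the jet axis. The plateau displacement at the
centre column is exactly $F/K_{\text{true}}$, so every downstream
estimate has an analytic target. The temporal profile is zero during the
baseline window, a 0.5 s smoothstep ramp to the plateau, and a symmetric
ramp back at the start of recovery; the protocol literature specifies
only the window durations, and a smooth ramp avoids single-frame
discontinuities at 10 fps. Viscoelastic creep and photon-transport
realism are explicitly out of scope.

What the phantom does *not* emulate: curved or irregular skin surfaces,
motion artefacts, shadowing, heterogeneous within-layer texture, and the
inter-subject variability of real skin. Segmentation scores on phantoms
are therefore upper bounds on clinical performance — the acceptance
checks treat the human-data metrics reported in clinical OCT skin
segmentation (accuracy 92%, Dice 0.89, IoU 0.82) as *lower bounds* that
the much easier synthetic task must clear, which validates the
implementation, not clinical transferability.

Default geometry for the desk-scale experiments: 128 × 128 px at
7.5 µm axial × 10 µm lateral pitch (the device's optical resolutions),
SC top at 0.10–0.20 mm, SC thickness 0.08–0.16 mm, stiffness
0.5–2.5 N/mm — bracketing the ~0.9–1.7 N/mm range reported for normal
and wounded skin — under a 50 kPa jet (acquisition rigs of this kind
state only a compressor limit of 40 PSI ≈ 276 kPa and a valve range up
to 0.5 MPa, so the
working pressure is a free parameter; 50 kPa keeps the largest phantom
indentation, 0.31 mm at K = 0.5 N/mm, well inside the 0.96 mm imaged
depth). The full 997 × 997 px raster used on real scans is supported but
not the test default.

## Image conditioning

The preprocessing chain mirrors standard practice: grayscale conversion
(Rec.601 luminance weights), a centre-anchored crop to a standard square
(997 px on real scans; centre anchoring preserves the central A-scan the
biomechanics uses), and Gaussian denoising. The Gaussian sigma is not
specified by the protocol; the default is 1 px, mild at 7.5–10 µm pitch.
The filter uses half-sample symmetric (reflective) boundaries and is
implemented as a separable convolution; a white-noise variance-reduction
test checks the implementation against the analytic factor
$1/(4\pi\sigma^2)$. The vendor's raw "time-bin" format is not
reverse-engineered; TIFF/PNG stacks with a JSON metadata sidecar are the
interchange format.

## Segmentation network

The SC segmenter is a standard U-Net: `depth` encoder levels of two 3×3
convolutions + ReLU followed by 2×2 max pooling, channels doubling per
level; a two-convolution bottleneck; a mirrored decoder with
nearest-neighbour upsampling, a 3×3 up-convolution, skip concatenation
and two further convolutions; and a 1×1 sigmoid head. It is implemented
directly on BLAS (im2col + gemm with hand-derived backpropagation and
Adam), which keeps the package dependency-free and CPU-friendly; the
backward pass is verified against numerical gradients in the test suite.

Hyperparameters are not standardized for this application, so the defaults
are the package's own: depth 4, base 16 channels (the desk-scale
experiments use base 8 — see below), combined BCE + soft-Dice loss
(robust for thin-structure class imbalance), Adam at 1e-3, batch 4–8,
threshold 0.5 with ties broken toward background, best-validation
checkpointing with early stopping (default cap 50 epochs, patience 10 —
informed by loss curves of this kind that plateau by ~50 epochs). All of
these are exposed in `trainConfig()`.

Data handling follows the clinical protocol's discipline: splits are
*patient-level* (here, phantom-series-level) so no subject leaks across
subsets; 60/20/20 train/validation/test; the validation subset selects
the checkpoint and the test subset is only ever scored. Evaluation
reports macro-averaged (per-image mean) pixel accuracy, Dice and IoU;
"accuracy" is pixel accuracy, noting that for a thin band this metric is
dominated by background and is the least informative of the three.

## Stiffness recovery experiment

The end-to-end check generates phantoms at
$K_{\text{true}} \in \{0.5, 1.0, 1.5, 2.0, 2.5\}$ N/mm at fixed force,
tracks the SC with either ground-truth or U-Net masks (landmark: centroid
of mask pixels in the central 10% of columns, matching "the center of the
segmented skin location"; the top boundary is available as an
alternative), and recovers $\hat K = F/\hat{\Delta d}$. With truth masks
the only error source is raster quantization (≤ 1 axial pixel = 7.5 µm),
bounding the median relative error at ≈ 5% over the sweep; with trained
masks segmentation noise enters and 20% is the acceptance bound. The
recovered $\hat K$ must be strictly monotone in $K_{\text{true}}$.

## Statistics battery

The analysis stage reproduces the comparison battery used in clinical
air-jet elastography reports: one-way ANOVA across skin statuses
(normal / wound / after treatment) with Fisher's LSD post hoc (LSD by
definition applies no multiplicity correction; Holm is available behind a
flag), a pooled-variance Student's t between limb locations (Welch behind
a flag), a two-way mixed-effects ICC over the six status × location
conditions, Cohen's d with confidence intervals, and Pearson correlation
between the OCT-derived and reference-device stiffness values.

Choices where the protocol under-specifies:

* **ICC form.** "Two-way mixed-effects" admits consistency and absolute
  agreement variants; the consistency form ICC(3,1)/ICC(3,k) is the
  default (the six conditions are fixed, and their mean differences are
  real effects one does not want charged to unreliability), with the
  agreement form behind `type = "agreement"`. CIs use the classical
  F-bounds on $MS_R/MS_E$.
* **Cohen's d.** Pooled-SD independent-groups form with the
  normal-approximation CI. Published d values of this kind are not always
  recomputable from printed means ± SE under this form (a paired
  formulation may underlie them); no variant is privileged, and the raw
  mean-difference CI (pooled t) is reported alongside.
* **Implementation vs oracle.** ANOVA, t, and Pearson call the standard
  `stats` machinery; ICC, LSD and Cohen's d are implemented from their
  defining formulas. Every statistic is cross-checked in the tests
  against independent brute-force sum-of-squares oracles at 1e-10
  relative tolerance, ANOVA satisfies $F = t^2$ against the pooled t for
  two groups, ICC(3,k) equals the Spearman–Brown step-up of ICC(3,1),
  and 10 000-replicate null simulations confirm nominal 5% size at
  n = 14 per group.

### The synthetic stiffness table

`simulateStiffnessTable()` emulates the repeated-measures design of such
a study: each of n = 14 subjects is measured at both limb locations in
all three statuses with both devices. Values are cell mean + subject
random intercept + residual noise; the reference device rescales the same
underlying measurement into its own units (×460, matching the N/m scale)
with added noise, which reproduces the strong inter-device correlations
(r ≥ 0.94) such studies report. Cell means follow the clinically reported pattern:
normal 0.90 N/mm at both locations, wound 1.30 (upper) / 1.70 (lower),
after treatment 0.95. Variance components (subject SD 0.25, residual SD
0.08 N/mm) were fixed by a design-stage power analysis: with a subject
intercept shared across conditions, the between-group tests are applied
to positively correlated samples, so the unpaired LSD/t machinery is
conservative under the null and the clinically reported significance pattern
(wound vs normal and wound vs after significant, normal vs after not,
location difference only in wound) reproduces in ≥ 90% of generator
seeds, which is the acceptance property. The resulting total SD
(≈ 0.26 N/mm) and SE (≈ 0.07) sit inside the range such studies
tabulate. One known divergence: with these components the simulated ICC is
high (≈ 0.9), whereas heterogeneous clinical wounds can yield much lower
single-measure reliability; the table generator models a cleaner
instrument than a wound clinic sees.

## Problem sizes and numerical choices

The desk-scale study the tests and the acceptance script run: 10 phantom
series ("patients") × 20 frames at 128 × 128 px (200 frames; 120/40/40
after the split), U-Net depth 4 with base 8 channels trained 8 epochs at
batch 4, and a five-point stiffness sweep of full 15 s series (150
frames each). These sizes were chosen so a complete run finishes on a
single CPU core in about ten minutes while leaving wide margins over the
acceptance bounds (held-out Dice is ≈ 0.99 against the 0.89 bound).
Scaling up (997 px rasters, base 16, 50 epochs) is a configuration
change, not a code change.

Other numerical details: weights use He initialization; the soft-Dice
loss uses a +1 smoothing term in numerator and denominator; probability
ties at the 0.5 threshold go to background (deterministic, conservative);
`displacement()` floors Δd at 0 while `stiffness()` refuses Δd ≤ 0
rather than returning infinity; both-empty masks define Dice = IoU = 1;
centre crops drop odd remainder rows/columns at the bottom/right; the
centre column of an even-width frame is the left-of-centre one. A noted
metadata quirk: a 5 × 5 mm field cropped to 997 px implies ≈ 5 µm/px
laterally, which conflicts with the stated 10 µm lateral optical
resolution; the package carries pixel pitch in the series metadata and
does not attempt to resolve the discrepancy.

## Reproducibility

Every stochastic component (phantom speckle, per-series geometry, patient
shuffle, weight initialization, minibatch order, table simulation) is
seeded; identical config + seed reproduces pixel-identical phantoms,
identical training histories and bit-identical pipeline CSVs.
`runPipeline()` derives stage seeds from one global seed, writes every
intermediate artifact, and records config, config checksum, seeds and
per-stage metrics in a JSON manifest.

## Worked example

```{r example}
library(octstiff)

cfg <- phantomConfig(imageHeightPx = 128, imageWidthPx = 128,
                     scTopDepthMm = 0.15, scThicknessMm = 0.12,
                     kTrueNPerMm = 1.5, seed = 42)
proto <- airJetProtocol(pressurePa = 5e4)   # 5/5/5 s, F = 0.157 N
ph <- generatePhantomSeries(cfg, proto)

res <- quantifyStiffness(ph$series, truthMasks(ph$truth), proto)
res   # K recovered within raster quantization of 1.5 N/mm
```

## Known limitations

* Phantom realism is first-order only (see above); clinical performance
  claims cannot be read off phantom metrics.
* The U-Net trains on CPU at desk scale; very large rasters or deep
  configurations are computationally expensive in pure R.
* Deformation is elastic and instantaneous; creep/recovery dynamics are
  not modelled, so the recovery window carries no extra information in
  phantoms.
* The statistics stage treats subjects as exchangeable and complete;
  missing cells are skipped, never imputed.
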