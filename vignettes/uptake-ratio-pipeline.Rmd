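---
title: "Atlas-template-based uptake-ratio analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas-template-based uptake-ratio analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

Longitudinal small-animal FDG-PET studies compare regional glucose
metabolism between an experimental group (here: rats after induced
subarachnoid hemorrhage, SAH) and sham-operated controls across serial
measurements. Raw PET volumes from different animals and sessions are not
spatially comparable: each scan sits in its own scanner pose, and PET alone
carries too little anatomy to delineate brain regions. The pipeline
implemented in **urpet** solves this the way the semi-automated
template-based tools in this field do:

1. build a PET template from the control-group scans,
2. align every study scan to that template (same-modality affine
   registration),
3. co-register the template with a structural MR volume carrying an integer
   label atlas (cross-modality affine registration, run twice as a
   refinement), and
4. carry every scan into atlas space through the composed transforms, so
   atlas labels define volumes of interest (VOIs) on every scan.

Quantification then uses the uptake ratio

\[ UR = \frac{\text{mean activity concentration in } VOI_{target}}
             {\text{mean activity concentration in } VOI_{wholebrain}}, \]

a semi-quantitative measure that cancels injected activity and body weight
(both appear as a global intensity scale common to numerator and
denominator). The standardized uptake value
\(SUV = C \,/\, (A_{inj}/w)\) — concentration over injected activity per
body weight — is computed alongside for comparison; unlike UR it inherits
the variance of dose and weight.

Group differences are evaluated with exact two-sided Mann–Whitney U tests
(no normality assumption is defensible at \(n = 7\) per group), Bonferroni
corrected for the serial measurements, with significance stars at adjusted
\(p \le 0.05/0.01/0.001\).

## Reading the UR definition

"Measured radioactivity" in a VOI is read as the *mean* activity
concentration, not the summed counts: uptake ratios in this tradition are
concentration ratios, and a sum-based UR would scale with region volume,
making cross-region comparison meaningless. The literal summed reading is
available as `ur_mode = "sum"`. Voxels flagged out-of-field by resampling
are excluded from numerator and denominator alike — zero-filling them would
bias the ratio.

## Registration machinery

Registration is intensity-based affine optimization over a coarse-to-fine
block-mean pyramid, with a deterministic BFGS descent on parameters
(translation in mm, Euler angles, per-axis log-scale, shear), centred on
the fixed image's world centroid so that rotation and translation are
decorrelated. All geometry lives in world millimetres; voxel indices are
0-based with the affine evaluated at voxel centres.

Metric choices:

* **NCC** (normalized cross-correlation) for PET-to-PET: the right choice
  within a modality, invariant to global intensity scaling.
* **NMI** (Studholme's overlap-invariant normalized mutual information) for
  the PET-template-to-MR stage. Plain MI is also available, but on
  blob-like brain images its affine optimum is displaced by roughly a voxel
  (the classic shrinkage pathology); NMI does not shrink and is exact when
  the images are already aligned. A correlation-ratio metric (`"cr"`) is
  provided as a third option.
* The fixed image is cropped to the bounding box of its intensity support
  (snapped to the pyramid factor so pyramid grids stay aligned), and the
  metric can be subsampled (`stride`) at fine levels — the usual
  speed/accuracy compromise.

Degenerate inputs are rejected: zero-variance images, and moving images
whose support covers less than 5% of the field of view (fitting background
is never meaningful). A failed scan registration flags the scan; it is
excluded from quantification and logged, and never silently zeroed.

The returned transform follows the pull-back convention: it maps
fixed-space world coordinates into moving-space coordinates and is directly
usable for resampling the moving image onto the fixed grid.

### Default profiles

`register_affine()` defaults to the thorough profile: 12 degrees of
freedom, three pyramid levels (×4, ×2, ×1), up to 200 iterations,
convergence at a relative cost change of 1e-6. `run_study()` uses a
desk-scale profile for its many per-scan registrations: 9 degrees of
freedom (scanner repositioning is rigid plus a modest scale), two levels
(×4, ×2), stride-2 metric sampling, centroid initialization, 30 iterations.
On the 64³ phantom this profile recovers transforms to well under half a
voxel while keeping a 56-scan study around a quarter of a minute.

### Template construction

The control-group template is the voxel-wise mean of intensity-normalized
scans (each divided by its whole-field mean), refined by two
register-and-average iterations. The template pose is anchored to the first
control scan — every warp is composed with the inverse of that scan's
transform — so iteration sharpens the average instead of drifting toward a
consensus pose. Averaging is out-of-field aware, and the final template is
renormalized to voxel mean 1. The initial mean is permutation-invariant in
the scan order; the anchored refinement is, by construction, anchored to
whichever scan is designated first.

### Known registration limitations

Cross-modality metrics on PSF-blurred PET versus sharp MR have optima that
sit a fraction of a voxel away from the true pose on this class of images;
we measured roughly 0.4–0.7 voxel for both NMI and the correlation ratio,
and verified it is a property of the metric surface (the cost at the found
optimum is genuinely better than at the true pose), not of the optimizer.
Because the template-to-MR transform is shared by every scan, this bias
shifts all regional means coherently and cancels from between-group and
within-group comparisons; it does, however, bound the absolute accuracy of
atlas-space placement at PET resolution.

Similarly, when two images with *different regional contrast* (an SAH scan
versus a sham template) are registered, the NCC optimum is displaced by a
few tenths of a voxel. This is inherent to intensity-based registration and
is the reason the exact noiseless-closure check below uses a null phantom.

## The digital phantom

`phantom_spec()` / `make_atlas()` / `simulate_study()` generate a complete
synthetic study with ground truth: generating transforms, true regional
means, and true URs. The phantom emulates the design the analysis assumes —
two groups of 7, four serial measurements (3 h, 1 d, 4 d, 7 d), ~0.8 mm PET
voxels at 64³, a high-resolution MR/atlas pair that the pipeline resizes to
PET resolution — and the disease's effect structure: gray matter, neocortex
and olfactory system elevated in the SAH group, white matter and basal
forebrain reduced.

Geometry. The brain is an ellipsoid; the five analysis regions are compact
structures (central white-matter core, two lateral gray-matter lobes, a
ventral basal-forebrain blob, an anterior olfactory bulb) plus a thin
dorsal neocortex shell, with an unlabelled `brain_tissue` label completing
the whole-brain VOI. Two properties of real labelled atlases matter here
and are built in deliberately:

* each analysis region is a *minority share* of whole-brain activity
  (10–15% for the large ones), so a regional effect does not re-enter its
  own UR denominator at full strength; opposite-direction effects
  (elevations and reductions) largely cancel there, as in the disease; and
* the large regions are *compact* (low surface-to-volume), so the 1.5 mm
  point-spread blur does not wash out their multiplicative effects — a
  thin-shell gray matter would lose half its effect to partial volume.

Noise model, from inside out: per-scan, per-region biological variability
(lognormal, CV 5%), a per-scan global intensity factor (lognormal, CV 15% —
dose/uptake variability that cancels in UR but not in SUV), Gaussian PSF
blur (1.5 mm FWHM), a random per-scan affine misalignment (uniform within
±1.6 mm, ±5°, scale 0.97–1.03), and voxel-wise Poisson counts (60 expected
counts per voxel at unit concentration). The biological CV default is
calibrated to the significance levels the study design reports: exact rank
tests at \(n = 7\) reaching \(p \le 0.01\)–\(0.001\) require near-complete
separation of the group UR distributions, which at ×1.3 / ×0.8 effects
corresponds to a regional CV of about 5%. Poisson noise approximates
reconstructed-image noise without modelling the reconstruction itself,
which is out of scope.

What the phantom does *not* emulate: real rat neuroanatomy, spatially
correlated reconstruction noise, attenuation/scatter residuals, motion
within a scan, and partial-volume structure finer than the PET grid.
Passing tests on the phantom therefore demonstrate the pipeline's
*mechanics* — geometry handling, registration recovery, quantification
identities, statistical calibration — not clinical validity on real data.

## Statistical details

The exact Mann–Whitney distribution is computed by the classical counting
recursion (coefficients of the Gaussian binomial), equivalent to full
enumeration of all \(\binom{n_1+n_2}{n_1}\) group assignments; the
two-sided p is twice the smaller tail at the observed U, capped at 1. Ties
switch to the midrank normal approximation with tie correction and
continuity correction — exact enumeration assumes a tie-free sample.
With \(n_1 = n_2 = 7\) the exact test attains a size of about 0.04 at
nominal 0.05 (discreteness makes it conservative), which the acceptance
suite verifies empirically.

Bonferroni families: the correction is applied over the *serial
measurements* — family size 4 (one between-group test per timepoint) for
between-group comparisons, 6 (all timepoint pairs) within groups. Both are
configurable, and `NULL` derives the family size from the comparisons
actually performed. Within-group serial comparisons use the same unpaired
test throughout; a paired alternative is deliberately out of scope.

## Problem sizes and numerical choices

The shipped validation exercises the full design at 64³ (the phantom's
native grid): registration recovery over 20 random perturbations,
noiseless closure of the complete pipeline on a null phantom, empirical
test size over 2000 null replicates, and end-to-end effect recovery over
50 independently seeded studies. The noiseless-closure tolerance of 1e-3
is only meaningful on the null phantom: with group effects present, the
NCC optimum between cross-contrast image pairs is legitimately displaced
(see above), which is a property of intensity-based registration, not an
implementation error.

Other numerical choices: trilinear interpolation everywhere for intensity
images and nearest-neighbour for label grids (labels are never averaged);
resizing preserves the world extent of the grid to within one output voxel;
out-of-field voxels are flagged, never zero-filled; all optimizer paths are
deterministic, so identical configuration and seed reproduce every CSV and
JSON artifact byte for byte.

## Using the package

```{r example}
library(urpet)

spec <- phantom_spec(seed = 17)
aset <- make_atlas(spec)
study <- simulate_study(aset, spec)

fit <- run_study(study$manifest, study$volumes, aset$mr, aset$atlas)
print(fit)
summary(fit)
plot(fit, region = "gray_matter")
```

or, configuration-driven (also available from the shell via
`inst/cli/urpet.R`):

```{r pipeline}
cfg <- list(study = list(phantom = list(n_per_group = 7)))
fit <- run_pipeline(cfg, seed = 17, out_dir = "results")
```
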