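---
title: "Methods: a digital liver phantom for SUV reproducibility studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a digital liver phantom for SUV reproducibility studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petliver)
```

## Purpose and scope

Liver standardised uptake values (SUV) are widely used as a reference-tissue
check and as a normalisation basis in [18F]FDG PET, yet the numbers one reads
off an image depend on technical choices that have nothing to do with the
patient: the size and placement of the volume of interest (VOI), the amount
of counts retained in the reconstruction, the reconstruction voxel size and
point-spread function, and — potentially — competition for tracer from a
large tumour burden. `petliver` provides a fully synthetic, fully controlled
test bed to quantify those effects: a digital liver phantom with a known
ground truth, standard uptake metrics (SUVmax, SUVpeak, SUVmean), fixed-
threshold metabolic tumour volume (MTV) segmentation, paired statistical
experiment drivers, and a guideline-style liver quality-control (QC) rule.

The phantom is an *emulation* of the statistical behaviour of reconstructed
PET images, not a physics simulation. It reproduces the properties that
matter for VOI-statistic reproducibility — a homogeneous organ with
multiplicative-looking noise whose magnitude scales with retained counts and
whose texture is correlated by the reconstruction point-spread function — and
deliberately omits scatter, randoms, attenuation, motion, iterative-
reconstruction non-stationarity and anatomical texture. Conclusions drawn
from it concern the *ordering and relative magnitude* of technical effects,
not absolute clinical values.

## The image model

An image is generated in four steps.

1. **Noiseless activity map.** On a voxel grid of a chosen shape and spacing,
   a liver is painted as a solid ellipsoid at `liver_suv` (default 2.2, a
   typical hepatic SUV) over a uniform background at `background_suv`
   (default 0.8). Optional spherical tumours are painted at their own SUV.
   A voxel belongs to a region when its *centre* lies inside the analytic
   surface; the same centre-inclusion rule is used everywhere in the package
   (VOI rasterisation, tumour painting) so volumes converge to the analytic
   value as the grid is refined.

2. **Tumour sink effect.** A large metabolically active tumour volume can
   act as a sink for the available tracer, lowering uptake elsewhere. The
   phantom models this as a saturating rescaling of the liver SUV:

   `effective_liver_suv = liver_suv / (1 + sink_coeff * MTV_ml / 1000)`

   With the default `sink_coeff = 0.3`, a 1000-mL tumour load lowers the
   liver from 2.2 to about 1.69; with `sink_coeff = 0` the liver is
   unaffected, which provides the negative control used in the tests.

3. **Count-dependent noise.** Independent zero-mean Gaussian noise is added
   to every voxel with standard deviation

   `sd = sigma0 / sqrt(count_fraction * voxel_volume_ml)`

   so that halving the counts or halving the voxel volume increases the
   voxel-level noise by sqrt(2) — the familiar Poisson-like scaling of
   percentage noise with retained counts. `count_fraction = 0.25`
   (quarter-count data) therefore carries twice the percentage noise of the
   full-count image, which is the headline quantity recomputed by
   `scripts/acceptance.R`.

4. **Reconstruction smoothing.** The noisy map is convolved with a separable
   3-D Gaussian whose full width at half maximum (FWHM) is set by the
   reconstruction profile, then negative voxels are clipped to zero.
   Because convolution is linear, the noise-free image equals the smoothed
   noiseless map exactly, and noise realisations differ from it only by
   smoothed white noise.

### Reconstruction profiles

`recon_profile()` provides four named presets spanning the range from
harmonised (EARL-style) to high-resolution reconstructions:

| name      | voxel (mm) | PSF FWHM (mm) |
|-----------|-----------:|--------------:|
| EARL1     | 4          | 7             |
| EARL2     | 4          | 5             |
| HR2MM     | 2          | 4             |
| HR2MMPSF  | 2          | 3             |

The phantom grid is derived from the profile: the field of view is fixed by
`shape * voxel_mm` of the specification and re-gridded at the profile's voxel
size, so switching from EARL1 to HR2MM doubles the matrix rather than
shrinking the anatomy.

### Noise calibration is closed-form

The specification parameter `cov_full` (default 0.12) states the liver
coefficient of variation (CoV = sd/mean over liver voxels) to be achieved at
full counts. Because the pipeline is linear — white noise of sd
`sigma0 / sqrt(f * v)` passed through a normalised separable kernel `k` — the
post-smoothing noise sd in the organ interior is exactly
`sigma0 * ||k||_2 / sqrt(f * v)`, where `||k||_2` is the L2 norm of the 3-D
kernel. `sigma0` is therefore solved analytically:

`sigma0 = cov_full * effective_liver_suv * sqrt(voxel_volume_ml) / ||k||_2`

This is exact and deterministic; no iterative tuning against realisations is
needed, and the measured liver CoV of generated phantoms matches `cov_full`
to within sampling error (verified by the test suite at 5% relative
tolerance over repeated realisations, and to 2% on the mean over 100
realisations).

### The reported liver mask is eroded

`generate_phantom()` returns a `liver_mask` eroded inward by
`liver_margin_mm` (default 12 mm, i.e. the ellipsoid semi-axes reduced by the
margin). The smoothing step blurs the liver/background edge over roughly two
FWHM, creating a deterministic intensity gradient near the boundary. If
boundary voxels were included, the liver CoV would contain a constant
blur-gradient component unrelated to image noise, and the CoV would no
longer scale as `1/sqrt(count_fraction)`. Eroding the reported mask makes
`liver_cov()` a clean noise measurement. The *painted anatomy* is still the
full ellipsoid; only the reporting mask shrinks. One consequence worth
noting: even at `cov_full = 0` the voxel values inside the eroded mask are
not perfectly constant — a residual deterministic gradient of order 1e-3
SUV survives the 12-mm margin — so "noise-free" assertions in the tests are
phrased as CoV below 0.5% plus bit-exact reproducibility rather than
exact constancy.

## Uptake metrics

All three metrics operate on a spherical VOI rasterised by voxel-centre
inclusion (`voi_mask()`):

* **SUVmax** — maximum voxel value in the VOI. Sensitive to both VOI size
  (a maximum over more voxels can only grow) and noise amplitude.
* **SUVmean** — arithmetic mean over the VOI. In a homogeneous organ it is
  nearly invariant to VOI size and to noise level, since zero-mean noise
  averages out.
* **SUVpeak** — the EANM-style peak: the highest mean over a 1-mL sphere
  (radius `(3 * 1000 / (4*pi))^(1/3)` ≈ 6.2 mm) whose centre voxel lies in
  the search VOI and whose sphere fits inside the image grid. Ties are
  broken by the first candidate in linear (column-major) index order, so the
  result is deterministic. Implementation note: because all candidate
  spheres are translates of one voxel-offset stencil on a regular grid, the
  stencil is computed once and applied by index shifts; the test suite pins
  this fast path to a brute-force re-derivation on random images with
  `expect_identical`.

If the requested 1-mL sphere exceeds the requested volume of a sub-voxel
grid, i.e. no admissible sphere exists or the sphere degenerates to a single
voxel, the definitions still apply: a sphere smaller than one voxel contains
exactly the centre voxel and SUVpeak reduces to SUVmax over the search
region.

## MTV segmentation

`segment_mtv()` thresholds the image at a fixed SUV (default 4.0,
*inclusive*: a voxel at exactly 4.0 is tumour), labels 3-D connected
components under 6-, 18- or 26-connectivity (default 26), optionally drops
components below `min_component_ml`, and reports per-component and total
volumes in mL. The labeller is a vectorised breadth-first search implemented
in the package; no installed dependency offered 3-D connectivity with a
selectable neighbourhood. Volumes are voxel counts times voxel volume, so a
voxelised 30-mm sphere agrees with its analytic 14.14 mL to within the
surface-voxel discretisation slack.

## SUV unit layer

`read_suv_image()`/`write_suv_image()` handle NIfTI volumes (via RNifti)
with a JSON sidecar holding acquisition metadata. Conversion between
activity concentration (Bq/mL) and body-weight SUV uses

`SUV = activity / (injected_dose * decay_factor / body_weight)`

with `decay_factor = 2^(-delta_min / half_life_min)` and the [18F]
half-life 109.77 min as default. Reading an image without a sidecar is
allowed for unitless workflows but is flagged (`units_assumed`), and
requesting conversion without metadata is an error rather than a guess.

## Experiment drivers and statistics

Each driver generates replicate phantoms that share anatomy and differ only
in the noise seed, extracts metrics, and returns raw per-replicate rows
plus medians, quartiles (type-7), and hypothesis tests:

* `run_voi_size_experiment()` — concentric VOIs of 10/15/20/30/50 mm on the
  *same* realisations; paired two-sided Wilcoxon signed-rank tests between
  consecutive diameters.
* `run_location_experiment()` — five VOI placements (centre plus offsets
  along the axes); each peripheral site compared with the centre, Holm-
  adjusted within each metric.
* `run_noise_experiment()` — full versus reduced count fractions with paired
  seeds; also reports the liver CoV per fraction and the CoV amplification
  ratio.
* `run_recon_experiment()` — the four reconstruction profiles applied to
  the same acquisition: the noise level `sigma0` is calibrated once under
  the specification's own profile and held fixed across profiles, modelling
  one raw dataset reconstructed several ways. Sharper reconstructions
  (smaller FWHM) then show higher voxel noise and larger SUVmax.
* `run_mtv_association_experiment()` — tumour loads of 0/50/200/500/1000 mL
  placed outside the liver; Spearman rank correlation between measured MTV
  and each liver metric. Loads above 500 mL are split into two spheres on
  opposite sides of the liver so the largest load fits the field of view.

Wilcoxon tests use the normal approximation (`exact = FALSE`); degenerate
comparisons (all paired differences zero, or a constant variable for
Spearman) are reported as p = 1 / rho = NA rather than errors, so noise-free
control runs summarise cleanly.

Default replicate counts (100 for VOI size, 30 elsewhere) and the phantom
sizes used in the test suite (the default 128×128×96 4-mm grid where the
claim concerns its own study conditions; 64×64×48 or 96×96×72 grids for
repeated-study checks) are the package's own choices, balancing statistical
resolution against runtime.

### VOI locations

`default_location_offsets()` places site A at the liver centre, B/C at
±40 mm on x, D at +30 mm on y and E at −25 mm on z. The x offsets probe
deep positions along the longest semi-axis; the y and z offsets are scaled
down so that a 30-mm VOI at the default (80, 60, 50) mm liver stays clear
of the blurred organ boundary. `run_location_experiment()` refuses
configurations where a VOI would protrude from the ellipsoid.

## Liver QC

`qc_liver()` measures SUVmean in a 3-cm spherical VOI and applies
`qc_decision()`: *pass* when the value lies in the inclusive range
[1.3, 3.0], *flag* otherwise, with a message pointing at the usual culprits
(body-weight entry, injected-activity entry or residual dose, scanner
calibration). The bounds are the guideline reference range for hepatic
SUVmean plausibility and are deliberately the function defaults rather than
hidden constants.

## Reproducing the quantitative claims

`scripts/acceptance.R` regenerates the package's headline number from
scratch: the ratio of the median liver CoV at quarter counts to full counts
over 50 paired phantoms (expected ≈ 2 by the `1/sqrt(f)` noise law). It
takes `--seed` and `--out` arguments and writes a small JSON file; see the
README for usage. The test suite (`testthat`, edition 3) additionally pins
the closed forms, the brute-force metric oracles, the monotonicity and
invariance patterns of each experiment, and the statistical calibration
(type-I error of the paired tests under the null).

## Limitations

* Gaussian noise plus Gaussian PSF is a stylised stand-in for iterative
  reconstruction; real PET noise is non-stationary and object-dependent.
* The liver is homogeneous; real hepatic texture adds variance to small-VOI
  metrics that the phantom does not model.
* The sink effect is a one-parameter phenomenological rescaling, not a
  kinetic model.
* Only body-weight SUV is implemented (no lean-body-mass or BSA variants).
* The QC range check evaluates a single VOI; it does not implement a full
  accreditation procedure.
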