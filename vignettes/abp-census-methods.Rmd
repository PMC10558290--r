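---
title: "Methods: quantifying cellular and cytosolic ABP concentrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying cellular and cytosolic ABP concentrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abpcensus)
```

# The measurement problem

Actin networks in budding yeast are built and torn down by roughly a
dozen conserved actin-binding proteins (ABPs). Modelling how these
proteins compete and cooperate requires two numbers per protein: its
total cellular concentration, and the fraction of it that is *free* in
the cytosol rather than bound to F-actin structures (cortical patches
and cables). `abpcensus` implements the complete quantification chain
for both numbers, plus the bookkeeping that turns them into an actin
budget, and a synthetic-microscopy generator that provides ground truth
for validating the imaging half of the pipeline.

# From blot band to molecules per cell

## Standard-curve densitometry

Known masses of purified protein are run beside lysate lanes; band
signal is regressed on mass by ordinary least squares
(`fit_standard_curve()`), and lysate bands are inverse-interpolated
(`quantify_lysate()`), normalised by loaded total protein to give an
abundance in ng ABP per µg total protein. Two deliberate choices:

* **Unweighted OLS.** The standards span about one decade of mass, so
  variance heterogeneity across the range is modest; no weighting is
  applied.
* **Interpolation only.** "Within the linear range" is read
  conservatively: a lysate lane is used only if its inverse-predicted
  mass lies inside `[min, max]` of the standard masses. Out-of-range
  lanes are excluded (and logged), never extrapolated, and never reach
  the replicate aggregate (`aggregate_replicates()`, mean ± sample SD).

## The conversion constant K

Concentration follows from abundance `a` (ng/µg) and molecular weight
`mw` (kDa) as

$$ C\;[\mu M] \;=\; a \cdot K / mw, $$

where K is dimensionally the cytoplasmic protein mass concentration in
g/L. Two modes are exposed (`conversion_constant()`):

* **First principles**: K = (protein mass per cell) / (cytosolic
  volume), with the volume from `cytosolic_volume()` — wet mass
  (6×10⁻¹¹ g) / density (1.1126 g/ml) × cytoplasm fraction (0.5) ≈ 27
  fL — giving K ≈ 148 g/L.
* **Calibrated (default)**: K solved from the actin row of the
  packaged reference table (13.2 µM × 41.8 kDa / 7.99 ng/µg ≈ 69.06).

The published table is internally consistent with the *calibrated*
value only; the stated cell constants imply a K about 2.1× larger. The
package defaults to the calibrated mode so that downstream numbers
reproduce the published table, and keeps the first-principles mode
available precisely so the discrepancy stays visible rather than
buried. Copy numbers then follow as `C × V × N_A`
(`concentration_to_molecules()`), with V ≈ 27 fL.

Proteins without usable antibodies are handled by two secondary routes:

* **GFP calibration** (`fit_gfp_calibration()`): per-cell GFP intensity
  regressed on Western-derived concentrations for tagged ABPs of known
  abundance; the fitted line (intensity on the y axis, matching its
  published orientation) is inverted to read off unknown
  concentrations.
* **Molar ratio** (`ratio_estimate_abundance()`): Tpm2 is ~6-fold less
  abundant than Tpm1. The division is applied on the *abundance* scale
  and then converted with Tpm2's own molecular weight; dividing the
  Tpm1 concentration directly by six would ignore the MW difference
  between the paralogs and does not reproduce the published Tpm2 row.

## Data-integrity notes on the packaged table

The reference table ships every printed value verbatim. Three rows are
not perfectly self-consistent with the table's own conversion
arithmetic, and the test suite pins them down rather than hiding them:

* the printed molecule counts of **Aip1** and **Cap1/2** are not
  reproducible as `conc × V × N_A` (all 13 other rows agree within
  ~2%);
* recomputing concentrations from abundance reproduces print within 1%
  for every Western-blot row except **Cap1/2** (~5%), and **Pfy1**
  (whose abundance column is itself a back-computed GFP value) lands at
  ~1.2%.

Capping protein is one record at heterodimer concentration
(`oligomer_n = 2`); Srv2 is stored per polypeptide with
`oligomer_n = 6` for hexamer accounting; Arp2/3 complex is represented
by the Arp2 subunit's concentration, as in the source table.

# The actin budget

The G-actin pool is estimated kinetically (`estimate_g_actin()`): a
cable elongating at 0.3 µm/s consumes 0.3 × 370 = 111 subunits/s, and a
formin elongating at 25 subunits s⁻¹ µM⁻¹ therefore needs
111 / 25 = 4.44 µM profilin–actin. F-actin is the remainder of the
13.2 µM total (`f_actin_by_subtraction()`). Binder-class sums
(`sum_binder_class()`) always exclude actin itself. Binding timescales
use the mean waiting time of a pseudo-first-order association,
`1/(k_on · C)` with a diffusion-limited `k_on` of 10 s⁻¹ µM⁻¹; "binds
within x seconds" is read as this mean time, since no quantile is
specified anywhere. Cofilin's cytosolic fraction could not be measured
with a functional GFP fusion; budget outputs that need it use an
assumed fraction (default 0.76, the midpoint of the 0.61–0.91 range
observed across the other ABPs) and carry an explicit
`fraction_assumed` flag.

# Measuring cytosolic fractions from two-channel stacks

The measurement follows the published recipe exactly
(`measure_stack()` composes the steps, all individually exported):

1. average-intensity z-projection of the ABP channel; maximum-intensity
   projection of the marker (patch/cable) channel;
2. cell segmentation on the average projection — by default a
   threshold segmenter (Otsu in log space, hole filling, connected
   components, minimum size, border flagging); any externally produced
   mask can be supplied instead, so learned segmenters plug in at this
   boundary;
3. a single scalar autofluorescence background per channel per
   session, measured on label-free cells (`estimate_background()`) and
   subtracted from all pixels;
4. a structure mask from the marker projection at a threshold (the
   "set point"), intersected with the cell mask;
5. fraction = mean(unmasked in-cell pixels) / mean(all in-cell
   pixels).

Numerical and design choices that were genuinely open:

* **Set point default.** The set point is an Otsu threshold of the
  *log-transformed* in-cell marker intensities. Linear-scale Otsu on an
  image dominated by a few very bright puncta places the cut near half
  the peak, which leaves most of each structure's PSF-blurred skirt
  outside the mask and inflates the apparent cytosol; the log transform
  places the cut in the valley between the background mode and the
  structure signal. A manual set point and a mask-dilation option are
  exposed, and `threshold_sweep()` quantifies sensitivity to ±25%
  changes around any set point.
* **No-structure guard.** If the in-cell marker maximum is less than
  ten MADs above the in-cell median, the marker contains no structure
  signal (pure noise tops out around four) and the mask is left empty;
  otherwise Otsu would carve noise pixels out of the cytosol of
  structure-free cells.
* **Background on the projection scale.** The average projection
  spreads in-cell signal over all 35 slices, so the measured background
  of an autofluorescent cell is its *per-projected-pixel* mean, not the
  per-voxel autofluorescence level. Both the background and the ABP
  measurement live on the same scale, which is what makes the scalar
  subtraction correct.
* **Fractions above 1** (possible on noisy input) are flagged, not
  clipped, so population means stay unbiased.
* **2D masking.** Masking operates on projections, as the source
  method does, not in 3D.
* **Degenerate inputs.** A structure mask covering the whole cell, an
  empty cell mask, or a non-positive whole-cell mean after background
  subtraction are hard errors, not NaNs.

# The synthetic-cell generator

`generate_cell_stack()` emulates the acquisition geometry: 35 z-slices
at 0.2 µm, 0.065 µm pixels, a spherical cell of radius 2.25 µm (2–2.5
µm across a population). The ABP channel holds a uniform cytosolic pool
(100 AU) plus the structures; the marker channel holds the structures
only; both get uniform in-cell autofluorescence (10 AU), an anisotropic
Gaussian PSF (σ = 0.1 µm lateral, 0.3 µm axial — the standard desk
approximation of a confocal PSF), Poisson shot noise (gain 1), and
Gaussian read noise (sd 2 AU), clipped at zero as a camera would.
Patches are 3D Gaussian puncta (σ = 0.1 µm, 15 per cell, on a cortical
shell at 0.8 r — endocytic-patch dimensions and density); cables are
Gaussian tubes along the mother–bud axis. Structure fields are
truncated to the cell, so total pre-noise signal decomposes exactly
into cytosol + structure integrals, and the ground-truth fraction is
**analytic**: the structure amplitude is solved from the requested
fraction before rendering. The recorded truth also carries pre- and
post-blur integrals so tests can verify that the PSF conserves
integrated intensity (within <1% boundary truncation) and therefore
that the ground-truth fraction is blur-invariant. Everything is
bitwise reproducible for a fixed seed.

What the generator deliberately does **not** emulate: bud-neck
geometry, photobleaching, temporal dynamics, depth-dependent PSF
variation, structured (non-uniform) autofluorescence, and segmentation
difficulty (cells sit on a dark background). Passing recovery tests on
these images therefore validates the *measurement arithmetic and
masking logic*, not robustness to the full messiness of real
micrographs — in particular not to segmentation errors, which the
plug-in boundary delegates to dedicated tools.

`generate_population()` draws projected areas uniformly (default
12–36 µm²) with fractions following a constant or linear-in-area law.
Its un-rendered fast path emits a per-cell manifest with
measurement-like noise on the fraction (sd 0.02) and lognormal total
intensities (CV 0.25 by default, within the 0.18–0.37 range observed
across ABP-GFP strains), which is what the population-statistics layer
consumes at n = 100; the rendered path produces actual stacks for the
imaging tests.

# Population statistics

`coefficient_of_variation()` is the sample SD over the mean.
`regress_vs_area()` operationalises "no major fluctuation over the
cell cycle" as: the 95% confidence interval of the OLS slope of
fraction (or total intensity) on projected cell area contains zero.
That criterion is this package's definition — the source reports
regressions without a formal test — and the raw slope and CI are always
reported alongside the verdict. When several proteins are screened no
multiplicity correction is applied (none is applied in the source);
reports note this. `compare_methods()` joins Western, GFP and
reference (mass-spectrometry) concentration tables, reporting ratios
and absolute differences, leaving proteins missing from a method as
absent rather than imputing.

# Known limitations

* **Cable masking bias.** Masking a cable removes its entire projected
  stripe, including the thick central cytosol columns above and below
  the cable, so measured fractions of cable-decorated proteins read
  systematically low (the test suite pins this at roughly −0.1 for a
  truth of 0.85 under default conditions). This is a property of
  projection-space masking itself; patch masks, which remove small
  cortical spots, do not suffer from it appreciably.
* The cytoplasm is a single compartment scalar (`cytoplasm_fraction`);
  no organelle-specific volumes.
* The conversion chain inherits whichever K mode is chosen; the two
  modes disagree by ~2.1× and the package cannot resolve which reflects
  reality — only which reproduces the published table.

# Problem sizes used in the tests

The suite validates fraction recovery at ground-truth fractions
{0.3, 0.5, 0.7, 0.9} with 20 seeded cells each at default noise
(median absolute error required < 0.05), threshold robustness at ±25%
around the automatic set point (< 0.05 spread), blot recovery over 200
simulated blots at 5% signal noise (mean within 2% of truth), and
population statistics at n = 100 cells. Stacks are 110×110×35 voxels;
the noise-convergence check runs at reduced size (9 slices, 0.6 µm
radius) over 60 noise realisations. These sizes were chosen to give
stable statistics at desk scale.
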