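---
title: "Methods: label-free TIS quantification in tismorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: label-free TIS quantification in tismorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tismorph` quantifies therapy-induced senescence (TIS) in cancer cell
cultures from two label-free modalities: multimodal nonlinear-optical (NLO)
microscopy and quantitative phase imaging (QPI). This vignette is the
package's own account of the models and procedures it implements, the
parameters that matter, the design decisions taken where the design was
genuinely open, and what the synthetic validation does and does not show.

## The measurement model

### NLO channels

One field of view (FOV) is a set of co-registered 2D rasters acquired
simultaneously: TPEF (endogenous two-photon fluorescence of the
mitochondrial coenzymes NAD(P)H and FAD, arbitrary units), SRS (stimulated
Raman gain at the 2850 cm⁻¹ CH₂ stretch, reported as the dimensionless
modulation ΔI/I after `normalize_srg()` divides the lock-in output by the
Stokes transmission — the ratio is invariant under common detector gain),
F-CARS and E-CARS (coherent anti-Stokes channels; forward detection carries
a nonresonant four-wave-mixing background, NRB, while epi detection
suppresses it and favours sub-wavelength scatterers), and the linear
transmission, in which cells appear dark against the substrate. The default
geometry is a 105 µm field sampled at 300 px, i.e. 350 nm pixels; the
Nyquist-limited resolution is therefore 700 nm.

### Raw-image corrections

Two acquisition artifacts are corrected before any metric is computed.

**1-pixel outliers** (cosmic rays on the detectors) are median-filtered:
a pixel is replaced by its 3×3-neighborhood median when it deviates from
that median by more than `z_thresh` (default 5) times the MAD-scaled local
spread (1.4826 × the window's median absolute deviation from its median).
The gate makes the filter conservative on textured regions while a flat
window (spread 0) rejects any deviating centre — exactly the isolated
cosmic-ray case. Two consequences are worth knowing: a *pair* of adjacent
extreme pixels is also corrected (the window median around each member is
still the surrounding level), and convex corners of high-contrast objects
can be shaved by one pixel. The synthetic presets therefore paint puncta
and droplets at ≥ 21 px so that real structures survive intact.

**Serpentine shift.** Bidirectional stage scanning can displace the
reverse-scan rows (0-based even rows, configurable) by an integer pixel
count. `correct_serpentine()` estimates a single global shift k̂ as the
integer |k| ≤ 10 maximizing the mean Pearson correlation between each even
row, circularly shifted by −k, and its adjacent odd rows; ties break toward
smaller |k|, and a constant raster returns k̂ = 0 with a warning flag. The
estimate runs on a winsorized copy (1st/99th percentile clipping): outliers
would otherwise dominate row correlations, while clipping cannot mix
information between rows. **Order matters**: `preprocess_image()` applies
the geometric correction *before* the outlier filter, because the median
filter drags displaced rows toward their neighbours and erases the very
misalignment being estimated (on test FOVs, filtering first turned an
injected +4 px shift into an estimated −2). With correction first, injected
shifts over the whole ±10 px window are recovered exactly on noise-free
FOVs and under the default noise.

### NLO metrics

The cell footprint is segmented from the transmission channel: Otsu
threshold on the normalized histogram (cells are the dark class),
morphological closing (disc radius 2 px), hole filling, and removal of
components under 50 px². The cleanup constants are package defaults, not
measured quantities, and are exposed as arguments. All per-FOV metrics are
computed over the union cell mask, matching a design in which each FOV
holds ~10 cells and the FOV is the unit of replication.

With the universal thresholds 0.25 a.u. (TPEF) and 2.2×10⁻⁴ ΔI/I (SRS):

* **TPEF area fraction** `[Area(TPEF)/Area(Cell)]%` — strict `>` at the
  threshold; monotonically non-increasing in the threshold.
* **Max(TPEF)** — the mean of the ⌈0.1·|mask|⌉ highest in-mask pixels.
  Together with the outlier filter this makes the "maximum" robust to
  single hot pixels.
* **Mitochondrial aggregation index** = Max(TPEF) × area fraction. A note
  on its algebra: because Max is a top-decile mean, a punctate pattern
  covering under 10% of the mask at *equal total signal* scores lower,
  not higher, than a diffuse one — the index rises in senescent cells only
  because the condensed puncta are genuinely brighter (higher local
  coenzyme density). The synthetic TIS presets therefore raise the puncta
  amplitude as the covered area shrinks; the directional test asserts
  punctate-with-elevated-peak > diffuse, which is the physically meaningful
  comparison.
* **Lipid metrics** from the thresholded SRS raster: 8-connected components
  (the common particle-analysis convention; 4-connectivity available) of
  area ≥ 5 px² are *clusters*; those whose circularity 4πA/P² lies in
  [0.3, 1] are flagged *quasi-single* droplets. The perimeter is the
  crack-edge count (exposed unit pixel edges), under which a w×h rectangle
  has P = 2(w+h); digital circularity is clamped at 1 before the range
  test. Summaries: covered-area percentage, mean quasi-single area (µm²,
  reported as missing when no droplet qualifies — never as 0), cluster
  count and clusters per µm² of cell.

### Colocalization

`coloc_report()` bundles three statistics over in-mask pixel pairs
(analysis in the cell mask by default; pass a full-raster mask for a
whole-FOV analysis):

* Pearson correlation (error on constant channels);
* the **quadrant Manders coefficients**: with crosshairs (t1, t2),
  M1 = N_TR/(N_TR+N_BR) and M2 = N_TR/(N_TR+N_TL) over the co-occurrence
  quadrants. This pixel-*frequency* form matches thresholded scatter
  plots; the classical intensity-weighted form is available separately as
  `manders_intensity()`. A zero denominator yields a missing value.
* the **Costes randomization control**: channel 2 is permuted `n_rand`
  times and p = (1 + #{PCC_rand ≥ PCC_obs})/(1 + n_rand), one-sided by the
  method's intent. Default block size is 1 px because the 350 nm pixel
  pitch exceeds the ~280 nm point-spread function, so adjacent pixels are
  not optically correlated; `block_px > 1` permutes square blocks for
  oversampled data. The permutation p-value is uniform under an
  independent-noise null and reaches its floor 1/(n_rand+1) for identical
  structured channels.

Default crosshairs are the universal TPEF/SRS thresholds; the CARS channels
have no instrument-defined threshold, so the default is Otsu on the in-mask
values, overridable per call.

### QPI morphometrics

A tomogram is a 3D refractive-index grid with voxel geometry and medium RI
(PBS, 1.3342). Segmentation takes voxels above `n_medium + delta_n`
(default margin 0.003 — the background RI is exact in the data model, so
the margin only needs to clear in-cell noise), applies a 3D closing (cube
radius 1) and drops 26-connected components under 100 voxels. Metrics:

* volume = voxel count × voxel volume;
* mean thickness = volume / projected xy footprint (max-column thickness
  is available as an alternative);
* **dry mass**: DM = Σ (n − n_medium)·dV / α in picograms, with the
  refraction increment α = 0.19 ml/g for bulk cell matter and 0.135 ml/g
  for lipid. The unit identity Δn 0.019 over 1 µm³ at 0.19 ml/g = 0.1 pg
  is exact by construction (1 µm³/(ml/g) = 1 pg). Negative Δn voxels
  (noise) contribute zero and are counted. The equivalent phase-integral
  route DM = λ/(2πα)·Σ φ·dA is implemented (`dry_mass_from_phase()`, with
  `phase_from_tomogram()` as the projector) and agrees with the volumetric
  route to numerical precision on noise-free phantoms — the printed
  phase-integral formula omits its λ/2πα prefactor in common shorthand,
  and the cross-validated pair fixes the convention.
* **lipid droplets**: cell voxels with RI in the inclusive band
  1.40 ≤ n ≤ 1.46; volume by voxel count and dry mass at α = 0.135 ml/g.
  Lipid dry mass uses Δn relative to the medium (not to cytoplasm); the
  alternative would subtract the surrounding cytoplasmic RI and is not
  what a band-segmentation of the raw grid computes.

### Statistics

All metric populations are compared with the two-sided Mann–Whitney U test
at significance level 0.05: exact when the pooled sample is ≤ 16 without
ties, otherwise the normal approximation with mid-ranks, tie-corrected
variance and continuity correction (the method used is recorded; complete
ties return p = 1). The M1-vs-M2 comparison uses the pooled two-sample t
test with explicit degenerate handling. `timecourse_report()` runs
control-vs-TIS at each time point plus within-group tests against the 0 h
baseline (baseline pairing, since comparisons are stated against the
treatment start), skips groups under 3 values with a reason, and attaches
the star labels (boundaries inclusive on the significant side; p = 0.05
earns `*`). No multiple-testing correction is applied by default, matching
the source analysis design; users can correct the returned p-value column
themselves (`p.adjust`).

## The synthetic-data generator

The generator is the package's test bed: it paints the structures the
metrics respond to and the artifacts the preprocessing must undo, with
full ground truth, under a single seed (identical parameters + seed give
bit-identical rasters, and the caller's RNG state is untouched).

What it emulates: elliptical cells (jittered radii) dark in transmission;
a diffuse perinuclear TPEF annulus (control) or bright puncta (TIS)
hitting a target area fraction; lipid droplets as disks painted jointly in
SRS (ΔI/I ~10⁻³ against the 2.2×10⁻⁴ threshold) and F-CARS (bright spots
on the NRB); dim F-CARS-only speckles standing in for sub-resolution lipid
accumulations amplified by the NRB, which dominate the F-CARS-positive
population of control cells and keep their SRS co-occurrence (M2) near
zero; an E-CARS texture that overlaps the TPEF pattern only partially in
controls (a radial sub-band plus off-pattern scatterers, tuned so the two
Manders fractions are comparable but not degenerate) and tracks the puncta
plus small droplets in TIS; per-channel Gaussian noise; 1-pixel outliers;
and the serpentine row shift. Tomograms are ellipsoidal cells of constant
RI sitting near the substrate with embedded lipid spheres in the
1.40–1.46 band and in-cell RI noise, background exactly 1.3342; ground
truth records the analytic volume (4/3·π·abc), mean thickness (4c/3 for an
ellipsoid), and dry mass.

Named presets per time point track the published trends qualitatively:
TPEF-positive area 15% → 4% of the cell while the puncta brighten
(aggregation index up ~2×), lipid area near zero until 24 h, ~3% at 72 h
and ~20% at 7 days with larger droplets in more clusters; tomogram cells
enlarging toward ~2.5× volume and flattening to ~75% thickness with dry
mass more than doubling and lipid volume/mass rising steeply. The 0 h TIS
preset equals the control preset, so time-zero comparisons are null by
construction. Published summary statistics do not constrain per-image
dispersion, so a log-normal per-FOV multiplier (SD 0.15) on droplet
density and TPEF area target supplies plate-to-plate variability — a
chosen, not inferred, value.

What it does **not** emulate: coherent image formation (no speckle, no
phase retrieval, no NRB spectral interference), Poisson photon statistics
(noise is additive Gaussian; the metrics are threshold-based, so the noise
family matters little below threshold), deformable or touching cells,
nuclei, and any spectral dimension. One knowingly exaggerated coupling:
because puncta brightness and condensation share a single amplitude
parameter, the presets raise the mean TPEF in late TIS by ~2–3× where the
published rise is ~40%; all *directional* conclusions are unaffected.
Passing tests therefore demonstrate that the pipeline recovers known
ground truth and reproduces the phenotype's direction under controlled
conditions — not that it would reproduce the paper's numeric values on
real images, which are not publicly deposited.

## Numerical choices and problem sizes

* Component labeling is exact (union-find over the voxel adjacency graph),
  8-connected in 2D and 26-connected in 3D by default.
* The crack-edge perimeter makes digital circularity ≤ π/4 for a square
  and ~0.14 for a 1×20 line; the quasi-single band [0.3, 1] was calibrated
  against this definition.
* Thresholds use strict `>` for area fractions and quadrant counts,
  inclusive bounds for the lipid RI band.
* File formats: multi-page TIFF with 32-bit samples under a per-page
  affine map recorded in a JSON sidecar (TIFF pages store [0,1]); round
  trips are exact to ~2×10⁻¹⁰ relative quantization. Tomograms are TIFF
  z-stacks with the same sidecar scheme.
* Default tomogram grid: 212×212×64 voxels over 80.47×80.47×39.67 µm (a
  4× downscale of the instrument grid) — tests and the acceptance script
  use this size or smaller phantoms (e.g. 106×106×48 in the directional
  unit test) so the whole suite runs in minutes; discretization error at
  these sizes stays under the 5% phantom tolerance for radii ≥ 10 voxels.
* The validation suite runs n = 10 FOVs/tomograms per condition for the
  directional tests and 500 repetitions for null calibrations at the
  statistics level (drawing 10-vs-10 samples from one FOV-level metric
  distribution); a full image-level null (identical presets for both
  conditions) is checked once rather than 500 times, purely for runtime.

## Known limitations

* Single global serpentine shift (not per-row-pair); adequate when the
  stage distortion is systematic.
* Per-FOV union-mask metrics; per-cell splitting of the 2D mask is not the
  default unit of analysis (the 3D pipeline is per-cell).
* CARS crosshair defaults (Otsu) are data-driven and will move with the
  intensity distribution; fix them in the config for cross-batch
  comparability.
* The Costes control permutes within the analysis mask; with very small
  masks (< ~100 px) the p-value grid is coarse.
* Quadrant Manders coefficients are count-based and intentionally differ
  from the classical intensity-weighted definition.
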