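# tismorph

Label-free quantification of therapy-induced senescence (TIS) in cancer cell
cultures from two complementary imaging modalities:

* **multimodal nonlinear-optical (NLO) microscopy** — co-registered 2D
  channels: two-photon excited fluorescence (TPEF, from the mitochondrial
  coenzymes NAD(P)H and FAD), stimulated Raman gain at the 2850 cm⁻¹
  CH₂-stretching band reported as the normalized modulation ΔI/I (SRS),
  forward- and epi-detected coherent anti-Stokes Raman scattering (F-CARS,
  E-CARS) and the linear Stokes transmission;
* **quantitative phase imaging (QPI)** — 3D refractive-index (RI) tomograms.

A small fraction of treated cancer cells escapes apoptosis and enters a
senescent state that can drive tumor dormancy and relapse. `tismorph`
implements the image-derived indices that flag this phenotype without any
staining — mitochondrial signal condensing into bright puncta, lipid
droplets accumulating from ~72 h after treatment, cells enlarging and
flattening while gaining dry mass — together with the statistics used to
monitor them over a treatment time course, and a seeded synthetic-data
generator with full ground truth so the entire pipeline is testable without
instrument data.

## What it computes

**Preprocessing** (`preprocess_image`): MAD-gated 3×3 median filtering of
1-pixel cosmic-ray outliers; automatic estimation and correction of the
serpentine scan shift of bidirectional stages (integer row
cross-correlation, `correct_serpentine`); SRG normalization
ΔI/I = lock-in signal / Stokes transmission (`normalize_srg`).

**NLO metrics** (`nlo_metrics`): the cell footprint is segmented from the
dark transmission regions (Otsu + closing + hole filling). On the union
mask, with the universal thresholds 0.25 a.u. (TPEF) and 2.2×10⁻⁴ ΔI/I
(SRS):

* `[Area(TPEF)/Area(Cell)]%` — percentage of the cell carrying coenzyme
  signal (`area_fraction_pct`);
* `Max(TPEF)` — mean of the top-decile in-mask pixels (`top_decile_max`);
* mitochondrial aggregation index `Max(TPEF) × [Area(TPEF)/Area(Cell)]%`
  (`aggregation_index`);
* lipid metrics from 8-connected components of the thresholded SRS raster
  (`detect_droplets`): clusters (area ≥ 5 px²), quasi-single droplets
  (additionally circularity 4πA/P² in [0.3, 1], crack-edge perimeter),
  covered-area percentage, mean quasi-single area, clusters per µm².

**Colocalization** (`coloc_report`): Pearson correlation, the
pixel-frequency (quadrant) Manders coefficients
M1 = N_TR/(N_TR+N_BR), M2 = N_TR/(N_TR+N_TL) under crosshair thresholds,
and the one-sided Costes randomization p-value
(1 + #{PCC_rand ≥ PCC_obs})/(1 + n_rand).

**QPI morphometrics** (`qpi_metrics`): segmentation of the RI grid against
the PBS background (1.3342); volume, projected area, mean thickness
(volume/footprint); dry mass DM = Σ Δn·dV/α with dn/dc α = 0.19 ml/g for
bulk cell matter (0.135 ml/g for lipid) — 1 µm³·Δn/α is directly in pg —
plus the equivalent phase-integral route DM = λ/(2πα)·∫φ dA; lipid
droplets as the inclusive RI band 1.40 ≤ n ≤ 1.46.

**Statistics** (`timecourse_report`): two-sided Mann–Whitney U tests
(exact for pooled n ≤ 16 without ties, tie/continuity-corrected normal
approximation otherwise), control-vs-TIS at each time point and
within-group against the 0 h baseline, with the star mapping
\*0.01<p≤0.05, \*\*p≤0.01, \*\*\*p≤0.001, \*\*\*\*p≤0.0001.

**Synthetic data** (`generate_nlo_fov`, `generate_qpi_tomogram`,
`generate_timecourse`, presets `nlo_preset`/`qpi_preset`): seeded,
bit-reproducible FOVs (300×300 px at 350 nm/px) and tomograms
(212×212×64 voxels over 80.47×80.47×39.67 µm) with known ground truth,
emulating control vs TIS phenotypes per time point.

## Worked example

```r
library(tismorph)

# one senescent field of view, 7 days after treatment, with ground truth
g  <- generate_nlo_fov(nlo_preset("TIS", "7d"), seed = 5)
pp <- preprocess_image(g$image)           # outliers + serpentine shift
m  <- segment_cells(pp$image$channels$transmission)
nlo_metrics(pp$image, mask = m)[, c("tpef_area_pct", "aggregation_index",
                                    "srs_area_pct", "cluster_count")]
#>   tpef_area_pct aggregation_index srs_area_pct cluster_count
#> 1      3.143558          20.33498     11.00568            52

coloc_report(pp$image, m, c("SRS", "FCARS"), n_rand = 99, seed = 1)
#> <coloc_result> SRS:FCARS: PCC=0.959 M1=0.990 M2=0.945 (t1=0.00022 t2=0.709, n=15492) Costes p=0.01
```

A 7-day TIS cell here carries coenzyme signal on only ~3% of its area (a
control sits near 15%), lipid droplets cover ~11% of the cytoplasm in 52
clusters, and nearly all above-threshold F-CARS pixels co-occur with SRS
(M2 ≈ 0.95; controls sit near 0), i.e. the bright CARS spots are genuine
lipid vibrations, not nonresonant background. The full two-condition
time-course pipeline is one call:

```r
res <- run_all(list(seed = 1), out_dir = "out")   # writes CSVs + provenance
subset(res$tests, comparison == "control_vs_TIS" & metric == "srs_area_pct")
```

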