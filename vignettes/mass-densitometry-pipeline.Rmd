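---
title: "Label-free mass densitometry: simulation, unmixing, segmentation and population statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free mass densitometry: simulation, unmixing, segmentation and population statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noripipe)
```

## The measurement model

Three-band stimulated Raman scattering (SRS) microscopy images a specimen at
the 2853, 2935 and 3420 cm^-1^ bands, which report CH~2~ groups (lipid-rich),
CH~3~ groups (protein-rich) and water. Writing the per-pixel concentration
vector as $c = (c_p, c_l, c_w)$ in g/ml and the instrument's reference
spectra as a $3 \times 3$ response matrix $S$ (rows = bands, columns =
components, calibrated on protein, lipid and water standards), the forward
model of the acquisition is

$$ I = S\,c + \eta, $$

with $\eta$ the band noise. The unmixing inverts this per pixel
($x = S^{-1} I$), clips negative raw components to zero (recording the
clipped fraction as a QC metric), and converts the result to absolute
concentrations by the *volume-fraction closure*: each pixel is rescaled by
the unique positive factor such that

$$ v_p c_p + v_l c_l + v_w c_w = 1, $$

where $v$ are partial specific volumes (defaults 0.735, 1.087 and
1.0 ml/g for protein, lipid and water). Because the closure divides out any
common gain, the output is invariant to the overall intensity scale of the
acquisition. Dry-mass density is $c_p + c_l$; with a pixel volume in
µm^3^, 1 g/ml equals 1 pg/µm^3^, so masses integrate directly from
density maps. The protein channel physically includes a residual
nucleic-acid contribution; it is reported as protein.

Per-pixel sensitivity is 15 mg/ml in the protein channel. Averaging a
compartment of $n$ pixels reduces the error as $\sigma/\sqrt{n}$
(`estimate_section_error()`): a mid-section cytoplasm of several hundred
pixels yields a per-cell error below 1.5 mg/ml, under 2% of a typical
80 mg/ml cell — far below the cell-to-cell variability, which is what makes
single-section densitometry of large populations statistically sound.

### The unclipped companion planes

`unmix_image()` returns, alongside the clipped, closure-normalised
concentration planes, the same solution *without* the nonnegativity clip
(`protein_raw`, `lipid_raw`). Clipping is the right presentation for a
concentration image, but it skews the noise of near-zero channels: nuclear
lipid (~5 mg/ml true, 15 mg/ml noise) is inflated by about +3.8 mg/ml, and
the closure then pushes nuclear protein down by roughly 0.5 mg/ml. Both
threshold statistics and compartment-mean estimation therefore use the
unclipped planes — averaging before clipping is the unbiased order for a
mean whose per-pixel noise straddles zero. This choice was made from the
error analysis above, and the recovery tests confirm that residual biases
are below ~0.15 mg/ml for every compartment.

## The synthetic-data generator

Because raw images for this kind of experiment are generally not public,
the package ships a first-class phantom generator that every downstream
stage is tested against. `phantom_spec()` declares the study conditions;
`sample_population()` draws ground-truth cells; `render_density_map()` /
`render_density_stack()` rasterise them; `srs_forward()` produces noisy
band images.

Geometry: cells are mildly elliptical ellipsoids (axis ratio 0.85-1,
axial semi-axis 0.8 of the in-plane minor axis) with one slightly
offset nucleus (radius fraction 0.60 ± 0.04 of the cell) and 1-3
spherical nucleoli (radius fraction 0.30 ± 0.05 of the nucleus, truncated
to [0.18, 0.45]). Placements are non-overlapping by rejection sampling; an
unplaceable request fails with the achievable count. At the default
0.25 µm pixel a ~15 µm cell spans several hundred pixels at
mid-section; optical sections are 1 µm apart. Ground-truth volume and
mass are *voxelised* quantities — mass is exactly the sum of density times
voxel volume over the rendered cell — so `integrate_zstack()` recovers them
to machine precision, an identity the tests assert.

Densities: per-cell compartment densities are normal draws (truncated at
zero, truncations counted) with the HeLa-like control distributions
(mg/ml): cytoplasmic protein 74.5 ± 5.2, cytoplasmic lipid 29.1 ± 5.3,
nucleoplasmic protein 81.9 ± 5.4, nucleolar protein 110.0 ± 5.9, and
nuclear lipid 5 ± 1. The three protein compartments share a per-cell
multiplicative crowding factor (CV 0.05), because compartment protein
densities co-vary within a cell — their ratios are far more conserved than
the densities themselves, across cells and even under osmotic challenge.
Residual SDs are shrunk so each *marginal* keeps exactly the stated
mean/SD; without this correlation a few percent of cells would carry
essentially no nucleolar contrast, which real populations do not show.
Lipid draws stay independent, reflecting the distinct regulation of lipid.
Cell volume has a 28% CV (radius CV ≈ 28%/3), matching the dispersion of
volume and dry mass in cultured populations, and cytoplasmic density is
drawn independently of volume so the mass-volume correlation structure
(R ≈ 0.97 for protein mass vs volume, ~0 for density vs volume) emerges
rather than being imposed.

Noise: band noise is injected in band space but calibrated in density
units — the perturbation added to $I$ is $S\,\varepsilon$ with
$\varepsilon$ Gaussian per channel (protein default 0.015 g/ml, the
lipid and water channels defaulting to the same value since no separate
figure is available) — so the unmixed protein noise SD equals the nominal
sensitivity up to the few-percent effect of clipping and renormalisation
(asserted within 10% by the tests).

Condition presets (`condition_presets()`) encode perturbations as fold
changes on the control: pump inhibition (protein folds 0.6/0.6/0.8,
lipid 0.7), strong hyperosmotic compression (nucleoplasm rising to meet
nucleolar density), hypoosmotic dilution, actin depolymerisation,
protein-synthesis inhibition (OPP/SE fold 0.3), proteasome inhibition,
mTOR inhibition, serum starvation, and genotoxic senescence
(protein 0.87/0.90/1.08, lipid 1.66, dry mass 12.6-fold, OPP/SE one
fifth, EdU labelling near zero, 87% of cells senescent).

`sample_fluorescence_features()` emits the matched per-cell assay table:
Hoechst proportional to DNA content (1x in G1, 2x in G2-M, uniform in S;
lognormal staining noise, sdlog 0.06), SE proportional to true dry mass,
OPP and anti-RPS6 proportional to SE through preset folds, EdU bimodal by
S-phase labelling, SA-β-gal linear in SE with Gaussian residuals (scaled
up in senescent cells), and YAP nuclear/cytoplasmic intensities at a
preset localisation ratio.

What the generator does **not** emulate: optical point-spread blur,
photobleaching, within-compartment texture (real cytoplasm is remarkably
homogeneous, so compartments are flat fields; a texture knob would be the
natural extension), organelles beyond nucleus and nucleoli, mitotic
morphology, and spatial correlation of noise. Passing recovery tests
therefore demonstrate the correctness of the *computational* chain under
the declared imaging model, not robustness to every property of real
micrographs.

## Segmentation

The compartment chain follows the classic thresholding recipe: cell bodies
are protein density above 0.0666 g/ml (holes filled, objects under
200 px removed, touching cells split by watershed on the distance
transform, border-touching cells excluded by default); nuclei are, per
cell, the largest connected region with lipid density below 0.0099 g/ml
(at least 50 px, holes filled; cells without one — e.g. mitotic cells —
are flagged and excluded from compartment statistics); nucleoli are
segmented per nucleus by Otsu's method on protein density (components of
5 px up to half the nucleus).

Numerical choices that matter:

* **Pre-smoothing.** Planes are Gaussian-smoothed (σ = 1.5 px) before
  thresholding, on the unclipped planes. The nucleolus stage uses a 3×3
  median filter plus a lighter blur (σ = 1.2 px): the median removes
  per-pixel noise without erasing nucleoli near the ~1 µm resolution
  limit, and matters because Otsu's criterion on a noisy near-Gaussian
  histogram otherwise prefers a "noise split" (between-class variance
  ≈ 0.64 of total for a pure Gaussian) over the structural split of a
  small nucleolus.
* **Boundary refinement.** A fixed threshold close to one of the two
  density levels it separates lands the smoothed contour systematically
  off the true edge — the 9.9 mg/ml lipid threshold sits ~5 mg/ml above
  the nuclear level but ~19 mg/ml below the cytoplasmic one, displacing a
  naive contour by 1-2 px. With `refine_boundaries` (default) the fixed
  thresholds *detect* compartments and the contour is then re-drawn at the
  midpoint of the measured inside/outside levels (the half-maximum
  contour), which is unbiased and sits many noise SDs from both levels.
  The nucleus refinement iterates twice so an initial noise-bitten
  fragment cannot corrupt the outside-level estimate. The final nucleolus
  contour is re-drawn on a coarser field (2× the stage blur) whose jitter
  is nearly uncorrelated with per-pixel measurement noise, so the mask
  does not preferentially collect up-noise pixels.
* **Otsu implementation.** 256 bins over each nucleus's own density range;
  between-class variance maximised exhaustively; ties break toward the
  lower threshold. A test proves equality with a brute-force search and
  cross-checks against the independent EBImage implementation.
* **Nucleolus contrast gate.** A nucleolus is only reported when the Otsu
  class separation exceeds `nucleolus_contrast_min` = 3 within-class SDs.
  Measured on phantoms: noise-only nuclei give ≈ 1.6 (the Gaussian
  fixed point), genuine nucleoli 4-7, and strongly compressed nuclei
  (hyperosmotic preset) 1-2 — reproducing the observed loss of nucleolar
  segmentation under strong osmotic compression. A relative
  between/total-variance floor cannot play this role: for *any* unimodal
  Gaussian histogram Otsu's split already attains ≈ 64% of total
  variance, so no small floor on that ratio ever rejects a structureless
  nucleus.
* **Measurement masks.** Compartment means are taken on unsmoothed,
  unclipped planes after eroding each mask (2 px body and nucleus, 2 px
  nucleolus with fallback to 1 or 0 for tiny ones) and excluding a 2 px
  dilation of the inner compartment, so residual boundary jitter cannot
  mix compartments. Mean — not median — densities are reported.
* **Watershed.** Tolerance 10 px on the distance transform: small enough
  to split genuinely touching cells, large enough that discretisation
  ripples along a single cell's ridge do not over-split it.

Segmentation quality at the default noise, measured against ground truth:
cell bodies and nuclei reach a Jaccard index above 0.9 per cell; nucleoli
— objects a few pixels across — reach ≈ 0.85 in the median with ≥ 95%
per-cell detection. For few-pixel objects a 0.9 Jaccard is not a
meaningful target (a symmetric half-pixel contour jitter alone costs
~0.15), which is why detection rate is the nucleolar quality metric.

## Cell-cycle gating, EdU, synthesis rate, senescence

`hoechst_gates()` normalises total nuclear Hoechst to the G1 peak — the
dominant mode of a Gaussian KDE with Silverman's bandwidth — and calls
stages by fixed gates on the normalised axis. The gate positions are not
quantified in the source material, so the defaults are this package's own:
G1 up to 1.25 and S up to 1.75. With DNA content uniform between 1× and
2× in S phase, the lower gate at 1.25 balances the G1/S split (a higher
cut near 1.35 would hand more than a third of S cells to G1 and pull
overall stage accuracy below 90% under the generator's own staining
noise); the defaults give ≈ 92% accuracy, asserted by test. Because the
normalisation divides by the detected peak, calls are invariant to any
intensity rescaling.

`edu_gate()` calls a cell replicating when its log EdU intensity exceeds
the EdU-negative mode plus three robust SDs (half-sample MAD below the
mode, so the positive tail cannot inflate the estimate).
`synthesis_rate()` reports per-cell OPP/SE ratios and the population
constant $k$ = median ratio (the slope of $y = kx$ through the scatter).
`senescence_fit()` fits the control SA-β-gal vs SE relation by least
squares *through the origin* ($y = ax$), takes $b$ as the RMSE of that
fit, and `senescence_call()` labels cells with $y > ax + 3b$; with
Gaussian control residuals the control false-positive rate is the
3-sigma tail (~0.13%), which the tests verify, and the doxorubicin-like
preset is recalled at its generated 87% senescent fraction.

`summarize_population()`, `pearson_cor()`, `anova_groups()` (classic
equal-variance one-way ANOVA, no multiple-testing correction, significance
codes N.S./*/**/***/**** at 0.05/0.01/0.001/0.0001), `fold_change()`
(per-cell values over the control *median*, summarised by the median
fold) and `variability_decomposition()` (pooled within-group SD vs SD of
group means) complete the population layer. All take data frames first
and return tibbles, so they chain with the pipe.

## Problem sizes and reproducibility

The package's own recovery analysis simulates 600 cells in fifty
448 × 448 px fields of 12 cells each — the same population size as the
headline live-cell dataset it emulates — and runs in a few minutes on one
core; unit tests use 6-40 cell fields. Every stochastic step takes an
explicit integer seed, and identical seed plus configuration gives
bit-identical output end to end (asserted by test). Stochastic assertions
use pre-registered tolerances: 3·SEM for recovered means, binomial
intervals for fractions.

## Known limitations

* The imaging model is per-pixel: no optical transfer function, so
  segmentation operates on sharper edges than a real microscope produces;
  conversely there is no within-compartment texture to exploit or to
  confound thresholds.
* The clip-before-normalise convention, kept for the displayed maps,
  biases *pixel-level* near-zero concentrations; quantification avoids
  this via the unclipped planes, but users reading pixel values off the
  clipped maps at very low concentrations should expect the skew.
* Fold-change presets are population-level multiplicative shifts; they do
  not model changed cell-to-cell dispersion under treatment.
* Whole-cell (z-stack) mode reuses the mid-section protein threshold for
  the volume segmentation; a dedicated 3-D threshold might differ.
* The senescence caller assumes homoscedastic control residuals; strongly
  mass-dependent residual spread would distort the 3-RMSE rule.
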