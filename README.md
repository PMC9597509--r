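# noripipe

Single-cell dry-mass densitometry with three-band stimulated Raman
scattering (SRS), as an end-to-end, fully tested R pipeline. Cultured
mammalian cells keep their cellular mass density (dry mass / volume) in a
remarkably narrow band — the coefficient of variation of cytoplasmic
protein density is ~7% while cell mass and volume each vary by ~28% — and
quantifying that requires imaging absolute protein and lipid
concentrations in single cells and their compartments. This package is for
computational biologists who want to analyse such band images, and, since
raw data of this kind are rarely public, for anyone who needs a realistic
synthetic benchmark: it generates ground-truth cell populations, renders
them as noisy SRS images, and recovers the population parameters through
the same analysis a real study would run.

## The method

Per pixel, the three band intensities follow `I = S c`, with `S` the 3×3
reference-spectra matrix (bands 2853/2935/3420 cm⁻¹ × components
protein/lipid/water) and `c` the concentration vector in g/ml. The
algorithm solves `S x = I`, clips negative components (recording the
fraction), and rescales each pixel so the volume-fraction closure
`v_p c_p + v_l c_l + v_w c_w = 1` holds (partial specific volumes 0.735,
1.087, 1.0 ml/g) — making the output an absolute concentration map,
invariant to instrument gain. Dry-mass density is `c_p + c_l`;
1 g/ml = 1 pg/µm³, so masses integrate directly from z-stacks.

Downstream, cell bodies are segmented at protein > 0.0666 g/ml, nuclei as
the largest in-cell region with lipid < 0.0099 g/ml, nucleoli by Otsu's
method on nuclear protein density, with watershed splitting of touching
cells; per-cell compartment means, masses and volumes feed a population
layer (CVs, Pearson correlations, one-way ANOVA significance codes, fold
changes to control medians, Hoechst cell-cycle gating, EdU gating, OPP/SE
synthesis rates, and an SA-β-gal senescence caller using the
`y = ax + 3b` rule). A mid-section average over several hundred pixels has
an error of `σ/√n` ≲ 1.5 mg/ml at the 15 mg/ml per-pixel sensitivity —
under 2% of a typical 80 mg/ml cell.

## Worked example

Simulate a control population, image it, and recover the compartment
densities:

```r
library(noripipe)

run <- run_pipeline(nori_config(n_cells = 60, seed = 7))
run
#> <nori_run> preset 'control': 60 cells segmented (60 simulated), seed 7
#> # A tibble: 4 × 7
#>   group   channel          n  mean    sd     cv flag
#>   <chr>   <chr>        <int> <dbl> <dbl>  <dbl> <chr>
#> 1 control cyto_lipid      60  28.7  4.82 0.168  ""
#> 2 control cyto_protein    60  74.5  5.54 0.0744 ""
#> 3 control nul_protein     59 110.   6.14 0.0560 ""
#> 4 control nup_protein     60  82.1  5.41 0.0660 ""
```

The summary is in mg/ml: the pipeline recovers the generator's cytoplasmic
protein 74.5 ± 5.2, cytoplasmic lipid 29.1 ± 5.3, nucleoplasmic protein
81.9 ± 5.4 and nucleolar protein 110.0 ± 5.9 distributions — note the CVs:
protein densities are tight (5-7%) while lipid is looser (~17%), and the
nucleolus : cytoplasm protein ratio is ≈ 1.5. One cell of 60 had no
detectable nucleolus (`n = 59`). Lower-level stages are exposed
individually (`sample_population()`, `render_density_map()`,
`srs_forward()`, `unmix_image()`, `segment_compartments()`,
`compartment_densities()`), per-cell tables are tibbles throughout, and
`autoplot()` methods display density maps and gating results. A thin
command-line wrapper lives at `inst/scripts/nori-pipeline.R`.

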