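# ramantex

Haralick texture analysis of Raman spectroscopic maps.

## The problem

Raman mapping of tumour sections produces a grid of vibrational spectra per
tissue region. After dimensionality reduction, the first principal component
of such maps typically tracks a dominant biochemical signal — in irradiated
tumour models, glycogen production. Summarising each map by its *mean*
glycogen score throws away the spatial arrangement, which is exactly where
radiation response heterogeneity lives. `ramantex` quantifies that spatial
structure: it turns each map into a gray-level image of scaled PC1 scores and
summarises its texture with five Haralick features computed from gray-level
co-occurrence matrices (GLCMs), then tests whether texture differs between
radiation dose groups.

It is written for spectroscopists and biostatisticians analysing gridded
hyperspectral maps with per-sample group structure (dose arms, treatment
arms), and ships a seeded synthetic-study generator so the entire pipeline is
testable without instrument data.

## The method

For a quantized image with gray levels `0 .. N_g - 1`, the GLCM at distance
`d` and angle `θ` counts ordered neighbour pairs `(i, j)` and is normalized
to probabilities `m(i, j)`. With 1-based level indices, the five features are

- homogeneity (angular second moment): `H = Σ_i Σ_j m(i,j)²`
- contrast: `Con = Σ_k k² P(|i−j| = k)`
- correlation: `Cor = (Σ_i Σ_j ij·m(i,j) − μ_x μ_y) / (σ_x σ_y)`
- entropy: `E = −Σ m log m` (natural log, `0 log 0 = 0`)
- local homogeneity (inverse difference moment): `LH = Σ m(i,j) / (1 + (i−j)²)`

computed per angle `θ ∈ {0°, 45°, 90°, 135°}` at `d = 1` and averaged.
Upstream, each spectrum passes through cosmic-ray spike removal
(running-median / MAD), Savitzky–Golay smoothing, asymmetric least squares
(ALS) baseline subtraction (`λ = 10⁴`, asymmetry `p = 0.05`) and volume
normalization. Downstream, per-map feature values are compared between dose
groups with pairwise Kruskal–Wallis tests and banded significance labels
(`*` for p in 0.025–0.05, `**` for 0.001–0.025, `***` below, `n.s.` above).

## Worked example

```r
library(ramantex)

# a three-arm murine-style study: 0/5/15 Gy, 4 mice per arm, 5-8 maps each
ds <- synthesize_study(study_design(seed = 11))
pp <- preprocess_dataset(ds)
fit <- fit_pca(pp, q = 3)
round(fit$model$explained_fraction, 3)
#> [1] 0.203 0.012 0.011

maps  <- gray_maps_from_scores(fit, n_levels = 8)
feats <- features_for_dataset(maps)
cmp   <- pairwise_dose_tests(feats)
cmp[cmp$feature == "Con", c("dose_a", "dose_b", "p_value", "label")]
#>   dose_a dose_b      p_value label
#> 4      0      5 2.249067e-07   ***
#> 5      0     15 2.045831e-06   ***
#> 6      5     15 1.397460e-01  n.s.
```

PC1 carries ~20 % of the variance (the planted glycogen signal); contrast
separates the control arm from both irradiated arms while the two irradiated
arms are indistinguishable — the irradiated maps are more heterogeneous, not
simply brighter. `run_pipeline(run_config(seed = 11), "out/")` performs the
same steps and writes every artifact (dataset CSV, PGM gray maps, feature and
comparison tables, box plots, run manifest); `inst/scripts/ramantex.R`
exposes each stage as a shell subcommand.

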