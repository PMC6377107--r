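---
title: "Methods: texture analysis of Raman score maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: texture analysis of Raman score maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramantex)
```

## Overview

`ramantex` quantifies the spatial heterogeneity of a biochemical signal —
prototypically glycogen production in irradiated tumour sections — across
gridded Raman maps. The pipeline is: spectral preprocessing, PCA score
imaging, gray-level co-occurrence (GLCM) texture features, and pairwise
rank tests across dose groups. This vignette records the model choices,
parameter semantics, numerical conventions, and the limits of what the
synthetic validation can show.

## The texture model

Each map is reduced to an image of PC1 scores, min–max scaled to $[0,1]$ and
quantized into $N_g$ uniform bins ($[k/N_g, (k+1)/N_g)$, last bin closed).
The GLCM at distance $d$ and angle $\theta$ counts ordered neighbour pairs
of gray levels; with symmetric counting (default) each pair is also counted
in the reverse direction, the natural convention when opposite directions
are later averaged. After normalization to probabilities $m(i,j)$, the five
features are the angular second moment ("homogeneity" $H$), contrast
$\mathrm{Con} = \sum_k k^2 P(|i-j|=k)$, correlation
$\mathrm{Cor} = (\sum_{ij} ij\,m(i,j) - \mu_x\mu_y)/(\sigma_x \sigma_y)$,
entropy $E = -\sum m \log m$ (natural log, $0\log 0 = 0$), and the inverse
difference moment ("local homogeneity"
$\mathrm{LH} = \sum m(i,j)/(1+(i-j)^2)$). Features are computed per angle
$\theta \in \{0^\circ, 45^\circ, 90^\circ, 135^\circ\}$ at $d = 1$ —
neighbour correlation decays with distance, so the unit offset carries the
texture signal — and averaged arithmetically to remove directional
dependence.

Conventions worth stating explicitly:

* $\sigma_x, \sigma_y$ in the correlation are marginal *standard
  deviations*. This is the standard Haralick definition and the only one
  under which $\mathrm{Cor} \in [-1, 1]$.
* Level indices in the correlation marginals are 1-based; the feature is
  invariant to any uniform index shift, so this cannot change results.
* A constant map has $\sigma_x\sigma_y = 0$; its correlation is reported as
  0 with an explicit `degenerate_correlation` flag rather than `NaN`, so
  feature tables stay rectangular.
* $N_g$ defaults to 8. Maps carry only 64–196 pixels, so a finer
  quantization starves the $N_g \times N_g$ co-occurrence matrix and
  degrades every feature toward its degenerate limit; 8 levels keeps a
  few pixel pairs per occupied cell even on an 8×8 map.
* Scaling scope for scores defaults to `global` (one min–max over the whole
  study): gray tones are then comparable across maps, and a map whose
  score *range* is narrow genuinely renders as few gray levels. `per_map`
  scaling is available; note it deliberately discards between-map level
  differences and therefore weakens dose effects planted in the score
  spread.

## Preprocessing

Four steps, in order, per spectrum:

1. **Cosmic-ray removal.** Channels whose positive residual from a running
   median (window 5) exceeds $8\times$ a robust noise scale are replaced by
   linear interpolation of non-flagged neighbours. The scale is the MAD of
   the residuals, floored by the first-difference noise estimate
   $\mathrm{mad}(\Delta y)/\sqrt{2}$; the floor keeps noise-free smooth
   peaks from being flagged (their residual MAD degenerates to 0), and both
   terms are invariant under subtraction of a smooth baseline, so baseline
   correction can never create new spike flags.
2. **Savitzky–Golay smoothing** (window 11, order 3): reproduces
   polynomials up to the order exactly; applied to whole spectra matrices
   via an equivalent banded operator.
3. **ALS baseline subtraction.** Iteratively reweighted Whittaker
   smoothing: minimise $\sum_i w_i (y_i - z_i)^2 + \lambda \sum (\Delta^2
   z)^2$ with $w_i = p$ above the baseline and $1-p$ below, $p = 0.05$.
   The smoothness constraint is specified on a log scale: the default
   `als_lambda_log10 = 4` means $\lambda = 10^4$. A linear-scale switch is
   provided, but $\lambda = 4$ in linear units barely penalises curvature
   on realistic spectra and leaves the baseline hugging every peak. Each
   iteration is a pentadiagonal banded Cholesky solve (compiled), $O(p)$
   per spectrum; iteration stops when the weight vector stabilises (max 20
   iterations, tolerance $10^{-6}$).
4. **Volume normalization**: division by the trapezoidal integral so every
   spectrum has unit integrated intensity. Negative residual intensities
   after baseline subtraction are *retained* — clipping would bias the
   subsequent mean-centred PCA — and only the normalization guard inspects
   the positive part.

The chain is exactly idempotent only in its first three steps and only on
peakless inputs (which it annihilates); on peaked spectra a second pass
re-shaves the peak wings by a few percent. The tests pin the achievable
version of this property rather than a nominal one.

## Dose comparison

Per feature and per unordered pair of dose groups, a two-group
Kruskal–Wallis test (tie-corrected mid-ranks, $\chi^2$ approximation, via
`stats::kruskal.test`) on per-map values, with labels `n.s.` ($p > 0.05$),
`*` ($0.025 < p \le 0.05$), `**` ($0.001 < p \le 0.025$) and `***`
($p \le 0.001$). Two deliberate simplifications mirror the study design
this package emulates: maps from one mouse are treated as independent
observations (a `mouse_median` clustering option collapses each mouse to
its median first), and no multiple-testing correction is applied across the
pairs (a Holm option exists, applied within feature). With two groups the
test is analytically the chi-square-approximated two-sided Wilcoxon
rank-sum test; the suite asserts that equivalence.

## The synthetic-data generator

The generator emulates a three-arm irradiation study: doses 0/5/15 Gy, four
mice per arm, 5–8 maps per mouse on a half-and-half mixture of 8×8 and
14×14 grids (≈ 74 maps in expectation). Per map, a *glycogen abundance
field* on $[0,1]$ is drawn as Gaussian white noise smoothed by a separable
Gaussian kernel (correlation length 1.5 px), rescaled to a target mean
(0.5) and standard deviation, and clipped. Each pixel's spectrum is the
two-component mixture $g\,S_{\mathrm{glyco}} + (1-g)\,S_{\mathrm{matrix}}$
of unit-area sums of Gaussian bands (glycogen bands at 490, 850, 1050,
1340 cm⁻¹; generic protein/lipid bands for the matrix), plus a random
quadratic fluorescence-like baseline, i.i.d. Gaussian channel noise, and
Poisson-placed single-channel spikes at least $20\times$ the noise scale —
well separated from noise so the spike-removal stage has an unambiguous
target.

The dose effect is planted in the field's *standard deviation*, not its
mean: radiation changes the spatial heterogeneity of glycogen, which is
precisely what texture features measure and mean-score analyses miss. A
small lognormal mouse-level multiplier (sd 0.05) induces the within-mouse
correlation visible in per-mouse box plots. The default effect map
(heterogeneity 0.05 / 0.065 / 0.065 for 0 / 5 / 15 Gy) was calibrated once
so that the irradiated-vs-control separation on the contrast feature is
Cohen's $d \approx 1.5$ under the default design; the two irradiated arms
are equal by construction — texture separates irradiated from control but
saturates between the two doses, the qualitative pattern the pipeline is
meant to resolve. Because the contrast feature resolves heterogeneity
differences of ~0.001 at this design size, even a token monotone increment
for the 15 Gy arm would plant a detectable 5-vs-15 effect; equality is the
faithful encoding of dose saturation.

Two mechanisms deserve emphasis because they determine what the validation
does and does not show. First, with global score scaling the dose effect
reaches the texture features mainly through each map's score *spread*
(wider spread → more occupied gray levels → higher contrast and entropy);
with per-map scaling the same planted effect is largely removed. Second,
the generator is stationary within a map: real tumour sections have
non-stationary architecture (necrotic cores, viable rims), instrument drift
and wavenumber miscalibration, none of which are modelled. Passing the
synthetic suites therefore demonstrates correctness of the computational
chain and its statistical calibration under the stated model — not
robustness to every artefact of real Raman maps.

## Numerical and degenerate-input choices

* Discretization bins are half-open with the top bin closed, so 1.0 maps to
  $N_g - 1$ and every output level is in range by construction.
* Constant score vectors scale to 0 with a warning (flagged, not dropped).
* GLCM computation refuses maps that admit no pixel pair at the requested
  offset, naming the failing angle; the feature-table builder converts
  per-map failures into warnings and continues.
* All generators are pure functions of their parameters and seed; per-map
  seeds are derived deterministically from the study seed, and every writer
  uses fixed decimal formatting so identical runs are byte-identical.
* Entropy uses the natural log by default (base-2 switch provided); its
  upper bound $\log N_g^2$ and the bounds $H, LH \in (0,1]$,
  $\mathrm{Con} \le (N_g-1)^2$, $\mathrm{Cor} \in [-1,1]$ are asserted
  property-style over random-map suites.

## Problem sizes used by the test suite

The statistical suites run at sizes chosen to make their Monte-Carlo
behaviour stable while staying desk-scale: the null-calibration check runs
200 simulated studies of 24 maps each (8×8 grids, 150-channel axis) through
the full pipeline and asserts a rejection rate of $0.05 \pm 0.03$ at
$\alpha = 0.05$; the dose-trend check runs 50 replicate studies at the full
default design (12 mice, ~74 maps, 700-channel axis) and requires the
contrast feature to separate control from both irradiated arms, and the
irradiated arms from each other not at all, in at least 80 % of replicates.
Oracle-equivalence suites compare the GLCM and all five features against an
exhaustive pair-enumeration oracle on 500 random maps at $10^{-10}$.

## Known limitations

* The Kruskal–Wallis default ignores mouse clustering; with few mice and
  strong mouse effects the per-pair error rate is optimistic. Use
  `cluster = "mouse_median"` when mice, not maps, are the unit of
  inference.
* Texture features on 8×8 maps rest on 112–224 pixel pairs per angle;
  their sampling variance is large, which is why comparisons pool 20+ maps
  per arm.
* ALS with $\lambda = 10^4$ tracks (and partially absorbs) peaks wider
  than roughly 10 channels; volume normalization then rescales the
  distortion uniformly, but very broad bands are attenuated relative to
  narrow ones.
* The RGB (PC1–3) map export is visualisation only; no colour-texture
  features are computed.
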