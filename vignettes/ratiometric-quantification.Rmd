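---
title: "Ratiometric two-channel immunofluorescence quantification: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratiometric two-channel immunofluorescence quantification: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratioquant)
```

## The measurement model

Semi-quantitative immunofluorescence estimates the expression of a target
protein in tissue sections by normalizing its stain intensity against a
housekeeping protein imaged in a second channel. Each microscope field is
captured twice — a green plane (target, FITC-conjugated secondary
antibody) and a red plane (housekeeping, Texas Red) — and for every
delineated cell the expression statistic is

$$
\mathrm{Ratio} \;=\;
\frac{\text{mean pixel intensity of the cell in the green plane}}
     {\text{mean pixel intensity of the same cell in the red plane}} .
$$

Because the housekeeping protein is assumed constitutively expressed, the
ratio cancels the multiplicative factors that vary between slides and
sessions — stain uptake, illumination intensity, exposure, detector gain.
This is the *gain invariance* the test suite asserts: multiplying both
planes by any constant leaves every ratio unchanged, while a green-only
gain scales ratios by exactly that factor. Additive offsets do **not**
cancel: a common background pushes every ratio toward 1, which is why the
synthetic fixtures default to zero background and why an optional
median-background subtraction is offered (see below).

A sample is summarized by a fixed-size random *cell collection* (default
30 cells, drawn uniformly without replacement across all of the sample's
fields): the collection's arithmetic mean ratio is the sample's **M.R**
and its n−1 standard deviation the sample SD. Groups of samples are then
compared on their M.R values with two-sided pooled (Student) or Welch
t-tests, one-way ANOVA for more than two groups, and chi-square or
Fisher's exact tests for clinical contingency tables.

## The synthetic forward model

No public micrographs accompany the study design this package targets, so
the generator is a first-class module with per-cell ground truth rather
than a test fixture. One `sample_spec()` describes one sample:

* each field contains `cells_per_image` non-overlapping elliptical cells,
  placed by rejection sampling fully inside the image (a bounded number of
  attempts; overcrowded geometries fail loudly rather than silently
  overlapping);
* cell $i$ carries a true expression ratio
  $r_i \sim \mathcal{N}(\mu,\ \sigma_\text{cell})$ truncated at zero, and
  a housekeeping level $L_i \sim \mathcal{N}(L,\ L\cdot\mathrm{cv})$
  truncated at zero;
* inside cell $i$ the noise-free red intensity is $L_i + b$ and the green
  intensity $r_i L_i + b$, with background $b$ elsewhere;
* per-pixel noise is additive Gaussian with SD `pixel_noise_sd`
  (optionally Poisson shot noise via `noise_model = "poisson"`), after
  which values are rounded to integer detector counts and clipped to the
  8- or 16-bit range.

A hierarchical layer (`group_sample_specs()`) draws each sample's true
mean ratio from $\mathcal{N}(\mu_\text{group},\ \sigma_\text{sample})$,
reproducing the between-sample spread (SDs of order 0.01–0.05 around
means of order 0.58–0.64) that grouped ratio studies report. The
published group summaries fix $\mu_\text{group}$ and
$\sigma_\text{sample}$ in the validation runs; the within-sample
dispersion is not published anywhere, so `between_cell_sd` stays a free
parameter with a default of 0.05 — large enough that the 30-cell
collection, not the measurement noise, dominates the M.R's sampling
error, which is the regime the ratio estimator is designed for.

Default generator conditions (chosen once, used by tests and validation):
`red_mean_level = 20000` counts with `red_cell_cv = 0.10` on a 16-bit
scale, `pixel_noise_sd = 300` counts (per-pixel SNR ≈ 65, a bright
well-stained slide; over a typical 80-pixel cell the induced ratio error
is ≈ 0.002, an order below `between_cell_sd`), `background_level = 0`,
cell semi-axes 4–7 px. Simulation-heavy runs use 2 fields of 16 cells at
96×96 px per sample so that a sample supplies just over the 30 cells a
collection needs; the study-scale demonstration uses 20 fields of 4 cells
per sample, mirroring a 20-image acquisition in which only a few cells
per field are usable.

### Seeding

One master seed governs everything. Per-sample and per-image streams are
derived by stable string hashing of `(seed, sample_id, image_index,
stage)`, so any field can be regenerated in isolation and adding samples
to a study never perturbs existing ones. Regeneration is byte-identical,
including the TIFF files.

## Numerical choices and degenerate inputs

* **Integer quantization.** Rendered images are integer count grids, as
  detector output is. A measured noise-free ratio therefore matches its
  generator truth exactly when the green product $r_i L_i$ is an integer,
  and to within half a count over the red level (≈ $10^{-4}$ at
  default levels) otherwise; the tests assert both regimes separately.
  Negative counts produced by noise below a zero background clamp
  silently to 0 — a photon detector cannot report them — while overflow
  beyond the bit depth warns with the clipped-pixel fraction, since it
  signals a mis-specified simulation.
* **Exclusions.** Cells touching the image border are excluded (their
  means are truncation-biased); cells below `min_cell_area` (default 5
  px) and cells with zero red mean (no housekeeping signal: the
  normalization is undefined) are excluded with warnings.
* **Collections.** A sample with fewer than `k_cells` measured cells
  yields all of them plus a warning rather than failing; an empty sample
  is an error. A single-cell collection takes SD 0 by convention.
  Collections pool across all of a sample's fields (whether the original
  protocol pooled per image or per sample is unstated; pooling across
  fields uses all available information and is stated here as this
  package's choice).
* **Zero-variance tests.** Two groups with zero variance and equal means
  give statistic 0, p 1; unequal means give an infinite statistic
  reported as p 0 with a warning. ANOVA on totally constant data is an
  error ("degenerate") rather than 0/0.
* **Background subtraction.** Off by default (the ratio protocol this
  models applies none). When enabled, the per-field median of
  background-labelled pixels is subtracted from each channel and clamped
  at zero — a constant-offset model that matches the generator's
  background term; a spatially varying (rolling-minimum) filter was
  considered and rejected as unidentifiable from single-field synthetic
  data.
* **Segmentation.** The primary path consumes supplied label masks (the
  digitized analogue of manual boundary delineation). The automated
  stand-in thresholds the red channel — the housekeeping stain marks all
  cells — with Otsu's method, labels connected components, removes
  those below `min_cell_area`, and renumbers in raster order. It is a
  convenience for mask-free data, not a replica of expert cell selection;
  in particular no cell-type preference (e.g. lymphocytes over tumor
  cells) is modelled, and the optional `include` flag on
  `select_cell_collection()` is the hook for externally supplied
  eligibility.
* **Interpretation of published "±".** Printed `M.R ± x` values are
  treated as standard deviations, not standard errors, when consumed by
  `t_test_from_summaries()`. Under the SD reading the reactive-vs-normal
  comparison gives p ≈ 0.005, consistent with the published "< 0.01"
  claim; under an SEM reading the test statistics would be implausibly
  large, so the SD reading is used throughout.

## What the validation shows — and what it cannot

The acceptance layer (`scripts/acceptance.R`, `tests/testthat/`)
establishes four things:

1. **Auditability of printed summaries.** The pooled t-test recomputed
   from the published group summary statistics alone reproduces the
   published significance pattern: reactive hyperplasia vs normal nodes
   rejects at the 1% level, the lymphoma-vs-control comparisons do not
   reject at 5%.
2. **Estimator correctness.** On noise-free fields, measured ratios equal
   generator truth (exactly, in the integer-exact regime); gain
   invariance holds; with noise on, sample M.R values land within
   standard Monte-Carlo error of the generator's means, at every group
   size in the design.
3. **Calibration of the testing layer.** The pooled t-test holds its
   nominal 5% size over 2,000 null studies (observed rates ≈ 0.04–0.055),
   Fisher's exact p equals exhaustive hypergeometric enumeration for
   every 2×2 table with N ≤ 40, F = t² for two groups, and the
   summary-statistics t-test equals the raw-data test exactly.
4. **Power pattern.** Under the published group means, SDs and sample
   sizes, the 9-vs-30 reactive-vs-normal design rejects in ≈ 80–95% of
   replicates while the 39-vs-39 lymphoma-vs-control design (Δ = 0.0153)
   rejects in ≈ 40–50% — the study's qualitative finding (a significant
   reactive effect, a non-significant lymphoma effect) is what this
   design would be expected to produce if the generative model is right.

What passing these tests does **not** show: that real stained sections
satisfy the model. The generator has flat backgrounds, no optical
point-spread blur, no spectral bleed-through between channels, no
photobleaching, no spatial autocorrelation of expression, and cells never
touch — all departures that bias real ratio measurements in ways
synthetic recovery cannot detect. The generator also says nothing about
whether a housekeeping protein truly is expression-invariant across
disease states, which is the method's central biological assumption.

## Known limitations

* Per-cell dispersion within a sample is a free parameter; if real
  within-sample heterogeneity is far from the 0.05 default, the power
  figures shift accordingly.
* The published table of group comparisons contains internal
  inconsistencies (a "P = 0.03" described as non-significant; a
  figure/abstract disagreement on the reactive-vs-normal p value); this
  package reports computed values only and does not attempt to
  reconcile them.
* Raw p values are reported with the number of tests performed; no
  multiplicity correction is applied, matching the protocol it models.
* Only plain single-plane grayscale TIFF is supported; proprietary
  microscope containers and OME metadata are out of scope.
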