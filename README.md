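# ratioquant

Ratiometric two-channel immunofluorescence quantification in R.

Pathology labs estimate protein expression in tissue sections
semi-quantitatively by dual immunofluorescence: the target protein is
stained in one channel (green, FITC) and a housekeeping protein in a
second (red, Texas Red), and each cell's expression is scored as

```
Ratio = mean green-plane pixel intensity of the cell
        ─────────────────────────────────────────────
        mean red-plane pixel intensity of the same cell
```

Because the housekeeping signal is assumed constant, the ratio cancels
slide-to-slide staining and illumination gain. A sample is summarized by
the mean ratio (**M.R**) and SD of a 30-cell random collection drawn
across its fields, and groups of samples (e.g. Hodgkin lymphoma,
non-Hodgkin lymphoma, normal and reactive-hyperplasia lymph nodes) are
compared with t-tests and one-way ANOVA, with chi-square/Fisher tests for
clinical contingency tables.

`ratioquant` implements the whole chain — TIFF/mask I/O, per-cell
measurement, collection sampling, sample summaries, group statistics —
plus a seeded synthetic micrograph generator with per-cell ground truth,
so every stage is testable without any real slide. It is organised as an
analysis workflow: the package in `R/` holds all computation; the
numbered drivers in `analysis/` run the study-scale simulation,
quantification, statistics and validation and write their tables under
`results/`.

## Worked example

Simulate one sample, measure its cells, and summarize:

```r
library(ratioquant)

spec <- sample_spec("S1", "demo", true_mean_ratio = 0.6, seed = 42,
                    n_images = 2, cells_per_image = 5,
                    between_cell_sd = 0, red_cell_cv = 0,
                    pixel_noise_sd = 0, image_shape = c(64, 64))
field <- render_field(draw_cell_truths(spec, 0), spec, 0)
measure_field(field$green, field$red, field$mask)
#>   sample_id field_id cell_id green_mean red_mean ratio n_pixels
#> 1        S1   S1_000       1      12000    20000   0.6       70
#> 2        S1   S1_000       2      12000    20000   0.6       96
#> 3        S1   S1_000       3      12000    20000   0.6       97
#> 4        S1   S1_000       4      12000    20000   0.6      105
#> 5        S1   S1_000       5      12000    20000   0.6       79
```

With all noise switched off the measured ratio equals the generator
truth exactly; the tests assert this, along with gain invariance and
recovery under realistic noise.

Group comparisons work from raw values or from published summary
statistics alone (`n`, `M.R`, `SD`):

```r
t_test_from_summaries(9, 0.6365, 0.017, 30, 0.5882, 0.047,
                      method = "t_pooled", group_a = "RLH", group_b = "normal")
#>   group_a group_b   method statistic df df2     p_value n_a n_b
#> 1     RLH  normal t_pooled  3.000557 37  NA 0.004802689   9  30
```

— i.e. the reactive-hyperplasia vs normal-node comparison rejects at the
1% level, while the lymphoma-vs-control comparisons computed the same way
(p ≈ 0.058 and 0.61) do not reject at 5%.

The full study-scale workflow (101 samples, 2,020 field triples, one
30-cell collection per sample — 3,030 cells analyzed):

```sh
Rscript analysis/01_simulate_study.R   # images + masks under scratch/study/
Rscript analysis/02_quantify.R         # per-cell table, results/samples.csv
Rscript analysis/03_group_statistics.R # comparison tables under results/
Rscript analysis/04_validation.R       # type-I error and power checks
```

`02_quantify.R` prints, for example:

```
analyzed 3030 cells in 101 sample collections
  HL       n=39  M.R = 0.5807 ± 0.0263
  NHL      n=23  M.R = 0.6144 ± 0.0217
  normal   n=30  M.R = 0.5984 ± 0.0528
  RLH      n=9   M.R = 0.6367 ± 0.0152
```

and `04_validation.R`:

```
type-I error at alpha 0.05 (2000 null studies): 0.0535
power, RLH vs normal design:  0.94
power, HL vs control design:  0.45
```

showing the pooled t-test holds its nominal size on null studies and
that, at the published group means and SDs, the 9-vs-30
reactive-vs-normal design is well powered while the 39-vs-39
lymphoma-vs-control design (Δ = 0.0153) is not — the study's qualitative
pattern.

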