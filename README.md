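# gliaclone

Clonal analysis of combinatorial multicolor (StarTrack-style) lineage
tracing data in the mouse cortex, for researchers studying the glial
potential of single embryonic progenitors.

In this assay, embryonic neural progenitors stochastically integrate up to
12 piggyBac reporters — six fluorescent proteins (XFPs), each in a
cytoplasmic and a nuclear form — and pass the combination to all progeny.
Each labeled cell in serial 50 µm adult sections is measured in 6 channels
× 2 compartments, and its presence pattern is written as a 12-digit color
code with the fixed digit map 1 YFP, 2 mKO, 3 mCerulean, 4 mCherry,
5 mT-Sapphire, 6 EGFP (cytoplasm block then nucleus block, e.g.
`100400 020400` = YFP cytoplasmic, mKO nuclear, mCherry both).

`gliaclone` turns per-cell intensity tables into clone calls and clonal
statistics:

* **Barcoding** — presence thresholding (`≥ 40` units by default) and
  encoding/decoding of the 12-digit code; barcode frequency tables.
* **Clone calling** — cells sharing a code are siblings if, for every
  reporter present in the code, their intensities differ by **strictly
  less than 80 units** (copy number scales fluorescence); violating
  groups are split by single-linkage clustering at that tolerance. Codes
  at **≥ 1% frequency** are ineligible to support a mixed-clone call
  (possible barcode collisions) and multi-type groups under such codes
  are reported as `ambiguous`.
* **Clone metrics** — size; rostro-caudal dispersion under the inclusive
  convention `(max − min section + 1) × 50 µm` (single-section clone =
  50 µm, seven-section span = 350 µm); composition (uniform: Ast, NG2,
  OL, NG2+OL — the latter because NG2-glia act as oligodendrocyte
  precursors; mixed: Ast+NG2, Ast+OL); laminar spread (restricted to
  lower layers V–VI vs spread into upper layers / corpus callosum).
* **Group statistics** — Lilliefors (KS) normality gate with the
  Dallal–Wilkinson p-value, Mann–Whitney (exact by enumeration for small
  tie-free samples), Kruskal–Wallis (exact by permutation for pooled
  n ≤ 10), with `*`/`**`/`***` at 0.05/0.01/0.001.
* **Synthetic cohorts & imaging** — a generator with known ground-truth
  clonal structure (stochastic reporter integration, copy-number
  intensities, six glial fate classes, clone sizes 4–49, spans 1–7
  sections) and a render → detect → quantify forward imaging model, so
  the whole pipeline is testable end to end without microscopy data.

## Worked example

```r
library(gliaclone)

pl <- run_pipeline(config = sim_config(n_progenitors = 200, seed = 11),
                   verbose = FALSE)
pl$cohort
#> <cohort_summary> 198 clones, 3040 cells
#>   Ast       n = 51 (26%)
#>   NG2       n = 81 (41%)
#>   OL        n = 33 (17%)
#>   NG2+OL    n = 20 (10%)
#>   Ast+NG2   n =  3 (2%)
#>   Ast+OL    n =  5 (3%)
#>   ambiguous n =  5 (3%)
#>   mixed clones: size 15.38 +/- 2.36 (SEM), dispersion 218.8 +/- 16.19 um (SEM)
#>   uniform clones: size 14.85 +/- 0.67 (SEM), dispersion 130.5 +/- 4.74 um (SEM)

pl$stats$dispersion_uniform_vs_mixed
#> Mann-Whitney (Wilcoxon rank-sum) test
#>   n = 185, 8  (approximate)
#>   U = 201.5, p = 0.0003478 ***
```

Reading the output: 200 simulated progenitors yield 198 called clones
(two same-code, same-copy collisions merged). Composition percentages are
integer-rounded fractions of called clones — at this seed the drawn NG2
share happened to be 41%. The five `ambiguous` clones are multi-type
groups whose code exceeded 1% of all 3,040 cells — at this small
simulated scale a single large clone can trip the rarity filter by
itself, which is faithful to the rule (real datasets have >10⁵ cells).
Mixed clones disperse further rostro-caudally than uniform ones
(218.8 vs 130.5 µm here), and the Mann–Whitney comparison flags that
difference; clone *sizes* do not differ significantly
(`pl$stats$size_uniform_vs_mixed`). `tidy(pl$cohort)`,
`glance(pl$cohort)` and `autoplot(pl$cohort)` give tabular and graphical
views.

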