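# thyrosens

Quantile-based assessment of central sensitivity to thyroid hormones in
pregnancy cohorts, with urinary-iodine outlier fencing, iodine-status
classification, and the stratified correlation / bootstrap machinery needed
to relate the two — plus a synthetic cohort generator so the whole pipeline
can be exercised and validated without patient data.

## The problem and the index

The hypothalamic–pituitary–thyroid axis is a negative-feedback loop:
pituitary TSH output responds to circulating free thyroxine (fT4). How
strongly it responds — *central sensitivity* — shifts during pregnancy and
may interact with iodine intake, for which spot urinary iodine (UI, μg/L)
is the standard proxy. The Thyroid Feedback Quantile-based Index summarises
central sensitivity per measurement occasion:

```
TFQI = cdf_fT4(x_fT4) − (1 − cdf_TSH(x_TSH))
```

with both CDFs taken over a reference sample (by default the whole
post-fence cohort, pooled across gestational periods). TFQI ∈ [−1, 1];
positive values mean the pituitary fails to suppress TSH despite ample fT4
(reduced sensitivity), negative values mean increased sensitivity. Being
rank-based, the index is invariant under monotone re-scalings of either
assay.

The package implements the full analysis pipeline: cohort CSV I/O and
validation → anti-TPO positivity (> 34 U/mL) → Tukey IQR fence on UI
(k = 1.5) → TFQI → per-period summaries → ANOVA / Tukey–Kramer /
chi-square / two-way ANOVA → per-period correlations stratified at
250 μg/L → pairs bootstrap (b = 1000) of the above-threshold TFQI–UI
correlation.

## Worked example

Score a tiny cohort (fT4 and TSH rising together — a textbook
reduced-sensitivity gradient):

```r
library(thyrosens)
co <- cohort(data.frame(
  sample_id = paste0("w", 1:5), period = "T1",
  tsh_uIU_mL = c(0.5, 1.0, 1.5, 2.0, 2.5),
  ft4_ng_dL  = c(1.0, 1.1, 1.2, 1.3, 1.4),
  ui_ug_L    = c(80, 120, 160, 210, 260)))
tt <- compute_tfqi(co)
as.data.frame(tt)[, c("sample_id", "tsh_uIU_mL", "ft4_ng_dL",
                      "cdf_ft4", "cdf_tsh", "tfqi")]
#>   sample_id tsh_uIU_mL ft4_ng_dL cdf_ft4 cdf_tsh tfqi
#> 1        w1        0.5       1.0     0.2     0.2 -0.6
#> 2        w2        1.0       1.1     0.4     0.4 -0.2
#> 3        w3        1.5       1.2     0.6     0.6  0.2
#> 4        w4        2.0       1.3     0.8     0.8  0.6
#> 5        w5        2.5       1.4     1.0     1.0  1.0
```

Each row's `cdf` values are its rank fractions in the cohort; the last row
holds both maxima, so its TFQI is exactly +1 — the least-sensitive extreme.

Run the end-to-end pipeline on a synthetic cohort generated under the
default study-like conditions (1075 occasions across three trimesters and
postpartum; seed makes everything reproducible):

```r
rep <- run_analysis(analysis_config(seed = 7))
rep
#> == Study report ==
#> Samples: 1075 in, 61 removed by UI fence, 1014 analysed
#>
#> Per-period summary (mean +/- SD):
#>   T1 n= 401  TSH 1.52+/-1.14  fT4 1.34+/-0.48 ng/dL (17.28 pmol/L)  anti-TPO 8%  TFQI -0.045+/-0.421  UI 121+/-52
#>   T2 n= 254  TSH 1.81+/-1.02  fT4 1.23+/-0.58 ng/dL (15.88 pmol/L)  anti-TPO 5%  TFQI +0.018+/-0.406  UI 130+/-54
#>   T3 n= 336  TSH 1.79+/-0.91  fT4 1.28+/-0.58 ng/dL (16.50 pmol/L)  anti-TPO 2%  TFQI +0.052+/-0.391  UI 128+/-49
#>   PP n=  23  TSH 1.41+/-1.22  fT4 1.30+/-0.31 ng/dL (16.67 pmol/L)  anti-TPO 0%  TFQI -0.124+/-0.415  UI 124+/-32
#>
#> Iodine status: 72% < 150, 36% < 100, 26% optimal (150-250)
#>
#> anti-TPO positivity x period: chi-square p = 0.002
#>
#> One-way ANOVA vs period:
#>   tsh   F(3,1010) = 6.29, p = 0.0003134
#>   ft4   F(3,1010) = 2.21, p = 0.08512
#>   tfqi  F(3,1010) = 4.29, p = 0.005121
#>   ui    F(3,1010) = 1.87, p = 0.1331
#>
#> TFQI vs UI above 250 ug/L:
#>   T1 r = +0.373 (n = 9, p = 0.322)
#>   T2 r = +0.769 (n = 8, p = 0.026)
#>   T3 r = +0.805 (n = 7, p = 0.029)
#>   PP not estimable (n = 0)
#>
#> Bootstrap (pairs, above threshold):
#>   T1 r = +0.371, 95% CI (-0.375, +0.929), n = 9, b = 1000
#>   T2 r = +0.786, 95% CI (+0.322, +0.986), n = 8, b = 1000
#>   T3 r = +0.805, 95% CI (+0.309, +0.990), n = 7, b = 1000
```

Reading the report: the fence removed the UI right tail and the injected
extreme values; iodine status is summarised against the 100/150/250 μg/L
thresholds; TSH (but not fT4 or the TFQI) varies by period; and the
above-250 strata — small by construction, as in real cohorts — carry the
positive TFQI–UI association that the generator's calibrated dependence
injects, with pairs-bootstrap intervals quantifying the uncertainty.
`write_report(rep, "out/")` writes the full CSV set plus `report.txt`.

A thin command-line wrapper is installed at `exec/thyrosens`
(`simulate`, `analyze`, `tfqi` subcommands); `cli_main()` is the same entry
point callable from R.

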