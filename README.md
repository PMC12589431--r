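# irtImpute

Item response theory (IRT) imputation of categorical missing data, with
the full evaluation machinery needed to benchmark it: MCAR/MAR
amputation, Little's MCAR test, quartile discretization of continuous
features, and per-cell F1 scoring.

## Who this is for, and the idea

Applied datasets -- epidemiological screening tables, graded product
catalogues, listings with a city label -- routinely have missing cells
in *categorical* columns, where continuous-data imputation machinery
fits awkwardly.  `irtImpute` treats the columns as items of a
psychometric scale: a single latent trait θ per case is assumed to
organize the responses, and three response models link the trait to the
observed categories,

* **2-PL** for binary items:
  `P(U = 1 | θ) = exp(a(θ − b)) / (1 + exp(a(θ − b)))`,
* **graded response model (GRM)** for ordered items: cumulative 2-PL
  boundary curves with a common slope; category probabilities are
  adjacent differences,
* **nominal response model (NRM)** for unordered items: a
  divide-by-total (softmax) over per-category slopes and intercepts,
  identified by fixing the first category at zero.

Item parameters are fitted jointly for all columns -- mixed families in
one analysis -- by Bock–Aitkin marginal maximum likelihood (EM over a
fixed quadrature grid, standard-normal prior).  Missing cells simply
drop out of the likelihood.  Each case is then scored by expected a
posteriori (EAP) estimation from whatever it did answer, and a missing
categorical cell is filled from the model-implied category
probabilities at that score: the 50% rule for binary targets, the
highest-probability category otherwise.  Outcome columns are never
consulted, so imputation cannot leak the thing you later want to
predict.

## Worked example

Build a synthetic diamonds-style benchmark (5-level ordinal target
"color"), fit the model on the 30%-MCAR variant, impute, and score
against the known truth:

```r
library(irtImpute)

cfg <- benchmarkPreset("ordinal")       # n = 2000, fixed preset seed
bm  <- makeBenchmark(cfg)               # truth + 8 amputed variants
amputed <- bm$variants$mcar_30$data
amputed
#> ResponseMatrix: 2000 cases x 8 items (600 unobserved cells, 3.8%)
#> items: color(ordinal), carat_band(ordinal), clarity(ordinal), cut(ordinal),
#>   depth_band(ordinal), table_band(ordinal), premium(binary), price_band(ordinal)

fit <- fitIRT(amputed)
fit
#> IRTFit: 8 items (1 2PL, 7 GRM); logLik -18948.9253; 64 EM iterations
head(itemParameters(fit), 6)
#>         item family parameter      value
#> 1      color    GRM         a  1.3262338
#> 2      color    GRM        b1 -1.6643741
#> 3      color    GRM        b2 -0.5630917
#> 4      color    GRM        b3  0.5405351
#> 5      color    GRM        b4  1.7274935
#> 6 carat_band    GRM         a  2.6235691
```

The generating item had `a = 1.4` and thresholds `(-1.6, -0.5, 0.5,
1.6)`, so the fit recovered the target item well.  Impute and score:

```r
report <- imputeDataset(amputed, fit, "color")
report
#> ImputationReport: 600 cell(s) of 'color' imputed
#>   case         eap       psd imputed priorOnly         p0        p1 ...
#> 1    1 -1.05487730 0.4727263       1     FALSE 0.30824535 0.3492658 ...
#> 2    6 -1.33390030 0.4348622       0     FALSE 0.39214956 0.3432654 ...

scoreImputation(report, bm$truth, "color")
#> F1 over 600 imputed cell(s): 0.3697 (weighted averaging)
#>  class   n precision    recall        f1
#>      0  89 0.4769231 0.3483146 0.4025974
#>      1 134 0.3214286 0.2686567 0.2926829
#>      2 157 0.3162393 0.4713376 0.3785166
#>      3 126 0.3214286 0.3571429 0.3383459
#>      4  94 0.6938776 0.3617021 0.4755245

scoreImputation(modalBaseline(amputed, "color"), bm$truth, "color")$aggregate
#> [1] 0.1085  # the floor any informative imputer must beat
```

An F1 of 0.37 against a modal-baseline floor of 0.11 on a 5-level
ordinal target is the expected picture: ordinal imputation is the hard
case, binary targets score around 0.7 on the matching preset.  The MAR
variants were produced by sorted top-removal on the high-slope
`carat_band` item, and Little's test flags them as expected:

```r
littleMCARTest(bm$variants$mar_30$data)
#> 	Little's MCAR test
#> chi-squared = 1137.7, df = 7, p-value < 2.2e-16
```

A thin command-line dispatcher over the same functions ships in
`inst/scripts/irtci` (subcommands `simulate`, `ampute`, `fit`,
`impute`, `evaluate`, `mcar-test`).

## Documentation

Every exported function carries roxygen documentation, and the methods
vignette (`vignettes/irt-imputation.Rmd`) describes the models, the EM,
the amputation and testing machinery, the design decisions, and the
limitations in detail.
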