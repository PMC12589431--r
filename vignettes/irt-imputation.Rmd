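---
title: "Latent-trait imputation of categorical missing data: models and methods"
author: "irtImpute"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-trait imputation of categorical missing data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irtImpute)
```

## The problem

Tabular datasets in epidemiology and applied prediction work routinely
carry missing cells in categorical columns -- a blood-pressure flag, a
quality grade, a city label.  Most principled imputation machinery
(multivariate-normal EM, MICE's default models) is built for continuous
data, and generic learners treat each column's imputation as a separate
supervised problem.  `irtImpute` takes the psychometric route instead:
treat the columns as *items*, assume a single latent trait $\theta$ per
case organizes the responses, fit item response models to all columns
jointly, score each case's trait from whatever it did answer, and fill
each missing categorical cell from the model-implied category
probabilities at that score.  Because the latent trait is estimated from
the observed feature columns only, the imputation never consults an
outcome column, avoiding the circularity of outcome-aware imputation.

## Response models

All three families use the logistic metric directly; no $D = 1.7$
scaling constant is applied anywhere.

**Binary items (2-PL).** With discrimination $a_i$ and difficulty
$b_i$,
$$P_i(U_i = 1 \mid \theta) = \frac{e^{a_i(\theta - b_i)}}{1 + e^{a_i(\theta - b_i)}}.$$

**Ordered items (graded response model).** For $K$ ordered categories, a
common slope $a_i$ and non-decreasing thresholds $b_{i1} \le \dots \le
b_{i,K-1}$ define cumulative boundary curves $P^*_{ik}(\theta) =
\mathrm{logit}^{-1}\!\big(a_i(\theta - b_{ik})\big)$, the probability of
responding in category $k$ or above.  Category probabilities are
adjacent differences, with the conventions $P^*_{i0} \equiv 1$ and
$P^*_{iK} \equiv 0$:
$$P_{ik}(\theta) = P^*_{ik}(\theta) - P^*_{i,k+1}(\theta).$$
The subtraction telescopes, so the categories always sum to one; the
threshold ordering guarantees they are non-negative.

**Unordered items (nominal response model).** Each category $j$ gets a
slope $a_{ij}$ and intercept $c_{ij}$, combined divide-by-total:
$$P_{ij}(\theta) = \frac{\exp(a_{ij}\theta + c_{ij})}
                        {\sum_{x=1}^{K} \exp(a_{ix}\theta + c_{ix})},$$
identified by fixing the first category at $a_{i1} = c_{i1} = 0$.  The
softmax is evaluated with max-subtraction, so slopes and trait values
producing logits up to $\pm 700$ neither overflow nor underflow.

A two-category graded item is exactly a 2-PL, and a two-category nominal
item with slopes $(0, a)$ and intercepts $(0, -ab)$ is the same curve;
both reductions are verified pointwise to $10^{-12}$ in the test suite.

## Estimation

Item parameters are estimated by marginal maximum likelihood with a
Bock--Aitkin EM over a fixed quadrature grid.  The prior is standard
normal -- this resolves the latent scale, and no rescaling is applied
afterwards.  The default grid is 41 equally spaced nodes on $[-5, 5]$
with normal-density weights renormalized to sum to one; refining to 81
nodes moves the marginal log-likelihood by well under 0.1% on the test
fixtures, which is the basis for the default.

Missing cells are handled by likelihood restriction: a case's
conditional likelihood at a node is the product over its *observed*
items only, so an unobserved cell contributes a factor of one and the
entire response pattern of every case still enters the fit.  The E-step
turns each case's prior-weighted likelihood into a posterior over nodes
and accumulates expected per-node category counts per item; the M-step
re-maximizes each item's expected complete-data log-likelihood with BFGS
on a transformed parameterization:

* GRM: `(log a, b1, log gaps)` -- the slope stays positive and the
  thresholds stay ordered by construction.  A negative common slope with
  ordered thresholds would make category probabilities negative; the
  equivalent model is obtained by reversing the category order, so
  positivity costs no generality.
* 2-PL: `(a, b)` unconstrained by default (a real column may relate
  negatively to the trait); `positiveSlopes = TRUE` switches to
  `(log a, b)`.
* NRM: free slopes and intercepts for categories $2..K$, the first
  category pinned at zero.

The M-step keeps the incumbent parameters whenever the optimizer fails
to improve the expected complete-data objective, which preserves the EM
ascent property exactly; the marginal log-likelihood trace is asserted
non-decreasing (tolerance $10^{-8}$) on every fixture.  Convergence is
declared when the absolute change in the marginal log-likelihood falls
below $10^{-6}$ (default), with a cap of 500 iterations and a warning
plus `converged = FALSE` on the returned object if the cap is hit.

**Starting values.** 2-PL: $a = 1$, $b$ from the inverse logistic of the
item proportion; GRM: $a = 1$, thresholds from inverse-logistic observed
cumulative proportions (tied values separated by $10^{-3}$); NRM:
intercepts from log observed proportions relative to the first category,
and slopes at small, linearly spaced values $0, 0.25, 0.5, \dots$.  The
NRM slopes are deliberately *not* started at zero: with an all-nominal
item set, zero slopes make every case's posterior equal the prior, and
the symmetry of the quadrature grid then zeroes the slope gradient of
the M-step objective -- a stationary point the EM cannot leave.  A small
ordered spread breaks the symmetry while remaining agnostic about the
fitted values.  All starts are deterministic; there are no random
restarts, so fits are reproducible and invariant to case order (asserted
to $10^{-10}$).

Items with a declared category that never occurs among observed cells
are refused by default -- a rare category that the data cannot inform is
surfaced, not hidden.  Setting `collapseRare = TRUE` in [irtControl()]
collapses such categories out of the item (codes remapped, levels
dropped) before estimation.

## Scoring and imputation

Each case is scored by expected a posteriori (EAP) estimation on the
same grid:
$$\hat\theta_i = \frac{\sum_q \theta_q \, w_q \, L_i(\theta_q)}
                      {\sum_q w_q \, L_i(\theta_q)},$$
with the posterior SD from the analogous second moment.  A case with no
observed items keeps the prior mean (0) and prior SD, and is flagged.
The default 41-node EAP matches 10,001-point fine-grid integration
within $10^{-3}$.

Imputation evaluates the target item's category probabilities at the
case's EAP score -- the plug-in rule.  A binary target is imputed 0 when
the probability of category 1 is below 50% and 1 above; an exact tie at
0.5 imputes 1 (configurable), with a message.  Ordinal and nominal
targets take the highest-probability category; ties resolve to the
lowest category index with a warning.  For ordinal items the argmax can
differ from rounding the expected category; the argmax is the
implemented and default behavior.  An alternative `method = "posterior"`
integrates the category probabilities over the full $\theta$ posterior
instead of plugging in the point estimate; it is off by default because
the point-score rule is the canonical one here, and the two differ
little for informative response patterns.

The target item *does* participate in model fitting -- its observed
cells inform its own parameters -- but a case's missing target cell
never informs that case's score, which follows automatically from
likelihood restriction.  Outcome and continuous columns ride along in
`caseData` and are never read by fitting, scoring, or imputation; the
test suite asserts that permuting an outcome column leaves the
imputation report bitwise identical.  Scoring and imputation contain no
sampling, so identical inputs always give identical outputs.

## Benchmarking machinery

**Amputation.** `induceMCAR` removes exactly
$\mathrm{round}(f \cdot n_{\mathrm{eligible}})$ observed target cells
uniformly at random under a seed.  `induceMAR` sorts cases by a
conditional variable -- stably, ties broken by original row index, so
the operation is deterministic -- and removes the target from the top
$\mathrm{round}(f \cdot n)$ cases of that order before restoring the
original row order.  "Top" defaults to descending (largest conditional
values amputed); the MAR structure holds either way and the direction is
a flag.  Both mechanisms touch nothing outside the target column, and
restoring the masked cells reproduces the original matrix exactly.

**Little's MCAR test.** The test compares each missingness pattern's
observed-variable means with grand means estimated by EM under
multivariate normality:
$$d^2 = \sum_j n_j (\bar y_{\mathrm{obs},j} - \hat\mu_{\mathrm{obs},j})^\top
        \hat\Sigma_{\mathrm{obs},j}^{-1}
        (\bar y_{\mathrm{obs},j} - \hat\mu_{\mathrm{obs},j}),
  \qquad \mathrm{df} = \sum_j k_j - k,$$
with the p-value from the upper $\chi^2$ tail.  The mean/covariance EM
is run to tolerance $10^{-8}$ with at most 200 iterations, and a ridge
of $10^{-8}$ is added to pattern covariance blocks before inversion.
Complete data (a single pattern) return a degenerate result with
df $= 0$, $p = 1$ rather than an error.  Mixed-type data are encoded
numerically: integer codes for binary/ordinal items and one indicator
per level *except the first* for nominal items -- a full set of $K$
indicators sums to one and would make every pattern covariance singular.
Under MCAR amputation of a correlated multivariate-normal fixture
($n = 500$, 1000 replicates) the empirical rejection rate at
$\alpha = 0.05$ sits near the nominal level, and under sorted
top-removal MAR it is essentially 1; both rates are recomputed by the
test suite and the acceptance script.

**Discretization.** Continuous features cannot enter an item response
model directly, so `quartileDiscretize` cuts them at empirical
$i/n_{\mathrm{bins}}$ quantiles (default quartiles) into ordinal codes,
left-closed/right-open with the last bin closed, giving equal bin counts
up to quantile ties.  Quantile cuts were chosen over eyeballed histogram
cuts because they are deterministic and shape-preserving in the sense
that matters here: equal-probability bins track the empirical
distribution wherever it concentrates.  The conversion is only used to
build items for fitting; saved imputed output of originally continuous
columns is never discretized.  Tied quantiles (heavily discrete data)
raise an error suggesting fewer bins.

**Scoring imputations.** Accuracy is measured only over the cells that
were amputed and imputed, as per-class one-vs-rest precision, recall and
$F1 = 2pr/(p+r)$ with $0/0 := 0$.  The default aggregate is weighted by
true class frequency, on the expectation that the missing cells' true
values are imbalanced; macro, micro and positive-class (binary) modes
are available and the mode is always recorded in the report.  The floor
to beat is the modal baseline: imputing every missing cell with the most
frequent observed category.

## The synthetic-data generator

Because the reference datasets for this kind of study are external and
the commercial estimator used on them is closed, all testing runs on
synthetic benchmarks with known ground truth.  `simulateTheta` draws
standard-normal traits; `simulateResponses` draws each cell from the
item's model-implied category distribution at the case's trait;
`makeBenchmark` derives the full amputation grid -- by default 2
mechanisms $\times$ 4 fractions (5/10/30/50%), i.e. eight amputed
variants of one complete dataset, with exact missing counts.

Three presets emulate the archetypal settings: a binary target among
mixed screening items (`"binary"`), a 5-level ordered grade among
quality bands (`"ordinal"`), and a 5-way unordered label among property
descriptors (`"nominal"`), each with $n = 2000$ cases by default and a
high-slope conditional item so that MAR removal genuinely depends on a
variable correlated with the target.  Slopes in the presets span
0.7--2.6 and locations span roughly $[-1.8, 1.6]$ -- the ranges a
well-behaved applied scale typically shows.

What the generator does *not* emulate: real columns whose dependence
needs more than one latent dimension, label noise, structurally missing
cells, or the exact marginal distributions of any particular public
dataset.  Passing benchmarks here therefore demonstrates that the
machinery is correct and that the method beats an uninformative baseline
when its model family generated the data; it does not by itself
establish performance on any specific real dataset.

## Problem sizes and numerical choices in the shipped checks

Parameter recovery is checked at $n = 2000$ cases, 10 items per family,
41 nodes -- recovered slopes and locations correlate above 0.9 with the
generating values with RMSEs near 0.1.  The preset imputation benchmarks
run the full MCAR grid at $n = 2000$ and require the IRT F1 to exceed
the modal baseline at every fraction.  Little's-test calibration uses
$n = 500$ with 1000 replicates.  Probability floors ($10^{-300}$) are
applied only inside log-likelihood accumulation, never to returned
probability vectors.

## Limitations

* One latent dimension, one group; no multidimensional or
  multiple-group models, and no 1-PL/3-PL or partial-credit variants.
* Point imputation only -- no multiple-imputation draws and hence no
  between-imputation variance.
* No item-parameter standard errors or fit statistics (M2, RMSEA).
* MNAR mechanisms are out of scope by design; the amputation module
  covers MCAR and single-conditional MAR.
* Little's test assumes multivariate normality of the encoded columns;
  with coarse categorical encodings it remains a directional check
  rather than an exact test.
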