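---
title: "External validation of QSAR models: methods and design notes"
author: "qsarval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{External validation of QSAR models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarval)
```

## Scope and assumptions

`qsarval` evaluates an already-fitted QSAR model from the only artefacts
external validation needs: the experimental activities $Y$ and the
model-calculated activities $Y'$ of the training and test compounds.
Activities are treated as unitless log-scale values throughout; no unit
conversion is attempted, and nothing chemical (descriptors, structures) is
consumed.  The package deliberately fits no model of its own — there is
therefore no `coef()` or `predict()` method on its report object; the
object is a *verdict*, with `print`, `summary`, `plot` and `residuals`
methods.

All five criterion families assume a genuine hold-out split: the test
compounds took no part in fitting.  `read_qsar_dataset()` enforces the
obvious corollary (a compound identifier may not appear in both splits).

## The metrics and their conventions

**Squared correlation.**  $r^2$ is the squared Pearson correlation between
$Y$ and $Y'$.  This makes it symmetric and independent of regression
direction, but also blind to sign: a perfectly anti-correlated model scores
$r^2 = 1$.  Since every criterion implicitly assumes positive association,
the metric carries the correlation sign as an attribute and `summary()`
warns when it is negative.

**Through-origin quantities.**  The slope of the least-squares line through
the origin of $Y$ on $Y'$ is $K = \sum YY'/\sum Y'^2$; the reverse slope is
$K' = \sum YY'/\sum Y^2$.  The forward determination coefficient `r0sq()`
is $1 - \sum(Y - KY')^2 / \sum(Y - \bar Y)^2$.  Because the through-origin
residual sum of squares can never beat the intercept model's, `r0sq()` never
exceeds $r^2$ (a property test asserts this on a thousand random vectors).
Published usage of the *reverse* coefficient is not uniform, and the
literature contains tabulated values that no single formula reproduces, so
`r0sq_reverse()` implements three selectable conventions:

* `reverse_centered` (default) — the standard reverse regression,
  $1 - \sum(Y' - K'Y)^2/\sum(Y' - \bar Y')^2$;
* `literal` — a formula that appears typeset in parts of the validation
  literature taken at face value, with the reverse slope applied on the
  experimental axis; it mixes the regression axes and can yield large
  negative values (for $Y' = 2Y$ it returns $-62$ on a three-point
  example), and is provided for reproducing such reports only;
* `uncentered` — the literal residual over $\sum Y'^2$.

The direction-symmetric `r0sq_uncentered()` is
$(\sum YY')^2/(\sum Y^2 \sum Y'^2)$, recommended by the regression
literature for intercept-free fits; it equals $K \cdot K'$ exactly, an
identity asserted to near machine precision in the tests.

**Roy's metric.**  `rm2(r2, r0sq) = r2 (1 - sqrt(r2 - r0sq))`.  When
$r^2 < r_0^2$ — routine under some reverse conventions — the metric is not
determinable; `rm2()` returns `NA` (R's missing value, distinct from
`NaN`), renderers print `ND`, and the criterion treats it as failed with an
explanatory subcheck rather than silently dropping the model.  A gap more
negative than $-10^{-12}$ is required before `NA` is returned, so exact
agreement computed in floating point (where $r^2 - r_0^2$ can land at
$-2\times10^{-16}$) still yields `rm2 = r2`.

**Lin's CCC** penalizes both scatter and location/scale shift; it equals 1
only for exact agreement and its magnitude never exceeds $|r|$.  The
printed denominator in parts of the QSAR literature contains a
per-observation term that is dimensionally inconsistent with Lin's
definition; the package computes the standard form, with the
$n(\bar Y - \bar Y')^2$ bias term.

## The five criteria

Thresholds are compared strictly as written: $r^2 > 0.6$,
$0.85 < K < 1.15$ (either slope suffices), relative gaps $< 0.1$,
$r_m^2 > 0.5$, $CCC > 0.8$, $p > 0.05$, and the method-5 inequalities with
their printed mix of $\le$ and $>$.  Two deliberate conventions:

* **Negative rule-III gaps pass.**  $(r^2 - r_0^2)/r^2$ can be negative
  when a convention yields $r_0^2 > r^2$; a negative gap satisfies
  "$< 0.1$".  Nothing is clipped.
* **Rounded inputs and the CCC threshold.**  When verdicts are computed
  from printed summary values (2 decimal places), a value printed as
  exactly 0.80 is indeterminate against a strict $> 0.8$: its unrounded
  value lies anywhere in $[0.795, 0.805)$.  Summary-mode CCC verdicts
  therefore allow half an ulp of the printed precision
  (`ccc_rule(x, printed_precision = 2)`); raw-data verdicts are strict.
  This is a statement about rounded inputs, not a relaxation of the
  criterion.

The method-4 t-test defaults to the pooled-variance (Student) form with
Welch available behind a flag, since published reports rarely state which
was used; both splits' absolute errors enter as independent samples,
two-sided.  Standard deviations default to the sample ($n-1$) denominator,
configurable to population.  The absolute-error subgroups are
$[0, 0.1)$, $[0.1, 0.2]$ and $(0.2, \infty)$ — boundary values belong to
the middle bin, matching the "< 0.1, 0.1–0.2, > 0.2" reading.

Method 5 uses only the test AAE, its SD and the training range.  The
empirical observation that models with $r^2 < 0.6$ come out BAD is left as
an observation; $r^2$ is not an input to the classifier.

No composite overall score is produced: the point of computing five
families side by side is that they disagree in instructive ways (high
$r^2$ with a biased scale, CCC passing outlier-inflated models whose SDs
mask a significant train/test error difference, and so on).

## The embedded benchmark and its reproduction

`qsar_benchmark44()` returns summary statistics for 44 published QSAR
models compiled from the literature, together with the derived values and
verdict letters reported alongside them.  `reproduce_benchmark()`
recomputes every derivable quantity from the input columns and tallies the
headline counts.  Three reproduction caveats, all visible in the tests:

* **Printed-cell inconsistencies.**  Thirteen of the ~480 reported derived
  cells contradict the benchmark's own input columns by direct arithmetic
  (e.g. a range-multiple column computed from a different range than the
  one tabulated, and one $AAE + 3SD$ cell printed as 0.03 where the inputs
  give 0.49).  The cell-level test asserts agreement within $\pm 0.01$
  after rounding for every other cell and pins the exception list so any
  fixture drift is caught.
* **Model 30 is boundary-degenerate.**  Its $AAE + 3SD$ equals
  $0.2 \times$ range *exactly* at the tabulated precision (0.470 vs
  0.470), so the GOOD/MODERATE decision depends on digits the summary
  table does not carry.  The reported letter (M) implies the unrounded
  value sat fractionally above; the computed letter from tabulated inputs
  is G.  Class percentages are therefore reported both ways.
* **Model 27 straddles rule III.**  Its reverse gap is 0.101; strict
  evaluation fails it (and must, for the total of 11 rule-set-invalid
  models to obtain), making it the one CCC-valid model that is not
  rule-valid.

Raw per-compound activities for the 44 models are not redistributed with
the package, so quantities that need them — per-model CCC, p-values and
error-bin percentages recomputed from compounds — are exercised on
synthetic data instead; the summary-level reproduction is exact.

## What the synthetic generator does and does not emulate

`synth_dataset()` draws experimental activities uniformly over a chosen
range and corrupts the "predictions" with a constant bias, additive noise
(Gaussian, or scaled Student-t with 3 degrees of freedom when
outlier-heavy tails are wanted) and an optional shifted-outlier subset
placed in either or both splits.  Defaults — 40 training and 10 test
compounds on a 4-log-unit range, noise SD 0.25 (expected absolute error
$\sigma\sqrt{2/\pi} \approx 0.2$), no bias, no contamination — were chosen
once to mirror a typical benchmarked model and are not tuning knobs.

This reproduces the error structure the criteria respond to, which is all
they can see.  It does **not** emulate descriptor-space clustering,
activity cliffs, heteroscedastic assay error, or the re-substitution
optimism of real training predictions (synthetic train and test errors are
exchangeable by construction unless contamination is asymmetric).
Passing tests on synthetic data therefore demonstrate correctness of the
computations and the direction of each criterion's response to bias,
noise and outliers — not that any real model is valid.

Determinism contract: one integer seed fully determines a dataset; grid
scenarios (`synth_grid()`) derive point seeds as `seed + index - 1`, so
the first grid point equals the base dataset and points are independent
draws.  The generator saves and restores the caller's RNG state.

## Numerical choices and problem sizes

Internal computation is in full double precision; rounding to the
conventional 2–3 decimals (half away from zero, as the published tables
round) happens only in renderers.  Degenerate inputs (constant vectors,
all-zero vectors, empty splits, non-positive ranges) raise classed
conditions (`qsarval_error_degenerate`, `_insufficient`, `_schema`,
`_usage`) rather than returning misleading numbers; the one deliberate
convention is $p = 1$ for a t-test between two zero-variance groups with
equal means.

Test-suite problem sizes are chosen to keep the full suite under a minute
on one CPU while leaving no property thinly sampled: metric/oracle
equivalence on 1,000 random vectors of lengths 3–50, the half-normal AAE
limit at $n = 10{,}000$ (asserted within three standard errors), and the
contamination-asymmetry power comparison at 200 seeded replicates.
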