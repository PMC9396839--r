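# qsarval

External validation of QSAR models from paired experimental and calculated
activities.

## The problem

A quantitative structure–activity relationship (QSAR) model earns its keep by
predicting the biological activity of compounds that were not used to fit it.
Judging that predictivity from a held-out test split is done, in practice,
with a handful of competing criterion families, each with its own blind
spots. `qsarval` implements the five in widest use and reports them side by
side — deliberately without collapsing them into a single score, because no
one criterion is sufficient on its own:

1. **Golbraikh–Tropsha rules.** With $r^2$ the squared Pearson correlation
   between experimental ($Y$) and calculated ($Y'$) test activities, and
   $K = \sum YY' / \sum Y'^2$, $K' = \sum YY' / \sum Y^2$ the slopes of the
   least-squares regressions through the origin, a model is valid when
   $r^2 > 0.6$, at least one slope lies in $(0.85, 1.15)$, and at least one
   of $(r^2 - r_0^2)/r^2$ and $(r^2 - r_0'^2)/r^2$ is below 0.1, where
   $r_0^2$ and $r_0'^2$ are the through-origin determination coefficients in
   the two directions.
2. **Roy's $r_m^2$.** $r_m^2 = r^2\,(1 - \sqrt{r^2 - r_0^2})$, valid when
   $r_m^2 > 0.5$; not determinable (ND) when $r^2 < r_0^2$, which some
   $r_0^2$ conventions routinely produce.
3. **Lin's concordance correlation coefficient.**
   $CCC = 2\sum(Y-\bar Y)(Y'-\bar Y') \big/ \left[\sum(Y-\bar Y)^2 +
   \sum(Y'-\bar Y')^2 + n(\bar Y - \bar Y')^2\right]$, valid when
   $CCC > 0.8$; unlike $r^2$ it punishes constant bias.
4. **Training/test error comparison.** A two-sided independent t-test
   between the absolute errors $|Y - Y'|$ of the training and test splits;
   valid when $r^2 > 0.6$ and $p > 0.05$.
5. **MAE vs training range.** With AAE the test-split mean absolute error,
   SD its standard deviation and $R$ the training-set activity range:
   GOOD when $AAE \le 0.1R$ and $AAE + 3SD \le 0.2R$; BAD when
   $AAE > 0.15R$ or $AAE + 3SD > 0.25R$; MODERATE otherwise.

Because published usage of the through-origin $r_0'^2$ is not uniform, three
conventions are implemented and selectable (`r0sq_reverse()`); `rm2()`
returns `NA` (rendered `ND`) when undefined rather than a misleading number.

## Worked example

```r
library(qsarval)

# a synthetic model: 40 training / 10 test compounds over a 4-log-unit
# activity range, noise SD 0.25, plus a constant prediction bias of 0.3
d <- synth_dataset(n_train = 40, n_test = 10, noise_sd = 0.25,
                   bias = 0.3, seed = 42)
v <- qsar_validate(d)
v
#> External validation of QSAR model 'synthetic' (raw data)
#>   method 1 Golbraikh-Tropsha rules    VALID
#>   method 2 rm2 > 0.5                  VALID
#>   method 3 CCC > 0.8                  VALID
#>   method 4 train/test error t-test    VALID
#>   method 5 MAE vs training range      BAD
#>   r2 = 0.961, rm2 = 0.96, CCC = 0.91, test AAE = 0.358 +/- 0.211, range = 3.94
```

The correlation-based criteria are happy ($r^2 = 0.96$) while the
error-magnitude criterion is not: the 0.3 bias plus noise pushes the test
AAE to 0.36, above 15 % of the training range — exactly the kind of
disagreement between criteria the package is built to expose.
`summary(v)` prints every subcheck with its numeric evidence,
`plot(v)` draws the absolute-error frequency bins and the residual plot,
and `residuals(v)` returns the signed test-split residuals.

The same verdicts work from printed summary statistics alone:

```r
b <- qsar_benchmark44()       # 44 published models, embedded
qsar_validate(b[9, ])
#> External validation of QSAR model '9' (summary data)
#>   ...
#>   method 5 MAE vs training range      BAD
#>   r2 = 0.834, rm2 = 0.75, CCC = 0.89, test AAE = 1.630 +/- 1.256, range = 14.46
```

A command-line front end is installed at
`system.file("scripts", "qsarval", package = "qsarval")` with subcommands
`evaluate`, `batch`, `reproduce` and `synth` over the standard CSV schema
(`compound_id,split,y_exp,y_calc`).

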