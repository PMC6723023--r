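# chromassay

Chemometric prediction of fruit biocompound content from pulp color.

Anthocyanins, carotenoids and polyphenols give fruit pulps their
characteristic colors, and determining them spectrophotometrically is slow
and solvent-hungry. For quality screening, the internal CIE L\*a\*b\* color
of a homogenized pulp can stand in for the wet assay: over samples of a
given fruit, the total anthocyanin content (TAC), total carotenoid content
(TCC) and total polyphenol content (TPC) are well described by a linear
model in the color coordinates,

```
Y = b0 + b1·L* + b2·a* + b3·b*
```

calibrated by ordinary least squares through the normal equations
(XᵀX)b = XᵀY, cleaned by discarding samples whose residuals exceed two
residual standard deviations and refitting, checked by partial-coefficient
t tests (tᵢ = bᵢ/√(Pᵢᵢ·S²) on n−4 degrees of freedom), and validated
against Horwitz coefficient-of-variation limits.

`chromassay` implements the whole workflow for analysts and method
developers in food chemistry:

- **Assay arithmetic** — pH-differential TAC (cyanidin-3-glucoside
  chloride, MW 484.84, ε 34300), Beer–Lambert TCC (β-carotene, extinction
  coefficient 2592 in hexane), Folin–Ciocalteu TPC with the
  Abs_B − Abs_A interference correction, ABTS/DPPH Trolox equivalents,
  maturity index (°Brix / titratable acidity), chroma and hue.
- **Calibration** — `fit_linear_model()`, `filter_by_residuals()`,
  `refit_filtered()`, `coefficient_t_statistics()`, `predict_content()`.
- **Validation** — `coefficient_of_variation()`, `horwitz_cv_limit()`
  (CV% = 2^(1 − 0.5·log₁₀C)), `validate_against_horwitz()` with the fixed
  16% (µg/g analytes) and 8% (mg/100 g analytes) acceptance bands or the
  continuous Horwitz function.
- **Synthetic data** — `synthetic_spec()` / `generate_fruit_dataset()`
  emulate the 15-sample × 3-replicate (n = 45) calibration design with
  configurable noise and outlier injection, plus exact inverse-assay
  absorbance records for round-trip testing.
- **Pipeline** — `run_pipeline()` / `write_report()` orchestrate
  fit → filter → refit → significance → predict → validate per
  fruit × analyte with CSV/JSON reports, and
  `inst/scripts/chromassay-cli.R` exposes the verbs
  `simulate`, `fit`, `predict`, `validate`, `run` from a shell.

Packaged reference tables (`reference_colors()`, `reference_models()`,
`reference_contents()`, `reference_maturity()`) carry published mean pulp
colors, fitted coefficients and measured contents for six tropical and
Andean fruits: araza, blackberry, Andean blueberry, naranjilla, tamarillo
and goldenberry.

## Worked example

Simulate a blackberry anthocyanin calibration with the study's replicate
structure, fit, filter, refit and predict:

```r
library(chromassay)

spec <- synthetic_spec(
  fruit_label = "blackberry",
  true_coefficients = c(1644.47, -13.53, -12.56, 18.42),  # mg/100 g per color unit
  color_means = c(10.68, 13.80, 4.95), color_sds = c(2.23, 3.90, 1.70),
  noise_sd = 40, analyte = "TAC", seed = 11)
d <- generate_fruit_dataset(spec)   # 15 samples x 3 replicates = 45 rows

fit <- fit_linear_model(d)
report <- filter_by_residuals(fit, d)   # two-sigma residual screen
final <- refit_filtered(d, report)
final
#> Linear color-content model (TAC, blackberry)
#>   content = 1590.08 + -11.6995 L* + -13.4076 a* + 26.5208 b*
#>   n = 43  R^2 = 0.8082  S^2 = 891.3

coefficient_t_statistics(final)
#>   term   estimate         t            p
#> 1   b0 1590.08013 35.760008 1.989115e-31
#> 2   b1  -11.69953 -5.139559 8.055530e-06
#> 3   b2  -13.40756 -5.375397 3.808436e-06
#> 4   b3   26.52082  8.960182 5.211188e-11

predict_content(final, L = 10.68, a = 13.80, b = 4.95)
#> [1] 1411.382
```

The filter dropped 2 of 45 rows, the refit R² rose from 0.71 to 0.81, all
four coefficients are significant (p ≪ 0.05), and the prediction at the
mean blackberry pulp color (1411 mg cyanidin-3-glucoside chloride/100 g)
sits within 0.5% of the 1417.8 mg/100 g implied by the generating
coefficients — the same closeness seen between experimental and predicted
values in the packaged reference tables.

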