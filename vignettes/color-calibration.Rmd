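---
title: "Calibrating biocompound content against pulp color: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating biocompound content against pulp color: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromassay)
```

## The model

Pigment chemistry ties fruit pulp color to biocompound content: anthocyanins
dominate the red–purple fruits (blackberry, Andean blueberry), carotenoids
the yellow–orange ones (araza, naranjilla, tamarillo, goldenberry), and
polyphenols contribute across the board. `chromassay` calibrates, per fruit
and per analyte, the linear model

$$Y = b_0 + b_1 L^* + b_2 a^* + b_3 b^* + \varepsilon$$

where $Y$ is the analyte content (TAC in mg cyanidin-3-glucoside
chloride/100 g, TCC in µg β-carotene/g, TPC in mg GAE/100 g, all dry
weight) and $(L^*, a^*, b^*)$ are the CIELAB coordinates of the homogenized
pulp. The assumptions are those of ordinary least squares: a linear mean
structure over the (narrow) color range spanned by one fruit at commercial
maturity, homoscedastic additive noise, and color coordinates that are not
collinear. Within a single fruit these are defensible; across fruits they
are not, which is why models are always fitted per fruit × analyte.

Estimation deliberately goes through the **normal equations**
$(X^\top X)\,b = X^\top Y$ rather than an orthogonal decomposition: the
inverse cross-product matrix $(X^\top X)^{-1}$ is needed anyway for the
partial-coefficient tests, the designs are tiny (n ≤ a few hundred, p = 4)
and well-conditioned, and the classical formulation keeps the algebra
transparent. The solver refuses rank-deficient designs outright instead of
falling back to a pseudo-inverse — a silent minimum-norm solution would be
meaningless as a calibration. The test suite cross-checks the solver
against an independent QR-based oracle.

## The fit–filter–refit cycle

1. `fit_linear_model()` estimates $b$, the residuals, the residual
   variance $S^2 = \mathrm{SSE}/(n-4)$, $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$,
   and $t_i = b_i / \sqrt{P_{ii} S^2}$ with $P_{ii}$ the diagonal of
   $(X^\top X)^{-1}$.
2. `filter_by_residuals()` keeps rows with $|e_i| < k\sigma$, where
   $\sigma = \sqrt{S^2}$ is the dof-corrected residual standard deviation
   of the *initial* fit and $k = 2$ by default. The inequality is strict:
   a row sitting exactly on the boundary is kept, matching the convention
   of keeping only deviations *lower than* $2\sigma$. Under Gaussian noise
   this retains about 95% of clean rows, which the acceptance suite checks
   as a 93–97% band over 400 simulated datasets.
3. `refit_filtered()` re-estimates on the kept rows, producing the final
   prediction equation; the filter report travels with the fit as
   provenance. One pass is the default (`filter_passes` in
   `pipeline_config()` makes it configurable), because the procedure being
   emulated describes a single re-analysis. Repeated passes on clean data
   keep trimming ~5% each time, so more passes buy little and bias the
   noise estimate down.

Significance of each color coordinate is judged two-sided on $n-4$ degrees
of freedom. An exactly saturated fit ($S^2 = 0$) reports infinite t for
non-zero coefficients and zero for zero ones rather than failing — it can
occur with noiseless synthetic data.

## Assay arithmetic

All assay conversions are pure arithmetic in full precision; rounding to
the 2 decimals customary in published tables is left to the reporting
layer.

- **TAC (pH-differential).** The buffers-and-wavelengths protocol defines
  only the pieces; the background-corrected absorbance is taken in the
  standard AOAC combination
  $A = (A_{510} - A_{700})_{\mathrm{pH}1.0} - (A_{510} - A_{700})_{\mathrm{pH}4.5}$,
  and $TAC = A \cdot MW \cdot DF \cdot 100 / (\epsilon \cdot W)$. A
  pre-combined $A$ is also accepted. The protocol describes pH-specific
  dilutions ($10^{-3}$ at pH 1.0, $10^{-1}$ at pH 4.5) yet the formula has
  one DF; the reading therefore carries a single DF and any per-pH
  dilution is the caller's responsibility. Negative corrected absorbances
  (below the detection limit — the situation of anthocyanins in the
  yellow–orange fruits) yield 0 with a warning, not an error.
- **TCC.** $TCC = A \cdot V_T \cdot 10^4 / (2592 \cdot W)$, with defaults
  taken verbatim (2592 for β-carotene in hexane, $10^4$ unit factor).
- **TPC and Trolox equivalents.** Calibration curves are linear
  (`calibration_curve()`); the packaged reference slopes/intercepts are
  the gallic acid curve (0.0011, 0.0529) and the Trolox curves for ABTS
  (0.0007, 0.0671) and DPPH (0.0013, 0.007). Because the source protocols
  do not state the extract volumes and masses linking mg/L to mg/100 g,
  `tpc_folin()` and `trolox_equivalents()` take `extract_volume`,
  `dilution_factor` and `sample_weight` as explicit arguments with no
  defaults — silent unit guessing would be worse than an error.
- **Chroma/hue.** $C^* = \sqrt{a^{*2}+b^{*2}}$, $h = \mathrm{atan2}(b^*,
  a^*)$ in degrees on $[0, 360)$, hue 0 at zero chroma. Published color
  tables in this literature sometimes swap the $C^*$ and $h$ columns; the
  implementation follows the definitions, not any particular layout.

## The synthetic-data generator

`synthetic_spec()` encodes the calibration study design: 15 samples per
fruit in triplicate (n = 45) — the defaults — with sample-level color
triplets drawn as independent Gaussians around the fruit's mean color
(means and SDs from the packaged color table when emulating a real fruit).
Independence across L\*, a\*, b\* is the simplest model consistent with
published summary tables, which report only means and SDs; a correlation
matrix can be injected when more is known. Replicates share the
sample-level color draw and add replicate-level measurement noise
(`replicate_sd`, default 0): the two-level structure mirrors the
sample/triplicate design, but since the within-sample variance partition
is never published, the default collapses to the simple one-level case.
L\* is clipped to [0, 100] because CIELAB lightness is bounded; the
chromatic axes are left unclipped.

Contents follow the linear model plus $N(0, \sigma^2)$ noise. Outliers —
the rows the 2σ filter exists to catch — are injected deterministically:
`floor(outlier_fraction × n)` rows chosen uniformly without replacement,
shifted by ±`outlier_shift`·σ with alternating sign, flagged in the
output. The floor/alternating rule is chosen for reproducibility and easy
testing, not realism.

`generate_absorbance_records()` analytically inverts each assay formula so
that the forward assay applied to the generated readings reproduces the
contents to floating-point accuracy; constant instrument baselines are
added so the background-correction terms are actually exercised.

What the generator does **not** emulate: instrument drift, pH/temperature
pigment degradation, ripening kinetics, non-Gaussian color distributions,
or correlation between content noise and color. Tests passing on this
synthetic world show the estimation machinery is correct under the model's
own assumptions; they do not show the linear model is adequate for any
particular real fruit.

## Validation

`coefficient_of_variation()` is the ordinary 100·sd/|mean|. Experimental
CV (CV\_E) is computed from the retained rows' measured contents; the
prediction CV (CV\_P) is the CV of the model's predictions over those same
rows, pairing each predicted mean with its own dispersion. The acceptance
limit is, by default, the fixed regime used in practice — 16% for µg/g
analytes (carotenoids) and an 8% upper band for mg/100 g analytes
(anthocyanins, polyphenols) — because that is how such methods are
actually judged; the continuous Horwitz function
$CV\% = 2^{1-0.5\log_{10} C}$ (16% at C = 10⁻⁶, i.e. 1 µg/g) is available
as `mode = "horwitz"`, with unit conversion to mass fraction
(mg/100 g → 10⁻⁵, µg/g → 10⁻⁶) so the verdict is invariant to the unit
chosen.

The packaged reference content table is shipped verbatim, including its
internal inconsistencies (a few CV entries differ between the table and
the accompanying text, and one fruit's predicted TPC appears in two
different versions). The package computes CVs from its own inputs and
makes no attempt to reconcile published typos.

## Prediction fidelity and problem sizes

Evaluating the packaged coefficient vectors at the packaged mean colors
reproduces the packaged predicted contents to within about 1% (checked for
blackberry TAC, Andean blueberry TPC, goldenberry TCC and TPC). Exact
equality is not expected: the published predictions were evidently
evaluated at the mean colors of the *filtered* samples, which are not
published, rather than at the full-sample means. One combination
(tamarillo TCC) cannot be reproduced from the published summaries at all
(~24% off) and is excluded from the fidelity checks. Rows are
replicate-level (n = 45) throughout, matching the study design;
`aggregate_replicates()` offers per-sample means for users who prefer
n = 15.

The statistical guarantees are checked at sizes chosen to keep the whole
suite under a few minutes on one core while leaving Monte-Carlo error well
inside the asserted bands: 500 replicates for parameter recovery (n = 45,
noise SD 50), 400 datasets for the 2σ retention band, 2000 simulations for
the t-test type-I error ([0.03, 0.07] at α = 0.05), 20 random instances
for solver–oracle agreement at 10 ≤ n ≤ 200, p ≤ 6.

## Known limitations

- A calibration is fruit- and maturity-window-specific; coefficients do
  not transfer across cultivars, seasons or color ranges, and the linear
  model extrapolates poorly (negative predictions are flagged, not
  clamped).
- The 2σ filter assumes the initial fit is not already ruined by the
  outliers it is meant to remove; with gross contamination a robust
  estimator would be needed.
- Filtering is per-analyte: a pulp sample may be kept for TPC and dropped
  for TAC. Whether joint filtering would be preferable is untested here.
- The Horwitz fixed bands are conventions, not statistics; the continuous
  mode is offered for users who want the actual trumpet function.
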