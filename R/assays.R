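# Deterministic assay arithmetic: raw spectrophotometric readings ->
# reported biocompound quantities.

#' Maturity index from soluble solids and titratable acidity
#'
#' The maturity index (MI) of a fruit is the ratio of total soluble solids
#' (degrees Brix) to titratable acidity (g acid / 100 g), the standard
#' field index of commercial ripeness.
#'
#' @param tss Total soluble solids, degrees Brix (>= 0). Vectorized.
#' @param ta Titratable acidity, g/100 g (> 0). Vectorized.
#' @return Dimensionless ratio TSS/TA.
#' @examples
#' maturity_index(tss = 3.83, ta = 2.40)  # 1.60
#' @export
maturity_index <- function(tss, ta) {
  check_number(tss, "tss", lower = 0, allow_vector = TRUE)
  check_number(ta, "ta", lower = 0, strict_lower = TRUE, allow_vector = TRUE)
  tss / ta
}

#' Chroma and hue angle from CIELAB chromatic coordinates
#'
#' Computes the cylindrical CIELAB coordinates: chroma
#' \eqn{C^* = \sqrt{a^{*2} + b^{*2}}} and hue angle
#' \eqn{h = \mathrm{atan2}(b^*, a^*)} in degrees mapped to [0, 360).
#' When chroma is exactly zero the hue is reported as 0 by convention.
#'
#' @param a_star Red(+)/green(-) coordinate. Vectorized.
#' @param b_star Yellow(+)/blue(-) coordinate. Vectorized.
#' @return A data.frame with columns \code{chroma} and \code{hue} (degrees).
#' @examples
#' chroma_hue(a_star = -4.25, b_star = 22.04)  # naranjilla pulp: C* 22.45
#' @export
chroma_hue <- function(a_star, b_star) {
  check_number(a_star, "a_star", allow_vector = TRUE)
  check_number(b_star, "b_star", allow_vector = TRUE)
  if (length(a_star) != length(b_star)) {
    stop_domain("`a_star` and `b_star` must have equal length")
  }
  chroma <- sqrt(a_star^2 + b_star^2)
  hue <- atan2(b_star, a_star) * 180 / pi
  hue <- hue %% 360
  hue[chroma == 0] <- 0
  data.frame(chroma = chroma, hue = hue)
}

#' pH-differential absorbance reading for anthocyanin quantification
#'
#' Bundles the four absorbance readings of the pH-differential method
#' (510 and 700 nm at pH 1.0 and pH 4.5) with the assay parameters.
#' Defaults are for cyanidin-3-glucoside chloride: molecular weight
#' 484.84 g/mol and molar absorptivity 34300 L mol^-1 cm^-1.
#'
#' @param abs_510_ph1,abs_700_ph1 Absorbances at pH 1.0 (>= 0).
#' @param abs_510_ph45,abs_700_ph45 Absorbances at pH 4.5 (>= 0).
#' @param dilution_factor Dilution factor DF (> 0).
#' @param sample_weight Sample weight W in grams (> 0).
#' @param molecular_weight Pigment molecular weight, g/mol.
#' @param molar_absorptivity Molar absorptivity epsilon, L mol^-1 cm^-1.
#' @return An object of class \code{ph_differential_reading}.
#' @seealso [tac_ph_differential()]
#' @export
ph_differential_reading <- function(abs_510_ph1, abs_700_ph1 = 0,
                                    abs_510_ph45 = 0, abs_700_ph45 = 0,
                                    dilution_factor, sample_weight,
                                    molecular_weight = 484.84,
                                    molar_absorptivity = 34300) {
  check_number(abs_510_ph1, "abs_510_ph1", lower = 0, allow_vector = TRUE)
  check_number(abs_700_ph1, "abs_700_ph1", lower = 0, allow_vector = TRUE)
  check_number(abs_510_ph45, "abs_510_ph45", lower = 0, allow_vector = TRUE)
  check_number(abs_700_ph45, "abs_700_ph45", lower = 0, allow_vector = TRUE)
  check_number(dilution_factor, "dilution_factor", lower = 0, strict_lower = TRUE,
               allow_vector = TRUE)
  check_number(sample_weight, "sample_weight", lower = 0, strict_lower = TRUE,
               allow_vector = TRUE)
  check_number(molecular_weight, "molecular_weight", lower = 0, strict_lower = TRUE)
  check_number(molar_absorptivity, "molar_absorptivity", lower = 0, strict_lower = TRUE)
  structure(
    list(abs_510_ph1 = abs_510_ph1, abs_700_ph1 = abs_700_ph1,
         abs_510_ph45 = abs_510_ph45, abs_700_ph45 = abs_700_ph45,
         dilution_factor = dilution_factor, sample_weight = sample_weight,
         molecular_weight = molecular_weight,
         molar_absorptivity = molar_absorptivity),
    class = "ph_differential_reading"
  )
}

#' Total anthocyanin content by the pH-differential method
#'
#' The background-corrected absorbance is the AOAC combination
#' \eqn{A = (A_{510} - A_{700})_{pH 1.0} - (A_{510} - A_{700})_{pH 4.5}},
#' and \eqn{TAC = A \cdot MW \cdot DF \cdot 100 / (\epsilon \cdot W)} in
#' mg cyanidin-3-glucoside chloride per 100 g dry weight. A pre-combined
#' absorbance may be supplied via \code{absorbance}, overriding the four
#' readings. A negative corrected absorbance (below detection limit)
#' yields 0 with a warning.
#'
#' @param reading A [ph_differential_reading()].
#' @param absorbance Optional pre-combined corrected absorbance A.
#' @return TAC in mg/100 g dry weight (vectorized over the readings).
#' @examples
#' r <- ph_differential_reading(abs_510_ph1 = 0.343, dilution_factor = 1000,
#'                              sample_weight = 0.25)
#' tac_ph_differential(r)  # 1939.36
#' @export
tac_ph_differential <- function(reading, absorbance = NULL) {
  if (!inherits(reading, "ph_differential_reading")) {
    stop_domain("`reading` must be a ph_differential_reading")
  }
  a <- if (is.null(absorbance)) {
    (reading$abs_510_ph1 - reading$abs_700_ph1) -
      (reading$abs_510_ph45 - reading$abs_700_ph45)
  } else {
    check_number(absorbance, "absorbance", allow_vector = TRUE)
  }
  neg <- a < 0
  if (any(neg)) {
    warning("negative corrected absorbance set to 0 (below detection limit)",
            call. = FALSE)
    a[neg] <- 0
  }
  a * reading$molecular_weight * reading$dilution_factor * 100 /
    (reading$molar_absorptivity * reading$sample_weight)
}

#' Total carotenoid content from absorbance at 450 nm
#'
#' Beer-Lambert quantification of total carotenoids as beta-carotene:
#' \eqn{TCC = A \cdot V_T \cdot 10^4 / (2592 \cdot W)} in micrograms of
#' beta-carotene per gram dry weight, with 2592 the specific extinction
#' coefficient of beta-carotene in hexane and 10^4 the unit-conversion
#' constant.
#'
#' @param absorbance Absorbance at 450 nm (>= 0). Vectorized.
#' @param total_volume Extract total volume VT in mL (> 0).
#' @param sample_weight Sample weight W in grams (> 0).
#' @param extinction_coefficient Specific extinction coefficient (default 2592).
#' @param unit_factor Unit-conversion constant (default 1e4).
#' @return TCC in micrograms beta-carotene per gram dry weight.
#' @examples
#' tcc_spectrophotometric(0.2592, total_volume = 50, sample_weight = 1)  # 50
#' @export
tcc_spectrophotometric <- function(absorbance, total_volume, sample_weight,
                                   extinction_coefficient = 2592,
                                   unit_factor = 1e4) {
  check_number(absorbance, "absorbance", lower = 0, allow_vector = TRUE)
  check_number(total_volume, "total_volume", lower = 0, strict_lower = TRUE,
               allow_vector = TRUE)
  check_number(sample_weight, "sample_weight", lower = 0, strict_lower = TRUE,
               allow_vector = TRUE)
  check_number(extinction_coefficient, "extinction_coefficient",
               lower = 0, strict_lower = TRUE)
  absorbance * total_volume * unit_factor /
    (extinction_coefficient * sample_weight)
}

#' Linear spectrophotometric calibration curve
#'
#' Represents a response = slope * concentration + intercept calibration.
#' The packaged reference curves are gallic acid for Folin-Ciocalteu
#' ([tpc_reference_curve()]), and Trolox for the ABTS and DPPH radical
#' assays ([abts_reference_curve()], [dpph_reference_curve()]).
#'
#' @param slope Response per concentration unit; must be non-zero.
#' @param intercept Response at zero concentration.
#' @param concentration_unit Unit label of the concentration axis.
#' @return An object of class \code{calibration_curve}.
#' @export
calibration_curve <- function(slope, intercept = 0,
                              concentration_unit = "mg/L") {
  check_number(slope, "slope")
  check_number(intercept, "intercept")
  if (slope == 0) stop_domain("`slope` must be non-zero")
  structure(list(slope = slope, intercept = intercept,
                 concentration_unit = concentration_unit),
            class = "calibration_curve")
}

#' @rdname calibration_curve
#' @export
tpc_reference_curve <- function() calibration_curve(0.0011, 0.0529, "mg/L")

#' @rdname calibration_curve
#' @export
abts_reference_curve <- function() calibration_curve(0.0007, 0.0671, "umol/L")

#' @rdname calibration_curve
#' @export
dpph_reference_curve <- function() calibration_curve(0.0013, 0.007, "umol/L")

#' Invert a calibration curve
#'
#' Maps an absorbance response back to a concentration,
#' (response - intercept) / slope. Concentrations below zero (responses
#' below the intercept) are returned as-is with a warning, not clamped:
#' near-blank readings legitimately invert to small negative values.
#'
#' @param curve A [calibration_curve()].
#' @param response Absorbance response(s).
#' @return Concentration in the curve's units.
#' @examples
#' invert_calibration(tpc_reference_curve(), 0.1629)  # 100 mg/L
#' @export
invert_calibration <- function(curve, response) {
  if (!inherits(curve, "calibration_curve")) {
    stop_domain("`curve` must be a calibration_curve")
  }
  check_number(response, "response", allow_vector = TRUE)
  conc <- (response - curve$intercept) / curve$slope
  if (any(conc < 0)) {
    warning("response below calibration intercept: negative concentration",
            call. = FALSE)
  }
  conc
}

#' Total polyphenol content by Folin-Ciocalteu
#'
#' Applies the A/B-fraction interference correction (net response =
#' Abs_B - Abs_A), inverts the gallic acid calibration curve to a
#' concentration in mg/L, and scales to mg gallic acid equivalents (GAE)
#' per 100 g dry weight:
#' \eqn{TPC = c \cdot V \cdot DF \cdot 100 / W} with V the extract volume
#' in litres, DF the dilution factor and W the sample weight in grams.
#'
#' @param abs_b Absorbance of the B (soluble) fraction. Vectorized.
#' @param abs_a Absorbance of the A (non-soluble) fraction. Vectorized.
#' @param curve Gallic acid [calibration_curve()]; defaults to the
#'   packaged reference curve.
#' @param extract_volume Extract volume in litres (> 0).
#' @param dilution_factor Dilution factor (> 0, default 1).
#' @param sample_weight Sample weight in grams (> 0).
#' @return TPC in mg GAE / 100 g dry weight.
#' @export
tpc_folin <- function(abs_b, abs_a, curve = tpc_reference_curve(),
                      extract_volume, dilution_factor = 1, sample_weight) {
  check_number(abs_b, "abs_b", lower = 0, allow_vector = TRUE)
  check_number(abs_a, "abs_a", lower = 0, allow_vector = TRUE)
  check_number(extract_volume, "extract_volume", lower = 0, strict_lower = TRUE,
               allow_vector = TRUE)
  check_number(dilution_factor, "dilution_factor", lower = 0, strict_lower = TRUE,
               allow_vector = TRUE)
  check_number(sample_weight, "sample_weight", lower = 0, strict_lower = TRUE,
               allow_vector = TRUE)
  conc <- invert_calibration(curve, abs_b - abs_a)
  conc * extract_volume * dilution_factor * 100 / sample_weight
}

#' Trolox-equivalent antioxidant activity
#'
#' Converts an ABTS or DPPH absorbance response into micromoles of Trolox
#' equivalents per gram of sample: the Trolox calibration curve is
#' inverted to a concentration in umol/L and scaled by
#' extract_volume (L) / sample_weight (g).
#'
#' @param curve Trolox [calibration_curve()] (see [abts_reference_curve()]
#'   and [dpph_reference_curve()]).
#' @param response Absorbance response(s).
#' @param extract_volume Extract volume in litres (> 0).
#' @param sample_weight Sample weight in grams (> 0).
#' @return Antioxidant activity in umol TE / g sample.
#' @examples
#' trolox_equivalents(dpph_reference_curve(), 0.267,
#'                    extract_volume = 0.01, sample_weight = 1)  # 2
#' @export
trolox_equivalents <- function(curve, response, extract_volume, sample_weight) {
  check_number(extract_volume, "extract_volume", lower = 0, strict_lower = TRUE,
               allow_vector = TRUE)
  check_number(sample_weight, "sample_weight", lower = 0, strict_lower = TRUE,
               allow_vector = TRUE)
  conc <- invert_calibration(curve, response)
  conc * extract_volume / sample_weight
}
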