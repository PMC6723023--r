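# Packaged reference tables for six tropical and Andean fruits (araza,
# blackberry, Andean blueberry, naranjilla, tamarillo, goldenberry):
# published mean pulp colors, fitted color-model coefficients, measured
# and predicted contents, and maturity parameters. Shipped as plain CSV
# under inst/extdata.

read_extdata <- function(file) {
  path <- system.file("extdata", file, package = "chromassay", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reference pulp color summary for six fruits
#'
#' Mean and standard deviation of the CIELAB pulp color coordinates
#' (L*, a*, b*) measured on homogenized pulps of six tropical and Andean
#' fruits (15 samples in triplicate per fruit).
#'
#' @return A data.frame with columns
#'   \code{fruit, L_mean, L_sd, a_mean, a_sd, b_mean, b_sd}.
#' @export
reference_colors <- function() read_extdata("fruit_colors.csv")

#' Reference color-model coefficients for six fruits
#'
#' Published least-squares coefficients of the linear model
#' content = b0 + b1 L* + b2 a* + b3 b* per fruit and analyte, with the
#' model determination coefficient. Fruit/analyte combinations where the
#' analyte was below the spectrophotometric detection limit (anthocyanins
#' in the yellow-orange fruits, carotenoids in the red-purple ones) are
#' absent from the table.
#'
#' @return A data.frame with columns
#'   \code{fruit, analyte, b0, b1, b2, b3, r2}.
#' @examples
#' m <- reference_models()
#' bb <- m[m$fruit == "blackberry" & m$analyte == "TAC", ]
#' predict_content(unlist(bb[c("b0", "b1", "b2", "b3")]),
#'                 L = 10.68, a = 13.80, b = 4.95)
#' @export
reference_models <- function() read_extdata("fruit_models.csv")

#' Reference experimental and predicted contents for six fruits
#'
#' Published experimental means, model-predicted means and their
#' coefficients of variation (CV_E, CV_P, percent) per fruit and analyte.
#' TAC in mg cyanidin-3-glucoside chloride/100 g, TCC in ug
#' beta-carotene/g, TPC in mg GAE/100 g, all dry weight.
#'
#' @return A data.frame with columns \code{fruit, analyte,
#'   experimental_mean, cv_e, predicted_mean, cv_p}.
#' @export
reference_contents <- function() read_extdata("fruit_contents.csv")

#' Reference maturity parameters for six fruits
#'
#' Titratable acidity (g/100 g), total soluble solids (degrees Brix) and
#' the resulting maturity index per fruit.
#'
#' @return A data.frame with columns \code{fruit, titratable_acidity,
#'   total_soluble_solids, maturity_index}.
#' @export
reference_maturity <- function() read_extdata("fruit_maturity.csv")
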