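# Method validation: coefficients of variation, Horwitz acceptance
# limits, and experimental-vs-predicted agreement.

#' Coefficient of variation in percent
#'
#' CV = 100 * sd / |mean|. Scale invariant: multiplying both mean and SD
#' by the same positive factor leaves the CV unchanged.
#'
#' @param mean Mean, analyte units; must be non-zero. Vectorized.
#' @param sd Standard deviation, same units (>= 0). Vectorized.
#' @return CV in percent.
#' @examples
#' coefficient_of_variation(1416.68, 158.71)  # 11.20
#' @export
coefficient_of_variation <- function(mean, sd) {
  check_number(mean, "mean", allow_vector = TRUE)
  check_number(sd, "sd", lower = 0, allow_vector = TRUE)
  if (any(mean == 0)) stop_domain("CV undefined for zero mean")
  100 * sd / abs(mean)
}

#' Horwitz coefficient-of-variation limit
#'
#' The Horwitz trumpet relates the acceptable inter-laboratory CV to the
#' analyte concentration expressed as a dimensionless mass fraction C:
#' \deqn{CV\% = 2^{1 - 0.5 \log_{10} C}}
#' It is strictly decreasing in C; at C = 10^-6 (1 ug/g) the limit is
#' 16\%, at C = 1 it is 2\%.
#'
#' @param concentration Mass fraction(s) in (0, 1].
#' @return CV limit in percent.
#' @examples
#' horwitz_cv_limit(1e-6)  # 16
#' @export
horwitz_cv_limit <- function(concentration) {
  check_number(concentration, "concentration", lower = 0, upper = 1,
               strict_lower = TRUE, allow_vector = TRUE)
  2^(1 - 0.5 * log10(concentration))
}

#' Convert a concentration to a dimensionless mass fraction
#'
#' @param value Concentration value(s).
#' @param unit Unit of \code{value}: \code{"mg_100g"} (x 1e-5) or
#'   \code{"ug_g"} (x 1e-6).
#' @return Mass fraction(s).
#' @export
mass_fraction <- function(value, unit = c("mg_100g", "ug_g")) {
  unit <- match.arg(unit)
  check_number(value, "value", lower = 0, allow_vector = TRUE)
  value * switch(unit, mg_100g = 1e-5, ug_g = 1e-6)
}

# Fixed per-regime CV acceptance limits (percent): 16% for ug/g-scale
# analytes (carotenoids), 8% upper band for mg/100 g analytes
# (anthocyanins, polyphenols).
fixed_cv_limit <- function(unit) switch(unit, ug_g = 16, mg_100g = 8)

#' Validate an analyte determination against a CV acceptance limit
#'
#' Compares the experimental CV (CV_E) and the model-prediction CV (CV_P)
#' against an acceptance limit, either the fixed per-regime thresholds
#' (16\% for ug/g analytes, 8\% for mg/100 g analytes; the default) or
#' the continuous Horwitz function evaluated at the experimental mean
#' converted to a mass fraction. Also reports the relative error between
#' experimental and predicted means.
#'
#' @param experimental_mean,experimental_sd Experimental mean (> 0) and SD.
#' @param predicted_mean,predicted_sd Model-predicted mean (> 0) and SD.
#' @param analyte Analyte label ("TAC", "TCC", "TPC").
#' @param fruit_label Fruit name carried into the summary.
#' @param unit Unit regime: \code{"mg_100g"} or \code{"ug_g"}.
#' @param mode \code{"fixed"} (default) or \code{"horwitz"}.
#' @return A one-row data.frame of class \code{validation_summary} with
#'   columns \code{fruit, analyte, experimental_mean, experimental_sd,
#'   predicted_mean, predicted_sd, cv_e, cv_p, horwitz_limit,
#'   passes_cv_e, passes_cv_p, passes_horwitz, relative_error}.
#' @export
validate_against_horwitz <- function(experimental_mean, experimental_sd,
                                     predicted_mean, predicted_sd,
                                     analyte = "TAC", fruit_label = "",
                                     unit = c("mg_100g", "ug_g"),
                                     mode = c("fixed", "horwitz")) {
  unit <- match.arg(unit)
  mode <- match.arg(mode)
  check_number(experimental_mean, "experimental_mean", lower = 0, strict_lower = TRUE)
  check_number(predicted_mean, "predicted_mean", lower = 0, strict_lower = TRUE)
  check_number(experimental_sd, "experimental_sd", lower = 0)
  check_number(predicted_sd, "predicted_sd", lower = 0)
  cv_e <- coefficient_of_variation(experimental_mean, experimental_sd)
  cv_p <- coefficient_of_variation(predicted_mean, predicted_sd)
  limit <- if (mode == "fixed") {
    fixed_cv_limit(unit)
  } else {
    horwitz_cv_limit(mass_fraction(experimental_mean, unit))
  }
  out <- data.frame(
    fruit = fruit_label, analyte = analyte,
    experimental_mean = experimental_mean, experimental_sd = experimental_sd,
    predicted_mean = predicted_mean, predicted_sd = predicted_sd,
    cv_e = cv_e, cv_p = cv_p, horwitz_limit = limit,
    passes_cv_e = cv_e <= limit, passes_cv_p = cv_p <= limit,
    passes_horwitz = max(cv_e, cv_p) <= limit,
    relative_error = 100 * abs(predicted_mean - experimental_mean) /
      experimental_mean,
    stringsAsFactors = FALSE
  )
  class(out) <- c("validation_summary", "data.frame")
  out
}

#' Relative error between experimental and predicted values
#'
#' Per-item percent error 100 |pred - exp| / exp plus the mean over the
#' valid items. Items with a zero experimental value are flagged and
#' excluded from the mean.
#'
#' @param experimental,predicted Numeric vectors of equal positive length.
#' @return A list with \code{table} (data.frame: experimental, predicted,
#'   relative_error, valid) and \code{mean_relative_error}.
#' @examples
#' compare_experimental_predicted(1416.69, 1413.00)$table$relative_error  # 0.26
#' @export
compare_experimental_predicted <- function(experimental, predicted) {
  check_number(experimental, "experimental", allow_vector = TRUE)
  check_number(predicted, "predicted", allow_vector = TRUE)
  if (length(experimental) != length(predicted) || length(experimental) == 0L) {
    stop_domain("`experimental` and `predicted` must have equal positive length")
  }
  valid <- experimental != 0
  rel <- rep(NA_real_, length(experimental))
  rel[valid] <- 100 * abs(predicted[valid] - experimental[valid]) /
    abs(experimental[valid])
  if (any(!valid)) {
    warning("zero experimental value(s) excluded from mean relative error",
            call. = FALSE)
  }
  list(table = data.frame(experimental = experimental, predicted = predicted,
                          relative_error = rel, valid = valid),
       mean_relative_error = mean(rel[valid]))
}
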