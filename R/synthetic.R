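# Synthetic fruit-pulp data with the statistical structure the
# calibration assumes: linear content-color dependence, a 15-sample x
# 3-replicate design, Gaussian noise, and an optional outlier fraction.

#' Specification for a synthetic fruit-pulp dataset
#'
#' Describes the generative model: sample-level color triplets drawn as
#' independent Gaussians around \code{color_means} (an optional
#' correlation matrix can be injected), replicated \code{n_replicates}
#' times with replicate-level color noise (default 0, i.e. replicates
#' share the sample draw), and contents generated as
#' b0 + b1 L* + b2 a* + b3 b* plus Normal(0, noise_sd^2) noise.
#' A fraction of rows is additionally shifted by
#' +/- outlier_shift * noise_sd to emulate inconsistent samples.
#' Defaults mirror the 15 samples x 3 replicates (n = 45) design of
#' fruit calibration studies.
#'
#' @param fruit_label Fruit name carried through to the dataset.
#' @param true_coefficients Numeric 4-vector (b0, b1, b2, b3), analyte units.
#' @param color_means Numeric 3-vector of mean (L*, a*, b*).
#' @param color_sds Numeric 3-vector of sample-level SDs (>= 0).
#' @param n_samples Number of samples (default 15).
#' @param n_replicates Replicates per sample (default 3).
#' @param noise_sd Additive content noise SD, analyte units (>= 0).
#' @param replicate_sd Replicate-level color noise SD (default 0).
#' @param outlier_fraction Fraction of rows shifted, in [0, 0.5).
#' @param outlier_shift Shift magnitude as a multiple of noise_sd.
#' @param analyte Analyte label for generated contents.
#' @param color_correlation Optional 3 x 3 correlation matrix for the
#'   color draw (default identity: independent coordinates).
#' @param seed Integer RNG seed.
#' @return An object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(fruit_label = "synthetic",
                           true_coefficients,
                           color_means,
                           color_sds = c(0, 0, 0),
                           n_samples = 15, n_replicates = 3,
                           noise_sd = 0, replicate_sd = 0,
                           outlier_fraction = 0, outlier_shift = 5,
                           analyte = "TAC",
                           color_correlation = NULL,
                           seed = 1L) {
  check_number(true_coefficients, "true_coefficients", allow_vector = TRUE)
  if (length(true_coefficients) != 4L) {
    stop_domain("`true_coefficients` must have length 4")
  }
  check_number(color_means, "color_means", allow_vector = TRUE)
  if (length(color_means) != 3L) stop_domain("`color_means` must have length 3")
  check_number(color_sds, "color_sds", lower = 0, allow_vector = TRUE)
  if (length(color_sds) != 3L) stop_domain("`color_sds` must have length 3")
  n_samples <- check_count(n_samples, "n_samples")
  n_replicates <- check_count(n_replicates, "n_replicates")
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(replicate_sd, "replicate_sd", lower = 0)
  check_number(outlier_fraction, "outlier_fraction", lower = 0, upper = 0.5,
               strict_upper = TRUE)
  check_number(outlier_shift, "outlier_shift", lower = 0)
  if (!is.null(color_correlation)) {
    color_correlation <- as.matrix(color_correlation)
    if (!all(dim(color_correlation) == c(3L, 3L)) ||
        max(abs(color_correlation - t(color_correlation))) > 1e-12) {
      stop_domain("`color_correlation` must be a symmetric 3 x 3 matrix")
    }
  }
  seed <- check_count(seed, "seed")
  structure(
    list(fruit_label = as.character(fruit_label),
         true_coefficients = as.numeric(true_coefficients),
         color_means = as.numeric(color_means),
         color_sds = as.numeric(color_sds),
         n_samples = n_samples, n_replicates = n_replicates,
         noise_sd = noise_sd, replicate_sd = replicate_sd,
         outlier_fraction = outlier_fraction, outlier_shift = outlier_shift,
         analyte = match.arg(analyte, c("TAC", "TCC", "TPC")),
         color_correlation = color_correlation, seed = seed),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic fruit-pulp spec:", x$fruit_label, "/", x$analyte, "\n")
  cat("  ", x$n_samples, "samples x", x$n_replicates, "replicates (n =",
      x$n_samples * x$n_replicates, ")\n")
  cat("  truth:", paste(format(x$true_coefficients, digits = 6), collapse = ", "),
      " noise SD:", x$noise_sd,
      " outliers:", x$outlier_fraction, "\n")
  invisible(x)
}

#' Generate pulp color samples
#'
#' Draws sample-level (L*, a*, b*) triplets from the spec's Gaussian
#' color distribution, expands them over replicates (adding
#' replicate-level noise if \code{replicate_sd > 0}), and clips L* to
#' [0, 100]. Deterministic for a fixed seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A data.frame with columns
#'   \code{sample_id, replicate, L, a, b}, one row per
#'   sample x replicate.
#' @export
generate_color_samples <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop_domain("`spec` must be a synthetic_spec")
  with_seed(spec$seed, {
    ns <- spec$n_samples; nr <- spec$n_replicates
    z <- matrix(stats::rnorm(ns * 3L), ncol = 3L)
    if (!is.null(spec$color_correlation)) {
      z <- z %*% chol(spec$color_correlation)
    }
    base <- sweep(sweep(z, 2L, spec$color_sds, `*`), 2L, spec$color_means, `+`)
    idx <- rep(seq_len(ns), each = nr)
    colors <- base[idx, , drop = FALSE]
    if (spec$replicate_sd > 0) {
      colors <- colors + matrix(stats::rnorm(ns * nr * 3L, sd = spec$replicate_sd),
                                ncol = 3L)
    }
    colors[, 1L] <- pmin(pmax(colors[, 1L], 0), 100)
    data.frame(sample_id = idx,
               replicate = rep(seq_len(nr), times = ns),
               L = colors[, 1L], a = colors[, 2L], b = colors[, 3L])
  })
}

#' Generate biocompound contents from colors under the linear model
#'
#' Computes value_i = b0 + b1 L_i + b2 a_i + b3 b_i + eps_i with
#' eps_i ~ Normal(0, noise_sd^2), then shifts floor(outlier_fraction * n)
#' rows (chosen uniformly without replacement) by
#' +/- outlier_shift * noise_sd with alternating sign.
#'
#' @param colors A data.frame with columns \code{L, a, b} (non-empty).
#' @param coefficients Numeric 4-vector (b0, b1, b2, b3).
#' @param noise_sd Noise SD in analyte units (>= 0).
#' @param outlier_fraction Fraction of rows to shift, in [0, 0.5).
#' @param outlier_shift Shift as a multiple of noise_sd.
#' @param seed Integer RNG seed.
#' @return A list with \code{values} (numeric vector) and
#'   \code{outlier_indices} (sorted integer vector).
#' @export
generate_biocompound_values <- function(colors, coefficients, noise_sd = 0,
                                        outlier_fraction = 0, outlier_shift = 5,
                                        seed = 1L) {
  colors <- as.data.frame(colors)
  if (nrow(colors) == 0L) stop_domain("`colors` must be non-empty")
  check_number(coefficients, "coefficients", allow_vector = TRUE)
  if (length(coefficients) != 4L) stop_domain("`coefficients` must have length 4")
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(outlier_fraction, "outlier_fraction", lower = 0, upper = 0.5,
               strict_upper = TRUE)
  n <- nrow(colors)
  noiseless <- coefficients[1L] + coefficients[2L] * colors$L +
    coefficients[3L] * colors$a + coefficients[4L] * colors$b
  with_seed(seed, {
    values <- noiseless + stats::rnorm(n, sd = noise_sd)
    n_out <- floor(outlier_fraction * n)
    out_idx <- integer(0)
    if (n_out > 0L) {
      out_idx <- sort(sample.int(n, n_out))
      signs <- rep_len(c(1, -1), n_out)
      values[out_idx] <- values[out_idx] + signs * outlier_shift * noise_sd
    }
    list(values = values, outlier_indices = out_idx)
  })
}

#' Generate a complete synthetic fruit dataset
#'
#' Composes [generate_color_samples()] and
#' [generate_biocompound_values()] into a [fruit_dataset()] with
#' replicate ids and ground-truth outlier flags. A noiseless spec yields
#' a dataset whose refit recovers the true coefficients exactly
#' (R^2 = 1).
#'
#' @param spec A [synthetic_spec()].
#' @return A [fruit_dataset()] with \code{n_samples * n_replicates} rows.
#' @examples
#' spec <- synthetic_spec(fruit_label = "blackberry",
#'                        true_coefficients = c(1644.47, -13.53, -12.56, 18.42),
#'                        color_means = c(10.68, 13.80, 4.95),
#'                        color_sds = c(2.23, 3.90, 1.70),
#'                        noise_sd = 50, seed = 1)
#' d <- generate_fruit_dataset(spec)
#' nrow(d)  # 45
#' @export
generate_fruit_dataset <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop_domain("`spec` must be a synthetic_spec")
  colors <- generate_color_samples(spec)
  gb <- generate_biocompound_values(colors, spec$true_coefficients,
                                    noise_sd = spec$noise_sd,
                                    outlier_fraction = spec$outlier_fraction,
                                    outlier_shift = spec$outlier_shift,
                                    seed = spec$seed + 1L)
  flags <- rep(FALSE, nrow(colors))
  flags[gb$outlier_indices] <- TRUE
  fruit_dataset(fruit = spec$fruit_label, L = colors$L, a = colors$a,
                b = colors$b, content = gb$values, analyte = spec$analyte,
                sample_id = colors$sample_id, replicate = colors$replicate,
                is_outlier = flags)
}

#' Generate raw absorbance records consistent with a dataset
#'
#' Analytically inverts the assay formula for the dataset's analyte so
#' that applying the forward assay operation to the generated readings
#' reproduces the dataset's contents (round-trip accurate to floating
#' point). Used to test assay arithmetic end to end. Small constant
#' instrument baselines are included so the background-correction terms
#' are exercised.
#'
#' @param dataset A [fruit_dataset()] with non-negative contents.
#' @param dilution_factor Dilution factor for TAC (default 1000).
#' @param sample_weight Sample weight in grams (TAC default 0.25; also
#'   used for TCC and TPC).
#' @param total_volume Extract volume in mL for TCC (default 50).
#' @param curve Gallic acid [calibration_curve()] for TPC.
#' @param extract_volume Extract volume in litres for TPC (default 0.025).
#' @return A data.frame of absorbance readings and assay parameters whose
#'   columns depend on the analyte (pH-differential readings for TAC,
#'   \code{abs_450} for TCC, \code{abs_a}/\code{abs_b} for TPC).
#' @export
generate_absorbance_records <- function(dataset, dilution_factor = 1000,
                                        sample_weight = 0.25,
                                        total_volume = 50,
                                        curve = tpc_reference_curve(),
                                        extract_volume = 0.025) {
  dataset <- as_fruit_dataset(dataset)
  content <- dataset$content
  if (any(content < 0)) stop_domain("contents must be non-negative to invert assays")
  base <- dataset[, c("fruit", "sample_id", "replicate", "analyte")]
  analyte <- dataset$analyte[1L]
  if (analyte == "TAC") {
    mw <- 484.84; eps <- 34300
    a <- content * eps * sample_weight / (mw * dilution_factor * 100)
    cbind(base,
          data.frame(abs_510_ph1 = a + 0.03, abs_700_ph1 = 0.02,
                     abs_510_ph45 = 0.06, abs_700_ph45 = 0.05,
                     dilution_factor = dilution_factor,
                     sample_weight = sample_weight))
  } else if (analyte == "TCC") {
    a <- content * 2592 * sample_weight / (total_volume * 1e4)
    cbind(base,
          data.frame(abs_450 = a, total_volume = total_volume,
                     sample_weight = sample_weight))
  } else {
    conc <- content * sample_weight / (extract_volume * 100)
    resp <- conc * curve$slope + curve$intercept
    cbind(base,
          data.frame(abs_b = resp + 0.1, abs_a = 0.1,
                     extract_volume = extract_volume,
                     dilution_factor = 1, sample_weight = sample_weight))
  }
}

#' Write and read fruit datasets as CSV
#'
#' The on-disk format is a plain comma-separated table with header
#' \code{fruit,sample_id,replicate,L,a,b,analyte,content,is_outlier},
#' UTF-8, "." decimal separator.
#'
#' @param dataset A [fruit_dataset()].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @seealso [read_dataset()]
#' @export
write_fruit_dataset <- function(dataset, path) {
  dataset <- as_fruit_dataset(dataset)
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
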