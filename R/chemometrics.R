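# Least-squares calibration of content = b0 + b1 L* + b2 a* + b3 b*
# via the normal equations, with residual filtering and coefficient tests.

#' Construct a fruit calibration dataset
#'
#' A fruit dataset is a data.frame of replicate-level rows, each carrying
#' a pulp color triplet (L*, a*, b*) and one biocompound content for a
#' single analyte (TAC, TCC or TPC). At least 5 rows are needed for the
#' 4-parameter color model.
#'
#' @param fruit Fruit label (single string).
#' @param L,a,b CIELAB color coordinates per row; L must lie in [0, 100].
#' @param content Biocompound content per row, analyte units.
#' @param analyte One of "TAC", "TCC", "TPC".
#' @param sample_id,replicate Optional integer identifiers; defaults number
#'   the rows 1..n with replicate 1.
#' @param is_outlier Optional logical flag per row (ground truth from the
#'   synthetic generator, or filled by filtering).
#' @return A data.frame of class \code{fruit_dataset} with columns
#'   \code{fruit, sample_id, replicate, L, a, b, analyte, content, is_outlier}.
#' @export
fruit_dataset <- function(fruit, L, a, b, content, analyte = "TAC",
                          sample_id = NULL, replicate = NULL,
                          is_outlier = NULL) {
  n <- length(L)
  if (length(a) != n || length(b) != n || length(content) != n) {
    stop_domain("L, a, b and content must have equal length")
  }
  check_number(L, "L", lower = 0, upper = 100, allow_vector = TRUE)
  check_number(a, "a", allow_vector = TRUE)
  check_number(b, "b", allow_vector = TRUE)
  if (!is.numeric(content)) stop_domain("`content` must be numeric")
  analyte <- match.arg(analyte, c("TAC", "TCC", "TPC"))
  if (is.null(sample_id)) sample_id <- seq_len(n)
  if (is.null(replicate)) replicate <- rep(1L, n)
  if (is.null(is_outlier)) is_outlier <- rep(FALSE, n)
  out <- data.frame(
    fruit = as.character(fruit), sample_id = as.integer(sample_id),
    replicate = as.integer(replicate),
    L = L, a = a, b = b,
    analyte = analyte, content = content, is_outlier = as.logical(is_outlier),
    stringsAsFactors = FALSE
  )
  class(out) <- c("fruit_dataset", "data.frame")
  out
}

#' Average replicates to per-sample means
#'
#' Collapses replicate-level rows to one row per sample (mean color and
#' mean content), for fitting on per-sample averages instead of the full
#' replicate-level table.
#'
#' @param dataset A [fruit_dataset()].
#' @return A \code{fruit_dataset} with one row per \code{sample_id}.
#' @export
aggregate_replicates <- function(dataset) {
  dataset <- as_fruit_dataset(dataset)
  agg <- stats::aggregate(dataset[, c("L", "a", "b", "content")],
                          by = list(sample_id = dataset$sample_id), FUN = mean)
  fruit_dataset(fruit = dataset$fruit[1L], L = agg$L, a = agg$a, b = agg$b,
                content = agg$content, analyte = dataset$analyte[1L],
                sample_id = agg$sample_id)
}

as_fruit_dataset <- function(x) {
  if (inherits(x, "fruit_dataset")) return(x)
  df <- as.data.frame(x)
  need <- c("L", "a", "b", "content")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop_domain("dataset is missing column(s): ", paste(missing, collapse = ", "))
  }
  fruit_dataset(
    fruit = if ("fruit" %in% names(df)) df$fruit[1L] else "unknown",
    L = df$L, a = df$a, b = df$b, content = df$content,
    analyte = if ("analyte" %in% names(df)) df$analyte[1L] else "TAC",
    sample_id = if ("sample_id" %in% names(df)) df$sample_id else NULL,
    replicate = if ("replicate" %in% names(df)) df$replicate else NULL,
    is_outlier = if ("is_outlier" %in% names(df)) df$is_outlier else NULL
  )
}

#' Pearson correlation matrix of content and color coordinates
#'
#' The 4 x 4 correlation matrix over (content, L*, a*, b*) used to judge
#' which color coordinates carry signal for an analyte before fitting.
#'
#' @param dataset A [fruit_dataset()] (or data.frame with columns
#'   \code{L, a, b, content}), at least 3 rows.
#' @return Symmetric 4 x 4 matrix with unit diagonal.
#' @export
correlation_matrix <- function(dataset) {
  dataset <- as_fruit_dataset(dataset)
  if (nrow(dataset) < 3L) stop_domain("need at least 3 rows for correlations")
  m <- cbind(content = dataset$content, L = dataset$L,
             a = dataset$a, b = dataset$b)
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    stop_domain("correlation undefined for constant column(s): ",
                paste(colnames(m)[sds == 0], collapse = ", "))
  }
  stats::cor(m)
}

#' Solve a least-squares problem through the normal equations
#'
#' Forms the cross-product system \eqn{(X^T X) b = X^T y} and solves it
#' directly, which is the classical mean-square formulation of
#' multidimensional regression. The inverse cross-product matrix is
#' returned as well, since its diagonal enters the partial-coefficient
#' t statistics. A rank-deficient design raises an error; no silent
#' pseudo-inverse fallback is attempted.
#'
#' @param design Numeric n x p design matrix (n >= p), including any
#'   intercept column.
#' @param response Numeric response vector of length n.
#' @return A list with \code{coefficients} (length p) and
#'   \code{xtx_inverse} (p x p inverse of the cross-product matrix).
#' @export
solve_normal_equations <- function(design, response) {
  design <- as.matrix(design)
  response <- as.numeric(response)
  n <- nrow(design); p <- ncol(design)
  if (length(response) != n) stop_domain("design and response sizes differ")
  if (n < p) stop_domain("need at least as many rows as parameters")
  if (qr(design)$rank < p) {
    stop_domain("design matrix is rank deficient; normal equations singular")
  }
  xtx <- crossprod(design)
  xty <- drop(crossprod(design, response))
  xtx_inv <- tryCatch(chol2inv(chol(xtx)),
                      error = function(e) stop_domain(
                        "normal equations singular: ", conditionMessage(e)))
  coef <- drop(solve(xtx, xty))
  names(coef) <- colnames(design)
  list(coefficients = coef, xtx_inverse = xtx_inv)
}

#' Fit the linear color-to-content model
#'
#' Fits content = b0 + b1 L* + b2 a* + b3 b* by least squares through
#' [solve_normal_equations()], and derives the quantities used downstream:
#' residuals, residual variance S^2 = SSE/(n - 4), the diagonal P_ii of
#' the inverse cross-product matrix, per-coefficient t statistics
#' t_i = b_i / sqrt(P_ii S^2), and R^2 = 1 - SSE/SST.
#'
#' @param dataset A [fruit_dataset()] (or data.frame with columns
#'   \code{L, a, b, content}) with at least 5 rows.
#' @return An object of class \code{regression_fit}: a list with
#'   \code{coefficients} (named b0..b3), \code{fitted}, \code{residuals},
#'   \code{s2}, \code{pii}, \code{t_statistics}, \code{r_squared},
#'   \code{n_used}, \code{dof}, \code{fruit}, \code{analyte}.
#' @examples
#' spec <- synthetic_spec(true_coefficients = c(10, 1, -2, 0.5),
#'                        color_means = c(50, 5, 20), color_sds = c(5, 2, 3))
#' fit <- fit_linear_model(generate_fruit_dataset(spec))
#' coef(fit)
#' @export
fit_linear_model <- function(dataset) {
  dataset <- as_fruit_dataset(dataset)
  n <- nrow(dataset)
  if (n < 5L) stop_domain("need at least 5 rows to fit 4 coefficients")
  X <- cbind(b0 = 1, b1 = dataset$L, b2 = dataset$a, b3 = dataset$b)
  y <- dataset$content
  sol <- solve_normal_equations(X, y)
  fitted <- drop(X %*% sol$coefficients)
  res <- y - fitted
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  dof <- n - 4L
  s2 <- sse / dof
  r2 <- if (sst > 0) 1 - sse / sst else if (sse <= 1e-24) 1 else NA_real_
  # numerical guard: exact fits can give 1 + eps
  if (!is.na(r2)) r2 <- min(max(r2, 0), 1)
  pii <- diag(sol$xtx_inverse)
  tstat <- compute_t(sol$coefficients, pii, s2)
  structure(
    list(coefficients = sol$coefficients, fitted = fitted, residuals = res,
         s2 = s2, pii = pii, t_statistics = tstat, r_squared = r2,
         n_used = n, dof = dof, xtx_inverse = sol$xtx_inverse,
         fruit = dataset$fruit[1L], analyte = dataset$analyte[1L],
         dataset = dataset),
    class = "regression_fit"
  )
}

compute_t <- function(coef, pii, s2) {
  if (s2 == 0) {
    t <- ifelse(coef == 0, 0, Inf * sign(coef))
  } else {
    t <- coef / sqrt(pii * s2)
  }
  names(t) <- names(coef)
  t
}

#' @export
coef.regression_fit <- function(object, ...) object$coefficients

#' @export
residuals.regression_fit <- function(object, ...) object$residuals

#' @export
print.regression_fit <- function(x, ...) {
  cat("Linear color-content model (", x$analyte, ", ", x$fruit, ")\n", sep = "")
  cat("  content =", format(x$coefficients[1], digits = 6),
      "+", format(x$coefficients[2], digits = 6), "L* +",
      format(x$coefficients[3], digits = 6), "a* +",
      format(x$coefficients[4], digits = 6), "b*\n")
  cat("  n =", x$n_used, " R^2 =", format(x$r_squared, digits = 4),
      " S^2 =", format(x$s2, digits = 4), "\n")
  invisible(x)
}

#' Partial-coefficient significance tests
#'
#' Tests each regression coefficient against zero using
#' \eqn{t_i = b_i / \sqrt{P_{ii} S^2}}, with \eqn{P_{ii}} the i-th
#' diagonal element of the inverse cross-product matrix and S^2 the
#' residual variance, on n - 4 degrees of freedom (two-sided).
#' A zero residual variance (exact fit) flags infinite t rather than
#' failing.
#'
#' @param fit A \code{regression_fit} from [fit_linear_model()].
#' @return A data.frame with columns \code{term, estimate, t, p}.
#' @export
coefficient_t_statistics <- function(fit) {
  if (!inherits(fit, "regression_fit")) stop_domain("`fit` must be a regression_fit")
  if (fit$dof < 1L) stop_domain("need at least 1 residual degree of freedom")
  t <- compute_t(fit$coefficients, fit$pii, fit$s2)
  p <- 2 * stats::pt(-abs(t), df = fit$dof)
  data.frame(term = names(fit$coefficients), estimate = unname(fit$coefficients),
             t = unname(t), p = unname(p), stringsAsFactors = FALSE)
}

#' Flag rows by the two-sigma residual criterion
#'
#' Keeps rows whose absolute residual is strictly below k times the
#' (degrees-of-freedom-corrected) residual standard deviation of the fit;
#' ties at exactly k sigma are kept. The default k = 2 is the classical
#' two-standard-deviation confidence band used to discard inconsistent
#' pulp samples before refitting.
#'
#' @param fit A \code{regression_fit} produced from \code{dataset}.
#' @param dataset The [fruit_dataset()] the fit was computed on.
#' @param k Positive threshold multiplier (default 2).
#' @return An object of class \code{filter_report}: list with
#'   \code{kept_indices}, \code{dropped_indices}, \code{sigma}, \code{k},
#'   \code{passes}.
#' @export
filter_by_residuals <- function(fit, dataset, k = 2) {
  if (!inherits(fit, "regression_fit")) stop_domain("`fit` must be a regression_fit")
  check_number(k, "k", lower = 0, strict_lower = TRUE)
  dataset <- as_fruit_dataset(dataset)
  if (length(fit$residuals) != nrow(dataset)) {
    stop_domain("fit residuals and dataset rows differ; fit must come from dataset")
  }
  sigma <- sqrt(fit$s2)
  res <- fit$residuals
  kept <- if (sigma == 0) seq_along(res) else which(abs(res) < k * sigma)
  dropped <- setdiff(seq_along(res), kept)
  structure(list(kept_indices = kept, dropped_indices = dropped,
                 sigma = sigma, k = k, passes = 1L),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Residual filter (k =", x$k, "): kept", length(x$kept_indices),
      "dropped", length(x$dropped_indices),
      "; sigma =", format(x$sigma, digits = 4), "\n")
  invisible(x)
}

#' Refit the model on the rows retained by a residual filter
#'
#' Re-estimates the color model on the kept rows only, establishing the
#' final prediction equation. The returned fit records the filter report
#' it was built from under \code{$provenance}.
#'
#' @param dataset The original [fruit_dataset()].
#' @param report A \code{filter_report} from [filter_by_residuals()].
#' @return A \code{regression_fit} on the kept rows.
#' @export
refit_filtered <- function(dataset, report) {
  if (!inherits(report, "filter_report")) stop_domain("`report` must be a filter_report")
  dataset <- as_fruit_dataset(dataset)
  kept <- report$kept_indices
  if (length(kept) < 5L) stop_domain("fewer than 5 rows kept; cannot refit")
  sub <- dataset[kept, , drop = FALSE]
  class(sub) <- c("fruit_dataset", "data.frame")
  fit <- fit_linear_model(sub)
  fit$provenance <- list(filter = report, n_initial = nrow(dataset))
  fit
}

#' Predict biocompound content from pulp color
#'
#' Evaluates the linear model b0 + b1 L* + b2 a* + b3 b*. Negative
#' predictions are returned unclamped with a warning (the linear model
#' can extrapolate below zero outside the calibration color range).
#'
#' @param coefficients Numeric 4-vector (b0, b1, b2, b3) or a
#'   \code{regression_fit}.
#' @param L,a,b Color coordinates; vectors of equal length.
#' @return Predicted content(s) in the analyte units of the coefficients.
#' @examples
#' # blackberry anthocyanin model evaluated at the mean blackberry color
#' predict_content(c(1644.47, -13.53, -12.56, 18.42),
#'                 L = 10.68, a = 13.80, b = 4.95)
#' @export
predict_content <- function(coefficients, L, a, b) {
  if (inherits(coefficients, "regression_fit")) {
    coefficients <- coefficients$coefficients
  }
  check_number(coefficients, "coefficients", allow_vector = TRUE)
  if (length(coefficients) != 4L) stop_domain("`coefficients` must have length 4")
  check_number(L, "L", allow_vector = TRUE)
  check_number(a, "a", allow_vector = TRUE)
  check_number(b, "b", allow_vector = TRUE)
  pred <- coefficients[1L] + coefficients[2L] * L +
    coefficients[3L] * a + coefficients[4L] * b
  if (any(pred < 0)) {
    warning("negative predicted content (extrapolation outside calibration range)",
            call. = FALSE)
  }
  unname(pred)
}
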