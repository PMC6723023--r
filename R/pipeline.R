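# Orchestration: read sample tables, run fit -> filter -> refit ->
# significance -> predict -> validate per fruit x analyte, emit reports.

dataset_columns <- c("fruit", "sample_id", "replicate", "L", "a", "b",
                     "analyte", "content")

#' Pipeline configuration
#'
#' Bundles the inputs and tuning parameters of the full calibration
#' pipeline. Datasets may be passed in memory (\code{datasets}, a list of
#' [fruit_dataset()]) or as a CSV path (\code{input}, read through
#' [read_dataset()]).
#'
#' @param datasets Optional list of [fruit_dataset()] objects.
#' @param input Optional CSV path (used when \code{datasets} is NULL).
#' @param analyte_map Optional named list mapping fruit label to the
#'   character vector of detectable analytes; combinations not listed are
#'   reported as "N.D" (non-detectable) and no model is fitted. NULL
#'   means every supplied combination is fitted.
#' @param filter_k Residual filter multiplier k (> 0, default 2).
#' @param filter_passes Number of filter-refit passes (default 1).
#' @param alpha Significance level for coefficient tests, in (0, 1).
#' @param validation_mode \code{"fixed"} or \code{"horwitz"}
#'   (see [validate_against_horwitz()]).
#' @param seed Integer seed recorded in the report (the pipeline itself
#'   is deterministic; the seed feeds any synthetic generation done by
#'   the caller).
#' @param output_dir Optional directory for [write_report()].
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(datasets = NULL, input = NULL, analyte_map = NULL,
                            filter_k = 2, filter_passes = 1, alpha = 0.05,
                            validation_mode = c("fixed", "horwitz"),
                            seed = 1L, output_dir = NULL) {
  check_number(filter_k, "filter_k", lower = 0, strict_lower = TRUE)
  filter_passes <- check_count(filter_passes, "filter_passes")
  check_number(alpha, "alpha", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  validation_mode <- match.arg(validation_mode)
  seed <- check_count(seed, "seed")
  if (is.null(datasets) && is.null(input)) {
    stop_domain("provide `datasets` or `input`")
  }
  structure(list(datasets = datasets, input = input, analyte_map = analyte_map,
                 filter_k = filter_k, filter_passes = filter_passes,
                 alpha = alpha, validation_mode = validation_mode,
                 seed = seed, output_dir = output_dir),
            class = "pipeline_config")
}

#' Read fruit calibration datasets from CSV
#'
#' Expects the header \code{fruit,sample_id,replicate,L,a,b,analyte,content}
#' (an \code{is_outlier} column is optional) and splits the rows into one
#' [fruit_dataset()] per fruit x analyte combination. Malformed rows
#' (non-numeric fields, L* outside [0, 100]) are collected with their
#' line numbers and raised as a validation error.
#'
#' @param path CSV file path.
#' @return A named list of [fruit_dataset()], names \code{fruit.analyte}.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(dataset_columns, names(df))
  if (length(missing) > 0L) {
    stop_domain("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) stop_domain("empty dataset file: ", path)
  problems <- character(0)
  for (col in c("L", "a", "b", "content")) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]))
    if (length(bad) > 0L) {
      problems <- c(problems, paste0("line ", bad + 1L, ": non-numeric ", col))
    }
    df[[col]] <- vals
  }
  bad_l <- which(!is.na(df$L) & (df$L < 0 | df$L > 100))
  if (length(bad_l) > 0L) {
    problems <- c(problems, paste0("line ", bad_l + 1L, ": L outside [0, 100]"))
  }
  if (length(problems) > 0L) {
    stop_domain("invalid rows in ", path, ":\n  ",
                paste(problems, collapse = "\n  "))
  }
  if (!"is_outlier" %in% names(df)) df$is_outlier <- FALSE
  key <- interaction(df$fruit, df$analyte, drop = TRUE)
  lapply(split(df, key), function(sub) {
    fruit_dataset(fruit = sub$fruit[1L], L = sub$L, a = sub$a, b = sub$b,
                  content = sub$content, analyte = sub$analyte[1L],
                  sample_id = sub$sample_id, replicate = sub$replicate,
                  is_outlier = as.logical(sub$is_outlier))
  })
}

analyte_unit <- function(analyte) if (analyte == "TCC") "ug_g" else "mg_100g"

run_combination <- function(dataset, config) {
  fruit <- dataset$fruit[1L]
  analyte <- dataset$analyte[1L]
  log <- character(0)
  fit <- fit_linear_model(dataset)
  log <- c(log, paste0("initial fit: n = ", fit$n_used,
                       ", R^2 = ", formatC(fit$r_squared, digits = 4, format = "f")))
  current <- dataset
  filters <- list()
  for (pass in seq_len(config$filter_passes)) {
    rep <- filter_by_residuals(fit, current, k = config$filter_k)
    rep$passes <- pass
    filters[[pass]] <- rep
    log <- c(log, paste0("filter pass ", pass, ": kept ",
                         length(rep$kept_indices), "/", nrow(current),
                         " rows (sigma = ",
                         formatC(rep$sigma, digits = 4, format = "g"), ")"))
    if (length(rep$dropped_indices) == 0L) break
    fit <- refit_filtered(current, rep)
    sub <- current[rep$kept_indices, , drop = FALSE]
    class(sub) <- c("fruit_dataset", "data.frame")
    current <- sub
  }
  tstats <- coefficient_t_statistics(fit)
  tstats$significant <- tstats$p < config$alpha
  mean_color <- c(L = mean(current$L), a = mean(current$a), b = mean(current$b))
  predicted_rows <- suppressWarnings(
    predict_content(fit$coefficients, current$L, current$a, current$b))
  predicted_at_mean <- suppressWarnings(
    predict_content(fit$coefficients, mean_color["L"], mean_color["a"],
                    mean_color["b"]))
  validation <- validate_against_horwitz(
    experimental_mean = mean(current$content),
    experimental_sd = stats::sd(current$content),
    predicted_mean = mean(predicted_rows),
    predicted_sd = stats::sd(predicted_rows),
    analyte = analyte, fruit_label = fruit,
    unit = analyte_unit(analyte), mode = config$validation_mode
  )
  log <- c(log, paste0("final fit: n = ", fit$n_used, ", R^2 = ",
                       formatC(fit$r_squared, digits = 4, format = "f")))
  list(status = "ok", fruit = fruit, analyte = analyte,
       coefficients = unname(fit$coefficients), r_squared = fit$r_squared,
       n_initial = nrow(dataset), n_used = fit$n_used,
       t_statistics = tstats,
       filter = list(k = config$filter_k,
                     passes = length(filters),
                     kept = length(filters[[length(filters)]]$kept_indices),
                     dropped = nrow(dataset) - fit$n_used,
                     sigma = filters[[length(filters)]]$sigma),
       mean_color = as.list(mean_color),
       predicted_at_mean_color = unname(predicted_at_mean),
       validation = validation, log = log)
}

#' Run the full calibration pipeline
#'
#' For every fruit x analyte dataset: fit the linear color model, apply
#' the residual filter and refit (as many passes as configured), test
#' coefficient significance, predict contents at the retained rows and
#' at their mean color, and build a validation summary. Combinations
#' marked non-detectable in \code{analyte_map} are reported as "N.D"
#' without fitting; an error in one combination is recorded and the
#' remaining combinations still run. The output is deterministic for a
#' fixed configuration.
#'
#' @param config A [pipeline_config()].
#' @return An object of class \code{pipeline_report}: list with
#'   \code{config} (parameters echoed back, including a digest),
#'   \code{results} (one entry per combination) and \code{log}.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop_domain("`config` must be a pipeline_config")
  }
  datasets <- config$datasets
  if (is.null(datasets)) datasets <- read_dataset(config$input)
  if (is.null(names(datasets)) || any(names(datasets) == "")) {
    names(datasets) <- vapply(datasets, function(d) {
      paste(d$fruit[1L], d$analyte[1L], sep = ".")
    }, character(1))
  }
  results <- list()
  log <- character(0)
  for (nm in names(datasets)) {
    d <- datasets[[nm]]
    fruit <- d$fruit[1L]; analyte <- d$analyte[1L]
    if (!is.null(config$analyte_map) &&
        !analyte %in% (config$analyte_map[[fruit]] %||% character(0))) {
      results[[nm]] <- list(status = "N.D", fruit = fruit, analyte = analyte)
      log <- c(log, paste0(nm, ": N.D (analyte non-detectable, no fit)"))
      next
    }
    res <- tryCatch(run_combination(d, config), error = function(e) {
      list(status = "error", fruit = fruit, analyte = analyte,
           message = conditionMessage(e))
    })
    results[[nm]] <- res
    log <- c(log, paste0(nm, ": ", res$status),
             if (res$status == "ok") paste0("  ", res$log))
  }
  conf_out <- config[setdiff(names(config), "datasets")]
  conf_out$digest <- config_digest(conf_out)
  conf_out$package_version <- as.character(utils::packageVersion("chromassay"))
  structure(list(config = conf_out, results = results, log = log),
            class = "pipeline_report")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Deterministic polynomial digest of the serialized configuration.
config_digest <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                        force = TRUE)
  h <- 0
  for (ch in utf8ToInt(as.character(s))) h <- (h * 31 + ch) %% 2147483647
  sprintf("%010d", h)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Calibration pipeline report:", length(x$results), "combination(s)\n")
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    if (r$status == "ok") {
      cat(sprintf("  %-28s R^2 = %.3f  n = %d/%d  pred = %.2f\n", nm,
                  r$r_squared, r$n_used, r$n_initial,
                  r$predicted_at_mean_color))
    } else {
      cat(sprintf("  %-28s %s\n", nm, r$status))
    }
  }
  invisible(x)
}

#' Write pipeline reports to disk
#'
#' Emits a coefficient table (\code{coefficients.csv}: one row per
#' combination with b0..b3 and R^2, "N.D" rows carried as NA), a
#' validation table (\code{validation.csv}: experimental/predicted means,
#' CVs, acceptance limit and pass flags) and/or a full JSON report with
#' configuration provenance.
#'
#' @param report A \code{pipeline_report} from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @param formats Subset of \code{c("csv", "json")}.
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir, formats = c("csv", "json")) {
  if (!inherits(report, "pipeline_report")) {
    stop_domain("`report` must be a pipeline_report")
  }
  formats <- match.arg(formats, several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  if ("csv" %in% formats) {
    coef_rows <- lapply(report$results, function(r) {
      if (r$status == "ok") {
        data.frame(fruit = r$fruit, analyte = r$analyte,
                   b0 = r$coefficients[1], b1 = r$coefficients[2],
                   b2 = r$coefficients[3], b3 = r$coefficients[4],
                   r2 = r$r_squared, stringsAsFactors = FALSE)
      } else {
        data.frame(fruit = r$fruit, analyte = r$analyte,
                   b0 = NA_real_, b1 = NA_real_, b2 = NA_real_,
                   b3 = NA_real_, r2 = NA_real_, stringsAsFactors = FALSE)
      }
    })
    coef_df <- if (length(coef_rows) > 0L) {
      do.call(rbind, coef_rows)
    } else {
      data.frame(fruit = character(0), analyte = character(0),
                 b0 = numeric(0), b1 = numeric(0), b2 = numeric(0),
                 b3 = numeric(0), r2 = numeric(0))
    }
    coef_path <- file.path(dir, "coefficients.csv")
    utils::write.csv(coef_df, coef_path, row.names = FALSE)
    written <- c(written, coef_path)
    val_rows <- Filter(Negate(is.null),
                       lapply(report$results, function(r) {
                         if (r$status == "ok") as.data.frame(r$validation) else NULL
                       }))
    val_df <- if (length(val_rows) > 0L) {
      do.call(rbind, val_rows)
    } else {
      as.data.frame(validate_against_horwitz(1, 0, 1, 0))[0, ]
    }
    val_path <- file.path(dir, "validation.csv")
    utils::write.csv(val_df, val_path, row.names = FALSE)
    written <- c(written, val_path)
  }
  if ("json" %in% formats) {
    json_path <- file.path(dir, "report.json")
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA, null = "null", force = TRUE,
                         dataframe = "rows")
    written <- c(written, json_path)
  }
  invisible(written)
}
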