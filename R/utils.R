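# Internal validation and RNG helpers.

stop_domain <- function(...) {
  stop(..., call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE,
                         allow_vector = FALSE) {
  if (!is.numeric(x) || anyNA(x)) {
    stop_domain("`", name, "` must be numeric and non-missing")
  }
  if (!allow_vector && length(x) != 1L) {
    stop_domain("`", name, "` must be a single number")
  }
  lo_ok <- if (strict_lower) all(x > lower) else all(x >= lower)
  hi_ok <- if (strict_upper) all(x < upper) else all(x <= upper)
  if (!lo_ok || !hi_ok) {
    stop_domain("`", name, "` must lie in ",
                if (strict_lower) "(" else "[", lower, ", ", upper,
                if (strict_upper) ")" else "]")
  }
  invisible(x)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    stop_domain("`", name, "` must be a positive integer")
  }
  as.integer(x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
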