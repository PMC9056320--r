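# Internal helpers: seeded evaluation and classed error conditions.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. `seed = NULL` evaluates as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(eval.parent(substitute(expr)))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Derive `n` reproducible child seeds (31-bit) from one parent seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

# Classed conditions so callers (and the CLI exit-code mapping) can
# distinguish usage/validation errors, data errors, and numerical failures.
stop_usage <- function(...) {
  stop(errorCondition(paste0(...), class = c("metsig_usage_error", "metsig_error")))
}
stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("metsig_data_error", "metsig_error")))
}
stop_numerical <- function(...) {
  stop(errorCondition(paste0(...), class = c("metsig_numerical_error", "metsig_error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_na = FALSE) {
  if (allow_na && length(x) == 1L && is.na(x)) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_usage(name, " must be a single finite number")
  }
  if (strict_lower && x <= lower) stop_usage(name, " must be > ", lower)
  if (!strict_lower && x < lower) stop_usage(name, " must be >= ", lower)
  if (x > upper) stop_usage(name, " must be <= ", upper)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
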