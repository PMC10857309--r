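# Internal helpers: classed conditions and seed handling.

cv_error <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "cogvergence_error", "error")))
}

format_error <- function(fmt, ...) cv_error("cogvergence_format_error", fmt, ...)
data_error   <- function(fmt, ...) cv_error("cogvergence_data_error", fmt, ...)
param_error  <- function(fmt, ...) cv_error("cogvergence_parameter_error", fmt, ...)
window_error <- function(fmt, ...) cv_error("cogvergence_window_error", fmt, ...)
input_error  <- function(fmt, ...) cv_error("cogvergence_input_error", fmt, ...)
report_error <- function(fmt, ...) cv_error("cogvergence_report_error", fmt, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
# seed = NULL means: use (and advance) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    param_error("'%s' must be a single finite number", name)
}
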