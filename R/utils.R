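#' @keywords internal
#' @useDynLib daavf, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

## Input-validation errors carry the class "daavf_input_error" so callers and
## tests can distinguish a contract violation from an unexpected failure.
fail_input <- function(...) {
  msg <- paste0(...)
  stop(structure(
    class = c("daavf_input_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

check_finite_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    fail_input(what, " must be a numeric matrix")
  }
  if (!all(is.finite(x))) fail_input(what, " contains non-finite entries")
  invisible(x)
}

## Seeds derived from a user seed stay below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(offset)) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- logging -------------------------------------------------------------

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

vf_log_level <- function(level = NULL) {
  if (!is.null(level)) {
    level <- match.arg(level, names(.log_levels))
    options(daavf.log_level = level)
  }
  getOption("daavf.log_level", "warn")
}

vf_log <- function(level, fmt, ...) {
  if (.log_levels[[level]] >= .log_levels[[vf_log_level()]]) {
    message(sprintf("[daavf %s] %s", level, sprintf(fmt, ...)))
  }
  invisible(NULL)
}

## md5 of the canonical JSON rendering of a configuration list
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tf))
}
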