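# Internal helpers shared across modules.

# Classed conditions so callers/tests can distinguish configuration problems,
# malformed data, and parse failures.
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "rtcit_error")))
}
abort_config <- function(msg) abort(msg, "rtcit_config_error")
abort_data   <- function(msg) abort(msg, "rtcit_data_error")
abort_parse  <- function(msg) abort(msg, "rtcit_parse_error")

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used when rendering report tables, so that
#' e.g. 0.125 at two decimals displays as 0.13. R's [round()] rounds half to
#' even, which is right for computation but not for presentation.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(0.125, -0.125), 2)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

fmt2 <- function(x) formatC(round_half_up(x, 2), format = "f", digits = 2)

# Resolve a possibly condition-named generator field to a scalar for one
# condition: scalars apply to both conditions, named length-2 vectors are
# looked up by condition name.
cond_param <- function(value, condition, field) {
  if (length(value) == 1L) return(unname(value))
  if (!is.null(names(value)) && condition %in% names(value)) {
    return(unname(value[[condition]]))
  }
  abort_config(sprintf(
    "field '%s' must be a scalar or a vector named by condition (%s)",
    field, paste(cit_conditions(), collapse = ", ")))
}

# Derive independent stage seeds from one master seed, so that pipeline
# stages can be rerun in isolation yet reproducibly.
derive_seeds <- function(seed, n) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  expr
}
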