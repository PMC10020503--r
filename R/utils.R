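# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Fixed-point rounding with ties going up (the convention used by the
#' printed co-prescription tables), as opposed to [round()]'s banker's
#' rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, ties away from zero.
#' @export
#' @examples
#' round_half_up(2.675, 2) # 2.68, where round() gives 2.67
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Format a p-value the way the cohort tables print it: 3 decimals,
# floored at "<0.001".
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
}

# Seed for patient i's substream under master seed s. A fixed affine
# counter scheme keeps earlier patients' draws unchanged when n grows.
substream_seed <- function(master, i) {
  as.integer((as.double(master) + as.double(i) * 1000003) %% 2147483629)
}

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("herbsurv_config_error", "error")))
}

stop_data <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("herbsurv_data_error", "error")))
}

# Days between two Date vectors as integer.
days_between <- function(from, to) as.integer(as.numeric(to) - as.numeric(from))

assert_prob_vector <- function(x, name, len = NULL) {
  if (!is.null(len) && length(x) != len)
    stop_config("`%s` must have length %d", name, len)
  if (any(!is.finite(x)) || any(x < 0))
    stop_config("`%s` must be non-negative and finite", name)
  if (abs(sum(x) - 1) > 1e-12)
    stop_config("`%s` must sum to 1 (got %.15f)", name, sum(x))
  invisible(x)
}
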