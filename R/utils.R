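#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed percentage tables in the
#' oculomotor literature are conventionally rounded half away from zero, so
#' 91.85 -> 91.9 and -0.25 -> -0.3 at one decimal.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# stop() with a call-free, field-naming message (config validation convention)
config_error <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

check_scalar_pos <- function(value, field) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) || value <= 0)
    config_error(field, "must be a single positive number")
  invisible(value)
}

# half-open window [t0, t1) on a 1-ms grid: bin start times t0 .. t1-1
window_bins <- function(window) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  seq(window[1], window[2] - 1L)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
}
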