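# Lambda schedules: sequences of coupling-parameter values along which the
# A -> B transformation is discretized.

#' Construct a lambda schedule
#'
#' @param values strictly increasing numeric vector in \[0, 1\], starting at
#'   0 and ending at 1.
#' @return Object of class `lambda_schedule` (numeric vector underneath).
#' @export
lambda_schedule <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2 || values[1] != 0 || values[length(values)] != 1 ||
      is.unsorted(values, strictly = TRUE) ||
      any(values < 0 | values > 1)) {
    abort_enmix(
      "lambda schedule must be strictly increasing from 0 to 1 within [0, 1]",
      "enmix_parameter_error"
    )
  }
  structure(values, class = "lambda_schedule")
}

#' @export
print.lambda_schedule <- function(x, ...) {
  cat(sprintf("<lambda_schedule> %d points: %s\n", length(x),
              paste(format(unclass(x)), collapse = " ")))
  invisible(x)
}

#' The 29-point production lambda schedule
#'
#' The default schedule used for production runs: 0.05 spacing through the
#' middle of the path with densified end regions (where the integrand
#' varies fastest as restraints switch on and off). The end-point spacings
#' approximate thirds and halves of 0.05 at the printed precision, so the
#' list is only symmetric about 0.5 to about 1e-3, not exactly.
#'
#' @return A [lambda_schedule()] of length 29.
#' @export
lambda_schedule_dense29 <- function() {
  lambda_schedule(c(
    0, 0.0167, 0.033, 0.05, 0.075, 0.1, 0.125, 0.15,
    0.2, 0.25, 0.3, 0.35, 0.4, 0.45, 0.5, 0.55, 0.6, 0.65, 0.7, 0.75, 0.8,
    0.85, 0.875, 0.9, 0.925, 0.95, 0.967, 0.983, 1
  ))
}

#' Evenly spaced lambda schedule
#'
#' @param n number of points (>= 2), endpoints included; `n = 21` gives the
#'   0.05-spaced schedule used for quick forward/reverse comparisons.
#' @return A [lambda_schedule()].
#' @export
lambda_schedule_uniform <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n)) {
    abort_enmix("n must be an integer >= 2", "enmix_parameter_error")
  }
  lambda_schedule(seq(0, 1, length.out = n))
}

resolve_schedule <- function(preset) {
  if (inherits(preset, "lambda_schedule")) return(preset)
  if (is.numeric(preset)) return(lambda_schedule(preset))
  if (identical(preset, "dense29")) return(lambda_schedule_dense29())
  m <- regmatches(preset, regexec("^uniform:?([0-9]+)$", preset))[[1]]
  if (length(m) == 2) return(lambda_schedule_uniform(as.integer(m[2])))
  abort_enmix(paste0("unknown schedule preset '", preset, "'"),
              "enmix_parameter_error")
}
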