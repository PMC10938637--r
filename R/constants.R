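# Physical constants and shared defaults (GROMACS unit system: nm, kJ/mol, K).

#' Boltzmann constant in kJ/mol/K
#'
#' The value used throughout the package to convert between energies in
#' kJ/mol and thermal energy at a given temperature.
#' @export
K_BOLTZMANN <- 0.00831446

#' Default simulation temperature in kelvin
#'
#' Physiological reference temperature; `k_B * 310 K` is approximately
#' 2.5775 kJ/mol.
#' @export
DEFAULT_TEMPERATURE <- 310

kBT <- function(temperature) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L, temperature > 0)
  K_BOLTZMANN * temperature
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_enmix <- function(msg, class) {
  stop(structure(
    class = c(class, "enmix_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
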