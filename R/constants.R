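#' Physical constants for electrophysiological unit conversions
#'
#' Bundles the Faraday constant, the molar gas constant and the absolute
#' temperature used throughout the package to convert between voltages,
#' valences and energies.  Recording temperature defaults to 298.15 K
#' (25 C), giving a thermal voltage RT/F of about 25.69 mV and RT of about
#' 2.479 kJ/mol.
#'
#' Package-wide unit conventions: toxin concentration in uM inside rate
#' equations, dissociation constants reported in nM, external K+ in mM,
#' membrane voltage in mV (depolarization positive), energies in kJ/mol.
#'
#' @param temperature Absolute temperature in kelvin.  Must be positive.
#'
#' @return An object of class `phys_constants`: a list with fields
#'   `faraday` (C mol^-1), `gas_constant` (J mol^-1 K^-1) and
#'   `temperature` (K).
#'
#' @examples
#' co <- phys_constants()
#' thermal_voltage(co)  # ~25.69 mV
#' rt_kj(co)            # ~2.479 kJ/mol
#' @export
phys_constants <- function(temperature = 298.15) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("'temperature' must be a single positive number (kelvin)")
  }
  structure(
    list(
      faraday = 96485.33212,
      gas_constant = 8.314462618,
      temperature = temperature
    ),
    class = "phys_constants"
  )
}

#' @describeIn phys_constants Thermal voltage RT/F in millivolts.
#' @param constants A `phys_constants` object.
#' @export
thermal_voltage <- function(constants = phys_constants()) {
  1000 * constants$gas_constant * constants$temperature / constants$faraday
}

#' @describeIn phys_constants Thermal energy RT in kJ/mol.
#' @export
rt_kj <- function(constants = phys_constants()) {
  constants$gas_constant * constants$temperature / 1000
}

#' @export
print.phys_constants <- function(x, ...) {
  cat(sprintf(
    "Physical constants: T = %.2f K, RT/F = %.4f mV, RT = %.4f kJ/mol\n",
    x$temperature, thermal_voltage(x), rt_kj(x)
  ))
  invisible(x)
}

# internal: single finite number check
.check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name))
  }
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name))
  if (nonneg && x < 0) stop(sprintf("'%s' must be >= 0", name))
  invisible(x)
}
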