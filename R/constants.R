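#' Physical constants and unit helpers
#'
#' `gas_constant_kcal()` returns the ideal gas constant in
#' kcal mol^-1 K^-1; `kj_to_kcal()` and `kcal_to_kj()` convert energies
#' between kJ/mol and kcal/mol (thermochemical calorie, 4.184 J).
#'
#' @return A numeric scalar (or vector for the converters).
#' @examples
#' gas_constant_kcal() * 298.15   # RT at 25 degrees C, kcal/mol
#' kj_to_kcal(4.184)              # 1
#' @export
gas_constant_kcal <- function() 1.98720425e-3

#' @rdname gas_constant_kcal
#' @param x energies in kJ/mol
#' @export
kj_to_kcal <- function(x) x / 4.184

#' @rdname gas_constant_kcal
#' @param x_kcal energies in kcal/mol
#' @export
kcal_to_kj <- function(x_kcal) x_kcal * 4.184

# default temperature (K) used throughout when none is supplied
default_temperature <- function() 298.15

# 15N chemical-shift weight used when combining 1H/15N displacements
default_nitrogen_scale <- function() 0.14
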