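#' Unit conversion and physical constants
#'
#' Film-balance quantities live in mixed practical units: surface pressure
#' \eqn{\pi} in mN/m and mean molecular area \eqn{A} in A^2 (square
#' Angstrom) per molecule. Their product is an energy per molecule:
#' 1 mN/m x 1 A^2 = 1e-3 N/m x 1e-20 m^2 = 1e-23 J. Multiplying by
#' Avogadro's number gives 6.02214076 J/mol per (mN/m A^2/molecule), the
#' constant used to convert isotherm integrals to molar excess Gibbs
#' energies.
#'
#' `kT_film_units()` returns k_B * T expressed in those same film units
#' (mN/m A^2), the natural scale of the two-dimensional ideal-gas term of a
#' Volmer-type equation of state. At 37 degrees C (310.15 K) it is
#' 428.2 mN/m A^2.
#'
#' @param temperature_C temperature in degrees Celsius.
#' @return `kT_film_units()`: a single numeric value in mN/m A^2.
#' @examples
#' kT_film_units(37)    # 428.2, the default thermal term at body temperature
#' MNM_A2_PER_MOL_TO_J  # 6.02214076
#' @export
kT_film_units <- function(temperature_C) {
  kB <- 1.380649e-23 # J/K
  # 1 mN/m A^2 = 1e-23 J, so kT [film units] = kB*T / 1e-23
  kB * (temperature_C + 273.15) / 1e-23
}

#' @rdname kT_film_units
#' @format `MNM_A2_PER_MOL_TO_J`: numeric scalar, J/mol per (mN/m A^2/molecule).
#' @export
MNM_A2_PER_MOL_TO_J <- 6.02214076
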