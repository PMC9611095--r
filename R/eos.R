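#' Pure-component 2D equation-of-state parameters
#'
#' The synthetic generator represents each pure film by a Volmer-type
#' equation of state with a cohesion pressure,
#' \deqn{A(\pi) = A_0 + \frac{kT}{\pi + \pi_c},}
#' optionally minus a sigmoidal area loss
#' \eqn{\Delta A \cdot \mathrm{logistic}((\pi - \pi_t)/w)} standing in for a
#' first-order liquid-expanded/liquid-condensed (LE-LC) transition plateau.
#' The lift-off area (area where pressure first rises from zero) is
#' \eqn{A_0 + kT/\pi_c}.
#'
#' @param A0 excluded (limiting) molecular area, A^2 > 0.
#' @param pi_c cohesion pressure, mN/m > 0; larger values soften lift-off.
#' @param kT_term thermal term kT in film units (mN/m A^2); default
#'   [kT_film_units()] at 37 C = 428.2.
#' @param plateau `NULL`, or `list(pi_t=, delta_A=, width=)`: plateau centre
#'   pressure (mN/m), area lost across the transition (A^2) and pressure
#'   width (mN/m).
#' @param collapse_pi collapse pressure in mN/m, or `NULL` if the film does
#'   not collapse inside the working range. Pure-film generation refuses to
#'   exceed it.
#' @param non_spreading logical; `TRUE` models an amphiphile that fails to
#'   form a monolayer (pressure stays at the noise floor at all areas, as a
#'   water-soluble drug does). Overrides all curve parameters.
#' @param id character label for the component.
#' @return A `pure_eos_params` object (a validated list).
#' @seealso [eos_area()], [generate_pure_isotherm()], and the presets
#'   [eos_dmpc()], [eos_non_spreading()], [eos_low_collapse()].
#' @export
pure_eos_params <- function(A0, pi_c, kT_term = kT_film_units(37),
                            plateau = NULL, collapse_pi = NULL,
                            non_spreading = FALSE, id = "component") {
  p <- structure(list(A0 = A0, pi_c = pi_c, kT_term = kT_term,
                      plateau = plateau, collapse_pi = collapse_pi,
                      non_spreading = isTRUE(non_spreading),
                      id = as.character(id)),
                 class = "pure_eos_params")
  if (!p$non_spreading) {
    stopifnot(A0 > 0, pi_c > 0, kT_term > 0)
    if (!is.null(plateau)) {
      stopifnot(all(c("pi_t", "delta_A", "width") %in% names(plateau)),
                plateau$pi_t > 0, plateau$delta_A > 0, plateau$width > 0)
      if (!is.null(collapse_pi) && plateau$pi_t >= collapse_pi)
        stop("plateau pi_t must lie below collapse_pi", call. = FALSE)
    }
  }
  p
}

#' Preset pure-component parameter sets
#'
#' Three parameter sets reproducing the landmark features of the study
#' system at 37 C:
#' * `eos_dmpc()`: a fluid phosphatidylcholine-like film, lift-off at
#'   `40 + 428.2/5.7 = 115.1` A^2 with a gaseous shoulder extending to
#'   ~130 A^2 and a liquid-expanded run below it; no collapse inside the
#'   0-35 mN/m working window.
#' * `eos_non_spreading()`: a water-soluble drug-like compound that fails to
#'   form a monolayer -- pressure stays at the noise floor down to small
#'   areas.
#' * `eos_low_collapse(pi_max)`: a bulky triacyl amphiphile whose film
#'   reaches a maximum pressure of about `pi_max` (6 or 8 mN/m in the
#'   motivating systems) and stays there on further compression.
#'
#' @param id component label.
#' @param pi_max maximum (collapse) pressure for the low-collapse preset,
#'   mN/m.
#' @return A [pure_eos_params] object.
#' @export
eos_dmpc <- function(id = "DMPC") {
  pure_eos_params(A0 = 40, pi_c = 5.7, kT_term = 428.2, id = id)
}

#' @rdname eos_dmpc
#' @export
eos_non_spreading <- function(id = "drug") {
  pure_eos_params(A0 = 1, pi_c = 1, non_spreading = TRUE, id = id)
}

#' @rdname eos_dmpc
#' @export
eos_low_collapse <- function(pi_max = 6, id = "triacyl-amphiphile") {
  # LE film from ~130 A^2 that tops out at pi_max: steep EOS + collapse cap
  pure_eos_params(A0 = 95, pi_c = 4, kT_term = 140, collapse_pi = pi_max,
                  id = id)
}

#' Noiseless area of a pure film at given surface pressures
#'
#' Evaluates the Volmer-type equation of state of [pure_eos_params()]
#' (including any plateau term). A non-spreading component has no
#' film of its own; its area contribution is defined as 0 at every
#' pressure, matching the analysis convention for a component that never
#' attains the target pressure.
#'
#' @param params a [pure_eos_params] object.
#' @param pressure numeric vector of surface pressures, mN/m (>= 0).
#' @return numeric vector of areas, A^2/molecule.
#' @export
eos_area <- function(params, pressure) {
  stopifnot(inherits(params, "pure_eos_params"), all(pressure >= 0))
  if (params$non_spreading) return(rep(0, length(pressure)))
  a <- params$A0 + params$kT_term / (pressure + params$pi_c)
  if (!is.null(params$plateau)) {
    pl <- params$plateau
    a <- a - pl$delta_A * stats::plogis((pressure - pl$pi_t) / pl$width)
  }
  a
}

#' Regular-solution excess-area parameters
#'
#' The generator's non-ideality model is a symmetric first-order
#' regular-solution term with exponential pressure decay:
#' \deqn{A_{ex}(\pi, X_2) = 4\, X_2 (1 - X_2)\, a_{ex}\, e^{-\pi/\pi_s}.}
#' The factor 4 normalises the composition envelope so that `a_ex` is the
#' excess area at the equimolar point and zero pressure. Positive `a_ex`
#' models repulsive component interactions (film expansion), negative
#' attractive ones. `pi_s` sets how fast the deviation fades as the film is
#' compressed (observed behaviour in mixed lipid/drug films: deviations
#' shrink at high pressure); `pi_s = Inf` gives a pressure-independent
#' excess.
#'
#' @param a_ex excess-area amplitude at X2 = 0.5, pi = 0, in A^2. `a_ex = 0`
#'   reproduces ideal mixing exactly.
#' @param pi_s pressure decay scale in mN/m (> 0, possibly `Inf`).
#' @return An `excess_params` object.
#' @export
excess_params <- function(a_ex = 0, pi_s = Inf) {
  stopifnot(is.numeric(a_ex), length(a_ex) == 1L,
            is.numeric(pi_s), length(pi_s) == 1L, pi_s > 0)
  structure(list(a_ex = a_ex, pi_s = pi_s), class = "excess_params")
}

#' Ground-truth excess quantities of the synthetic model
#'
#' `excess_area_model()` evaluates the excess-area law of [excess_params()]
#' at given pressure and composition. `dgex_closed_form()` integrates it
#' analytically:
#' \deqn{\Delta G_{ex}(\pi^*, X_2) = N_A \cdot 10^{-23} \cdot
#'   4 X_2 (1-X_2)\, a_{ex}\, \pi_s (1 - e^{-\pi^*/\pi_s})\ \mathrm{J/mol},}
#' with the constant-excess limit \eqn{6.02214\, a_{ex} 4X_2(1-X_2) \pi^*}
#' as `pi_s -> Inf`. These closed forms are the oracle every numerical
#' stage of the analysis is validated against.
#'
#' @param ex an [excess_params] object.
#' @param pressure surface pressure(s), mN/m.
#' @param x2 mole fraction(s) of component 2.
#' @param pi_star upper integration pressure(s), mN/m.
#' @return numeric vector: A^2 for `excess_area_model()`, J/mol for
#'   `dgex_closed_form()`.
#' @export
excess_area_model <- function(ex, pressure, x2) {
  stopifnot(inherits(ex, "excess_params"))
  4 * x2 * (1 - x2) * ex$a_ex * exp(-pressure / ex$pi_s)
}

#' @rdname excess_area_model
#' @export
dgex_closed_form <- function(ex, x2, pi_star) {
  stopifnot(inherits(ex, "excess_params"))
  envelope <- 4 * x2 * (1 - x2) * ex$a_ex
  integral <- if (is.finite(ex$pi_s)) {
    ex$pi_s * (1 - exp(-pi_star / ex$pi_s))
  } else {
    pi_star
  }
  MNM_A2_PER_MOL_TO_J * envelope * integral
}
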