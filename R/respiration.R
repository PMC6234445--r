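# Respiratory flow parameters: from breathing pattern to phase flow rates,
# per-branch flow rates, inlet velocities and the dimensionless numbers that
# justify the steady laminar modelling assumptions.

#' Breathing pattern
#'
#' @param tidal_volume Tidal volume in mL per breath.
#' @param respiratory_rate Breaths per minute.
#' @param ie_ratio Inspiration-to-expiration time ratio as a length-2 numeric
#'   `c(t_i, t_e)` of positive relative durations; stored normalized so that
#'   `t_i = 1`.
#' @return An object of class `breathing_pattern`.
#' @examples
#' breathing_pattern(39, 36, c(1, 1.5)) # infant normal breathing
#' @export
breathing_pattern <- function(tidal_volume, respiratory_rate, ie_ratio = c(1, 2)) {
  stopifnot(is.numeric(tidal_volume), length(tidal_volume) == 1L, tidal_volume >= 0,
            is.numeric(respiratory_rate), length(respiratory_rate) == 1L,
            respiratory_rate > 0,
            is.numeric(ie_ratio), length(ie_ratio) == 2L, all(ie_ratio > 0))
  structure(list(tidal_volume = tidal_volume,
                 respiratory_rate = respiratory_rate,
                 ie_ratio = ie_ratio / ie_ratio[1]),
            class = "breathing_pattern")
}

#' Air properties
#'
#' Defaults are standard-atmosphere sea-level air.
#'
#' @param density kg/m^3.
#' @param dynamic_viscosity kg/(m s).
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1.225, dynamic_viscosity = 1.7894e-5) {
  stopifnot(density > 0, dynamic_viscosity > 0)
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity),
            class = "fluid_properties")
}

#' Minute ventilation
#'
#' @param pattern A [breathing_pattern()].
#' @return Minute ventilation in mL/min (tidal volume times respiratory rate).
#' @examples
#' minute_ventilation(breathing_pattern(500, 14, c(1, 1.7))) # 7000 mL/min
#' @export
minute_ventilation <- function(pattern) {
  stopifnot(inherits(pattern, "breathing_pattern"))
  pattern$tidal_volume * pattern$respiratory_rate
}

#' Phase flow rates
#'
#' Converts minute ventilation to constant (square-wave) phase flow rates.
#' Inspiration lasts a fraction `t_i/(t_i + t_e)` of the breath, so moving the
#' minute ventilation during that fraction alone requires
#' `Q_insp = MV (t_i + t_e)/t_i`; analogously for expiration.
#'
#' @inheritParams minute_ventilation
#' @return Named numeric `c(inspiration =, expiration =)` in L/min.
#' @examples
#' phase_flow_rates(breathing_pattern(39, 36, c(1, 1.5))) # 3.51, 2.34 L/min
#' @export
phase_flow_rates <- function(pattern) {
  mv <- minute_ventilation(pattern) / 1000 # L/min
  ti <- pattern$ie_ratio[1]; te <- pattern$ie_ratio[2]
  c(inspiration = mv * (ti + te) / ti, expiration = mv * (ti + te) / te)
}

#' Per-branch flow rate at a given airway generation
#'
#' Under the symmetric dichotomous (Weibel) split, generation `g` has `2^g`
#' parallel branches each carrying `Q_total / 2^g`.
#'
#' @param Q_total Whole-lung flow rate in L/min.
#' @param generation Generation index (trachea = 0), non-negative integer.
#' @return Flow rate per branch in m^3/s.
#' @examples
#' branch_flow_rate(18.90, 6) # adult inspiratory G6 branch flow
#' @export
branch_flow_rate <- function(Q_total, generation) {
  stopifnot(is.numeric(Q_total), Q_total >= 0, length(generation) == 1L)
  if (generation < 0 || generation != round(generation))
    stop("generation must be a non-negative integer")
  (Q_total / 2^generation) * 1e-3 / 60 # L/min -> m^3/s
}

#' Mean (plug) inlet velocity for a branch
#'
#' @param Q_branch Branch volumetric flow rate in m^3/s.
#' @param diameter Branch inner diameter in m.
#' @return Mean axial velocity in m/s, `Q / (pi D^2 / 4)`.
#' @export
mean_inlet_velocity <- function(Q_branch, diameter) {
  stopifnot(Q_branch >= 0, diameter > 0)
  Q_branch / (pi * diameter^2 / 4)
}

#' Reynolds number
#'
#' @param U Characteristic (mean) velocity, m/s.
#' @param D Characteristic length (airway diameter), m.
#' @param fluid A [fluid_properties()].
#' @return `rho U D / mu`, dimensionless.
#' @export
reynolds_number <- function(U, D, fluid = fluid_properties()) {
  stopifnot(U >= 0, D > 0, inherits(fluid, "fluid_properties"))
  fluid$density * U * D / fluid$dynamic_viscosity
}

#' Womersley number
#'
#' Ratio of oscillatory inertia to viscous forces,
#' `alpha = (D/2) sqrt(omega rho / mu)` with `omega = 2 pi f` and `f` the
#' breathing frequency in Hz.  The radius `D/2` is used as the
#' characteristic length; with the embedded airway dimensions and breathing
#' rates this definition reproduces the reference inlet values 0.25 (infant),
#' 0.34 (child) and 0.44 (adult) at G6.  Small values (alpha < 1) justify
#' treating each breathing phase as quasi-steady.
#'
#' @param D Airway diameter in m.
#' @param respiratory_rate Breaths per minute.
#' @param fluid A [fluid_properties()].
#' @return Womersley number, dimensionless.
#' @examples
#' womersley_number(1.0e-3, 36) # infant G6, about 0.25
#' @export
womersley_number <- function(D, respiratory_rate, fluid = fluid_properties()) {
  stopifnot(D > 0, respiratory_rate > 0, inherits(fluid, "fluid_properties"))
  omega <- 2 * pi * respiratory_rate / 60
  (D / 2) * sqrt(omega * fluid$density / fluid$dynamic_viscosity)
}
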