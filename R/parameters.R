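# Kinetic parameter containers and the free-energy mapping.
#
# The model has three independent parameters.  Internally all kinetics are
# computed from the rate triple (k_S, k_on, k_off); the thermodynamic triple
# (delta_G, k_S, k_off) is an equivalent view through
# delta_G = -kB * T * log(k_on / k_off).

.kB <- 1.380649e-23          # Boltzmann constant, J/K
.DG_SCALE <- 1e-21           # delta_G is reported in units of 1e-21 J
.TIME_UNITS <- c(minute = 60, hour = 3600, day = 86400)  # seconds per unit

match_time_unit <- function(time_unit) {
  match.arg(time_unit, names(.TIME_UNITS))
}

#' Thermal energy kB*T
#'
#' @param temperature Absolute temperature in kelvin (default 300).
#' @return kB*T expressed in units of 1e-21 J (so 4.1419 at 300 K).
#' @examples
#' thermal_energy()        # ~4.14
#' @export
thermal_energy <- function(temperature = 300) {
  stopifnot(is.numeric(temperature), temperature > 0)
  .kB * temperature / .DG_SCALE
}

#' Kinetic rate triple of the two-state release model
#'
#' Constructs the rate-constant parameterization (`k_S`, `k_on`, `k_off`) of
#' the reversible-binding release model.  `k_S` is the lumped first-order
#' transport rate constant (diffusion/convection/osmosis under perfect sink),
#' `k_on` and `k_off` the association and disassociation rate constants of the
#' drug-carrier interaction.  All three share the declared time unit.
#'
#' @param k_S Transport rate constant, 1/time. Must be positive.
#' @param k_on Association rate constant, 1/time. Nonnegative.
#' @param k_off Disassociation rate constant, 1/time. Nonnegative.
#' @param time_unit One of `"minute"`, `"hour"`, `"day"`.
#' @return An object of class `rate_parameters`.
#' @details A parameter set with `k_on > 0` and `k_off == 0` is rejected as
#'   degenerate: bound drug that can never disassociate would never be
#'   released, and the cumulative-release limit would fall short of 1.
#' @seealso [thermo_parameters()], [delta_g_from_rates()]
#' @export
rate_parameters <- function(k_S, k_on = 0, k_off = 0, time_unit = "hour") {
  time_unit <- match_time_unit(time_unit)
  stopifnot(is.numeric(k_S), length(k_S) == 1L, is.finite(k_S),
            is.numeric(k_on), length(k_on) == 1L, is.finite(k_on),
            is.numeric(k_off), length(k_off) == 1L, is.finite(k_off))
  if (k_S <= 0) stop("k_S must be positive", call. = FALSE)
  if (k_on < 0 || k_off < 0) stop("rate constants must be nonnegative", call. = FALSE)
  if (k_on > 0 && k_off == 0) {
    stop("degenerate parameters: k_on > 0 with k_off = 0 traps bound drug forever",
         call. = FALSE)
  }
  structure(list(k_S = k_S, k_on = k_on, k_off = k_off, time_unit = time_unit),
            class = "rate_parameters")
}

#' Thermodynamic parameter triple (delta_G, k_S, k_off)
#'
#' The preferred three-parameter description of the model: the free-energy
#' difference between the free and bound drug states replaces `k_on` via
#' `delta_G = -kB*T*log(k_on/k_off)`.  Negative `delta_G` favors binding and
#' suppresses the initial burst.
#'
#' @param delta_G Free-energy difference between free and bound states,
#'   in units of 1e-21 J.
#' @param k_S Transport rate constant, 1/time.
#' @param k_off Disassociation rate constant, 1/time. `k_off = 0` collapses
#'   the model to the pure single-exponential transport limit.
#' @param temperature Absolute temperature in kelvin, default 300.
#' @param time_unit One of `"minute"`, `"hour"`, `"day"`.
#' @return An object of class `thermo_parameters`.
#' @export
thermo_parameters <- function(delta_G, k_S, k_off, temperature = 300,
                              time_unit = "hour") {
  time_unit <- match_time_unit(time_unit)
  stopifnot(is.numeric(delta_G), length(delta_G) == 1L, is.finite(delta_G),
            is.numeric(k_S), length(k_S) == 1L, is.finite(k_S),
            is.numeric(k_off), length(k_off) == 1L, is.finite(k_off),
            is.numeric(temperature), length(temperature) == 1L)
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  if (k_S <= 0) stop("k_S must be positive", call. = FALSE)
  if (k_off < 0) stop("k_off must be nonnegative", call. = FALSE)
  structure(list(delta_G = delta_G, k_S = k_S, k_off = k_off,
                 temperature = temperature, time_unit = time_unit),
            class = "thermo_parameters")
}

#' Free energy difference from association/disassociation rates
#'
#' `delta_g_from_rates()` evaluates `-kB*T*log(k_on/k_off)`;
#' `rates_from_delta_g()` inverts it, returning `k_on = k_off *
#' exp(-delta_G/(kB*T))`.
#'
#' @param k_on,k_off Strictly positive rate constants (same time unit).
#' @param delta_G Free-energy difference, 1e-21 J.
#' @param temperature Kelvin, default 300.
#' @return `delta_g_from_rates`: delta_G in 1e-21 J; `rates_from_delta_g`:
#'   the implied `k_on`.
#' @examples
#' delta_g_from_rates(0.0172, 0.0136)   # ~ -0.97e-21 J
#' @export
delta_g_from_rates <- function(k_on, k_off, temperature = 300) {
  stopifnot(is.numeric(k_on), is.numeric(k_off))
  if (any(k_on == 0)) {
    stop("k_on = 0 is the pure transport limit (Case 1); delta_G is -Inf there",
         call. = FALSE)
  }
  if (any(k_off == 0)) {
    stop("k_off must be positive: zero disassociation leaves delta_G undefined",
         call. = FALSE)
  }
  if (any(k_on < 0) || any(k_off < 0)) {
    stop("rate constants must be positive", call. = FALSE)
  }
  -thermal_energy(temperature) * log(k_on / k_off)
}

#' @rdname delta_g_from_rates
#' @export
rates_from_delta_g <- function(delta_G, k_off, temperature = 300) {
  stopifnot(is.numeric(delta_G), is.numeric(k_off), all(k_off >= 0))
  k_off * exp(-delta_G / thermal_energy(temperature))
}

#' Equilibrium free/bound split at t = 0
#'
#' Before release starts the association reaction is at equilibrium, so the
#' initially free fraction is `k_off/(k_on + k_off)` and the bound fraction
#' `k_on/(k_on + k_off)`.  The free fraction is the magnitude of the initial
#' burst.
#'
#' @param k_on,k_off Nonnegative rate constants.  `k_on = k_off = 0` is taken
#'   as "all drug free" (pure transport) with a message.
#' @return Named numeric vector `c(free = ..., bound = ...)`, summing to 1.
#' @examples
#' equilibrium_fractions(0.03, 0.0199)  # free ~0.399
#' @export
equilibrium_fractions <- function(k_on, k_off) {
  stopifnot(is.numeric(k_on), length(k_on) == 1L, k_on >= 0,
            is.numeric(k_off), length(k_off) == 1L, k_off >= 0)
  if (k_on + k_off == 0) {
    message("k_on = k_off = 0: treating all drug as initially free")
    return(c(free = 1, bound = 0))
  }
  c(free = k_off / (k_on + k_off), bound = k_on / (k_on + k_off))
}

#' Convert between the rate and thermodynamic parameterizations
#'
#' @param x A `rate_parameters` or `thermo_parameters` object (or, for
#'   `as_thermo_parameters`, a full-variant [fit_release_model()] result).
#' @param temperature Kelvin, used when converting rates to delta_G.
#' @return `as_rate_parameters`: a `rate_parameters` object;
#'   `as_thermo_parameters`: a `thermo_parameters` object.
#' @export
as_rate_parameters <- function(x, ...) UseMethod("as_rate_parameters")

#' @export
as_rate_parameters.rate_parameters <- function(x, ...) x

#' @export
as_rate_parameters.thermo_parameters <- function(x, ...) {
  k_on <- rates_from_delta_g(x$delta_G, x$k_off, x$temperature)
  rate_parameters(x$k_S, k_on = k_on, k_off = x$k_off, time_unit = x$time_unit)
}

#' @rdname as_rate_parameters
#' @export
as_thermo_parameters <- function(x, ...) UseMethod("as_thermo_parameters")

#' @export
as_thermo_parameters.thermo_parameters <- function(x, ...) x

#' @export
as_thermo_parameters.rate_parameters <- function(x, temperature = 300, ...) {
  if (x$k_on == 0) {
    stop("k_on = 0 has no finite delta_G; keep the rate parameterization ",
         "or fit the single-exponential variant", call. = FALSE)
  }
  thermo_parameters(delta_g_from_rates(x$k_on, x$k_off, temperature),
                    k_S = x$k_S, k_off = x$k_off, temperature = temperature,
                    time_unit = x$time_unit)
}

#' Re-express rates (or a curve) in another time unit
#'
#' Rate constants scale by the ratio of unit durations (a rate per minute is
#' 60 times the rate per hour); curve times scale inversely.  Mixing units in
#' arithmetic is an error elsewhere in the package, so conversion is always
#' explicit.
#'
#' @param x `rate_parameters`, `thermo_parameters` or `release_curve`.
#' @param to Target unit: `"minute"`, `"hour"` or `"day"`.
#' @return Object of the same class in the new unit.
#' @export
convert_time_unit <- function(x, to) UseMethod("convert_time_unit")

#' @export
convert_time_unit.rate_parameters <- function(x, to) {
  to <- match_time_unit(to)
  f <- .TIME_UNITS[[to]] / .TIME_UNITS[[x$time_unit]]
  rate_parameters(x$k_S * f, x$k_on * f, x$k_off * f, time_unit = to)
}

#' @export
convert_time_unit.thermo_parameters <- function(x, to) {
  to <- match_time_unit(to)
  f <- .TIME_UNITS[[to]] / .TIME_UNITS[[x$time_unit]]
  thermo_parameters(x$delta_G, x$k_S * f, x$k_off * f,
                    temperature = x$temperature, time_unit = to)
}

#' @export
print.rate_parameters <- function(x, ...) {
  cat(sprintf("Rate parameters (per %s): k_S = %g, k_on = %g, k_off = %g\n",
              x$time_unit, x$k_S, x$k_on, x$k_off))
  invisible(x)
}

#' @export
print.thermo_parameters <- function(x, ...) {
  cat(sprintf(
    "Model parameters (per %s, T = %g K):\n  delta_G = %g x 1e-21 J, k_S = %g, k_off = %g\n",
    x$time_unit, x$temperature, x$delta_G, x$k_S, x$k_off))
  invisible(x)
}
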