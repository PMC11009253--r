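#' Stimulus values bounding a fractional-activation window
#'
#' For the Boltzmann sigmoid, the stimulus at fractional activation `f` is
#' `midpoint + slope * ln(f / (1 - f))`; the default 10-90% window therefore
#' spans `midpoint -/+ ln(9) * slope`, a width of `2 ln(9)` slope factors
#' (about 4.394 of them).
#'
#' @param params a `boltzmann_fit`, or a numeric vector
#'   `c(midpoint, slope_factor)`.
#' @param lo,hi fractional activations, `0 < lo < hi < 1`.
#' @return named numeric `c(lower, upper)` in stimulus units.
#' @examples
#' activation_range(c(5.8, 1.4))  # ~ (2.7, 8.9) mN/m
#' @export
activation_range <- function(params, lo = 0.1, hi = 0.9) {
  stopifnot(lo > 0, hi < 1, lo < hi)
  p <- params_midpoint_slope(params)
  c(lower = p[1] + p[2] * log(lo / (1 - lo)),
    upper = p[1] + p[2] * log(hi / (1 - hi)))
}

params_midpoint_slope <- function(params) {
  if (inherits(params, "boltzmann_fit")) {
    c(params$coefficients[["midpoint"]], params$coefficients[["slope_factor"]])
  } else if (is.numeric(params) && length(params) >= 2) {
    p <- unname(params[1:2])
    if (p[2] <= 0) stop("invalid-argument: slope factor must be positive")
    p
  } else stop("invalid-argument: expected a boltzmann_fit or c(midpoint, slope)")
}

#' Channel gating energetics from a tension-domain Boltzmann fit
#'
#' Under the two-state model, opening expands the channel's in-plane
#' cross-sectional area by dA, so tension favors the open state by `-T * dA`
#' and \deqn{P_O = \frac{1}{1 + \exp((\Delta G - T \Delta A)/k_B T_{abs})}.}
#' Matching to the empirical sigmoid `1/(1 + exp((T50 - T)/k))` identifies
#' \deqn{\Delta A = k_B T_{abs} / k, \qquad
#'       \Delta G = T_{50} \, \Delta A = (T_{50}/k) \, k_B T_{abs},}
#' where `k` is the slope factor in N/m. dG is the intrinsic open-closed free
#' energy difference at zero tension, reported both in joules and in units of
#' `k_B * T_abs`.
#'
#' Only tension-domain fits are admissible: the fit's `stimulus_units` must
#' be `"mN/m"` (numeric parameter input is taken to be in mN/m).
#'
#' @param params a tension-domain `boltzmann_fit`, or numeric
#'   `c(midpoint, slope_factor)` in mN/m.
#' @param temperature absolute temperature in K (default 298.15, recordings
#'   at 25 C).
#' @return a `channel_energetics` object: `delta_A_nm2`, `delta_G_joules`,
#'   `delta_G_kBT`, `temperature`, plus the input parameters.
#' @examples
#' channel_energetics(c(4.4, 1.7))  # TRAAK-like: dA ~ 2.4 nm2, dG ~ 2.6 kBT
#' @export
channel_energetics <- function(params, temperature = 298.15) {
  stopifnot(is.numeric(temperature), temperature > 0)
  if (inherits(params, "boltzmann_fit") &&
      !identical(params$stimulus_units, "mN/m"))
    stop(sprintf(
      "invalid-argument: energetics need a tension-domain fit (mN/m), got '%s'",
      params$stimulus_units))
  p <- params_midpoint_slope(params)
  kT <- .k_boltzmann * temperature            # J
  slope_si <- p[2] * 1e-3                     # mN/m -> N/m
  delta_A_m2 <- kT / slope_si                 # J / (N/m) = m^2
  delta_G_kBT <- p[1] / p[2]
  structure(list(delta_A_nm2 = delta_A_m2 * 1e18,
                 delta_G_joules = delta_G_kBT * kT,
                 delta_G_kBT = delta_G_kBT,
                 temperature = temperature,
                 midpoint = p[1], slope_factor = p[2]),
            class = "channel_energetics")
}

#' @export
print.channel_energetics <- function(x, ...) {
  cat(sprintf(
    "Channel energetics at %.2f K (T50 = %.2f, slope = %.2f mN/m):\n",
    x$temperature, x$midpoint, x$slope_factor))
  cat(sprintf("  dA = %.2f nm^2\n  dG = %.3g J (%.2f kBT)\n",
              x$delta_A_nm2, x$delta_G_joules, x$delta_G_kBT))
  invisible(x)
}
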