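#' Hydrophone calibration
#'
#' A calibrated hydrophone converts acoustic pressure to voltage; the
#' frequency-specific Pascals-per-volt factor from its calibration sheet
#' inverts that.
#'
#' @param pa_per_volt conversion factor, Pa/V; must be > 0.
#' @param frequency_MHz optional frequency the factor applies at.
#' @return a `hydrophone_calibration` object.
#' @export
hydrophone_calibration <- function(pa_per_volt, frequency_MHz = NA_real_) {
  stopifnot(is.numeric(pa_per_volt), pa_per_volt > 0)
  structure(list(pa_per_volt = pa_per_volt, frequency_MHz = frequency_MHz),
            class = "hydrophone_calibration")
}

#' Convert a hydrophone voltage trace to an acoustic pressure waveform
#'
#' Scales the voltage record by the calibration factor, records the peak
#' pressure, and computes the corresponding acoustic intensity (see
#' [intensity_from_pressure()]).
#'
#' @param volts voltage samples (V).
#' @param cal a [hydrophone_calibration()], or a bare Pa/V scalar.
#' @param sample_rate sampling rate in Hz (metadata).
#' @return an `acoustic_waveform`: list with `samples_Pa`, `sample_rate`,
#'   `p_peak_Pa`, `intensity_W_cm2`.
#' @export
voltage_to_pressure <- function(volts, cal, sample_rate = NA_real_) {
  if (is.numeric(cal)) cal <- hydrophone_calibration(cal)
  stopifnot(inherits(cal, "hydrophone_calibration"), is.numeric(volts))
  samples <- volts * cal$pa_per_volt
  p_peak <- if (length(samples)) max(abs(samples)) else 0
  structure(list(samples_Pa = samples, sample_rate = sample_rate,
                 p_peak_Pa = p_peak,
                 intensity_W_cm2 = intensity_from_pressure(p_peak)),
            class = "acoustic_waveform")
}

#' Acoustic intensity from peak pressure
#'
#' Time-averaged intensity of a sinusoidal ultrasound wave at peak pressure
#' `p`:
#' \deqn{I = \frac{(p \times 0.707)^2}{1.48 \times 10^6\ \mathrm{kg\,m^{-2}\,s^{-1}}}
#'       \times \frac{1}{100^2}\ \mathrm{W/cm^2},}
#' i.e. RMS pressure squared over the characteristic acoustic impedance of
#' water, converted from W/m2 to W/cm2. The peak-to-RMS factor is kept as the
#' literal 0.707 so computed intensities match the published arithmetic
#' exactly.
#'
#' @param p_peak_Pa peak acoustic pressure in Pa (vectorized, >= 0).
#' @param impedance medium characteristic impedance, kg m-2 s-1 (water by
#'   default).
#' @return intensity in W/cm2.
#' @examples
#' intensity_from_pressure(0.172e6)  # ~ 1.0 W/cm2
#' @export
intensity_from_pressure <- function(p_peak_Pa, impedance = 1.48e6) {
  stopifnot(is.numeric(p_peak_Pa), impedance > 0)
  if (any(p_peak_Pa < 0)) stop("invalid-argument: peak pressure must be >= 0")
  (p_peak_Pa * 0.707)^2 / impedance / 100^2
}

#' Midpoint of an ultrasound power dose-response
#'
#' Fits the same Boltzmann sigmoid as [fit_boltzmann()] to normalized
#' currents versus acoustic power (W/cm2). The midpoint power is an empirical
#' dose-response parameter: no channel energetics can be derived from a
#' power-domain fit (the returned fit carries `stimulus_units = "W/cm2"` and
#' [channel_energetics()] refuses it).
#'
#' @param points data.frame with columns `power_W_cm2` and `I_over_Imax`
#'   (optionally `patch`).
#' @param mode,patch,... passed to [fit_boltzmann()].
#' @return a `boltzmann_fit` in the power domain.
#' @export
power_response_midpoint <- function(points, mode = "global", patch = NULL,
                                    ...) {
  stopifnot(all(c("power_W_cm2", "I_over_Imax") %in% names(points)))
  fit_boltzmann(I_over_Imax ~ power_W_cm2, points, mode = mode,
                patch = patch, stimulus_units = "W/cm2", ...)
}
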