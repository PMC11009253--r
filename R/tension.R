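#' Convert pressure from mmHg to pascals
#'
#' Pressure-clamp hardware reports applied pressure in mmHg; the Young-Laplace
#' calculation is done in SI units. 1 mmHg = 133.322 Pa.
#'
#' @param dP_mmHg numeric vector of pressures in mmHg (sign preserved).
#' @return pressures in Pa.
#' @examples
#' pressure_to_pascals(-60)   # -7999.32 Pa
#' @export
pressure_to_pascals <- function(dP_mmHg) {
  stopifnot(is.numeric(dP_mmHg))
  if (any(!is.finite(dP_mmHg))) stop("invalid-argument: pressure must be finite")
  dP_mmHg * .mmHg_per_Pa
}

#' Membrane tension from the Young-Laplace relation
#'
#' For a hemispherical patch of radius of curvature `r` under a transmembrane
#' pressure difference `dP`, membrane tension is `T = |dP| * r / 2`. The
#' magnitude is used because positive- and negative-pressure stimulation both
#' generate tension (with opposite curvature); curvature direction, if needed,
#' is metadata carried alongside.
#'
#' Tensions below `min_measurable` (default 0.36 mN/m, the lowest tension the
#' imaging approach resolves) are flagged via the `"below_range"` attribute;
#' they are returned, not censored. Tension of a perfectly flat patch is
#' undefined — radii above `flat_radius_um` should be treated as unreliable
#' (see [tension_series()]).
#'
#' @param dP_pa pressure difference in Pa (sign ignored).
#' @param r_m patch radius of curvature in metres; must be > 0.
#' @param min_measurable flag threshold in mN/m.
#' @return tension in mN/m, with logical attribute `below_range`.
#' @examples
#' laplace_tension(8000, 1.5e-6)  # 6 mN/m
#' @export
laplace_tension <- function(dP_pa, r_m, min_measurable = 0.36) {
  stopifnot(is.numeric(dP_pa), is.numeric(r_m))
  if (any(r_m <= 0)) stop("invalid-geometry: radius must be positive")
  T_mNm <- abs(dP_pa) * r_m / 2 * 1e3
  attr(T_mNm, "below_range") <- T_mNm < min_measurable
  T_mNm
}

# convenience: tension in mN/m from mmHg and micrometres
# (133.322 Pa/mmHg * 1e-6 m/um / 2 * 1e3 = 0.066661 per mmHg*um)
tension_mNm <- function(dP_mmHg, r_um) {
  as.numeric(laplace_tension(pressure_to_pascals(dP_mmHg), r_um * 1e-6))
}

#' Per-step tension series from circle fits and applied pressures
#'
#' Joins each stimulus step's applied pressure with the patch radius fitted
#' from the movie frame at that step's peak current, and computes Laplace
#' tension. Steps with a missing fit are reported as `NA` rows flagged
#' `"missing_fit"`, never silently dropped. Fits with radius above
#' `flat_radius_um` are flagged `"flat_patch"`: tension in near-flat membranes
#' is increasingly unreliable. Tensions below 0.36 mN/m carry a
#' `"below_range"` flag.
#'
#' @param pressures_mmHg numeric vector, one applied pressure per step.
#' @param fits list of [fit_circle_algebraic()] / [fit_circle_three_point()]
#'   results (entries may be `NULL` for unanalyzable steps). Each fit needs
#'   `radius_um` set (see [radius_physical()]).
#' @param step_ids optional step identifiers (default `seq_along(pressures)`).
#' @param frame_index optional per-step frame provenance.
#' @param flat_radius_um flag threshold for near-flat patches (µm).
#' @return data.frame: `step_id`, `dP_mmHg`, `dP_Pa`, `r_um`, `T_mN_per_m`,
#'   `frame_index`, `fit_method`, `flags`.
#' @export
tension_series <- function(pressures_mmHg, fits, step_ids = NULL,
                           frame_index = NULL, flat_radius_um = 25) {
  n <- length(pressures_mmHg)
  if (length(fits) != n)
    stop("invalid-argument: need one fit (possibly NULL) per step")
  if (is.null(step_ids)) step_ids <- seq_len(n)
  if (is.null(frame_index)) frame_index <- rep(NA_integer_, n)
  out <- data.frame(
    step_id = step_ids,
    dP_mmHg = as.numeric(pressures_mmHg),
    dP_Pa = pressure_to_pascals(as.numeric(pressures_mmHg)),
    r_um = rep(NA_real_, n), T_mN_per_m = rep(NA_real_, n),
    frame_index = frame_index,
    fit_method = rep(NA_character_, n), flags = rep("", n),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    f <- fits[[i]]
    if (is.null(f) || is.null(f$radius_um) || is.na(f$radius_um)) {
      out$flags[i] <- "missing_fit"
      next
    }
    out$r_um[i] <- f$radius_um
    out$fit_method[i] <- f$method
    Ti <- laplace_tension(out$dP_Pa[i], f$radius_um * 1e-6)
    out$T_mN_per_m[i] <- as.numeric(Ti)
    flags <- character(0)
    if (f$radius_um > flat_radius_um) flags <- c(flags, "flat_patch")
    if (attr(Ti, "below_range")) flags <- c(flags, "below_range")
    out$flags[i] <- paste(flags, collapse = ";")
  }
  out
}
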