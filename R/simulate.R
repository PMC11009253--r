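#' Channel gating ground truth for synthetic experiments
#'
#' Parameters of a simulated mechanosensitive channel population in one
#' patch. Defaults are TRAAK-like: midpoint tension 4.4 mN/m and slope factor
#' 1.7 mN/m (the printed global-fit values), hundreds of channels at ~1-2 pA
#' single-channel current, and a resting (basal) tension at the low end of
#' the ~0.5-4 mN/m range patches exhibit from lipid-glass adhesion. The
#' default current noise is 5% of the maximal macroscopic current. For an
#' MscS-like patch use e.g. `channel_model(3.7, 1.1, n_channels = 30,
#' i_single = -12)`.
#'
#' @param T50_true midpoint tension, mN/m.
#' @param slope_true slope factor, mN/m; > 0.
#' @param n_channels channel count; >= 1.
#' @param i_single single-channel current, pA; non-zero (sign = polarity).
#' @param basal_tension resting tension, mN/m; >= 0.
#' @param current_noise_sd additive Gaussian current noise SD, pA.
#' @return a `channel_model` object.
#' @export
channel_model <- function(T50_true = 4.4, slope_true = 1.7, n_channels = 400,
                          i_single = 1.5, basal_tension = 0.5,
                          current_noise_sd = 0.05 * abs(n_channels * i_single)) {
  stopifnot(slope_true > 0, n_channels >= 1, i_single != 0,
            basal_tension >= 0, current_noise_sd >= 0)
  structure(list(T50_true = T50_true, slope_true = slope_true,
                 n_channels = as.integer(round(n_channels)),
                 i_single = i_single, basal_tension = basal_tension,
                 current_noise_sd = current_noise_sd),
            class = "channel_model")
}

#' Patch geometry and acquisition ground truth
#'
#' Describes the simulated patch mechanics and the imaging system. The patch
#' radius response to pressure is a phenomenological hyperbola (see
#' [patch_radius_for_pressure()]); `compliance_pressure` is the pressure at
#' which the patch radius is twice the pipette radius. Frame rate defaults to
#' the 120 Hz acquisition used experimentally.
#'
#' @param pipette_radius pipette inner radius, um; > 0.
#' @param compliance_pressure patch compliance scale, mmHg; > 0.
#' @param pixel_scale um per pixel; > 0.
#' @param frame_rate imaging rate, Hz; > 0.
#' @param flat_cap radius assigned to an unpressurized (flat) patch, um.
#' @param frame_dim frame size `c(rows, cols)` in px.
#' @return a `geometry_model` object.
#' @export
geometry_model <- function(pipette_radius = 1.5, compliance_pressure = 20,
                           pixel_scale = 0.05, frame_rate = 120,
                           flat_cap = 50 * pipette_radius,
                           frame_dim = c(128L, 128L)) {
  stopifnot(pipette_radius > 0, compliance_pressure > 0, pixel_scale > 0,
            frame_rate > 0, flat_cap > pipette_radius,
            length(frame_dim) == 2, all(frame_dim >= 8))
  structure(list(pipette_radius = pipette_radius,
                 compliance_pressure = compliance_pressure,
                 pixel_scale = pixel_scale, frame_rate = frame_rate,
                 flat_cap = flat_cap, frame_dim = as.integer(frame_dim)),
            class = "geometry_model")
}

#' Piecewise-constant pressure step protocol
#'
#' Builds the stimulus record for a sweep of pressure steps: each step holds
#' its pressure for `step_duration` seconds, separated by `inter_step`
#' seconds at zero pressure (the sweep also opens with one inter-step period
#' so a pre-stimulus baseline exists). Step onset/offset times are annotated
#' per step.
#'
#' @param step_pressures pressures in mmHg, one per step (may be empty).
#' @param step_duration step length, s; > 0.
#' @param inter_step gap between steps, s; > 0.
#' @param sample_rate sampling rate of the trace, Hz; > 0.
#' @return a `stimulus_protocol`: list with `time_s`, `pressure_mmHg`,
#'   `sample_rate`, and a `steps` data.frame (`step_id`, `pressure_mmHg`,
#'   `t_on`, `t_off`).
#' @export
make_pressure_protocol <- function(step_pressures, step_duration = 0.5,
                                   inter_step = 0.5, sample_rate = 2000) {
  if (step_duration <= 0 || inter_step <= 0 || sample_rate <= 0)
    stop("invalid-argument: durations and sample rate must be positive")
  n <- length(step_pressures)
  if (n == 0) {
    return(structure(list(time_s = numeric(0), pressure_mmHg = numeric(0),
                          sample_rate = sample_rate,
                          steps = data.frame(step_id = integer(0),
                                             pressure_mmHg = numeric(0),
                                             t_on = numeric(0),
                                             t_off = numeric(0))),
                     class = "stimulus_protocol"))
  }
  period <- step_duration + inter_step
  t_on <- inter_step + (seq_len(n) - 1) * period
  t_off <- t_on + step_duration
  total <- inter_step + n * period
  time_s <- seq(0, total, by = 1 / sample_rate)
  pressure <- numeric(length(time_s))
  for (i in seq_len(n)) {
    in_step <- time_s >= t_on[i] & time_s < t_off[i]
    pressure[in_step] <- step_pressures[i]
  }
  structure(list(time_s = time_s, pressure_mmHg = pressure,
                 sample_rate = sample_rate,
                 steps = data.frame(step_id = seq_len(n),
                                    pressure_mmHg = step_pressures,
                                    t_on = t_on, t_off = t_off)),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("Pressure protocol: %d step(s), %g Hz sampling, %.2f s total\n",
              nrow(x$steps), x$sample_rate,
              if (length(x$time_s)) max(x$time_s) else 0))
  invisible(x)
}

#' Forward model: patch radius of curvature under pressure
#'
#' Phenomenological fixture inverted by the analysis pipeline: an
#' unpressurized patch is nearly flat (radius capped at `flat_cap`), and with
#' increasing pressure magnitude the radius decreases hyperbolically toward
#' the pipette radius,
#' \deqn{r(\Delta P) = r_{pip} (1 + P_c / |\Delta P|),}
#' capped above at `flat_cap`. This makes Laplace tension
#' `T = |dP| r / 2` strictly increasing in `|dP|`. It reproduces the
#' qualitative behavior of real patches, not their mechanics.
#'
#' @param g a [geometry_model()].
#' @param dP pressure(s), mmHg (sign ignored).
#' @return radius of curvature in um.
#' @export
patch_radius_for_pressure <- function(g, dP) {
  stopifnot(inherits(g, "geometry_model"))
  adP <- abs(dP)
  r <- ifelse(adP > 0,
              g$pipette_radius * (1 + g$compliance_pressure / adP),
              g$flat_cap)
  pmin(r, g$flat_cap)
}

#' Simulate macroscopic current from a tension trace
#'
#' `I(t) = n_channels * i_single * P_O(T(t)) + N(0, current_noise_sd)`, with
#' `P_O` the two-state Boltzmann open probability at the channel's true
#' midpoint and slope. Reproducible given `seed`.
#'
#' @param ch a [channel_model()].
#' @param tension_trace tension series, mN/m; finite and >= 0.
#' @param seed RNG seed for the noise draw.
#' @return current trace in pA.
#' @export
simulate_currents <- function(ch, tension_trace, seed = 1L) {
  stopifnot(inherits(ch, "channel_model"))
  if (any(!is.finite(tension_trace)) || any(tension_trace < 0))
    stop("invalid-argument: tension trace must be finite and non-negative")
  po <- boltzmann_open_prob(tension_trace, ch$T50_true, ch$slope_true)
  ideal <- ch$n_channels * ch$i_single * po
  if (ch$current_noise_sd == 0) return(ideal)
  ideal + with_local_seed(seed, function()
    rnorm(length(ideal), 0, ch$current_noise_sd))
}

#' Render a synthetic fluorescence frame of a patched membrane
#'
#' Draws the patch membrane as a bright circular arc over a dark background:
#' the arc is the left-opening semicircle of radius `r_um / pixel_scale`
#' pixels whose apex (leftmost point) sits at `arc_center = c(col, row)`,
#' with a Gaussian radial cross-section of width `arc_sigma` px. In the
#' noise-free limit every row crossed by the arc has exactly one brightest
#' pixel. Additive Gaussian read noise (`noise_sd`) and optional Poisson shot
#' noise are applied on top.
#'
#' @param g a [geometry_model()] (frame size and pixel scale).
#' @param r_um arc radius of curvature, um; > 0.
#' @param arc_center apex position `c(col, row)` in px; must be inside the
#'   frame.
#' @param intensity arc peak intensity (arbitrary units).
#' @param noise_sd additive Gaussian noise SD (same units).
#' @param seed RNG seed.
#' @param arc_sigma radial Gaussian width of the membrane image, px.
#' @param shot_noise add Poisson shot noise (intensity-scaled) as well.
#' @return numeric intensity matrix `g$frame_dim`.
#' @export
render_patch_frame <- function(g, r_um, arc_center, intensity = 100,
                               noise_sd = 0, seed = 1L, arc_sigma = 1.2,
                               shot_noise = FALSE) {
  stopifnot(inherits(g, "geometry_model"), r_um > 0)
  nr <- g$frame_dim[1]; nc <- g$frame_dim[2]
  apex_col <- arc_center[1]; cy <- arc_center[2]
  if (apex_col < 1 || apex_col > nc || cy < 1 || cy > nr)
    stop("invalid-geometry: arc apex outside the frame")
  r_px <- r_um / g$pixel_scale
  cx <- apex_col + r_px  # circle center, to the right of the apex
  row_idx <- matrix(seq_len(nr), nr, nc)
  col_idx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d <- sqrt((col_idx - cx)^2 + (row_idx - cy)^2)
  img <- intensity * exp(-(d - r_px)^2 / (2 * arc_sigma^2))
  img[col_idx > cx] <- 0  # left-opening arc only: one crossing per row
  if (shot_noise || noise_sd > 0) {
    img <- with_local_seed(seed, function() {
      out <- img
      if (shot_noise) {
        gain <- max(intensity, 1) / 50  # ~50 photons at peak
        out <- rpois(length(out), pmax(out, 0) / gain) * gain
        out <- matrix(out, nr, nc)
      }
      if (noise_sd > 0) out <- out + rnorm(length(out), 0, noise_sd)
      out
    })
  }
  img
}

# rows the arc visibly crosses; stay clear of the tangent rows where the
# brightest-pixel rule degrades
arc_row_range <- function(g, r_um, cy, frac = 0.85) {
  r_px <- r_um / g$pixel_scale
  half <- floor(min(r_px * frac, (g$frame_dim[1] - 2) / 2))
  rows <- seq.int(max(1, round(cy) - half), min(g$frame_dim[1], round(cy) + half))
  rows
}

#' Simulate a complete patch experiment
#'
#' Generates one synthetic patch: the pressure protocol drives the forward
#' geometry model (radius per step, hence stimulus tension per step), the
#' channel model turns the tension trace into a macroscopic current sweep,
#' and one fluorescence frame per step is rendered at the step midpoint. The
#' driving tension is `max(basal_tension, stimulus tension)`: resting tension
#' sets the floor of channel activity between and during weak steps, while
#' the analysis — like the experimental one — only knows the stimulus-induced
#' tension.
#'
#' @param ch a [channel_model()].
#' @param g a [geometry_model()].
#' @param protocol a [make_pressure_protocol()] result.
#' @param seed RNG seed (currents, image noise).
#' @param render `"per_step"` (one frame at each step midpoint), or
#'   `"none"` (no imaging; truth radii only).
#' @param arc_intensity,arc_noise_sd frame rendering parameters; the default
#'   noise is 0 (use `0.2 * arc_intensity` for the calibrated realistic
#'   level).
#' @param arc_apex_col apex column of the rendered arc, px.
#' @param patch_id bookkeeping identifier.
#' @return a `simulated_patch`: list with `protocol`, `sweep` (data.frame
#'   `time_s`, `current_pA`, `pressure_mmHg`), `stack` (an [image_stack()] or
#'   `NULL`), `truth` (models plus per-step `r_true_um`, `T_true_mN_per_m`),
#'   `patch_id`, `seed`.
#' @export
simulate_patch <- function(ch, g, protocol = NULL, seed = 1L,
                           render = c("per_step", "none"),
                           arc_intensity = 100, arc_noise_sd = 0,
                           arc_apex_col = 28, patch_id = "patch_1") {
  render <- match.arg(render)
  stopifnot(inherits(ch, "channel_model"), inherits(g, "geometry_model"))
  if (is.null(protocol))
    protocol <- make_pressure_protocol(c(-5, -10, -20, -40, -80, -140))
  steps <- protocol$steps
  r_true <- patch_radius_for_pressure(g, steps$pressure_mmHg)
  T_true <- tension_mNm(steps$pressure_mmHg, r_true)

  # stimulus tension over the time base, floored by basal tension
  T_stim <- numeric(length(protocol$time_s))
  for (i in seq_len(nrow(steps))) {
    in_step <- protocol$time_s >= steps$t_on[i] & protocol$time_s < steps$t_off[i]
    T_stim[in_step] <- T_true[i]
  }
  T_drive <- pmax(T_stim, ch$basal_tension)
  current <- simulate_currents(ch, T_drive, seed = split_seed(seed, 1))
  sweep <- data.frame(time_s = protocol$time_s, current_pA = current,
                      pressure_mmHg = protocol$pressure_mmHg)

  stack <- NULL
  if (render == "per_step" && nrow(steps) > 0) {
    cy <- ceiling(g$frame_dim[1] / 2)
    frame_times <- (steps$t_on + steps$t_off) / 2
    frames <- lapply(seq_len(nrow(steps)), function(i)
      render_patch_frame(g, r_true[i], c(arc_apex_col, cy),
                         intensity = arc_intensity, noise_sd = arc_noise_sd,
                         seed = split_seed(seed, 100 + i)))
    # per-frame ROI: the rows each frame's arc visibly crosses
    roi <- lapply(r_true, function(r)
      list(rows = arc_row_range(g, r, cy), cols = seq_len(g$frame_dim[2])))
    stack <- image_stack(frames, frame_rate = g$frame_rate,
                         pixel_scale = g$pixel_scale,
                         frame_times = frame_times, roi = roi)
  }
  structure(list(protocol = protocol, sweep = sweep, stack = stack,
                 truth = list(channel = ch, geometry = g,
                              steps = data.frame(steps,
                                                 r_true_um = r_true,
                                                 T_true_mN_per_m = T_true)),
                 patch_id = patch_id, seed = seed),
            class = "simulated_patch")
}

#' @export
print.simulated_patch <- function(x, ...) {
  cat(sprintf(
    "Simulated patch '%s': %d step(s), %d sweep samples, %s frames (seed %d)\n",
    x$patch_id, nrow(x$truth$steps), nrow(x$sweep),
    if (is.null(x$stack)) "no" else length(x$stack$frames), x$seed))
  invisible(x)
}

#' Generate a cohort of simulated patches
#'
#' Simulates `n_patches` patches sharing the same channel gating parameters
#' (up to the stated jitter, zero by default) while the patch geometry —
#' pipette radius, compliance — and the basal tension and channel count vary
#' between patches. The same pressure protocol therefore produces different
#' tensions in different patches: current-pressure relations disperse across
#' the cohort while current-tension relations collapse onto one Boltzmann,
#' exactly the behavior that identifies tension (not pressure) as the
#' gating stimulus. Per-patch seeds are split deterministically from `seed`.
#'
#' @param n_patches number of patches; >= 1. The reference cohort size is 12
#'   (the TRAAK dataset).
#' @param ch_mean mean [channel_model()].
#' @param g_mean mean [geometry_model()].
#' @param jitter named list of between-patch spreads:
#'   `pipette_radius_cv`, `compliance_cv` (lognormal CVs),
#'   `n_channels_cv` (lognormal CV), `basal_tension_sd` (truncated normal,
#'   mN/m), `T50_sd`, `slope_sd` (normal, mN/m; 0 by default — gating is a
#'   channel property, not a patch property).
#' @param protocol shared [make_pressure_protocol()]; the default six steps
#'   (-5 to -140 mmHg) sweep the mean patch from sub-threshold (~2.5 mN/m)
#'   to saturating (~16 mN/m) tension, satisfying the saturating-response
#'   requirement.
#' @param seed root RNG seed.
#' @param render,arc_noise_sd passed to [simulate_patch()].
#' @return list of `simulated_patch` objects.
#' @export
generate_cohort <- function(n_patches = 12, ch_mean = channel_model(),
                            g_mean = geometry_model(), jitter = list(),
                            protocol = NULL, seed = 1L,
                            render = "per_step", arc_noise_sd = 0) {
  stopifnot(n_patches >= 1)
  jit <- modifyList(list(pipette_radius_cv = 0.2, compliance_cv = 0.3,
                         n_channels_cv = 0.5, basal_tension_sd = 0.3,
                         T50_sd = 0, slope_sd = 0), jitter)
  if (is.null(protocol))
    protocol <- make_pressure_protocol(c(-5, -10, -20, -40, -80, -140))
  draws <- with_local_seed(seed, function() {
    data.frame(
      pip = rlnorm(n_patches, log(g_mean$pipette_radius), jit$pipette_radius_cv),
      comp = rlnorm(n_patches, log(g_mean$compliance_pressure), jit$compliance_cv),
      nch = pmax(1, round(rlnorm(n_patches, log(ch_mean$n_channels),
                                 jit$n_channels_cv))),
      basal = pmax(0, rnorm(n_patches, ch_mean$basal_tension,
                            jit$basal_tension_sd)),
      T50 = rnorm(n_patches, ch_mean$T50_true, jit$T50_sd),
      slope = pmax(0.05, rnorm(n_patches, ch_mean$slope_true, jit$slope_sd))
    )
  })
  lapply(seq_len(n_patches), function(i) {
    ch_i <- channel_model(
      T50_true = draws$T50[i], slope_true = draws$slope[i],
      n_channels = draws$nch[i], i_single = ch_mean$i_single,
      basal_tension = draws$basal[i],
      current_noise_sd = ch_mean$current_noise_sd / ch_mean$n_channels *
        draws$nch[i])
    g_i <- geometry_model(
      pipette_radius = draws$pip[i], compliance_pressure = draws$comp[i],
      pixel_scale = g_mean$pixel_scale, frame_rate = g_mean$frame_rate,
      flat_cap = 50 * draws$pip[i], frame_dim = g_mean$frame_dim)
    simulate_patch(ch_i, g_i, protocol, seed = split_seed(seed, i),
                   render = render, arc_noise_sd = arc_noise_sd,
                   patch_id = sprintf("patch_%02d", i))
  })
}
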