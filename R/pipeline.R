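#' Analyze one patch: currents, radii, tensions, normalized response
#'
#' Runs the per-patch stages in experiment order: peak current per stimulus
#' step (baseline-subtracted), frame selection at the peak-current time,
#' brightest-pixel membrane detection, continuity filtering, circle fit,
#' Laplace tension, normalization to Imax, and QC. Stage failures on a step
#' leave that step's radius/tension `NA` (flagged), never abort the patch.
#'
#' @param patch a [simulate_patch()] result, or a list with components
#'   `sweep` (`time_s`, `current_pA`, `pressure_mmHg`), `protocol`
#'   (a `stimulus_protocol`), and `stack` (an [image_stack()], optional),
#'   plus `patch_id`.
#' @param filter continuity filter passed to [enforce_continuity()].
#' @param filter_params named list of filter parameters.
#' @param circle_method `"algebraic"` or `"geometric"` (refined) circle fit.
#' @param roi detection region; defaults to the stack's stored ROI.
#' @param basal_threshold,saturation_tol QC thresholds (see [qc_patch()]).
#' @param baseline peak-current baseline convention (see [peak_current()]).
#'   The default `"none"` measures peaks against the amplifier zero: the
#'   two-state model's resting floor is part of the curve being fitted, so
#'   subtracting the pre-step (basal channel) current would distort the
#'   unit-amplitude Boltzmann.
#' @param smooth_s running-mean width (s) before peak picking.
#' @param use_truth_radii use the simulator's true radii instead of imaging
#'   (only possible for simulated patches; for imaging-free studies).
#' @return a `patch_analysis`: list with `patch_id`, `steps` (per-step table:
#'   pressures, peak currents, radii, tensions, flags), `normalized`
#'   (a [normalize_currents()] result in the tension domain), `qc`
#'   (a [qc_patch()] verdict), `basal_fraction`, `fold_activation`.
#' @export
analyze_patch <- function(patch, filter = "median_residual",
                          filter_params = list(),
                          circle_method = c("algebraic", "geometric"),
                          roi = NULL, basal_threshold = 0.25,
                          saturation_tol = 0.10, baseline = "none",
                          smooth_s = 0.05, use_truth_radii = FALSE) {
  circle_method <- match.arg(circle_method)
  steps <- patch$protocol$steps
  if (!nrow(steps)) stop("invalid-argument: protocol has no steps")
  sweep <- patch$sweep

  responses <- lapply(seq_len(nrow(steps)), function(i)
    peak_current(sweep, c(steps$t_on[i], steps$t_off[i]),
                 baseline = baseline, smooth_s = smooth_s,
                 step_id = steps$step_id[i]))
  peaks <- vapply(responses, function(r) r$peak_current, numeric(1))

  fits <- vector("list", nrow(steps))
  frame_idx <- rep(NA_integer_, nrow(steps))
  step_flags <- character(nrow(steps))
  if (use_truth_radii) {
    if (is.null(patch$truth))
      stop("invalid-argument: use_truth_radii needs a simulated patch")
    for (i in seq_len(nrow(steps))) {
      fits[[i]] <- list(radius_um = patch$truth$steps$r_true_um[i],
                        method = "truth")
    }
  } else if (!is.null(patch$stack)) {
    if (is.null(roi)) roi <- patch$stack$roi
    # roi may be one region or a per-frame list of regions
    per_frame_roi <- !is.null(roi) && is.null(roi$rows)
    for (i in seq_len(nrow(steps))) {
      res <- tryCatch({
        fi <- frame_index_for_time(patch$stack, responses[[i]]$t_peak)
        roi_i <- if (per_frame_roi) roi[[fi]] else roi
        pts <- detect_membrane_points(patch$stack$frames[[fi]], roi = roi_i)
        pts <- do.call(enforce_continuity,
                       c(list(pts = pts, method = filter), filter_params))
        fit <- fit_circle_algebraic(
          pts, refine = if (circle_method == "geometric") "geometric" else "none")
        fit <- radius_physical(fit, patch$stack$pixel_scale)
        list(fit = fit, fi = fi)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        step_flags[i] <- paste0("stage_failure: ", conditionMessage(res))
      } else {
        fits[[i]] <- res$fit
        frame_idx[i] <- res$fi
      }
    }
  } else {
    step_flags[] <- "no_imaging"
  }

  tens <- tension_series(steps$pressure_mmHg, fits, step_ids = steps$step_id,
                         frame_index = frame_idx)
  tens$flags <- ifelse(step_flags != "",
                       paste(tens$flags, step_flags, sep = ";"), tens$flags)
  tens$peak_current_pA <- peaks
  tens$I_over_Imax <- abs(peaks) / max(abs(peaks))

  norm <- normalize_currents(responses, stimulus = tens$T_mN_per_m,
                             patch_id = patch$patch_id)

  # basal activity relative to Imax: median pre-protocol current against the
  # amplifier zero (not baseline-subtracted — basal activity IS the baseline)
  pre <- sweep$time_s < steps$t_on[1]
  basal_abs <- if (any(pre)) abs(median(sweep$current_pA[pre])) else 0
  imax_abs <- attr(norm, "imax_pA")
  basal_fraction <- basal_abs / imax_abs
  qc <- qc_patch(norm, basal_fraction, basal_threshold = basal_threshold,
                 saturation_tol = saturation_tol)
  structure(list(patch_id = patch$patch_id, steps = tens, normalized = norm,
                 qc = qc, basal_fraction = basal_fraction,
                 fold_activation = fold_activation(basal_abs, imax_abs)),
            class = "patch_analysis")
}

#' @export
print.patch_analysis <- function(x, ...) {
  cat(sprintf("Patch '%s': %d steps, basal I/Imax = %.3f, %.1f-fold activation; ",
              x$patch_id, nrow(x$steps), x$basal_fraction, x$fold_activation))
  print(x$qc)
  invisible(x)
}

#' Analyze a cohort end to end
#'
#' Orchestrates the full pipeline over a list of patches (in memory or read
#' from a [run_simulate()] output directory): per-patch analysis, QC-based
#' exclusion, pooled global Boltzmann fits in the tension and pressure
#' domains, and channel energetics from the tension-domain fit. Per-patch
#' failures are isolated: a patch whose analysis errors is reported in the
#' QC ledger and the run continues.
#'
#' @param patches list of patches (see [analyze_patch()]), or a directory
#'   written by [run_simulate()].
#' @param filter,filter_params,circle_method,basal_threshold,saturation_tol,use_truth_radii
#'   passed to [analyze_patch()].
#' @param fit_mode `"global"` or `"per_patch"` Boltzmann fitting.
#' @param baseline,smooth_s peak-current conventions (see [analyze_patch()]).
#' @param temperature absolute temperature (K) for energetics.
#' @param seed seed recorded in the report and used for fit restarts.
#' @return an `analysis_report`: list with `per_patch` (analyses),
#'   `points` (pooled tidy table), `fit_tension`, `fit_pressure`,
#'   `energetics`, `qc_ledger` (data.frame of verdicts and reasons),
#'   `excluded`, `config`.
#' @export
run_analyze <- function(patches, filter = "median_residual",
                        filter_params = list(), circle_method = "algebraic",
                        fit_mode = "global", basal_threshold = 0.25,
                        saturation_tol = 0.10, temperature = 298.15,
                        baseline = "none", smooth_s = 0.05,
                        use_truth_radii = FALSE, seed = 1L) {
  if (is.character(patches) && length(patches) == 1)
    patches <- read_simulated_cohort(patches)
  analyses <- lapply(patches, function(p) {
    tryCatch(
      analyze_patch(p, filter = filter, filter_params = filter_params,
                    circle_method = circle_method,
                    basal_threshold = basal_threshold,
                    saturation_tol = saturation_tol,
                    baseline = baseline, smooth_s = smooth_s,
                    use_truth_radii = use_truth_radii),
      error = function(e) structure(
        list(patch_id = p$patch_id, error = conditionMessage(e)),
        class = "patch_failure"))
  })
  failed <- vapply(analyses, inherits, logical(1), "patch_failure")
  qc_ledger <- do.call(rbind, lapply(analyses, function(a) {
    if (inherits(a, "patch_failure"))
      data.frame(patch_id = a$patch_id, pass = FALSE,
                 reasons = paste0("failure: ", a$error))
    else
      data.frame(patch_id = a$patch_id, pass = a$qc$pass,
                 reasons = paste(a$qc$reasons, collapse = ";"))
  }))
  kept <- analyses[!failed]
  kept <- kept[vapply(kept, function(a) a$qc$pass, logical(1))]
  excluded <- qc_ledger$patch_id[!qc_ledger$pass]

  points <- do.call(rbind, lapply(kept, function(a) {
    data.frame(patch_id = a$patch_id, step_id = a$steps$step_id,
               dP_mmHg = a$steps$dP_mmHg, r_um = a$steps$r_um,
               T_mN_per_m = a$steps$T_mN_per_m,
               I_over_Imax = a$steps$I_over_Imax, flags = a$steps$flags)
  }))

  fit_T <- fit_P <- energ <- NULL
  if (!is.null(points) && sum(is.finite(points$T_mN_per_m)) >= 4) {
    ok <- is.finite(points$T_mN_per_m)
    fit_T <- tryCatch(
      fit_boltzmann(I_over_Imax ~ T_mN_per_m, points[ok, ],
                    mode = fit_mode, patch = points$patch_id[ok],
                    stimulus_units = "mN/m", seed = seed),
      error = function(e) e)
    fit_P <- tryCatch(
      fit_boltzmann(I_over_Imax ~ abs(dP_mmHg), points,
                    mode = fit_mode, patch = points$patch_id,
                    stimulus_units = "mmHg", seed = seed),
      error = function(e) e)
    if (inherits(fit_T, "boltzmann_fit"))
      energ <- channel_energetics(fit_T, temperature = temperature)
  }
  structure(list(per_patch = analyses, points = points,
                 fit_tension = fit_T, fit_pressure = fit_P,
                 energetics = energ, qc_ledger = qc_ledger,
                 excluded = excluded,
                 config = list(filter = filter, filter_params = filter_params,
                               circle_method = circle_method,
                               fit_mode = fit_mode,
                               basal_threshold = basal_threshold,
                               saturation_tol = saturation_tol,
                               temperature = temperature, seed = seed,
                               use_truth_radii = use_truth_radii)),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  n_tot <- nrow(x$qc_ledger)
  cat(sprintf("Analysis report: %d patch(es), %d excluded by QC\n",
              n_tot, length(x$excluded)))
  if (inherits(x$fit_tension, "boltzmann_fit")) {
    cat("Tension-domain global fit:\n")
    print(x$fit_tension)
  }
  if (!is.null(x$energetics)) print(x$energetics)
  invisible(x)
}

#' Simulate a cohort and write it to disk
#'
#' Writes, per patch: the sweep table (`<id>_sweep.csv`: `time_s`,
#' `current_pA`, `pressure_mmHg`), the image stack
#' (`<id>_stack.csv` + JSON metadata sidecar, see [write_stack_csv()]),
#' and a ground-truth sidecar (`<id>_truth.json`), plus a `manifest.csv`.
#' Deterministic given `seed`.
#'
#' @param out_dir writable output directory (created if missing).
#' @param n_patches,ch_mean,g_mean,jitter,protocol,seed,arc_noise_sd passed
#'   to [generate_cohort()].
#' @param render `"per_step"` or `"none"` (no stacks written).
#' @return invisibly, the manifest data.frame.
#' @export
run_simulate <- function(out_dir, n_patches = 12, ch_mean = channel_model(),
                         g_mean = geometry_model(), jitter = list(),
                         protocol = NULL, seed = 1L, render = "per_step",
                         arc_noise_sd = 0) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("io-error: cannot create output directory")
  if (n_patches == 0) {
    manifest <- data.frame(patch_id = character(0), sweep = character(0),
                           stack = character(0), truth = character(0))
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    return(invisible(manifest))
  }
  cohort <- generate_cohort(n_patches, ch_mean = ch_mean, g_mean = g_mean,
                            jitter = jitter, protocol = protocol, seed = seed,
                            render = render, arc_noise_sd = arc_noise_sd)
  manifest <- do.call(rbind, lapply(cohort, function(p) {
    id <- p$patch_id
    sweep_f <- file.path(out_dir, paste0(id, "_sweep.csv"))
    write.csv(p$sweep, sweep_f, row.names = FALSE)
    stack_f <- NA_character_
    if (!is.null(p$stack)) {
      stack_f <- file.path(out_dir, paste0(id, "_stack.csv"))
      write_stack_csv(p$stack, stack_f)
    }
    truth_f <- file.path(out_dir, paste0(id, "_truth.json"))
    tr <- p$truth
    jsonlite::write_json(
      list(patch_id = id, seed = p$seed,
           channel = unclass(tr$channel), geometry = unclass(tr$geometry),
           steps = tr$steps,
           protocol = list(sample_rate = p$protocol$sample_rate,
                           steps = p$protocol$steps)),
      truth_f, auto_unbox = TRUE, digits = NA)
    data.frame(patch_id = id, sweep = basename(sweep_f),
               stack = if (is.na(stack_f)) NA_character_ else basename(stack_f),
               truth = basename(truth_f))
  }))
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a simulated cohort back from disk
#'
#' @param dir directory written by [run_simulate()].
#' @return list of patches suitable for [run_analyze()].
#' @export
read_simulated_cohort <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$patch_id[i]
    sweep <- read.csv(file.path(dir, manifest$sweep[i]))
    truth <- jsonlite::read_json(file.path(dir, manifest$truth[i]),
                                 simplifyVector = TRUE)
    stack <- NULL
    if (!is.na(manifest$stack[i]))
      stack <- read_stack_csv(file.path(dir, manifest$stack[i]))
    proto <- structure(
      list(time_s = sweep$time_s, pressure_mmHg = sweep$pressure_mmHg,
           sample_rate = truth$protocol$sample_rate,
           steps = as.data.frame(truth$protocol$steps)),
      class = "stimulus_protocol")
    structure(list(protocol = proto, sweep = sweep, stack = stack,
                   truth = list(channel = truth$channel,
                                geometry = truth$geometry,
                                steps = as.data.frame(truth$steps)),
                   patch_id = id, seed = truth$seed),
              class = "simulated_patch")
  })
}
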