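#' Peak current of a stimulus step
#'
#' Extracts the peak macroscopic current within a stimulus window after
#' baseline subtraction. The baseline is the median current over
#' `baseline_window` (default: the 100 ms immediately preceding the window).
#' Polarity `"auto"` picks the side (positive or negative deflection) with
#' the larger absolute baseline-subtracted extremum; ties in the trace are
#' resolved toward the earliest time point.
#'
#' The two-state gating model predicts a nonzero current floor at rest, so
#' for Boltzmann fitting the pipeline measures peaks against the amplifier
#' zero (`baseline = "none"`); pre-step subtraction (`"pre_step"`) removes
#' the resting current as well and is appropriate for evoked-increment
#' questions. `smooth_s` applies a running mean before the extremum is taken
#' — the raw-sample maximum of a noisy plateau is biased upward by the noise
#' order statistics.
#'
#' @param sweep data.frame with columns `time_s` and `current_pA`.
#' @param window numeric `c(t_start, t_end)` in seconds; must intersect the
#'   sweep.
#' @param polarity `"auto"`, `"positive"`, or `"negative"`.
#' @param baseline `"pre_step"` (median over `baseline_window`) or `"none"`
#'   (amplifier zero).
#' @param baseline_window optional `c(t0, t1)`; default `window[1] - 0.1` to
#'   `window[1]`. If no samples fall in it, baseline is 0 (flagged).
#' @param smooth_s running-mean width in seconds applied before peak picking
#'   (0 = raw samples).
#' @param step_id bookkeeping identifier.
#' @return a `step_response`: list with `step_id`, `peak_current` (pA,
#'   baseline-subtracted, signed), `baseline_pA`, `t_peak`, `window`,
#'   `polarity`, `flags`.
#' @export
peak_current <- function(sweep, window,
                         polarity = c("auto", "positive", "negative"),
                         baseline = c("pre_step", "none"),
                         baseline_window = NULL, smooth_s = 0,
                         step_id = NA_integer_) {
  polarity <- match.arg(polarity)
  baseline <- match.arg(baseline)
  stopifnot(all(c("time_s", "current_pA") %in% names(sweep)),
            length(window) == 2, window[1] < window[2])
  if (window[2] < min(sweep$time_s) || window[1] > max(sweep$time_s))
    stop("out-of-range: window outside the sweep")
  if (is.null(baseline_window)) baseline_window <- c(window[1] - 0.1, window[1])
  flags <- character(0)
  if (baseline == "none") {
    bl <- 0
  } else {
    in_bl <- sweep$time_s >= baseline_window[1] &
      sweep$time_s < baseline_window[2]
    if (any(in_bl)) {
      bl <- median(sweep$current_pA[in_bl])
    } else {
      bl <- 0
      flags <- c(flags, "no_baseline_samples")
    }
  }
  current <- sweep$current_pA
  if (smooth_s > 0 && nrow(sweep) > 2) {
    dt <- median(diff(sweep$time_s))
    k <- max(1L, round(smooth_s / dt))
    if (k > 1) {
      sm <- stats::filter(current, rep(1 / k, k), sides = 2)
      current <- ifelse(is.na(sm), current, as.numeric(sm))
    }
  }
  in_w <- sweep$time_s >= window[1] & sweep$time_s <= window[2]
  if (!any(in_w)) stop("out-of-range: no samples inside the window")
  tt <- sweep$time_s[in_w]
  cc <- current[in_w] - bl
  i_pos <- which.max(cc)   # earliest on ties
  i_neg <- which.min(cc)
  pick <- switch(polarity,
    positive = i_pos,
    negative = i_neg,
    auto = if (abs(cc[i_pos]) >= abs(cc[i_neg])) i_pos else i_neg)
  structure(list(step_id = step_id, peak_current = cc[pick],
                 baseline_pA = bl, t_peak = tt[pick],
                 window = window, polarity = polarity, flags = flags),
            class = "step_response")
}

#' Normalize step responses to the patch maximum
#'
#' `I/Imax`: each step's peak current magnitude divided by the largest peak
#' magnitude recorded from that patch, so patches with different channel
#' counts can be compared. Normalization is on magnitudes, so inward-current
#' channels (e.g. MscS at -60 mV) map into \[0, 1\] as well.
#'
#' @param responses list of [peak_current()] results, or a numeric vector of
#'   peak currents (pA).
#' @param stimulus optional per-step stimulus values carried into the output
#'   (tension mN/m, pressure mmHg, or power W/cm2).
#' @param patch_id bookkeeping identifier.
#' @return a `normalized_response`: data.frame with `step_id`, `stimulus`,
#'   `I_over_Imax`, plus attributes `imax_pA` and `patch_id`.
#' @export
normalize_currents <- function(responses, stimulus = NULL, patch_id = NA) {
  if (is.numeric(responses)) {
    peaks <- responses
    ids <- seq_along(peaks)
  } else {
    peaks <- vapply(responses, function(r) r$peak_current, numeric(1))
    ids <- vapply(responses, function(r) as.integer(r$step_id), integer(1))
  }
  if (!length(peaks)) stop("invalid-argument: no responses to normalize")
  mags <- abs(peaks)
  imax <- max(mags)
  if (imax == 0)
    stop("undefined-normalization: all peak currents are zero")
  if (is.null(stimulus)) stimulus <- NA_real_
  out <- data.frame(step_id = ids, stimulus = stimulus,
                    I_over_Imax = mags / imax)
  structure(out, imax_pA = imax, patch_id = patch_id,
            class = c("normalized_response", "data.frame"))
}

#' Fold activation of a patch
#'
#' Ratio of the maximal evoked current magnitude to the basal current
#' magnitude. The basal magnitude is floored to avoid division blow-up on
#' near-zero baselines; a floor of one single-channel current is a physically
#' motivated choice when the baseline is indistinguishable from zero.
#'
#' @param basal_current basal (pre-stimulus) current, pA.
#' @param max_current maximal evoked current, pA.
#' @param floor minimum basal magnitude used in the ratio (pA).
#' @return fold activation (dimensionless).
#' @examples
#' fold_activation(0.5, 20.6)  # 41.2-fold
#' @export
fold_activation <- function(basal_current, max_current, floor = 1e-12) {
  stopifnot(is.numeric(basal_current), is.numeric(max_current), floor >= 0)
  abs(max_current) / pmax(abs(basal_current), floor)
}

#' Quality-control verdict for a patch
#'
#' Two exclusion rules: (1) patches with basal activity above
#' `basal_threshold` of Imax (default 0.25) are not analyzed — a high
#' baseline indicates substantial resting tension or leaky seal and
#' invalidates the normalization floor; (2) a saturating current response is
#' required — the responses at the two largest stimuli must agree within
#' `saturation_tol` of Imax (default 0.10), otherwise Imax (and hence every
#' normalized point) is not pinned down.
#'
#' @param resp a [normalize_currents()] result with stimulus values set (used
#'   to order the steps), or a data.frame with `stimulus` and `I_over_Imax`.
#' @param basal_fraction the patch's basal current as a fraction of Imax.
#' @param basal_threshold exclusion threshold on `basal_fraction`.
#' @param saturation_tol tolerance on the two largest-stimulus responses.
#' @return a `qc_verdict`: list with logical `pass` and character `reasons`
#'   (`"basal"` and/or `"saturation"` on failure).
#' @export
qc_patch <- function(resp, basal_fraction, basal_threshold = 0.25,
                     saturation_tol = 0.10) {
  stopifnot(is.numeric(basal_fraction), length(basal_fraction) == 1)
  reasons <- character(0)
  if (basal_fraction > basal_threshold) reasons <- c(reasons, "basal")
  d <- as.data.frame(resp)
  if (any(is.finite(d$stimulus))) d <- d[is.finite(d$stimulus), , drop = FALSE]
  if (nrow(d) >= 2) {
    ord <- order(d$stimulus)
    top2 <- d$I_over_Imax[tail(ord, 2)]
    if (abs(diff(top2)) > saturation_tol) reasons <- c(reasons, "saturation")
  } else {
    reasons <- c(reasons, "saturation")
  }
  structure(list(pass = length(reasons) == 0, reasons = reasons,
                 basal_fraction = basal_fraction),
            class = "qc_verdict")
}

#' @export
print.qc_verdict <- function(x, ...) {
  if (x$pass) cat("QC: PASS\n")
  else cat("QC: FAIL (", paste(x$reasons, collapse = ", "), ")\n", sep = "")
  invisible(x)
}
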