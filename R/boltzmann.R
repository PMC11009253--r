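#' Two-state Boltzmann open probability
#'
#' `P_O(T) = 1 / (1 + exp((midpoint - T) / slope))`: the open probability of a
#' two-state channel whose opening expands its in-plane cross-sectional area,
#' so that tension `T` tilts the open/closed equilibrium. The same sigmoid is
#' used for pressure- and acoustic-power-domain dose-response curves, where
#' the parameters are empirical.
#'
#' @param stimulus stimulus values (tension mN/m, pressure mmHg, or W/cm2).
#' @param midpoint stimulus at half-maximal activation.
#' @param slope slope factor (same units as stimulus); must be > 0.
#' @return open probability / fractional activation in (0, 1).
#' @export
boltzmann_open_prob <- function(stimulus, midpoint, slope) {
  stopifnot(slope > 0)
  1 / (1 + exp((midpoint - stimulus) / slope))
}

#' Fit a Boltzmann sigmoid to normalized current responses
#'
#' The central model of the package: least-squares fit of
#' \deqn{I/I_{max}(s) = \frac{1}{1 + \exp((s_{50} - s)/k)}}
#' to normalized peak currents versus stimulus, with amplitude fixed at 1
#' (data are normalized to the patch maximum; set `free_amplitude = TRUE` for
#' a sensitivity variant with a free scale). In the tension domain `s_50` is
#' the midpoint tension T50 (mN/m) and `k` the slope factor, from which
#' channel energetics follow (see [channel_energetics()]).
#'
#' `mode = "global"` pools all points (optionally from many patches) into one
#' fit, the primary analysis when single patches do not span the full curve.
#' `mode = "per_patch"` fits each patch separately and reports the mean and
#' SEM of the parameters across patches.
#'
#' Optimization is multi-start quasi-Newton on (midpoint, log slope) with an
#' analytic gradient: one deterministic start (midpoint at the median
#' stimulus, slope at a quarter of the stimulus span) plus `n_starts - 1`
#' jittered restarts drawn under `seed`. Convergence tolerance is 1e-10 on
#' the sum of squares. Parameter covariance comes from the Jacobian at the
#' optimum; 95% confidence intervals are t-based. If the data do not bracket
#' the midpoint (all points clearly below/above half-activation) the fit is
#' flagged `"unbracketed_midpoint"`, and if a CI is wider than the stimulus
#' span it is flagged `"ci_exceeds_span"` — such fits are unreliable.
#'
#' @param formula model formula, `response ~ stimulus`, with the response
#'   already normalized to \[0, 1\].
#' @param data data.frame containing the formula variables (and `patch`).
#' @param mode `"global"` (pool everything) or `"per_patch"`.
#' @param patch optional patch identifier: a column name in `data` or a
#'   vector; required for `mode = "per_patch"`, used for bookkeeping in
#'   global fits.
#' @param stimulus_units unit label carried into downstream energetics
#'   checks; `"mN/m"` for tension fits.
#' @param free_amplitude fit a free amplitude instead of fixing it at 1.
#' @param n_starts number of optimizer starts (>= 1).
#' @param seed RNG seed for the jittered restarts.
#' @return an object of class `boltzmann_fit` with components
#'   `coefficients` (midpoint, slope_factor), `se`, `ci95`, `vcov`,
#'   `r.squared`, `fitted.values`, `residuals`, `data`, `n`, `n_patches`,
#'   `mode`, `stimulus_units`, `ss`, `flags`, and (per-patch mode)
#'   `patch_fits`.
#' @examples
#' s <- seq(0.5, 9, length.out = 24)
#' d <- data.frame(tension = s, resp = boltzmann_open_prob(s, 4.4, 1.7))
#' fit <- fit_boltzmann(resp ~ tension, d)
#' coef(fit)
#' @export
fit_boltzmann <- function(formula, data, mode = c("global", "per_patch"),
                          patch = NULL, stimulus_units = "mN/m",
                          free_amplitude = FALSE, n_starts = 9, seed = 1L) {
  mode <- match.arg(mode)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (ncol(mf) != 2)
    stop("invalid-argument: formula must be response ~ stimulus")
  x <- mf[[2]]
  stim_name <- names(mf)[2]
  if (!is.null(patch)) {
    if (is.character(patch) && length(patch) == 1 && patch %in% names(data))
      patch <- data[[patch]]
    if (length(patch) != nrow(mf))
      stop("invalid-argument: patch must match the data rows")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (!is.null(patch)) patch <- patch[ok]
  if (length(x) < 4)
    stop("insufficient-points: need at least 4 points for a Boltzmann fit")

  if (mode == "per_patch") {
    if (is.null(patch)) stop("invalid-argument: per_patch mode needs patch ids")
    ids <- unique(patch)
    fits <- lapply(ids, function(id) {
      tryCatch(
        fit_boltzmann_core(x[patch == id], y[patch == id],
                           free_amplitude, n_starts, seed),
        error = function(e) e)
    })
    names(fits) <- as.character(ids)
    okf <- !vapply(fits, inherits, logical(1), "error")
    if (!any(okf)) stop("fit-failure: no patch could be fitted")
    cf <- t(vapply(fits[okf], function(f) f$coefficients, numeric(2)))
    est <- colMeans(cf)
    sem <- apply(cf, 2, stats::sd) / sqrt(sum(okf))
    out <- structure(list(
      coefficients = est, se = sem,
      ci95 = cbind(lower = est - 1.96 * sem, upper = est + 1.96 * sem),
      vcov = NULL,
      r.squared = mean(vapply(fits[okf], function(f) f$r.squared, 1)),
      fitted.values = NULL, residuals = NULL,
      data = data.frame(stimulus = x, response = y, patch = patch),
      n = length(x), n_patches = sum(okf), mode = "per_patch",
      stimulus_units = stimulus_units, stim_name = stim_name,
      free_amplitude = free_amplitude, ss = NA_real_,
      flags = if (any(!okf)) "patch_fit_failures" else character(0),
      patch_fits = fits, call = match.call()), class = "boltzmann_fit")
    return(out)
  }

  core <- fit_boltzmann_core(x, y, free_amplitude, n_starts, seed)
  core$data <- data.frame(stimulus = x, response = y,
                          patch = if (is.null(patch)) NA else patch)
  core$n_patches <- if (is.null(patch)) 1L else length(unique(patch))
  core$mode <- "global"
  core$stimulus_units <- stimulus_units
  core$stim_name <- stim_name
  core$call <- match.call()
  core
}

# multi-start least squares on (midpoint, log slope); amplitude optional
fit_boltzmann_core <- function(x, y, free_amplitude = FALSE,
                               n_starts = 9, seed = 1L) {
  if (length(x) < 4)
    stop("insufficient-points: need at least 4 points for a Boltzmann fit")
  x <- unname(x); y <- unname(y)
  span <- diff(range(x))
  if (span <= 0) stop("invalid-argument: stimulus values are all identical")
  npar <- if (free_amplitude) 3L else 2L

  ssfun <- function(par) {
    m <- par[1]; s <- exp(par[2])
    a <- if (free_amplitude) par[3] else 1
    f <- a / (1 + exp((m - x) / s))
    sum((f - y)^2)
  }
  grfun <- function(par) {
    m <- par[1]; s <- exp(par[2])
    a <- if (free_amplitude) par[3] else 1
    p <- 1 / (1 + exp((m - x) / s))
    f <- a * p
    r <- f - y
    dfdm <- -a * p * (1 - p) / s
    dfdls <- a * p * (1 - p) * (m - x) / s
    g <- c(2 * sum(r * dfdm), 2 * sum(r * dfdls))
    if (free_amplitude) g <- c(g, 2 * sum(r * p))
    g
  }

  start0 <- c(median(x), log(span / 4))
  if (free_amplitude) start0 <- c(start0, max(abs(y), 0.5))
  starts <- list(start0)
  if (n_starts > 1) {
    jit <- with_local_seed(seed, function() {
      lapply(seq_len(n_starts - 1), function(i) {
        s <- c(runif(1, min(x), max(x)), log(span / 4) + rnorm(1, 0, 1))
        if (free_amplitude) s <- c(s, max(abs(y), 0.5) * exp(rnorm(1, 0, 0.2)))
        s
      })
    })
    starts <- c(starts, jit)
  }

  best <- NULL
  any_conv <- FALSE
  for (st in starts) {
    opt <- tryCatch(
      optim(st, ssfun, grfun, method = "BFGS",
            control = list(reltol = 1e-14, maxit = 1000)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (opt$convergence == 0) any_conv <- TRUE
    if (is.null(best) || opt$value < best$value - 1e-10) best <- opt
  }
  if (is.null(best) || !any_conv)
    stop(sprintf("fit-failure: Boltzmann fit did not converge in %d starts (best SS %.4g)",
                 length(starts), if (is.null(best)) NA else best$value))

  m <- best$par[1]; s <- exp(best$par[2])
  a <- if (free_amplitude) best$par[3] else 1
  p <- 1 / (1 + exp((m - x) / s))
  f <- a * p
  ss <- best$value
  n <- length(x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss / ss_tot else NA_real_

  # Jacobian w.r.t. (midpoint, slope[, amplitude]) on the natural scale
  J <- cbind(-a * p * (1 - p) / s, a * p * (1 - p) * (m - x) / s^2)
  if (free_amplitude) J <- cbind(J, p)
  dof <- n - npar
  sigma2 <- if (dof > 0) ss / dof else NA_real_
  vc <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  flags <- character(0)
  if (is.null(vc)) {
    se <- rep(NA_real_, npar)
    flags <- c(flags, "singular_information")
  } else {
    se <- sqrt(pmax(diag(vc), 0))
  }
  est_names <- if (free_amplitude) c("midpoint", "slope_factor", "amplitude")
               else c("midpoint", "slope_factor")
  if (!is.null(vc)) dimnames(vc) <- list(est_names, est_names)
  tcrit <- if (dof > 0) qt(0.975, dof) else NA_real_
  est <- c(midpoint = m, slope_factor = s)
  if (free_amplitude) est <- c(est, amplitude = a)
  names(se) <- names(est)
  ci <- cbind(lower = est - tcrit * se, upper = est + tcrit * se)

  # identifiability diagnostics
  if (max(y) < 0.5 * max(a, 1) || min(y) > 0.5 * max(a, 1))
    flags <- c(flags, "unbracketed_midpoint")
  span_x <- diff(range(x))
  if (any(is.finite(ci[1, ])) && diff(ci[1, ]) > 2 * span_x)
    flags <- c(flags, "ci_exceeds_span")

  structure(list(coefficients = est, se = se, ci95 = ci, vcov = vc,
                 r.squared = r2, fitted.values = f, residuals = y - f,
                 data = data.frame(stimulus = x, response = y),
                 n = n, n_patches = 1L, mode = "global",
                 stimulus_units = NA_character_, stim_name = "stimulus",
                 free_amplitude = free_amplitude, ss = ss, flags = flags),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Boltzmann %s fit (%s domain)\n", x$mode, x$stimulus_units))
  cf <- cbind(estimate = x$coefficients, se = x$se, x$ci95)
  print(round(cf, digits))
  cat(sprintf("n = %d points, %d patch(es); R^2 = %.3f\n",
              x$n, x$n_patches, x$r.squared))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.boltzmann_fit <- function(object, ...) {
  ar <- tryCatch(activation_range(object), error = function(e) NULL)
  structure(list(fit = object, activation_range = ar,
                 sigma = if (!is.na(object$ss) && object$n > 2)
                   sqrt(object$ss / (object$n - length(object$coefficients)))
                 else NA_real_),
            class = "summary.boltzmann_fit")
}

#' @export
print.summary.boltzmann_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$activation_range))
    cat(sprintf("10-90%% activation range: %.2f - %.2f %s\n",
                x$activation_range[1], x$activation_range[2],
                x$fit$stimulus_units))
  if (is.finite(x$sigma))
    cat(sprintf("residual sd: %.4f (normalized current units)\n", x$sigma))
  invisible(x)
}

#' @export
coef.boltzmann_fit <- function(object, ...) object$coefficients

#' @export
vcov.boltzmann_fit <- function(object, ...) object$vcov

#' @export
confint.boltzmann_fit <- function(object, parm, level = 0.95, ...) {
  if (level != 0.95)
    stop("invalid-argument: only 95% intervals are stored")
  ci <- object$ci95
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
fitted.boltzmann_fit <- function(object, ...) object$fitted.values

#' @export
residuals.boltzmann_fit <- function(object, ...) object$residuals

#' Predicted fractional activation from a Boltzmann fit
#'
#' @param object a `boltzmann_fit`.
#' @param newdata optional data.frame containing the stimulus variable used
#'   in the fit (or a column named `stimulus`), or a numeric vector of
#'   stimulus values. Defaults to the fitted data.
#' @param ... unused.
#' @return predicted I/Imax values.
#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    s <- object$data$stimulus
  } else if (is.numeric(newdata)) {
    s <- newdata
  } else {
    nm <- if (object$stim_name %in% names(newdata)) object$stim_name
          else "stimulus"
    if (!nm %in% names(newdata))
      stop("invalid-argument: newdata lacks the stimulus variable")
    s <- newdata[[nm]]
  }
  a <- if (object$free_amplitude) object$coefficients[["amplitude"]] else 1
  a * boltzmann_open_prob(s, object$coefficients[["midpoint"]],
                          object$coefficients[["slope_factor"]])
}

#' Simulate normalized responses from a fitted Boltzmann curve
#'
#' Draws `nsim` replicate response vectors at the fitted stimulus values:
#' fitted curve plus iid Gaussian noise at the residual standard deviation.
#'
#' @param object a global-mode `boltzmann_fit`.
#' @param nsim number of replicate data sets.
#' @param seed RNG seed.
#' @param ... unused.
#' @return data.frame with `nsim` columns (`sim_1`, ...), one row per point.
#' @export
simulate.boltzmann_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$fitted.values))
    stop("invalid-argument: simulate needs a global-mode fit")
  sdres <- sqrt(object$ss / max(object$n - length(object$coefficients), 1))
  gen <- function() {
    out <- replicate(nsim, object$fitted.values + rnorm(object$n, 0, sdres))
    out <- as.data.frame(out)
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  }
  if (is.null(seed)) gen() else with_local_seed(seed, gen)
}

#' Plot a Boltzmann fit with its data
#'
#' Normalized responses against stimulus with the fitted sigmoid, midpoint
#' marker, and 10-90% activation range.
#'
#' @param x a `boltzmann_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.boltzmann_fit <- function(x, ...) {
  d <- x$data
  plot(d$stimulus, d$response,
       xlab = sprintf("stimulus (%s)", x$stimulus_units),
       ylab = expression(I / I[max]),
       pch = 16, col = gray(0.35), ...)
  s <- seq(min(d$stimulus), max(d$stimulus), length.out = 200)
  lines(s, boltzmann_open_prob(s, x$coefficients[["midpoint"]],
                               x$coefficients[["slope_factor"]]), lwd = 2)
  abline(v = x$coefficients[["midpoint"]], lty = 2)
  ar <- tryCatch(activation_range(x), error = function(e) NULL)
  if (!is.null(ar)) abline(v = ar, lty = 3, col = gray(0.5))
  invisible(x)
}
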