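#' Time-resolved fluorescence image stack
#'
#' Container for patch fluorescence movies: a list of equally sized intensity
#' matrices with the acquisition frame rate and pixel scale. Frames may be a
#' dense movie (implicit times `(i - 1) / frame_rate`) or a sparse selection
#' of analyzed frames with explicit `frame_times`.
#'
#' @param frames list of numeric matrices, all the same dimension.
#' @param frame_rate acquisition rate in Hz (default 120).
#' @param pixel_scale micrometres per pixel.
#' @param frame_times optional explicit frame times in seconds (sparse stacks).
#' @param roi optional default detection region, `list(rows =, cols =)`.
#' @return an `image_stack` object.
#' @export
image_stack <- function(frames, frame_rate = 120, pixel_scale,
                        frame_times = NULL, roi = NULL) {
  stopifnot(is.list(frames), frame_rate > 0, pixel_scale > 0)
  if (length(frames)) {
    dims <- vapply(frames, dim, integer(2))
    if (any(dims != dims[, 1])) stop("invalid-argument: frames differ in shape")
  }
  if (!is.null(frame_times) && length(frame_times) != length(frames))
    stop("invalid-argument: one frame_time per frame required")
  structure(list(frames = frames, frame_rate = frame_rate,
                 pixel_scale = pixel_scale, frame_times = frame_times,
                 roi = roi),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- if (length(x$frames)) dim(x$frames[[1]]) else c(0, 0)
  cat(sprintf("Image stack: %d frame(s) of %dx%d px, %g Hz, %g um/px%s\n",
              length(x$frames), d[1], d[2], x$frame_rate, x$pixel_scale,
              if (is.null(x$frame_times)) "" else " (sparse times)"))
  invisible(x)
}

#' Frame index matching a stimulus time
#'
#' Movie frames are time-matched to the stimulus record by multiplying frame
#' rate and time: index `floor(t * frame_rate) + 1` (1-based), clamped to the
#' stack. For sparse stacks with explicit `frame_times`, the nearest recorded
#' frame is returned instead.
#'
#' @param stack an [image_stack()].
#' @param t time in seconds; must lie within the stack duration.
#' @return integer frame index (1-based).
#' @export
frame_index_for_time <- function(stack, t) {
  stopifnot(inherits(stack, "image_stack"), is.numeric(t), length(t) == 1)
  n <- length(stack$frames)
  if (n == 0) stop("out-of-range: empty stack")
  if (!is.null(stack$frame_times)) {
    ft <- stack$frame_times
    margin <- max(1 / stack$frame_rate,
                  if (length(ft) > 1) median(diff(sort(ft))) / 2 else Inf)
    if (t < min(ft) - margin || t > max(ft) + margin)
      stop("out-of-range: time outside recorded frames")
    return(which.min(abs(ft - t)))
  }
  duration <- n / stack$frame_rate
  if (t < 0 || t > duration)
    stop("out-of-range: time outside stack duration")
  as.integer(min(floor(t * stack$frame_rate) + 1, n))
}

#' Detect membrane points as the brightest pixel per row
#'
#' Within the region of interest, the maximum-intensity column of every row is
#' selected as a membrane point — the fluorescently labelled membrane arc is
#' the dominant bright structure crossing each row. Ties are broken toward the
#' smallest column index (deterministic and order-independent). Optional
#' contrast enhancement clips intensities at the 1st/99th percentiles before
#' detection only; stored data are never modified.
#'
#' @param frame numeric intensity matrix (rows x columns).
#' @param roi `list(rows =, cols =)` of integer index vectors; must be
#'   non-empty and inside the frame.
#' @param enhance logical; percentile contrast clipping before detection.
#' @return a `membrane_points` object: data.frame with `row`, `col`,
#'   `intensity` (one point per ROI row) and a `frame_index` attribute.
#' @export
detect_membrane_points <- function(frame, roi = NULL, enhance = FALSE) {
  stopifnot(is.matrix(frame), is.numeric(frame))
  if (is.null(roi)) roi <- list(rows = seq_len(nrow(frame)),
                                cols = seq_len(ncol(frame)))
  rows <- as.integer(roi$rows); cols <- as.integer(roi$cols)
  if (!length(rows) || !length(cols))
    stop("invalid-argument: empty ROI")
  if (min(rows) < 1 || max(rows) > nrow(frame) ||
      min(cols) < 1 || max(cols) > ncol(frame))
    stop("invalid-argument: ROI outside frame")
  sub <- frame[rows, cols, drop = FALSE]
  if (enhance) {
    q <- stats::quantile(sub, c(0.01, 0.99), names = FALSE)
    if (q[2] > q[1]) sub <- pmin(pmax(sub, q[1]), q[2])
  }
  idx <- apply(sub, 1, which.max)   # which.max: first (leftmost) on ties
  pts <- data.frame(row = rows, col = cols[idx],
                    intensity = sub[cbind(seq_along(rows), idx)])
  membrane_points(pts, frame_index = NA_integer_)
}

#' @rdname detect_membrane_points
#' @param pts data.frame with columns `row`, `col` and optionally `intensity`.
#' @param frame_index frame provenance.
#' @export
membrane_points <- function(pts, frame_index = NA_integer_) {
  stopifnot(all(c("row", "col") %in% names(pts)))
  if (anyDuplicated(pts$row))
    stop("invalid-argument: at most one point per row")
  if (!"intensity" %in% names(pts)) pts$intensity <- NA_real_
  pts <- pts[order(pts$row), c("row", "col", "intensity")]
  rownames(pts) <- NULL
  structure(pts, frame_index = frame_index,
            class = c("membrane_points", "data.frame"))
}

# re-wrap a filtered subset, preserving provenance
subset_points <- function(pts, keep) {
  membrane_points(as.data.frame(pts)[keep, , drop = FALSE],
                  frame_index = attr(pts, "frame_index"))
}

#' Remove outlier membrane points to enforce continuity
#'
#' The brightest-pixel rule occasionally latches onto debris or noise off the
#' membrane; outlier coordinates are removed with one of three filters before
#' circle fitting:
#' \describe{
#'   \item{`max_jump`}{walk the rows in order and drop any point whose column
#'     differs from the previously retained point by more than `threshold`
#'     pixels (default 5). Cheap; assumes the arc is locally smooth.}
#'   \item{`median_residual`}{fit a provisional algebraic circle to all
#'     points, then drop points whose absolute radial residual exceeds
#'     `c_mult` (default 3) times the median absolute residual.}
#'   \item{`ransac_circle`}{repeatedly fit exact circles through random point
#'     triples and keep the largest consensus set with radial residuals within
#'     `tol` pixels (default 2; `iters` = 500 draws, seeded).}
#' }
#'
#' @param pts a `membrane_points` set with at least 3 points.
#' @param method filter choice.
#' @param threshold `max_jump` column-jump limit in px.
#' @param c_mult `median_residual` multiplier.
#' @param tol,iters,seed `ransac_circle` inlier tolerance (px), iteration
#'   count, and RNG seed.
#' @return the retained `membrane_points` subset.
#' @export
enforce_continuity <- function(pts,
                               method = c("max_jump", "median_residual",
                                          "ransac_circle"),
                               threshold = 5, c_mult = 3,
                               tol = 2, iters = 500, seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(pts, "membrane_points"))
  n <- nrow(pts)
  if (n < 3) stop("insufficient-points: need at least 3 points")
  keep <- switch(method,
    max_jump = {
      k <- logical(n); k[1] <- TRUE
      last <- pts$col[1]
      for (i in seq_len(n)[-1]) {
        if (abs(pts$col[i] - last) <= threshold) {
          k[i] <- TRUE
          last <- pts$col[i]
        }
      }
      k
    },
    median_residual = {
      # iterate: outliers drag the provisional circle, so refit on the
      # retained set until membership stabilizes
      k <- rep(TRUE, n)
      for (it in 1:10) {
        fit <- fit_circle_algebraic(subset_points(pts, k))
        d <- sqrt((pts$col - fit$center[1])^2 + (pts$row - fit$center[2])^2)
        res <- abs(d - fit$radius_px)
        med <- median(res[k])
        k_new <- k & (res <= max(c_mult * med, 1e-9))
        if (sum(k_new) < 3 || identical(k_new, k)) { k <- k_new; break }
        k <- k_new
      }
      k
    },
    ransac_circle = {
      best <- NULL
      valid_model <- FALSE
      with_local_seed(seed, function() {
        for (it in seq_len(iters)) {
          tri <- sample.int(n, 3)
          fit <- tryCatch(
            fit_circle_three_point(c(pts$col[tri[1]], pts$row[tri[1]]),
                                   c(pts$col[tri[2]], pts$row[tri[2]]),
                                   c(pts$col[tri[3]], pts$row[tri[3]])),
            error = function(e) NULL)
          if (is.null(fit)) next
          valid_model <<- TRUE
          d <- sqrt((pts$col - fit$center[1])^2 + (pts$row - fit$center[2])^2)
          inl <- abs(d - fit$radius_px) <= tol
          if (is.null(best) || sum(inl) > sum(best)) best <<- inl
        }
      })
      if (!valid_model || is.null(best))
        stop("insufficient-points: no valid circle consensus (degenerate geometry)")
      best
    })
  if (sum(keep) < 3)
    stop("insufficient-points: fewer than 3 points survive continuity filtering")
  subset_points(pts, keep)
}

#' Read and write image stacks as plain-text CSV
#'
#' Stacks are serialized to a long-format CSV (`frame`, `time_s`, `row`,
#' `col`, `intensity`) with stack metadata in a JSON sidecar
#' (`<path>.meta.json`). A text format is used so synthetic fixtures stay
#' human-inspectable and portable.
#'
#' @param stack an [image_stack()].
#' @param path CSV file path.
#' @return `write_stack_csv` returns `path` invisibly; `read_stack_csv`
#'   returns an [image_stack()].
#' @export
write_stack_csv <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  times <- stack$frame_times
  if (is.null(times)) times <- (seq_along(stack$frames) - 1) / stack$frame_rate
  tabs <- lapply(seq_along(stack$frames), function(i) {
    f <- stack$frames[[i]]
    data.frame(frame = i, time_s = times[i],
               row = rep(seq_len(nrow(f)), times = ncol(f)),
               col = rep(seq_len(ncol(f)), each = nrow(f)),
               intensity = as.vector(f))
  })
  write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  meta <- list(frame_rate = stack$frame_rate, pixel_scale = stack$pixel_scale,
               frame_times = times, roi = stack$roi,
               dim = if (length(stack$frames)) dim(stack$frames[[1]]) else c(0, 0))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack_csv
#' @export
read_stack_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  tab <- read.csv(path)
  frames <- lapply(split(tab, tab$frame), function(d) {
    f <- matrix(0, meta$dim[1], meta$dim[2])
    f[cbind(d$row, d$col)] <- d$intensity
    f
  })
  names(frames) <- NULL
  # roi is read un-simplified: it is either one region or a per-frame list
  raw <- jsonlite::read_json(paste0(path, ".meta.json"),
                             simplifyVector = FALSE)
  roi <- NULL
  if (!is.null(raw$roi)) {
    as_region <- function(r) list(rows = as.integer(unlist(r$rows)),
                                  cols = as.integer(unlist(r$cols)))
    roi <- if (!is.null(raw$roi$rows)) as_region(raw$roi)
           else lapply(raw$roi, as_region)
  }
  image_stack(frames, frame_rate = meta$frame_rate,
              pixel_scale = meta$pixel_scale,
              frame_times = as.numeric(meta$frame_times), roi = roi)
}
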