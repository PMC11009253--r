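#' @rdname fit_circle_algebraic
#' @param center,radius_px,rms_residual_px,n_points,method internal constructor
#'   fields.
#' @export
circle_fit <- function(center, radius_px, rms_residual_px, n_points, method) {
  stopifnot(radius_px > 0)
  structure(
    list(center = c(x = unname(center[1]), y = unname(center[2])),
         radius_px = unname(radius_px), radius_um = NA_real_,
         rms_residual_px = unname(rms_residual_px), n_points = n_points,
         method = method),
    class = "circle_fit"
  )
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("Circle fit (%s): center (%.3f, %.3f) px, radius %.3f px",
              x$method, x$center[1], x$center[2], x$radius_px))
  if (!is.na(x$radius_um)) cat(sprintf(" = %.4f um", x$radius_um))
  cat(sprintf("\n  n = %d points, rms residual %.4g px\n",
              x$n_points, x$rms_residual_px))
  invisible(x)
}

#' Exact circle through three points
#'
#' Solves the circle through three non-collinear pixel coordinates via the
#' determinant intermediates
#' \deqn{A = x_1(y_2-y_3) - y_1(x_2-x_3) + x_2 y_3 - x_3 y_2}
#' \deqn{B = (x_1^2+y_1^2)(y_3-y_2) + (x_2^2+y_2^2)(y_1-y_3) + (x_3^2+y_3^2)(y_2-y_1)}
#' \deqn{C = (x_1^2+y_1^2)(x_2-x_3) + (x_2^2+y_2^2)(x_3-x_1) + (x_3^2+y_3^2)(x_1-x_2)}
#' \deqn{D = (x_1^2+y_1^2)(x_3 y_2-x_2 y_3) + (x_2^2+y_2^2)(x_1 y_3-x_3 y_1) +
#'          (x_3^2+y_3^2)(x_2 y_1-x_1 y_2)}
#' giving center \eqn{(-B/2A, -C/2A)} and radius
#' \eqn{\sqrt{(B^2 + C^2 - 4AD)/(4A^2)}}. This is the manual three-point
#' method: points are picked along the fluorescent membrane curve and the
#' resulting circle is overlaid on the image for validation.
#'
#' @param p1,p2,p3 numeric length-2 vectors `c(x, y)` in pixels
#'   (x = column, y = row).
#' @return a `circle_fit` (rms residual 0 by construction).
#' @examples
#' fit_circle_three_point(c(0, 1), c(1, 0), c(0, -1))  # unit circle
#' @export
fit_circle_three_point <- function(p1, p2, p3) {
  pts <- rbind(p1, p2, p3)
  if (!is.numeric(pts) || ncol(pts) != 2 || any(!is.finite(pts)))
    stop("invalid-argument: points must be finite length-2 numeric vectors")
  if (any(duplicated(pts))) stop("invalid-argument: points must be distinct")
  x <- pts[, 1]; y <- pts[, 2]
  A <- x[1] * (y[2] - y[3]) - y[1] * (x[2] - x[3]) + x[2] * y[3] - x[3] * y[2]
  s <- x^2 + y^2
  B <- s[1] * (y[3] - y[2]) + s[2] * (y[1] - y[3]) + s[3] * (y[2] - y[1])
  C <- s[1] * (x[2] - x[3]) + s[2] * (x[3] - x[1]) + s[3] * (x[1] - x[2])
  D <- s[1] * (x[3] * y[2] - x[2] * y[3]) + s[2] * (x[1] * y[3] - x[3] * y[1]) +
    s[3] * (x[2] * y[1] - x[1] * y[2])
  scale2 <- max(1, max(abs(s)))
  if (abs(A) <= 1e-12 * scale2)
    stop("degenerate-geometry: the three points are collinear")
  center <- c(-B / (2 * A), -C / (2 * A))
  radius <- sqrt((B^2 + C^2 - 4 * A * D) / (4 * A^2))
  circle_fit(center, radius, 0, 3L, "three_point")
}

# extract an (x, y) matrix from a membrane_points object or x/y input
as_xy <- function(pts) {
  if (inherits(pts, "membrane_points")) {
    cbind(x = pts$col, y = pts$row)
  } else if (is.matrix(pts) || is.data.frame(pts)) {
    m <- as.matrix(pts[, 1:2])
    colnames(m) <- c("x", "y")
    m
  } else stop("invalid-argument: expected membrane points or an (x, y) matrix")
}

#' Least-squares circle fit to a point set
#'
#' Fits a circle to the detected membrane point list. The algebraic (Kasa) fit
#' minimizes \eqn{\sum_i (x_i^2 + y_i^2 + a x_i + b y_i + c)^2} in closed form
#' via the linear normal equations; `refine = "geometric"` polishes it by
#' minimizing the orthogonal residuals \eqn{\sum_i (d_i - r)^2} over the
#' center (with \eqn{r = \bar d} profiled out). Both report the geometric rms
#' residual \eqn{\sqrt{\mathrm{mean}((d_i - r)^2)}} in pixels.
#'
#' On exactly three non-collinear points both routes interpolate and agree
#' with [fit_circle_three_point()] to numerical precision.
#'
#' @param pts a `membrane_points` object, or a matrix/data.frame whose first
#'   two columns are x (column) and y (row) pixel coordinates.
#' @param refine `"none"` (pure algebraic) or `"geometric"`.
#' @return a `circle_fit` with method `"algebraic"` or `"geometric"`.
#' @seealso [fit_circle_three_point()], [radius_physical()]
#' @export
fit_circle_algebraic <- function(pts, refine = c("none", "geometric")) {
  refine <- match.arg(refine)
  xy <- as_xy(pts)
  if (nrow(xy) < 3) stop("insufficient-points: need at least 3 points")
  x <- xy[, 1]; y <- xy[, 2]
  M <- cbind(x, y, 1)
  rhs <- -(x^2 + y^2)
  qrM <- qr(M)
  if (qrM$rank < 3)
    stop("degenerate-geometry: points are collinear (rank-deficient fit)")
  abc <- qr.coef(qrM, rhs)
  center <- c(-abc[1] / 2, -abc[2] / 2)
  r2 <- sum(center^2) - abc[3]
  if (!is.finite(r2) || r2 <= 0)
    stop("degenerate-geometry: no real circle fits these points")
  radius <- sqrt(r2)
  method <- "algebraic"
  if (refine == "geometric") {
    obj <- function(cc) {
      d <- sqrt((x - cc[1])^2 + (y - cc[2])^2)
      sum((d - mean(d))^2)
    }
    opt <- optim(center, obj, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 500))
    center <- opt$par
    radius <- mean(sqrt((x - center[1])^2 + (y - center[2])^2))
    method <- "geometric"
  }
  d <- sqrt((x - center[1])^2 + (y - center[2])^2)
  rms <- sqrt(mean((d - radius)^2))
  circle_fit(center, radius, rms, nrow(xy), method)
}

#' Convert a fitted radius from pixels to micrometres
#'
#' @param fit a `circle_fit`, or a numeric radius in pixels.
#' @param pixel_scale micrometres per pixel; must be > 0.
#' @return for a `circle_fit`, the same object with `radius_um` filled in;
#'   for a numeric input, the radius in micrometres.
#' @examples
#' radius_physical(100, 0.05)  # 5 um
#' @export
radius_physical <- function(fit, pixel_scale) {
  stopifnot(is.numeric(pixel_scale), pixel_scale > 0)
  if (is.numeric(fit)) return(fit * pixel_scale)
  stopifnot(inherits(fit, "circle_fit"))
  fit$radius_um <- fit$radius_px * pixel_scale
  fit
}
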