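# Fixture generators shared across tests. These stay independent of the
# package's rendering/detection path: arcs are sampled analytically.

# points on a circle, optionally with isotropic Gaussian noise
make_arc_points <- function(center = c(0, 0), r = 50, n = 100,
                            theta = c(pi / 4, 3 * pi / 4), noise_sd = 0,
                            seed = NULL) {
  gen <- function() {
    th <- seq(theta[1], theta[2], length.out = n)
    x <- center[1] + r * cos(th)
    y <- center[2] + r * sin(th)
    if (noise_sd > 0) {
      x <- x + rnorm(n, 0, noise_sd)
      y <- y + rnorm(n, 0, noise_sd)
    }
    cbind(x = x, y = y)
  }
  if (is.null(seed)) gen() else { set.seed(seed); gen() }
}

# a membrane_points object tracing a circle: one point per row, as the
# brightest-pixel detector would produce (columns need not be integers here)
make_arc_rows <- function(center_col = 100, center_row = 64, r = 60,
                          rows = NULL, side = "left") {
  if (is.null(rows))
    rows <- seq(ceiling(center_row - 0.8 * r), floor(center_row + 0.8 * r))
  dy <- rows - center_row
  dx <- sqrt(r^2 - dy^2)
  col <- if (side == "left") center_col - dx else center_col + dx
  membrane_points(data.frame(row = rows, col = col, intensity = 1))
}

# closed-form Boltzmann used as an independent oracle (deliberately not the
# package's boltzmann_open_prob)
oracle_sigmoid <- function(s, mid, slope) 1 / (1 + exp((mid - s) / slope))

# brute-force 2-D grid search minimizing the Boltzmann SS; the independent
# optimizer oracle
grid_search_boltzmann <- function(x, y, mid_range, slope_range,
                                  n_mid = 2000, n_slope = 2000,
                                  chunk = 100) {
  mids <- seq(mid_range[1], mid_range[2], length.out = n_mid)
  slopes <- seq(slope_range[1], slope_range[2], length.out = n_slope)
  best <- list(ss = Inf, mid = NA, slope = NA)
  for (i0 in seq(1, n_slope, by = chunk)) {
    sl <- slopes[i0:min(i0 + chunk - 1, n_slope)]
    for (s in sl) {
      # vectorized over the midpoint grid: n_mid x n_points
      f <- 1 / (1 + exp(outer(mids, x, "-") / s))
      ss <- rowSums((f - matrix(y, n_mid, length(y), byrow = TRUE))^2)
      k <- which.min(ss)
      if (ss[k] < best$ss) best <- list(ss = ss[k], mid = mids[k], slope = s)
    }
  }
  best$cell_mid <- diff(mid_range) / (n_mid - 1)
  best$cell_slope <- diff(slope_range) / (n_slope - 1)
  best
}
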