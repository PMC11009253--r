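make_test_stack <- function(n_frames = 3, dim = c(8, 8), rate = 120) {
  image_stack(replicate(n_frames, matrix(0, dim[1], dim[2]),
                        simplify = FALSE),
              frame_rate = rate, pixel_scale = 0.05)
}

test_that("frame lookup multiplies frame rate and time, with clamping", {
  stack <- make_test_stack(n_frames = 120, rate = 120)
  expect_identical(frame_index_for_time(stack, 0), 1L)
  # 120 Hz, t = 0.5 s -> the 61st frame holds [0.5, 0.5083) s
  expect_equal(frame_index_for_time(stack, 0.5), 61)
  # exactly at the stack duration: clamp to the last frame
  expect_equal(frame_index_for_time(stack, 1.0), 120)
  expect_error(frame_index_for_time(stack, -0.01), "out-of-range")
  expect_error(frame_index_for_time(stack, 1.01), "out-of-range")
})

test_that("sparse stacks match times to the nearest recorded frame", {
  stack <- image_stack(replicate(3, matrix(0, 4, 4), simplify = FALSE),
                       frame_rate = 120, pixel_scale = 0.05,
                       frame_times = c(0.75, 1.75, 2.75))
  expect_equal(frame_index_for_time(stack, 1.70), 2)
  expect_equal(frame_index_for_time(stack, 0.51), 1)
  expect_error(frame_index_for_time(stack, 5.0), "out-of-range")
})

test_that("brightest-pixel detection matches the rendered arc exactly", {
  g <- geometry_model(frame_dim = c(64, 64))
  r_um <- 1.6  # 32 px
  frame <- render_patch_frame(g, r_um, arc_center = c(14, 32), noise_sd = 0)
  rows <- 10:54
  pts <- detect_membrane_points(frame, roi = list(rows = rows, cols = 1:64))
  # analytic arc: apex at col 14, center (14 + r_px, 32)
  r_px <- r_um / g$pixel_scale
  expect_cols <- round(14 + r_px - sqrt(r_px^2 - (rows - 32)^2))
  expect_equal(pts$col, expect_cols)
  expect_equal(pts$row, rows)
})

test_that("detection tie-breaks to the leftmost column and handles tiny ROIs", {
  flat <- matrix(1, 10, 10)
  pts <- detect_membrane_points(flat, roi = list(rows = 1:10, cols = 1:10))
  expect_true(all(pts$col == 1))
  one <- detect_membrane_points(flat, roi = list(rows = 5, cols = 2:9))
  expect_equal(nrow(one), 1)
  expect_equal(one$col, 2)
  expect_error(detect_membrane_points(flat, roi = list(rows = integer(0),
                                                       cols = 1:10)),
               "invalid-argument")
  expect_error(detect_membrane_points(flat, roi = list(rows = 1:11,
                                                       cols = 1:10)),
               "invalid-argument")
})

test_that("all three continuity filters keep clean arcs and remove implanted outliers", {
  arc <- make_arc_rows(center_col = 110, center_row = 60, r = 55,
                       rows = 20:100)
  arc$col <- round(arc$col)
  arc <- membrane_points(as.data.frame(arc))
  n <- nrow(arc)
  # clean arc: everything retained
  for (m in c("max_jump", "median_residual", "ransac_circle"))
    expect_equal(nrow(enforce_continuity(arc, m)), n)

  # implant 5 outliers >= 20 px off-curve (replacing detections on 5 rows)
  bad_rows <- c(25, 40, 60, 80, 95)
  spoiled <- as.data.frame(arc)
  spoiled$col[spoiled$row %in% bad_rows] <-
    spoiled$col[spoiled$row %in% bad_rows] + c(25, -30, 40, 22, -28)
  spoiled <- membrane_points(spoiled)
  for (m in c("max_jump", "median_residual", "ransac_circle")) {
    kept <- enforce_continuity(spoiled, m)
    expect_false(any(kept$row %in% bad_rows), info = m)
  }
  # ransac with tol 2 px removes all 5 outliers and no inliers
  kept <- enforce_continuity(spoiled, "ransac_circle", tol = 2, seed = 5)
  expect_setequal(kept$row, setdiff(arc$row, bad_rows))
})

test_that("ransac on collinear points reports insufficient consensus", {
  line <- membrane_points(data.frame(row = 1:20, col = 2 * (1:20)))
  expect_error(enforce_continuity(line, "ransac_circle"),
               "insufficient-points")
  expect_error(enforce_continuity(line[1:2, ], "max_jump"),
               "insufficient-points")
})

test_that("rendered frames are deterministic and fail outside the frame", {
  g <- geometry_model(frame_dim = c(32, 32))
  f1 <- render_patch_frame(g, 0.8, c(8, 16), noise_sd = 5, seed = 42)
  f2 <- render_patch_frame(g, 0.8, c(8, 16), noise_sd = 5, seed = 42)
  f3 <- render_patch_frame(g, 0.8, c(8, 16), noise_sd = 5, seed = 43)
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
  expect_error(render_patch_frame(g, 0.8, c(40, 16)), "invalid-geometry")
})

test_that("render -> detect -> fit round-trips the radius within half a pixel", {
  g <- geometry_model(frame_dim = c(128, 128))
  for (r_px in c(30, 45, 60)) {
    r_um <- r_px * g$pixel_scale
    frame <- render_patch_frame(g, r_um, arc_center = c(20, 64), noise_sd = 0)
    half <- floor(0.85 * r_px)
    pts <- detect_membrane_points(frame,
                                  roi = list(rows = (64 - half):(64 + half),
                                             cols = 1:128))
    fit <- fit_circle_algebraic(pts)
    expect_lt(abs(fit$radius_px - r_px), 0.5)
    # physical round trip
    fit <- radius_physical(fit, g$pixel_scale)
    expect_lt(abs(fit$radius_um - r_um), 0.5 * g$pixel_scale)
  }
})

test_that("image stacks survive a CSV round trip", {
  g <- geometry_model(frame_dim = c(16, 16))
  frames <- list(render_patch_frame(g, 0.4, c(4, 8), noise_sd = 2, seed = 1),
                 render_patch_frame(g, 0.5, c(4, 8), noise_sd = 2, seed = 2))
  stack <- image_stack(frames, frame_rate = 120, pixel_scale = 0.05,
                       frame_times = c(0.25, 0.75),
                       roi = list(rows = 3:14, cols = 1:16))
  path <- file.path(tempdir(), "stack_roundtrip.csv")
  write_stack_csv(stack, path)
  back <- read_stack_csv(path)
  expect_equal(back$frames, stack$frames, tolerance = 1e-12)
  expect_equal(back$pixel_scale, stack$pixel_scale)
  expect_equal(back$frame_times, stack$frame_times)
  expect_equal(back$roi$rows, 3:14)
})
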