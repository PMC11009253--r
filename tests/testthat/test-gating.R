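make_step_sweep <- function(plateau = 50, baseline = 5, t_on = 0.5,
                            t_off = 1.0, total = 1.5, rate = 1000) {
  t <- seq(0, total, by = 1 / rate)
  i <- ifelse(t >= t_on & t < t_off, plateau, baseline)
  data.frame(time_s = t, current_pA = i)
}

test_that("peak extraction recovers plateaus, polarities, and tie order", {
  sw <- make_step_sweep(plateau = 50, baseline = 5)
  r <- peak_current(sw, c(0.5, 1.0))
  expect_equal(r$peak_current, 45)        # baseline-subtracted by default
  r2 <- peak_current(sw, c(0.5, 1.0), baseline = "none")
  expect_equal(r2$peak_current, 50)       # against amplifier zero
  expect_equal(r2$baseline_pA, 0)

  # flat trace: zero after baseline subtraction
  flat <- make_step_sweep(plateau = 5, baseline = 5)
  expect_equal(peak_current(flat, c(0.5, 1.0))$peak_current, 0)

  # inward current (negative polarity), auto-detected
  neg <- make_step_sweep(plateau = -120, baseline = -3)
  rn <- peak_current(neg, c(0.5, 1.0))
  expect_equal(rn$peak_current, -117)

  # two equal extrema: the earliest wins
  sw2 <- data.frame(time_s = seq(0, 1, by = 0.01),
                    current_pA = 0)
  sw2$current_pA[c(31, 71)] <- 10
  rt <- peak_current(sw2, c(0.2, 0.9), baseline = "none")
  expect_equal(rt$t_peak, 0.30)

  expect_error(peak_current(sw, c(5, 6)), "out-of-range")
})

test_that("smoothed peak picking suppresses the noise order-statistic bias", {
  set.seed(8)
  sw <- make_step_sweep(plateau = 100, baseline = 0, rate = 2000)
  sw$current_pA <- sw$current_pA + rnorm(nrow(sw), 0, 5)
  raw <- peak_current(sw, c(0.5, 1.0), baseline = "none")$peak_current
  smo <- peak_current(sw, c(0.5, 1.0), baseline = "none",
                      smooth_s = 0.05)$peak_current
  expect_gt(raw, 110)            # raw max rides the noise
  expect_lt(abs(smo - 100), 5)   # smoothed peak sits near the plateau
})

test_that("normalization maps magnitudes onto [0, 1] with the max at 1", {
  n <- normalize_currents(c(1, 2, 4))
  expect_equal(n$I_over_Imax, c(0.25, 0.5, 1))
  expect_equal(normalize_currents(7)$I_over_Imax, 1)
  # inward-current channels normalize on magnitudes
  nm <- normalize_currents(c(-3, -6, -12, -1.5))
  expect_true(all(nm$I_over_Imax >= 0 & nm$I_over_Imax <= 1))
  expect_equal(sum(nm$I_over_Imax == 1), 1)
  expect_error(normalize_currents(c(0, 0)), "undefined-normalization")
})

test_that("fold activation divides max by floored basal magnitude", {
  expect_equal(fold_activation(0.5, 20.6), 41.2)
  expect_equal(fold_activation(3, 3), 1)
  expect_equal(fold_activation(0, 10, floor = 1), 10)
  # closed-form oracle: simulated patch fold = P_O(T_max) / P_O(T_basal)
  po <- function(T) 1 / (1 + exp((4.4 - T) / 1.7))
  ch <- channel_model(T50_true = 4.4, slope_true = 1.7, n_channels = 100,
                      i_single = 1, basal_tension = 0.5,
                      current_noise_sd = 0)
  basal <- simulate_currents(ch, 0.5)
  maxc <- simulate_currents(ch, 9)
  expect_equal(fold_activation(basal, maxc), po(9) / po(0.5),
               tolerance = 1e-12)
})

test_that("QC enforces the basal-activity cap and saturation requirement", {
  resp <- data.frame(stimulus = c(2, 4, 6, 8, 10),
                     I_over_Imax = c(0.1, 0.3, 0.7, 0.93, 1.0))
  v <- qc_patch(resp, basal_fraction = 0.10)
  expect_true(v$pass)
  # basal activity above 0.25 of Imax: excluded
  v2 <- qc_patch(resp, basal_fraction = 0.30)
  expect_false(v2$pass)
  expect_true("basal" %in% v2$reasons)
  # two largest-stimulus responses within 0.10: saturating
  expect_true(qc_patch(data.frame(stimulus = 1:4,
                                  I_over_Imax = c(0.2, 0.6, 0.93, 0.97)),
                       0.05)$pass)
  # ramp still rising at the top: not saturating
  v3 <- qc_patch(data.frame(stimulus = 1:4,
                            I_over_Imax = c(0.1, 0.3, 0.6, 1.0)), 0.05)
  expect_false(v3$pass)
  expect_true("saturation" %in% v3$reasons)
})
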