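test_that("pressure protocols annotate steps and handle degenerate inputs", {
  p <- make_pressure_protocol(c(-5, -10, -20, -40, -80, -140),
                              step_duration = 0.5, inter_step = 0.5)
  expect_equal(nrow(p$steps), 6)
  expect_equal(p$steps$t_off - p$steps$t_on, rep(0.5, 6))
  # trace is piecewise constant at the annotated pressures
  for (i in 1:6) {
    in_step <- p$time_s >= p$steps$t_on[i] & p$time_s < p$steps$t_off[i]
    expect_true(all(p$pressure_mmHg[in_step] == p$steps$pressure_mmHg[i]))
  }
  expect_true(all(p$pressure_mmHg[p$time_s < p$steps$t_on[1]] == 0))

  empty <- make_pressure_protocol(numeric(0))
  expect_equal(length(empty$time_s), 0)
  expect_equal(nrow(empty$steps), 0)

  zero <- make_pressure_protocol(0)
  expect_true(all(zero$pressure_mmHg == 0))
  expect_error(make_pressure_protocol(-10, step_duration = 0),
               "invalid-argument")
})

test_that("patch radius decreases hyperbolically toward the pipette radius", {
  g <- geometry_model(pipette_radius = 1.5, compliance_pressure = 20)
  expect_equal(patch_radius_for_pressure(g, -20), 3.0)
  expect_equal(patch_radius_for_pressure(g, 0), g$flat_cap)
  # asymptote: at |dP| = 1e4 x compliance the radius is the pipette radius
  # within 0.1%
  r_far <- patch_radius_for_pressure(g, -1e4 * 20)
  expect_lt(abs(r_far - 1.5) / 1.5, 1e-3)
  # monotone non-increasing in |dP|, hence tension strictly increasing
  dP <- seq(1, 120, by = 1)
  r <- patch_radius_for_pressure(g, -dP)
  expect_true(all(diff(r) <= 0))
  T <- 0.066661 * dP * r
  expect_true(all(diff(T) > 0))
})

test_that("simulated currents follow the two-state model with seedable noise", {
  ch <- channel_model(T50_true = 4.4, slope_true = 1.7, n_channels = 200,
                      i_single = 2, current_noise_sd = 0)
  # midpoint tension: exactly half of the channels conduct
  expect_equal(simulate_currents(ch, 4.4), 0.5 * 200 * 2)
  # zero tension: closed-form floor (~7% of max for TRAAK parameters)
  expect_equal(simulate_currents(ch, 0), 200 * 2 / (1 + exp(4.4 / 1.7)),
               tolerance = 1e-12)
  expect_equal(simulate_currents(ch, 0) / (200 * 2), 0.070, tolerance = 5e-3)
  # monotone in tension when noise-free
  ramp <- seq(0, 12, length.out = 100)
  expect_true(all(diff(simulate_currents(ch, ramp)) > 0))
  # noise is reproducible given the seed
  chn <- channel_model(current_noise_sd = 10)
  expect_identical(simulate_currents(chn, ramp, seed = 3),
                   simulate_currents(chn, ramp, seed = 3))
  expect_false(identical(simulate_currents(chn, ramp, seed = 3),
                         simulate_currents(chn, ramp, seed = 4)))
  expect_error(simulate_currents(ch, c(-1, 2)), "invalid-argument")
})

test_that("channel and geometry models validate their invariants", {
  expect_error(channel_model(slope_true = 0))
  expect_error(channel_model(i_single = 0))
  expect_error(channel_model(basal_tension = -1))
  expect_error(geometry_model(pipette_radius = 0))
  expect_silent(channel_model(i_single = -12, n_channels = 30))  # MscS-like
})

test_that("simulated patches tie protocol, sweep, stack and truth together", {
  ch <- channel_model(basal_tension = 0, current_noise_sd = 0)
  g <- geometry_model()
  p <- simulate_patch(ch, g, seed = 5)
  expect_equal(nrow(p$sweep), length(p$protocol$time_s))
  expect_equal(length(p$stack$frames), nrow(p$protocol$steps))
  expect_equal(p$truth$steps$T_true_mN_per_m,
               0.066661 * abs(p$truth$steps$pressure_mmHg) *
                 p$truth$steps$r_true_um, tolerance = 1e-9)
  # determinism
  p2 <- simulate_patch(ch, g, seed = 5)
  expect_identical(p$sweep, p2$sweep)
  expect_identical(p$stack$frames, p2$stack$frames)
})

test_that("cohorts share gating truth while geometry disperses tensions", {
  # zero jitter: patches identical up to noise seeds
  co0 <- generate_cohort(3, jitter = list(pipette_radius_cv = 0,
                                          compliance_cv = 0,
                                          n_channels_cv = 0,
                                          basal_tension_sd = 0),
                         seed = 7, render = "none")
  truths <- lapply(co0, function(p) p$truth$steps$T_true_mN_per_m)
  expect_equal(truths[[1]], truths[[2]])
  expect_equal(truths[[1]], truths[[3]])

  # jittered: same pressures, different tensions across patches
  co <- generate_cohort(4, seed = 7, render = "none")
  Tmax <- sapply(co, function(p) max(p$truth$steps$T_true_mN_per_m))
  expect_gt(sd(Tmax), 0)
  T50s <- sapply(co, function(p) p$truth$channel$T50_true)
  expect_true(all(T50s == T50s[1]))  # gating is a channel property

  expect_equal(length(generate_cohort(1, seed = 1, render = "none")), 1)
})
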