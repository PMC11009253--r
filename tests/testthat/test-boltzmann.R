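test_that("noise-free Boltzmann samples are recovered to numerical precision", {
  s <- seq(0.5, 12, length.out = 30)
  d <- data.frame(tension = s, resp = oracle_sigmoid(s, 4.4, 1.7))
  fit <- fit_boltzmann(resp ~ tension, d)
  expect_equal(unname(coef(fit)), c(4.4, 1.7), tolerance = 1e-6)
  expect_equal(fit$r.squared, 1, tolerance = 1e-9)
  expect_equal(fit$stimulus_units, "mN/m")
  expect_lt(max(abs(residuals(fit))), 1e-7)
})

test_that("model methods are mutually consistent", {
  set.seed(21)
  s <- rep(seq(1, 11, length.out = 8), 3)
  d <- data.frame(tension = s,
                  resp = oracle_sigmoid(s, 5.8, 1.4) + rnorm(length(s), 0, 0.03),
                  patch = rep(c("a", "b", "c"), each = 8))
  fit <- fit_boltzmann(resp ~ tension, d, patch = "patch")
  expect_s3_class(fit, "boltzmann_fit")
  expect_equal(fit$n_patches, 3)
  expect_equal(fitted(fit) + residuals(fit), d$resp, tolerance = 1e-12)
  expect_equal(unname(predict(fit, data.frame(tension = coef(fit)[["midpoint"]]))),
               0.5, tolerance = 1e-9)
  ci <- confint(fit)
  expect_true(ci["midpoint", "lower"] < coef(fit)[["midpoint"]],
              ci["midpoint", "upper"] > coef(fit)[["midpoint"]])
  # vcov diagonal matches the stored standard errors
  expect_equal(sqrt(diag(vcov(fit))), fit$se, tolerance = 1e-9)
  # simulate: deterministic under a seed, correct shape
  s1 <- simulate(fit, nsim = 3, seed = 9)
  s2 <- simulate(fit, nsim = 3, seed = 9)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(fit$n, 3L))
  expect_output(print(summary(fit)), "activation range")
})

test_that("per-patch mode reports the mean and SEM across patch fits", {
  s <- seq(1, 11, length.out = 10)
  d <- do.call(rbind, lapply(1:4, function(i)
    data.frame(tension = s, resp = oracle_sigmoid(s, 4 + 0.2 * i, 1.5),
               patch = i)))
  fit <- fit_boltzmann(resp ~ tension, d, mode = "per_patch", patch = "patch")
  expect_equal(fit$mode, "per_patch")
  expect_equal(fit$n_patches, 4)
  per <- t(sapply(fit$patch_fits, coef))
  expect_equal(unname(coef(fit)), unname(colMeans(per)), tolerance = 1e-12)
  expect_equal(unname(fit$se),
               unname(apply(per, 2, sd) / 2), tolerance = 1e-12)
  expect_equal(unname(coef(fit))[1], mean(4 + 0.2 * (1:4)), tolerance = 1e-4)
})

test_that("data that never cross the midpoint are flagged as unreliable", {
  s <- seq(0.2, 2, length.out = 10)           # all far below a ~6 midpoint
  d <- data.frame(tension = s, resp = oracle_sigmoid(s, 6, 1.5))
  fit <- tryCatch(fit_boltzmann(resp ~ tension, d), error = function(e) e)
  if (inherits(fit, "error")) {
    expect_match(conditionMessage(fit), "fit-failure")
  } else {
    expect_true(any(c("unbracketed_midpoint", "ci_exceeds_span",
                      "singular_information") %in% fit$flags))
  }
})

test_that("free-amplitude variant recovers a sub-unity plateau", {
  s <- seq(0.5, 12, length.out = 24)
  d <- data.frame(tension = s, resp = 0.8 * oracle_sigmoid(s, 4.4, 1.7))
  fit <- fit_boltzmann(resp ~ tension, d, free_amplitude = TRUE)
  expect_equal(unname(coef(fit)), c(4.4, 1.7, 0.8), tolerance = 1e-5)
})

test_that("least-squares optimum matches a dense grid search on small problems", {
  # quick version of the oracle cross-check (coarse grid; the acceptance
  # suite runs the full 2000 x 2000 one)
  set.seed(33)
  s <- seq(1, 11, length.out = 18)
  y <- oracle_sigmoid(s, 5.2, 1.6) + rnorm(18, 0, 0.05)
  fit <- fit_boltzmann(resp ~ tension, data.frame(tension = s, resp = y))
  g <- grid_search_boltzmann(s, y, c(1, 11), c(0.1, 6),
                             n_mid = 400, n_slope = 400)
  expect_lte(fit$ss, g$ss + 1e-10)
  expect_lt(abs(coef(fit)[["midpoint"]] - g$mid), g$cell_mid)
  expect_lt(abs(coef(fit)[["slope_factor"]] - g$slope), g$cell_slope)
})

test_that("activation range follows the closed form and inverts the fit", {
  # TREK-2 printed parameters reproduce the printed 10-90% range
  ar <- activation_range(c(5.8, 1.4))
  expect_equal(unname(round(ar, 1)), c(2.7, 8.9))
  # f = 0.5 is the midpoint exactly; width is 2 ln(9) slope factors
  expect_equal(unname(activation_range(c(5.8, 1.4), 0.5 - 1e-12, 0.5)[2]),
               5.8, tolerance = 1e-6)
  expect_equal(unname(diff(activation_range(c(3, 2)))), 2 * log(9) * 2,
               tolerance = 1e-12)
  # self-consistency: the range of a fitted noise-free curve is the
  # generator's range
  s <- seq(0.5, 12, length.out = 20)
  fit <- fit_boltzmann(resp ~ tension,
                       data.frame(tension = s,
                                  resp = oracle_sigmoid(s, 4.4, 1.7)))
  expect_equal(unname(activation_range(fit)),
               unname(activation_range(c(4.4, 1.7))), tolerance = 1e-5)
})

test_that("channel energetics identities hold and wrong domains are refused", {
  en <- channel_energetics(c(4.4, 1.7), temperature = 298.15)
  kB <- 1.380649e-23
  expect_equal(en$delta_G_joules / (kB * 298.15) - en$delta_G_kBT, 0,
               tolerance = 1e-12)
  expect_equal(en$delta_A_nm2, kB * 298.15 / (1.7e-3) * 1e18,
               tolerance = 1e-12)
  expect_equal(en$delta_G_kBT, 4.4 / 1.7, tolerance = 1e-12)
  # dA shrinks as the response gets shallower (slope factor grows)
  slopes <- c(1, 2, 5, 20, 100)
  dAs <- sapply(slopes, function(k) channel_energetics(c(4.4, k))$delta_A_nm2)
  expect_true(all(diff(dAs) < 0))
  expect_lt(dAs[length(dAs)], 0.05)
  # power-domain fits carry no energetics
  s <- seq(0.2, 4, length.out = 12)
  pfit <- power_response_midpoint(
    data.frame(power_W_cm2 = s, I_over_Imax = oracle_sigmoid(s, 1.8, 0.5)))
  expect_error(channel_energetics(pfit), "invalid-argument")
})
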