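test_that("noiseless decay-corrected series are linear; uncorrected ones bend down", {
  ph <- phantom_spec(well_grid(list(well_condition()), n_cols = 1),
                     noise_scale = Inf, background_dose_rate = 0, seed = 1)
  sim <- simulate_stack(ph)
  ser <- extract_uptake_series(sim$stack, sim$mask)
  fit <- fit_uptake_rate(ser)
  expect_gte(fit$r_squared, 0.999)
  # undo the correction: t * exp(-lambda t) curves downward while
  # t < 2/lambda (~317 min for F-18); the late tail flattens out
  dcf <- decay_correction_factor(ser$start_min, ser$duration_min)
  raw <- ser$uptake / dcf
  d2 <- diff(raw, differences = 2)
  expect_true(all(d2[ser$mid_min[2:(length(d2) + 1)] < 2 / (log(2) / 109.77)]
                  < 0))
  expect_lt(mean(d2), 0)
  # and the uncorrected series is far from linear
  expect_lt(fit_uptake_rate(ser$mid_min, raw)$r_squared, 0.6)
})

test_that("uptake values do not depend on ROI size for homogeneous wells", {
  cond <- well_condition()
  ph <- phantom_spec(list(
    list(center = c(30, 30), radius_px = 8, condition = cond),
    list(center = c(30, 90), radius_px = 17, condition = cond)),
    noise_scale = Inf, seed = 2)
  sim <- simulate_stack(ph)
  ser <- extract_uptake_series(sim$stack, sim$mask)
  u1 <- ser$uptake[ser$roi == 1]
  u2 <- ser$uptake[ser$roi == 2]
  expect_equal(u1, u2, tolerance = 1e-3)  # differ only by PSL quantization
})

test_that("extract_uptake_series validates masks and labels", {
  ph <- control_phantom(seed = 3)
  sim <- simulate_stack(ph)
  expect_error(
    extract_uptake_series(sim$stack, sim$mask[-1, , drop = FALSE]),
    "does not match")
  expect_error(extract_uptake_series(sim$stack, sim$mask, labels = c(1, 99)),
               "99")
  expect_error(
    extract_uptake_series(sim$stack,
                          matrix(0L, nrow(sim$mask), ncol(sim$mask))),
    "no ROI labels")
})

test_that("late-frame values rely on the exponential start-time correction", {
  ph <- control_phantom(seed = 4, noise_scale = Inf)
  sim <- simulate_stack(ph)
  s_ref <- extract_uptake_series(sim$stack, sim$mask, reference_min = 0)
  s_late <- extract_uptake_series(sim$stack, sim$mask, reference_min = 60)
  # shifting the reference rescales every frame by exp(-lambda * shift)
  expect_equal(s_late$uptake / s_ref$uptake,
               rep(2^(-60 / 109.77), nrow(s_ref)))
})

test_that("fit_uptake_rate recovers exact lines and flags degenerate input", {
  t <- seq(22.5, 382.5, by = 60)
  fit <- fit_uptake_rate(t, 0.002 * t + 0.1)
  expect_equal(unname(coef(fit)["slope"]), 0.002)
  expect_equal(unname(coef(fit)["intercept"]), 0.1)
  expect_equal(fit$r_squared, 1)
  flat <- fit_uptake_rate(t, rep(0.5, length(t)))
  expect_equal(unname(coef(flat)["slope"]), 0)
  expect_error(fit_uptake_rate(1, 2), "at least 2")
  expect_error(fit_uptake_rate(c(10, 10), c(1, 2)), "zero variance")
})

test_that("slope estimation is equivariant under dose rescaling", {
  ph <- control_phantom(seed = 5)
  sim <- simulate_stack(ph)
  ser <- extract_uptake_series(sim$stack, sim$mask)
  f1 <- fit_uptake_rate(ser)
  ser2 <- ser
  ser2$uptake <- ser2$uptake * 3.7
  f2 <- fit_uptake_rate(ser2)
  expect_equal(unname(coef(f2)["slope"]), 3.7 * unname(coef(f1)["slope"]))
})

test_that("uptake_fit behaves like a small model object", {
  t <- seq(22.5, 382.5, by = 60)
  set.seed(6)
  fit <- fit_uptake_rate(t, 0.002 * t + 0.1 + rnorm(length(t), 0, 1e-3))
  expect_named(coef(fit), c("intercept", "slope"))
  expect_equal(predict(fit, c(0, 100)),
               unname(coef(fit)["intercept"] + coef(fit)["slope"] * c(0, 100)),
               ignore_attr = TRUE)
  expect_equal(fitted(fit) + residuals(fit), 0.002 * t + 0.1,
               tolerance = 0.01)
  expect_output(print(fit), "rate")
  expect_output(print(summary(fit)), "slope")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
})

test_that("fit_uptake_rates fits each ROI of a series table", {
  ph <- phantom_spec(well_grid(replicate(3, well_condition(),
                                         simplify = FALSE), n_cols = 3),
                     seed = 7)
  sim <- simulate_stack(ph)
  rates <- fit_uptake_rates(extract_uptake_series(sim$stack, sim$mask))
  expect_equal(nrow(rates), 3)
  expect_true(all(rates$n_frames == 7))
  expect_true(all(rates$r_squared > 0.99))
  ser <- extract_uptake_series(sim$stack, sim$mask)
  expect_error(fit_uptake_rate(ser), "fit_uptake_rates")
})

test_that("percent-of-control handles identity, ratios, and degenerate controls", {
  df <- data.frame(condition = rep(c("control", "a"), each = 4),
                   slope = c(2, 2, 2, 2, 1, 1, 1, 1))
  p <- relative_to_control(df)
  expect_equal(p$percent[p$condition == "control"], 100)
  expect_equal(p$percent[p$condition == "a"], 50)
  expect_error(relative_to_control(df, control = "missing"), "not present")
  df0 <- data.frame(condition = rep(c("control", "a"), each = 2),
                    slope = c(0, 0, 1, 1))
  expect_error(relative_to_control(df0), "zero")
})

test_that("attenuation thickness inverts the transmission ratio", {
  calib <- plate_calibration()
  mu <- 0.002
  d_bg <- matrix(5000, 10, 10)
  bg <- matrix(dose_to_psl(d_bg, calib), 10, 10)
  tis <- matrix(dose_to_psl(d_bg * exp(-mu * 100), calib), 10, 10)
  th <- attenuation_thickness_map(bg, tis, calib, mu_per_um = mu)
  expect_equal(th, matrix(100, 10, 10), tolerance = 1e-9)
  # equal images: zero thickness; brighter tissue clamps at zero
  expect_equal(attenuation_thickness_map(bg, bg, calib, mu),
               matrix(0, 10, 10))
  expect_equal(attenuation_thickness_map(tis, bg, calib, mu),
               matrix(0, 10, 10))
  expect_error(attenuation_thickness_map(bg, tis[-1, ], calib, mu),
               "same shape")
  expect_error(attenuation_thickness_map(bg, tis, calib, mu_per_um = 0),
               "> 0")
})
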