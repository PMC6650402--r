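test_that("trapping rate follows the competitive-inhibition kinetics", {
  base <- well_condition(glucose_mM = 0)
  at_km <- well_condition(glucose_mM = base$km_glucose_mM)
  expect_equal(trapping_rate(at_km), trapping_rate(base) / 2)
  expect_equal(trapping_rate(well_condition(viable_cell_density = 0)), 0)
  # linear in activity and in cell density
  expect_equal(trapping_rate(well_condition(fdg_activity_MBq = 0.2)) /
                 trapping_rate(well_condition(fdg_activity_MBq = 0.1)), 2)
  expect_equal(trapping_rate(well_condition(viable_cell_density = 0.5)),
               trapping_rate(well_condition()) / 2)
})

test_that("fitted glucose Km reproduces the reference inhibition series", {
  km <- fit_km_glucose()
  expect_gt(km, 0.5)
  expect_lt(km, 20)
  # the frozen default is the fit
  expect_equal(as.numeric(km), well_condition()$km_glucose_mM)
  pred <- attr(km, "predicted") / 100
  expect_lt(max(abs(pred - c(0.89, 0.73, 0.44, 0.39, 0.23))), 0.12)
})

test_that("identical seeds give bit-identical stacks", {
  ph <- control_phantom(seed = 42)
  a <- simulate_stack(ph)
  b <- simulate_stack(ph)
  expect_identical(a$stack$frames, b$stack$frames)
  c_ <- simulate_stack(ph, seed = 43)
  expect_false(identical(a$stack$frames, c_$stack$frames))
})

test_that("a zero-activity well reads the tissue-attenuated ambient background", {
  ph <- control_phantom(seed = 7, cond = well_condition(fdg_activity_MBq = 0))
  sim <- simulate_stack(ph)
  ser <- extract_uptake_series(sim$stack, sim$mask)
  expected <- ph$background_dose_rate *
    exp(-ph$mu_per_um * well_condition()$tissue_thickness_um)
  expect_equal(mean(ser$uptake), expected, tolerance = 0.03)
  # flat in time: the fitted slope is negligible against the control rate
  fit <- fit_uptake_rate(ser)
  expect_lt(abs(coef(fit)["slope"]), 0.02 * trapping_rate(well_condition()))
})

test_that("doubling medium activity doubles the recovered slope", {
  ph <- phantom_spec(well_grid(list(
    well_condition(fdg_activity_MBq = 0.04625),
    well_condition(fdg_activity_MBq = 0.0925)), n_cols = 2), seed = 12)
  r <- recover_rates(ph)
  expect_equal(r$slope[2] / r$slope[1], 2, tolerance = 0.05)
})

test_that("recovered slopes are unbiased across replicate noise realizations", {
  truth <- trapping_rate(well_condition())
  est <- vapply(1:200, function(i) {
    r <- recover_rates(control_phantom(seed = 1000 + i))
    r$slope
  }, numeric(1))
  expect_lt(abs(mean(est) / truth - 1), 0.02)
})

test_that("scenario presets reproduce the study designs", {
  sc3 <- scenario("fig3_glucose", seed = 5)
  expect_equal(nrow(sc3$design), 6 * 4)
  expect_setequal(unique(sc3$design$condition),
                  c("control", "1 mM", "2 mM", "5 mM", "10 mM", "20 mM"))
  expect_equal(sort(unique(sc3$design$glucose_mM)), c(0, 1, 2, 5, 10, 20))

  sc2 <- scenario("fig2_activity", seed = 5)
  expect_equal(sort(unique(sc2$design$fdg_activity_MBq)),
               c(0.0115625, 0.023125, 0.04625, 0.0925, 0.185, 0.37))
  expect_equal(nrow(sc2$design), 6 * 4)

  sc4 <- scenario("fig4_growth", seed = 5)
  expect_equal(nrow(sc4$design), 3 * 5)  # five tissues per day

  sc5 <- scenario("fig5_insult", seed = 5)
  expect_equal(sc5$design$viability[sc5$design$condition == "KOH"][1], 0.14)

  expect_error(scenario("fig9_unknown", seed = 5))
  expect_error(scenario("fig2_activity"), "seed")
})

test_that("hypoxia raises uptake with ground-truth viability intact", {
  ratios <- vapply(1:4, function(i) {
    sc <- scenario("fig6_hypo", seed = 600 + i)
    sim <- simulate_stack(sc$phantom)
    r <- fit_uptake_rates(extract_uptake_series(sim$stack, sim$mask))
    r$condition <- sc$design$condition
    expect_true(all(sim$truth$viability[
      sc$design$condition == "hypoxia"] == 1))
    p <- relative_to_control(r)
    p$percent[p$condition == "hypoxia"]
  }, numeric(1))
  expect_equal(mean(ratios), 235, tolerance = 0.15)
})

test_that("invalid phantom geometry and schedules are rejected", {
  cond <- well_condition()
  expect_error(phantom_spec(list(
    list(center = c(20, 20), radius_px = 15, condition = cond),
    list(center = c(30, 30), radius_px = 15, condition = cond))), "overlap")
  expect_error(phantom_spec(list(
    list(center = c(5, 5), radius_px = 17, condition = cond))), "fit")
  expect_error(exposure_schedule(c(0, 30), 45), "overlap")
  expect_error(exposure_schedule(c(60, 0), 45), "increasing")
})

test_that("assay readout is mean-preserving lognormal noise on the truth", {
  v <- assay_readout(rep(1, 4000), cv = 0.04, seed = 9)
  expect_equal(mean(v), 1, tolerance = 0.01)
  expect_equal(stats::sd(v), 0.04, tolerance = 0.15)
  expect_equal(assay_readout(c(0, 0), seed = 1), c(0, 0))
})
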