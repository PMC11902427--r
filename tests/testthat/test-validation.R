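test_that("mean absolute difference behaves as a metric on aligned series", {
  x <- stats::rnorm(100)
  expect_equal(mean_abs_diff(x, x), 0)
  expect_equal(mean_abs_diff(x, x + 1.5), 1.5)
  expect_error(mean_abs_diff(x, x[-1]), "equal length")
  truth <- make_truth_spec(70, 0)
  cap <- generate_motion(motion_profile(n_cycles = 1, peak_flexion = 80,
                                        period = 8), seed = 2)
  meas <- generate_loadcell(cap, truth, cell_sim_config(), seed = 2)
  sim <- simulate_chest_force(cap, truth)$force_kgf
  expect_lt(mean_abs_diff(sim, meas$measured_force), 1e-9)
})

test_that("the ascending-only filter zeroes exactly the non-ascend frames", {
  cap <- generate_motion(motion_profile(n_cycles = 2, peak_flexion = 60,
                                        period = 3), seed = 3)
  ann <- segment_phases(cap)
  meas <- stats::runif(nrow(cap), 1, 2)
  filt <- active_mod_filter(meas, ann)
  asc <- ann$phase == "ascend"
  expect_identical(filt[asc], meas[asc])
  expect_true(all(filt[!asc] == 0))
  expect_error(active_mod_filter(meas[-1], ann), "aligned")

  ramp <- capture_series((0:199)/60, seq(80, 0, length.out = 200))
  ann_up <- segment_phases(ramp)   # pure ascent
  expect_identical(active_mod_filter(meas[1:200], ann_up), meas[1:200])
})

test_that("filtering out descents reduces the deviation on contaminated captures", {
  truth <- make_truth_spec(0, 100)
  for (seed in 1:5) {
    cap <- generate_motion(motion_profile(n_cycles = 4, peak_flexion = 70,
                                          period = 2.5), seed = seed)
    meas <- generate_loadcell(cap, truth,
                              cell_sim_config(descent_contamination_amp = 2,
                                              noise_sd_force = 0.1),
                              seed = seed)
    sim <- simulate_chest_force(cap, truth)
    before <- mean_abs_diff(sim$force_kgf, meas$measured_force)
    after <- mean_abs_diff(active_mod_filter(sim$force_kgf, sim$annotation),
                           active_mod_filter(meas$measured_force, sim$annotation))
    expect_lte(after, before)
  }
})

test_that("simulated and experimental risks coincide on self-consistent captures", {
  truth <- make_truth_spec(70, 70)
  cap <- generate_loadcell(
    generate_motion(motion_profile(n_cycles = 3, peak_flexion = 70,
                                   period = 2.5), seed = 4),
    truth, cell_sim_config(), seed = 4)
  rk <- compare_risk(cap, truth)
  expect_lt(abs(rk$difference), 1e-6)
  expect_lt(rk$risk_simulated, rk$risk_unassisted)

  zero <- make_zero_spec()
  cap0 <- generate_loadcell(
    generate_motion(motion_profile(n_cycles = 3, peak_flexion = 70,
                                   period = 2.5), seed = 4),
    zero, cell_sim_config(), seed = 4)
  rk0 <- compare_risk(cap0, zero)
  expect_equal(rk0$risk_simulated, rk0$risk_unassisted)
  expect_equal(rk0$risk_experimental, rk0$risk_unassisted)
})

test_that("unfiltered descent contamination biases the experimental risk", {
  truth <- make_truth_spec(0, 100)
  cap <- generate_motion(motion_profile(n_cycles = 4, peak_flexion = 75,
                                        period = 2.5, pause_fraction = 0.5),
                         seed = 6)
  # contamination is extra measured force on descents; the experimental branch
  # reads all measured force as device assistance, so contaminated captures
  # must drive the paired risks apart while clean ones keep them equal
  clean <- generate_loadcell(cap, truth, cell_sim_config(), seed = 6)
  dirty <- generate_loadcell(cap, truth,
                             cell_sim_config(descent_contamination_amp = 3),
                             seed = 6)
  expect_lt(abs(compare_risk(clean, truth)$difference), 1e-6)
  expect_gt(abs(compare_risk(dirty, truth)$difference), 1e-6)
  # the ascending-only filter restores the agreement
  expect_lt(abs(compare_risk(dirty, truth, use_active_mod = TRUE)$difference),
            abs(compare_risk(dirty, truth)$difference))
})

test_that("capture-set validation aggregates per-capture deviations", {
  truth <- make_truth_spec()
  pset <- generate_capture_set(truth, c(100, 40), 2, "passive", seed = 15)
  aset <- generate_capture_set(truth, c(100, 40), 1, "active", seed = 16)
  rep <- validate_capture_set(c(pset, aset), truth)
  expect_s3_class(rep, "validation_report")
  # active captures appear twice: raw and active_mod
  expect_equal(nrow(rep), 4 + 2 * 2)
  expect_equal(attr(rep, "aggregate_mean"), mean(rep$mean_abs_force_diff))
  expect_true(all(rep$mean_abs_force_diff < 1e-9))
  expect_true(all(abs(rep$risk_difference) < 1e-6))
  expect_equal(rep$risk_difference,
               rep$risk_experimental - rep$risk_simulated)
})

test_that("per-capture force deviation concentrates at the folded-normal mean", {
  truth <- make_truth_spec(70, 0)
  sigma <- 0.25
  expected <- sigma * sqrt(2 / pi)
  cap0 <- generate_motion(motion_profile(n_cycles = 1, peak_flexion = 80,
                                         period = 8), seed = 1)
  se <- sigma * sqrt(1 - 2 / pi) / sqrt(nrow(cap0))
  devs <- vapply(1:20, function(s) {
    cap <- generate_loadcell(
      generate_motion(motion_profile(n_cycles = 1, peak_flexion = 80,
                                     period = 8), seed = s),
      truth, cell_sim_config(noise_sd_force = sigma), seed = s + 100)
    sim <- simulate_chest_force(cap, truth)$force_kgf
    mean_abs_diff(sim, cap$measured_force)
  }, numeric(1))
  expect_true(all(abs(devs - expected) < 3 * se))
  expect_lt(abs(mean(devs) - expected), 3 * se / sqrt(20))
})
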