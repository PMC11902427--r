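# Fixtures built in code: a ground-truth device spec independent of the
# shipped YAML file, plus small helpers used across the suite.

make_passive_table <- function() {
  passive_keypoint_table(
    characteristic_angles = c(10, 30, 50, 65, 80),
    torque_ratios = c(0, 0.2, 0.5, 0.8, 1),
    tau_max = stats::setNames(seq(0, 30, by = 3), seq(0, 100, by = 10))
  )
}

make_active_table <- function() {
  scale_active_percentages(data.frame(
    eta = c(40, 70, 100),
    tau_a_max = c(8, 14, 20),
    vel_lim = c(30, 24, 18),
    vel_max = c(70, 64, 58)
  ))
}

make_truth_spec <- function(eta_p = 100, eta_a = 100, psi_a = 30) {
  exoskeleton_spec(
    passive_table = make_passive_table(),
    active_table = make_active_table(),
    assistance = assistance_config(eta_p, eta_a, psi_a),
    body = body_dimensions(d_tt = 0.45, d_mt = 0.25),
    device_weight = 7.5
  )
}

# a device that applies no force at any setting
make_zero_spec <- function() {
  exoskeleton_spec(
    passive_table = passive_keypoint_table(
      c(10, 30, 50, 65, 80), c(0, 0.2, 0.5, 0.8, 1),
      stats::setNames(rep(0, 11), seq(0, 100, by = 10))),
    active_table = active_keypoint_table(
      data.frame(eta = seq(0, 100, by = 10), tau_a_max = 0, vel_lim = 0,
                 slope = 0, intercept = 0)),
    assistance = assistance_config(100, 100, 30),
    body = body_dimensions(0.45, 0.25),
    device_weight = 0
  )
}

# run the standard noise-free calibration study: generate sets, calibrate
run_roundtrip_calibration <- function(truth, seed = 11, cfg = cell_sim_config(),
                                      reps = 3) {
  pset <- generate_capture_set(truth, c(100, 70, 40), reps, "passive", cfg,
                               seed = seed)
  aset <- generate_capture_set(truth, c(100, 70, 40), reps, "active", cfg,
                               seed = seed + 1)
  cal <- calibrate_from_captures(pset, aset,
    characteristic_angles = truth$passive_table$characteristic_angles,
    assistance = truth$assistance, body = truth$body,
    device_weight = truth$device_weight)
  list(cal = cal, pset = pset, aset = aset)
}
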