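test_that("passive spline passes through its keypoints at every percentage", {
  tab <- make_passive_table()
  for (eta in seq(10, 100, by = 10)) {
    tmax <- tab$tau_max[as.character(eta)]
    expect_equal(passive_torque(tab$characteristic_angles, tab, eta),
                 unname(tab$torque_ratios * tmax), tolerance = 1e-12)
  }
})

test_that("passive torque clamps outside the characteristic range and vanishes at 0 %", {
  tab <- make_passive_table()
  expect_equal(passive_torque(c(-20, 0, 10), tab, 100), c(0, 0, 0))
  expect_equal(passive_torque(c(80, 90, 150), tab, 100), rep(30, 3))
  expect_equal(passive_torque(seq(-10, 120, by = 1), tab, 0),
               numeric(131))
})

test_that("passive torque is non-decreasing in flexion on a dense grid", {
  tab <- make_passive_table()
  grid <- seq(0, 90, length.out = 1000)
  for (eta in seq(10, 100, by = 10)) {
    tau <- passive_torque(grid, tab, eta)
    expect_true(all(diff(tau) >= -1e-12))
  }
})

test_that("active torque honours the three-piece law and its boundaries", {
  tab <- make_active_table()
  for (eta in seq(10, 100, by = 10)) {
    row <- tab[tab$eta == eta, ]
    expect_equal(active_torque(row$vel_lim / 2, tab, eta), 0)
    expect_equal(active_torque(2 * row$vel_max, tab, eta), row$tau_a_max)
    mid <- (row$vel_lim + row$vel_max) / 2
    expect_equal(active_torque(mid, tab, eta), row$tau_a_max / 2,
                 tolerance = 1e-12)
    # continuity at both breakpoints
    eps <- 1e-9
    expect_lt(abs(active_torque(row$vel_lim + eps, tab, eta)), 1e-6)
    expect_lt(abs(active_torque(row$vel_max - eps, tab, eta) - row$tau_a_max),
              1e-6)
  }
  expect_equal(active_torque(0:200, tab, 0), numeric(201))
})

test_that("active torque rejects negative speeds and off-grid percentages", {
  tab <- make_active_table()
  expect_error(active_torque(-1, tab, 100), "non-negative")
  expect_error(active_torque(10, tab, 55), "steps of ten|0, 10")
  expect_error(passive_torque(10, make_passive_table(), 55), "steps of ten|0, 10")
})

test_that("total torque is the sum of independently evaluated modes", {
  spec <- make_truth_spec(50, 50)
  theta <- 45
  speeds <- seq(0, 120, by = 2.5)
  combined <- total_torque(theta, speeds, TRUE, spec)
  tp <- passive_torque(theta, spec$passive_table, 50)
  ta <- active_torque(speeds, spec$active_table, 50)
  expect_equal(combined, tp + ta)
  # active disabled drops only the active part
  expect_equal(total_torque(theta, speeds, FALSE, spec), rep(tp, length(speeds)))
  # fully off device
  spec0 <- make_truth_spec(0, 0)
  expect_equal(total_torque(theta, speeds, FALSE, spec0), numeric(length(speeds)))
})

test_that("passive percentage scaling distributes differences evenly", {
  full <- scale_passive_percentages(c("100" = 30, "70" = 24))
  expect_identical(unname(full[c("80", "90")]), c(26, 28))
  expect_identical(unname(full[c("70", "100")]), c(24, 30))
  single <- scale_passive_percentages(c("40" = 12))
  expect_identical(unname(single[c("0", "20")]), c(0, 6))
  three <- scale_passive_percentages(c("100" = 30, "70" = 24, "40" = 12))
  expect_identical(unname(three[c("40", "70", "100")]), c(12, 24, 30))
  expect_error(scale_passive_percentages(c("100" = 10, "70" = 24)),
               "non-decreasing")
})

test_that("active percentage scaling interpolates rows and rebuilds their lines", {
  tab <- scale_active_percentages(data.frame(
    eta = c(40, 100), tau_a_max = c(8, 20), vel_lim = c(16, 10),
    vel_max = c(56, 50)))
  r70 <- tab[tab$eta == 70, ]
  expect_identical(r70$tau_a_max, 14)
  expect_identical(r70$vel_lim, 13)
  # every generated row: line through (vel_lim, 0)
  expect_true(all(abs(tab$intercept + tab$slope * tab$vel_lim) < 1e-12))
  # anchors reproduced bit-exactly
  expect_identical(tab$tau_a_max[tab$eta == 40], 8)
  expect_identical(tab$tau_a_max[tab$eta == 100], 20)
  expect_identical(tab$vel_lim[tab$eta == 100], 10)
  expect_error(scale_active_percentages(data.frame(
    eta = c(40, 100), tau_a_max = c(8, 20), vel_lim = c(16, 10),
    vel_max = c(16, 50))), "vel_max > vel_lim|degenerate")
})

test_that("torque is non-decreasing in the assistance percentage", {
  ptab <- make_passive_table()
  atab <- make_active_table()
  for (theta in c(20, 45, 70)) {
    tau <- vapply(seq(0, 100, by = 10),
                  function(e) passive_torque(theta, ptab, e), numeric(1))
    expect_true(all(diff(tau) >= -1e-12))
  }
  for (v in c(10, 25, 40, 80)) {
    tau <- vapply(seq(0, 100, by = 10),
                  function(e) active_torque(v, atab, e), numeric(1))
    expect_true(all(diff(tau) >= -1e-12))
  }
})

test_that("keypoint table validation rejects malformed inputs", {
  expect_error(passive_keypoint_table(c(10, 30, 50, 65), c(0, 0.2, 0.5, 1),
                                      c("100" = 30)), "five")
  expect_error(passive_keypoint_table(c(10, 30, 20, 65, 80),
                                      c(0, 0.2, 0.5, 0.8, 1), c("100" = 30)),
               "strictly increasing")
  expect_error(passive_keypoint_table(c(10, 30, 50, 65, 80),
                                      c(0, 0.5, 0.2, 0.8, 1), c("100" = 30)),
               "non-decreasing")
  expect_error(passive_keypoint_table(c(10, 30, 50, 65, 80),
                                      c(0, 0.2, 0.5, 0.8, 0.9), c("100" = 30)),
               "equal 1")
  expect_error(active_keypoint_table(data.frame(
    eta = 50, tau_a_max = 10, vel_lim = 20, slope = 0.5, intercept = -3)),
    "intercept")
})
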