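analytic_passive_curve <- function(table, eta, d_tt, lo = 0, hi = 85, n = 2000) {
  grid <- seq(lo, hi, length.out = n)
  tau <- passive_torque(grid, table, eta)
  structure(data.frame(abscissa = grid,
                       force = n_to_kgf(2 * tau / d_tt),
                       dispersion = 0),
            n_source_curves = 1L,
            class = c("averaged_curve", "data.frame"))
}

analytic_active_curve <- function(table, eta, d_tt, hi = 110, n = 2000) {
  grid <- seq(0, hi, length.out = n)
  tau <- active_torque(grid, table, eta)
  structure(data.frame(abscissa = grid,
                       force = n_to_kgf(2 * tau / d_tt),
                       dispersion = 0),
            n_source_curves = 1L,
            class = c("averaged_curve", "data.frame"))
}

test_that("normalize_and_average is exact on degenerate trace sets", {
  tr <- data.frame(abscissa = seq(0, 10, by = 0.5),
                   force = sin(seq(0, 10, by = 0.5)))
  one <- normalize_and_average(list(tr), grid_size = 21)
  expect_equal(one$force, tr$force, tolerance = 1e-12)
  expect_equal(attr(one, "n_source_curves"), 1L)

  two <- normalize_and_average(list(tr, tr))
  expect_true(all(two$dispersion == 0))

  shifted <- transform(tr, force = force + 2)
  avg <- normalize_and_average(list(tr, shifted), grid_size = 21)
  expect_equal(avg$force, tr$force + 1, tolerance = 1e-12)

  expect_error(normalize_and_average(list(
    data.frame(abscissa = 0:5, force = 0:5),
    data.frame(abscissa = 10:15, force = 0:5))), "overlap")
})

test_that("passive anchors round-trip through a noise-free analytic curve", {
  tab <- make_passive_table()
  d_tt <- 0.45
  for (eta in c(40, 70, 100)) {
    cv <- analytic_passive_curve(tab, eta, d_tt)
    a <- extract_passive_anchor(cv, tab$characteristic_angles, d_tt)
    truth_max <- unname(tab$tau_max[as.character(eta)])
    expect_lt(abs(a$tau_max - truth_max) / truth_max, 1e-6)
    expect_lt(max(abs(a$torque_ratios - tab$torque_ratios)), 1e-6)
  }
})

test_that("scaling a curve scales tau_max but not the ratios", {
  tab <- make_passive_table()
  cv <- analytic_passive_curve(tab, 100, 0.45)
  doubled <- cv
  doubled$force <- 2 * doubled$force
  a1 <- extract_passive_anchor(cv, tab$characteristic_angles, 0.45)
  a2 <- extract_passive_anchor(doubled, tab$characteristic_angles, 0.45)
  expect_equal(a2$tau_max, 2 * a1$tau_max, tolerance = 1e-9)
  expect_equal(a2$torque_ratios, a1$torque_ratios, tolerance = 1e-9)
})

test_that("degenerate passive curves raise calibration errors", {
  flat <- structure(data.frame(abscissa = seq(0, 85, length.out = 100),
                               force = 0, dispersion = 0),
                    n_source_curves = 1L,
                    class = c("averaged_curve", "data.frame"))
  expect_error(extract_passive_anchor(flat, c(10, 30, 50, 65, 80), 0.45),
               "non-positive")
  short <- structure(data.frame(abscissa = seq(20, 60, length.out = 50),
                                force = 1, dispersion = 0),
                     n_source_curves = 1L,
                     class = c("averaged_curve", "data.frame"))
  expect_error(extract_passive_anchor(short, c(10, 30, 50, 65, 80), 0.45),
               "range")
})

test_that("active hinge parameters round-trip through a noise-free curve", {
  tab <- make_active_table()
  d_tt <- 0.45
  for (eta in c(40, 70, 100)) {
    row <- tab[tab$eta == eta, ]
    fit <- extract_active_anchor(analytic_active_curve(tab, eta, d_tt), d_tt)
    expect_lt(abs(fit$tau_a_max - row$tau_a_max) / row$tau_a_max, 1e-6)
    expect_lt(abs(fit$vel_lim - row$vel_lim) / row$vel_lim, 1e-6)
    expect_lt(abs(fit$vel_max - row$vel_max) / row$vel_max, 1e-6)
    expect_lt(abs(fit$intercept - row$intercept) / abs(row$intercept), 1e-5)
  }
})

test_that("a curve without a plateau is rejected", {
  lin <- structure(data.frame(abscissa = seq(0, 60, length.out = 200),
                              force = seq(0, 60, length.out = 200) * 0.1,
                              dispersion = 0),
                   n_source_curves = 1L,
                   class = c("averaged_curve", "data.frame"))
  expect_error(extract_active_anchor(lin, 0.45), "plateau")
})

test_that("build_spec reproduces anchor curves and handles passive-only devices", {
  tab <- make_passive_table()
  anchors <- c("40" = 12, "70" = 21, "100" = 30)
  spec <- build_spec(anchors, tab$torque_ratios, tab$characteristic_angles,
                     active_anchors = NULL,
                     assistance = assistance_config(100, 0, 30),
                     body = body_dimensions(0.45, 0.25))
  for (eta in c(40, 70, 100)) {
    expect_equal(passive_torque(tab$characteristic_angles, spec$passive_table, eta),
                 passive_torque(tab$characteristic_angles, tab, eta))
  }
  expect_equal(active_torque(seq(0, 100, by = 5), spec$active_table, 100),
               numeric(21))
  expect_error(build_spec(c("40" = 20, "100" = 10), tab$torque_ratios,
                          tab$characteristic_angles, NULL,
                          assistance = assistance_config(100, 0, 30),
                          body = body_dimensions(0.45, 0.25)),
               "non-decreasing")
})

test_that("full capture-set calibration recovers the generating model", {
  truth <- make_truth_spec()
  rt <- run_roundtrip_calibration(truth, seed = 11, reps = 1)
  cal <- rt$cal
  expect_equal(unname(cal$passive_anchors[c("100", "70", "40")]),
               c(30, 21, 12), tolerance = 1e-9)
  expect_equal(cal$passive_ratios, truth$passive_table$torque_ratios,
               tolerance = 1e-9)
  truth_rows <- truth$active_table[match(cal$active_anchors$eta,
                                         truth$active_table$eta), ]
  expect_equal(cal$active_anchors$tau_a_max, truth_rows$tau_a_max,
               tolerance = 1e-7)
  expect_equal(cal$active_anchors$vel_lim, truth_rows$vel_lim,
               tolerance = 1e-6)
})
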