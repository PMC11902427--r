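# Model development from repeated captures: reduce the traces recorded at
# each assistance percentage to one averaged force curve, then extract the
# keypoint parameters that pin the torque-curve families.

#' Normalize traces to a common grid and average them
#'
#' Each trace (chest force against flexion angle for passive captures, or
#' against ascent speed for active captures) is resampled by linear
#' interpolation onto a common grid spanning the intersection of the
#' abscissa ranges; the pointwise mean and spread are returned.
#'
#' @param curves A list of data.frames, each with columns `abscissa` and
#'   `force` (kgf); at least one trace with at least two points.
#' @param grid_size Number of grid points for the uniform grid (default 200).
#' @param grid `"uniform"` for an equally spaced grid of `grid_size` points,
#'   or `"union"` to use every source abscissa inside the common range --
#'   exact at the original sample points, which the calibration fits rely on.
#' @return An object of class `averaged_curve`: a data.frame with `abscissa`,
#'   `force` (mean) and `dispersion` (sd, 0 for a single trace), plus an
#'   `n_source_curves` attribute.
#' @export
normalize_and_average <- function(curves, grid_size = 200L,
                                  grid = c("uniform", "union")) {
  grid <- match.arg(grid)
  if (!is.list(curves) || length(curves) == 0L)
    stop("at least one trace is required", call. = FALSE)
  for (tr in curves) {
    if (!is.data.frame(tr) || !all(c("abscissa", "force") %in% names(tr)) ||
        nrow(tr) < 2L)
      stop("each trace needs columns abscissa and force with >= 2 points",
           call. = FALSE)
  }
  lo <- max(vapply(curves, function(tr) min(tr$abscissa), numeric(1)))
  hi <- min(vapply(curves, function(tr) max(tr$abscissa), numeric(1)))
  if (hi <= lo)
    stop("trace abscissa ranges do not overlap; cannot build a common grid",
         call. = FALSE)
  gx <- if (grid == "uniform") {
    seq(lo, hi, length.out = grid_size)
  } else {
    u <- sort(unique(unlist(lapply(curves, function(tr) tr$abscissa))))
    u[u >= lo & u <= hi]
  }
  mat <- vapply(curves, function(tr) {
    o <- order(tr$abscissa)
    stats::approx(tr$abscissa[o], tr$force[o], xout = gx, ties = mean)$y
  }, numeric(length(gx)))
  mat <- matrix(mat, nrow = length(gx))
  structure(data.frame(abscissa = gx,
                       force = rowMeans(mat),
                       dispersion = apply(mat, 1L, stats::sd)),
            n_source_curves = length(curves),
            class = c("averaged_curve", "data.frame"))
}

# Evaluate an averaged curve off its grid. Shape-preserving spline through
# the grid points (same dialect as the passive model family, third-order
# accurate on smooth data); falls back to linear for very short curves.
curve_force_at <- function(curve, x) {
  ok <- !duplicated(curve$abscissa)
  xs <- curve$abscissa[ok]; ys <- curve$force[ok]
  x <- pmin(pmax(x, min(xs)), max(xs))
  if (length(xs) < 4L) return(stats::approx(xs, ys, xout = x)$y)
  stats::splinefun(xs, ys, method = "monoH.FC")(x)
}

# Measured chest force (kgf, both cells summed) -> per-side torque (N*m).
# Per side the chest carries half the total force at lever d_tt.
force_kgf_to_side_torque <- function(force_kgf, d_tt) {
  kgf_to_n(force_kgf) / 2 * d_tt
}

# Evaluate the averaged curve at characteristic angle k using only points in
# the half-section to its left. The model family is smooth inside a section
# but kinked at the knots (clamped flat beyond the last one), so one-sided
# evaluation avoids the chord bias of interpolating across a kink. A cubic
# least-squares fit over the window is exact when the underlying section is a
# cubic and averages noise otherwise.
eval_at_knot <- function(curve, knots, k) {
  a <- knots[k]
  w <- if (k > 1L) (a - knots[k - 1L]) / 2 else (knots[2L] - a) / 2
  sel <- curve$abscissa >= a - w & curve$abscissa <= a
  if (sum(sel) < 5L) return(curve_force_at(curve, a))
  x <- curve$abscissa[sel] - a          # center at the knot: intercept = value
  y <- curve$force[sel]
  fit <- stats::lm.fit(cbind(1, x, x^2, x^3), y)
  unname(fit$coefficients[1L])
}

#' Extract a passive anchor from an averaged curve
#'
#' Converts the averaged chest-force curve to per-side torque through the
#' chest lever arm, reads the maximum torque at the last characteristic angle
#' and the torque ratio at each characteristic angle.
#'
#' @param curve An [normalize_and_average()] result with flexion-angle
#'   abscissa (degrees).
#' @param characteristic_angles The five characteristic angles, degrees; must
#'   lie inside the curve's range.
#' @param d_tt Chest lever arm, m.
#' @return A list with `tau_max` (N*m, per side) and `torque_ratios`
#'   (length 5).
#' @export
extract_passive_anchor <- function(curve, characteristic_angles, d_tt) {
  stopifnot(inherits(curve, "averaged_curve"), length(characteristic_angles) == 5L)
  rng <- range(curve$abscissa)
  if (any(characteristic_angles < rng[1L] - 1e-9) ||
      any(characteristic_angles > rng[2L] + 1e-9))
    stop("characteristic angles must lie inside the averaged curve's range",
         call. = FALSE)
  force_at <- vapply(seq_along(characteristic_angles), function(k) {
    eval_at_knot(curve, characteristic_angles, k)
  }, numeric(1))
  tau <- force_kgf_to_side_torque(force_at, d_tt)
  tau_max <- tau[5L]
  if (!is.finite(tau_max) || tau_max <= 0)
    stop("calibration failed: non-positive torque at the last characteristic angle",
         call. = FALSE)
  list(tau_max = tau_max, torque_ratios = tau / tau_max)
}

#' Extract an active anchor by fitting the three-piece hinge law
#'
#' Fits the active law (zero below a velocity threshold, affine up to a
#' saturation speed, constant above) to an averaged force-against-ascent-speed
#' curve by exhaustive search over candidate breakpoint pairs on the curve's
#' own grid, with the slope solved in closed form by least squares for each
#' candidate. Deterministic; no random restarts.
#'
#' @param curve An [normalize_and_average()] result with ascent-speed
#'   abscissa (deg/s); must extend beyond the plateau onset.
#' @param d_tt Chest lever arm, m.
#' @return A list with `tau_a_max` (N*m per side), `vel_lim`, `vel_max`
#'   (deg/s), `slope`, `intercept`, and the fit's `rmse` (N*m).
#' @export
extract_active_anchor <- function(curve, d_tt) {
  stopifnot(inherits(curve, "averaged_curve"))
  v <- curve$abscissa
  y <- force_kgf_to_side_torque(curve$force, d_tt)
  n <- length(v)
  if (n < 8L) stop("curve too short to fit the hinge law", call. = FALSE)
  # candidate breakpoints on a trimmed subgrid of the abscissa
  cand <- v[seq.int(1L, n, by = max(1L, n %/% 100L))]
  best <- NULL
  for (a in cand) {
    for (b in cand) {
      if (b <= a) next
      z <- pmin(pmax(v - a, 0), b - a)   # hinge basis with unit slope
      szz <- sum(z * z)
      if (szz == 0) next
      s <- sum(y * z) / szz
      if (s <= 0) next
      r <- y - s * z
      sse <- sum(r * r)
      if (is.null(best) || sse < best$sse)
        best <- list(a = a, b = b, s = s, sse = sse)
    }
  }
  if (is.null(best))
    stop("calibration failed: no rising section found in the active curve",
         call. = FALSE)
  # polish the breakpoints off-grid: slope stays closed-form per candidate
  obj <- function(p) {
    a <- p[1L]; b <- p[2L]
    if (b <= a + 1e-9) return(Inf)
    z <- pmin(pmax(v - a, 0), b - a)
    szz <- sum(z * z)
    if (szz == 0) return(Inf)
    s <- sum(y * z) / szz
    if (s <= 0) return(Inf)
    sum((y - s * z)^2)
  }
  opt <- stats::optim(c(best$a, best$b), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000L))
  if (is.finite(opt$value) && opt$value <= best$sse) {
    a <- opt$par[1L]; b <- opt$par[2L]
    z <- pmin(pmax(v - a, 0), b - a)
    s <- sum(y * z) / sum(z * z)
    best <- list(a = a, b = b, s = s, sse = opt$value)
  }
  # plateau must be observed: saturation inside the measured speed range
  if (best$b >= max(v) - 1e-9)
    stop(paste("calibration failed: no plateau detectable -- the curve never",
               "saturates inside the measured speed range"), call. = FALSE)
  tau_a_max <- best$s * (best$b - best$a)
  if (tau_a_max <= 0)
    stop("calibration failed: fitted saturation torque is non-positive",
         call. = FALSE)
  list(tau_a_max = tau_a_max,
       vel_lim = best$a,
       vel_max = best$b,
       slope = best$s,
       intercept = -best$s * best$a,
       rmse = sqrt(best$sse / n))
}

#' Build calibration traces from a capture set
#'
#' Turns each capture into a (abscissa, force) trace: flexion angle against
#' measured chest force for passive captures, ascent speed against measured
#' chest force on activated ascending frames for active captures. Traces are
#' grouped by assistance percentage.
#'
#' @param capture_set A list of elements with `capture`, `eta_p`, `eta_a`,
#'   `mode` (as from [generate_capture_set()]).
#' @param mode `"passive"` or `"active"`: which channel to trace.
#' @param psi_a Activation angle used to mask active frames, degrees.
#' @param median_window Optional odd window (frames) for median-filter
#'   cleaning of the measured force; 0 disables.
#' @return A named list (one element per percentage) of lists of traces.
#' @export
calibration_traces <- function(capture_set, mode = c("passive", "active"),
                               psi_a = 30, median_window = 0L) {
  mode <- match.arg(mode)
  out <- list()
  for (item in capture_set) {
    pct <- if (mode == "passive") item$eta_p else item$eta_a
    cap <- item$capture
    if (!"measured_force" %in% names(cap))
      stop("captures must carry a measured force channel", call. = FALSE)
    force <- cap$measured_force
    if (median_window >= 3L)
      force <- stats::runmed(force, k = median_window, endrule = "keep")
    tr <- if (mode == "passive") {
      data.frame(abscissa = cap$theta_c, force = force)
    } else {
      ann <- segment_phases(cap)
      keep <- activation_mask(ann, psi_a)
      # anchor the zero section: keep pre-threshold ascending frames too
      keep <- keep | ann$phase == "ascend"
      data.frame(abscissa = ann$ascent_speed[keep], force = force[keep])
    }
    key <- as.character(pct)
    out[[key]] <- c(out[[key]], list(tr))
  }
  out
}

#' Calibrate a full specification from a capture set
#'
#' The end-to-end model-development step: group captures by percentage,
#' average the traces per percentage, extract passive and active anchors,
#' scale them to every percentage and assemble the calibrated specification.
#'
#' @param passive_set,active_set Capture sets for the two modes (either may
#'   be `NULL`); see [generate_capture_set()].
#' @param characteristic_angles The five characteristic flexion angles, deg.
#' @param assistance An [assistance_config()] (selected percentages and the
#'   activation angle).
#' @param body A [body_dimensions()].
#' @param device_weight Device weight, kgf.
#' @param shoulder_fraction Shoulder share of the device weight.
#' @param median_window Median-filter cleaning window (frames), 0 disables.
#' @return A list of class `calibration_result` with `spec` (the calibrated
#'   [exoskeleton_spec()]), `passive_anchors`, `passive_ratios`,
#'   `active_anchors` (data.frame with fit residuals), and `curves` (the
#'   averaged curves per percentage and mode).
#' @export
calibrate_from_captures <- function(passive_set = NULL, active_set = NULL,
                                    characteristic_angles,
                                    assistance, body,
                                    device_weight = 0, shoulder_fraction = 0.5,
                                    median_window = 0L) {
  stopifnot(inherits(assistance, "assistance_config"),
            inherits(body, "body_dimensions"))
  if (is.null(passive_set))
    stop("passive captures are required (the passive table anchors the model)",
         call. = FALSE)
  curves <- list(passive = list(), active = list())
  p_traces <- calibration_traces(passive_set, "passive",
                                 psi_a = assistance$psi_a,
                                 median_window = median_window)
  p_anchors <- numeric(0)
  ratio_acc <- NULL
  for (pct in names(p_traces)) {
    cv <- normalize_and_average(p_traces[[pct]], grid = "union")
    curves$passive[[pct]] <- cv
    a <- extract_passive_anchor(cv, characteristic_angles, body$d_tt)
    p_anchors[pct] <- a$tau_max
    ratio_acc <- rbind(ratio_acc, a$torque_ratios)
  }
  # the ratio vector is shared across percentages; average the per-percentage
  # estimates (identical in the noise-free limit)
  ratios <- colMeans(ratio_acc)
  ratios <- pmin(pmax(ratios, 0), 1)
  ratios <- cummax(ratios)     # enforce monotone non-decreasing estimates
  ratios[length(ratios)] <- 1
  a_anchors <- NULL
  if (!is.null(active_set)) {
    a_traces <- calibration_traces(active_set, "active",
                                   psi_a = assistance$psi_a,
                                   median_window = median_window)
    for (pct in names(a_traces)) {
      cv <- normalize_and_average(a_traces[[pct]], grid = "union")
      curves$active[[pct]] <- cv
      fit <- extract_active_anchor(cv, body$d_tt)
      a_anchors <- rbind(a_anchors,
                         data.frame(eta = as.integer(pct),
                                    tau_a_max = fit$tau_a_max,
                                    vel_lim = fit$vel_lim,
                                    vel_max = fit$vel_max,
                                    rmse = fit$rmse))
    }
  }
  spec <- build_spec(p_anchors, ratios, characteristic_angles,
                     active_anchors = a_anchors,
                     assistance = assistance, body = body,
                     device_weight = device_weight,
                     shoulder_fraction = shoulder_fraction)
  structure(list(spec = spec,
                 passive_anchors = p_anchors,
                 passive_ratios = ratios,
                 active_anchors = a_anchors,
                 curves = curves),
            class = "calibration_result")
}

#' Assemble a full exoskeleton specification from calibrated anchors
#'
#' Scales the passive and active anchors to every assistance percentage and
#' bundles the result with activation angle, body dimensions and device
#' weight. Passive-only calibration yields an all-zero active table.
#'
#' @param passive_anchors Named numeric vector of per-side maximum torques
#'   keyed by anchor percentage (from [extract_passive_anchor()]).
#' @param torque_ratios The shared length-5 ratio vector.
#' @param characteristic_angles The five characteristic angles, degrees.
#' @param active_anchors Optional data.frame with columns `eta`, `tau_a_max`,
#'   `vel_lim`, `vel_max` (from [extract_active_anchor()]); `NULL` for a
#'   passive-only device.
#' @param assistance An [assistance_config()] (also carries `psi_a`).
#' @param body A [body_dimensions()].
#' @param device_weight Device weight, kgf.
#' @param shoulder_fraction Shoulder share of the device weight.
#' @return An [exoskeleton_spec()].
#' @export
build_spec <- function(passive_anchors, torque_ratios, characteristic_angles,
                       active_anchors = NULL, assistance, body,
                       device_weight = 0, shoulder_fraction = 0.5) {
  tau_map <- scale_passive_percentages(passive_anchors)
  passive <- passive_keypoint_table(characteristic_angles, torque_ratios, tau_map)
  if (is.null(active_anchors)) {
    full <- valid_percentages()
    active <- active_keypoint_table(
      data.frame(eta = full, tau_a_max = 0, vel_lim = 0, slope = 0, intercept = 0))
  } else {
    active <- scale_active_percentages(active_anchors)
  }
  exoskeleton_spec(passive, active, assistance, body,
                   device_weight = device_weight,
                   shoulder_fraction = shoulder_fraction)
}
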