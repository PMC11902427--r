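# Parametric torque model of a lumbar exoskeleton with combined passive
# (angle-dependent) and active (ascent-velocity-dependent) assistance.
#
# The passive curve family is pinned by a keypoint table: five characteristic
# flexion angles, five torque ratios (fractions of the maximum torque), and a
# per-percentage maximum torque. The active family is one row per assistance
# percentage: [tau_a_max, vel_lim, slope, intercept], a hinge law that is zero
# below the velocity threshold, affine up to the saturation velocity, and
# constant above it.

#' Assistance configuration
#'
#' The user-facing setting of the device: a passive percentage, an active
#' percentage (each 0-100 in steps of ten, as the device UI enforces) and the
#' activation angle above which rising motion can trigger active assistance.
#'
#' @param eta_p Passive assistance percentage (multiple of ten in 0-100).
#' @param eta_a Active assistance percentage (multiple of ten in 0-100).
#' @param psi_a Activation angle in degrees of lumbar flexion; active
#'   assistance only engages when ascending from a flexion beyond this angle.
#' @return An object of class `assistance_config`.
#' @export
assistance_config <- function(eta_p = 0, eta_a = 0, psi_a = 30) {
  eta_p <- check_percentage(eta_p, "eta_p")
  eta_a <- check_percentage(eta_a, "eta_a")
  stopifnot(is.numeric(psi_a), length(psi_a) == 1L, is.finite(psi_a), psi_a >= 0)
  structure(list(eta_p = eta_p, eta_a = eta_a, psi_a = as.numeric(psi_a)),
            class = "assistance_config")
}

#' Passive keypoint table
#'
#' Compact parameterization of the passive torque-curve family: five
#' characteristic flexion angles, the torque at each expressed as a fraction
#' of the maximum torque, and a mapping from assistance percentage to the
#' per-side maximum torque. A single ratio vector is shared across
#' percentages; only the maximum torque scales.
#'
#' @param characteristic_angles Strictly increasing vector of 5 flexion
#'   angles, degrees.
#' @param torque_ratios Non-decreasing vector of 5 fractions in \[0, 1\]; the
#'   last must equal 1 (the curve reaches its maximum at the last
#'   characteristic angle).
#' @param tau_max Named numeric vector mapping percentage ("0" ... "100") to
#'   per-side maximum torque in N*m; must be non-decreasing in the percentage
#'   and zero at 0.
#' @return An object of class `passive_keypoint_table`.
#' @export
passive_keypoint_table <- function(characteristic_angles, torque_ratios, tau_max) {
  characteristic_angles <- as.numeric(characteristic_angles)
  torque_ratios <- as.numeric(torque_ratios)
  if (length(characteristic_angles) != 5L || length(torque_ratios) != 5L)
    stop("exactly five characteristic angles and five torque ratios are required",
         call. = FALSE)
  if (any(!is.finite(characteristic_angles)) || any(diff(characteristic_angles) <= 0))
    stop("characteristic angles must be finite and strictly increasing", call. = FALSE)
  if (any(!is.finite(torque_ratios)) || any(torque_ratios < 0) || any(torque_ratios > 1))
    stop("torque ratios must lie in [0, 1]", call. = FALSE)
  if (any(diff(torque_ratios) < 0))
    stop("torque ratios must be non-decreasing: the device provides progressively greater force with flexion",
         call. = FALSE)
  if (abs(torque_ratios[5L] - 1) > 1e-12)
    stop("the torque ratio at the last characteristic angle must equal 1", call. = FALSE)
  tau_max <- check_tau_max_map(tau_max, "tau_max")
  structure(list(characteristic_angles = characteristic_angles,
                 torque_ratios = torque_ratios,
                 tau_max = tau_max),
            class = "passive_keypoint_table")
}

check_tau_max_map <- function(tau_max, what) {
  if (is.null(names(tau_max)) || any(!nzchar(names(tau_max))))
    stop(sprintf("%s must be a named vector keyed by percentage", what), call. = FALSE)
  pct <- as.integer(names(tau_max))
  if (anyNA(pct) || any(!(pct %in% valid_percentages())))
    stop(sprintf("%s percentages must be multiples of ten in 0-100", what), call. = FALSE)
  o <- order(pct)
  tau_max <- as.numeric(tau_max)[o]
  pct <- pct[o]
  if (any(!is.finite(tau_max)) || any(tau_max < 0))
    stop(sprintf("%s values must be finite and non-negative", what), call. = FALSE)
  if (any(diff(tau_max) < 0))
    stop(sprintf("%s must be non-decreasing in the percentage", what), call. = FALSE)
  if (0L %in% pct && tau_max[pct == 0L] != 0)
    stop(sprintf("%s at percentage 0 must be 0", what), call. = FALSE)
  stats::setNames(tau_max, pct)
}

#' Active keypoint table
#'
#' One row per assistance percentage of the active hinge law:
#' `tau_a_max` (saturation torque, N*m per side), `vel_lim` (ascent-speed
#' threshold, deg/s), `slope` (N*m per deg/s) and `intercept` (N*m). The line
#' `slope * v + intercept` passes through `(vel_lim, 0)`; the saturation speed
#' `vel_max = (tau_a_max - intercept) / slope` is derived.
#'
#' @param rows A data.frame with columns `eta`, `tau_a_max`, `vel_lim`,
#'   `slope`, `intercept`; one row per percentage.
#' @return An object of class `active_keypoint_table` (the validated
#'   data.frame, with a derived `vel_max` column).
#' @export
active_keypoint_table <- function(rows) {
  need <- c("eta", "tau_a_max", "vel_lim", "slope", "intercept")
  if (!is.data.frame(rows) || !all(need %in% names(rows)))
    stop("rows must be a data.frame with columns eta, tau_a_max, vel_lim, slope, intercept",
         call. = FALSE)
  rows <- rows[order(rows$eta), need]
  if (any(!(rows$eta %in% valid_percentages())) || anyDuplicated(rows$eta))
    stop("eta must be distinct multiples of ten in 0-100", call. = FALSE)
  if (any(rows$tau_a_max < 0) || any(diff(rows$tau_a_max) < 0))
    stop("tau_a_max must be non-negative and non-decreasing in eta", call. = FALSE)
  if (any(rows$eta == 0L & rows$tau_a_max != 0))
    stop("tau_a_max at eta = 0 must be 0", call. = FALSE)
  if (any(rows$vel_lim < 0))
    stop("vel_lim must be non-negative", call. = FALSE)
  active <- rows$tau_a_max > 0
  if (any(active & rows$slope <= 0))
    stop("slope must be positive wherever tau_a_max > 0", call. = FALSE)
  ic <- -rows$slope * rows$vel_lim
  if (any(abs(rows$intercept - ic) > 1e-9 * pmax(1, abs(ic))))
    stop("intercept must equal -slope * vel_lim (the line passes through (vel_lim, 0))",
         call. = FALSE)
  rows$vel_max <- ifelse(active,
                         (rows$tau_a_max - rows$intercept) / rows$slope,
                         rows$vel_lim)
  if (any(active & rows$vel_max <= rows$vel_lim))
    stop("derived vel_max must exceed vel_lim", call. = FALSE)
  rownames(rows) <- NULL
  structure(rows, class = c("active_keypoint_table", "data.frame"))
}

#' Full exoskeleton specification
#'
#' Bundles the calibrated passive and active keypoint tables with the selected
#' assistance configuration, the wearer's lever-arm dimensions and the device
#' weight. Total device torque is the sum of the two modes.
#'
#' @param passive_table A [passive_keypoint_table()].
#' @param active_table An [active_keypoint_table()].
#' @param assistance An [assistance_config()].
#' @param body A [body_dimensions()].
#' @param device_weight Device weight in kgf (>= 0).
#' @param shoulder_fraction Fraction of the device weight carried at the
#'   shoulders, the remainder at the pelvis.
#' @return An object of class `exoskeleton_spec`.
#' @export
exoskeleton_spec <- function(passive_table, active_table, assistance, body,
                             device_weight = 0, shoulder_fraction = 0.5) {
  stopifnot(inherits(passive_table, "passive_keypoint_table"),
            inherits(active_table, "active_keypoint_table"),
            inherits(assistance, "assistance_config"),
            inherits(body, "body_dimensions"))
  stopifnot(is.numeric(device_weight), length(device_weight) == 1L,
            is.finite(device_weight), device_weight >= 0)
  stopifnot(is.numeric(shoulder_fraction), length(shoulder_fraction) == 1L,
            shoulder_fraction >= 0, shoulder_fraction <= 1)
  structure(list(passive_table = passive_table,
                 active_table = active_table,
                 assistance = assistance,
                 body = body,
                 device_weight = as.numeric(device_weight),
                 shoulder_fraction = as.numeric(shoulder_fraction)),
            class = "exoskeleton_spec")
}

lookup_tau_max <- function(table, eta_p) {
  eta_p <- check_percentage(eta_p, "eta_p")
  key <- as.character(eta_p)
  if (!key %in% names(table$tau_max))
    stop(sprintf("no maximum torque calibrated for eta_p = %d; run scale_passive_percentages()",
                 eta_p), call. = FALSE)
  unname(table$tau_max[key])
}

lookup_active_row <- function(table, eta_a) {
  eta_a <- check_percentage(eta_a, "eta_a")
  i <- match(eta_a, table$eta)
  if (is.na(i))
    stop(sprintf("no active row for eta_a = %d; run scale_active_percentages()", eta_a),
         call. = FALSE)
  table[i, ]
}

#' Passive assistance torque at a flexion angle
#'
#' Evaluates the passive torque curve for one assistance percentage: a
#' shape-preserving (monotone Hermite) spline through the five keypoints
#' `(angle_i, ratio_i * tau_max)`, evaluated section by section. Below the
#' first characteristic angle the torque is held at the first keypoint's value
#' (zero when the first ratio is zero); beyond the last angle it is clamped at
#' the maximum torque.
#'
#' @param theta_c Lumbar flexion angle(s), degrees (0 = upright, vectorized).
#' @param table A [passive_keypoint_table()].
#' @param eta_p Passive assistance percentage.
#' @return Per-side torque in N*m, same length as `theta_c`.
#' @export
passive_torque <- function(theta_c, table, eta_p) {
  stopifnot(inherits(table, "passive_keypoint_table"))
  if (any(!is.finite(theta_c))) stop("theta_c must be finite", call. = FALSE)
  tmax <- lookup_tau_max(table, eta_p)
  if (tmax == 0) return(numeric(length(theta_c)) )
  ang <- table$characteristic_angles
  tau <- table$torque_ratios * tmax
  # monoH.FC preserves monotonicity between monotone knots (no overshoot)
  f <- stats::splinefun(ang, tau, method = "monoH.FC")
  out <- f(theta_c)
  out[theta_c <= ang[1L]] <- tau[1L]
  out[theta_c >= ang[5L]] <- tau[5L]
  out
}

#' Active assistance torque at an ascent speed
#'
#' The piecewise-linear active law: zero below the velocity threshold, affine
#' through `(vel_lim, 0)` and `(vel_max, tau_a_max)` in between, and constant
#' at `tau_a_max` above the saturation speed.
#'
#' @param ascent_speed Non-negative magnitude of trunk extension velocity,
#'   deg/s (vectorized). Zero while descending or holding; callers rectify the
#'   sign upstream.
#' @param table An [active_keypoint_table()].
#' @param eta_a Active assistance percentage.
#' @return Per-side torque in N*m.
#' @export
active_torque <- function(ascent_speed, table, eta_a) {
  stopifnot(inherits(table, "active_keypoint_table"))
  if (any(!is.finite(ascent_speed)) || any(ascent_speed < 0))
    stop("ascent_speed must be a non-negative magnitude (rectify the sign upstream)",
         call. = FALSE)
  row <- lookup_active_row(table, eta_a)
  if (row$tau_a_max == 0) return(numeric(length(ascent_speed)))
  out <- row$slope * ascent_speed + row$intercept
  out[ascent_speed < row$vel_lim] <- 0
  out[ascent_speed > row$vel_max] <- row$tau_a_max
  out
}

#' Total exoskeleton torque
#'
#' Sum of the passive and active contributions, `tau_E = tau_P + tau_A`. The
#' active term only contributes on frames where the activation rule holds
#' (ascending from a flexion beyond the activation angle), signalled by
#' `active_enabled`.
#'
#' @param theta_c Lumbar flexion angle(s), degrees.
#' @param ascent_speed Ascent-speed magnitude(s), deg/s.
#' @param active_enabled Logical (recycled): whether active assistance is
#'   engaged on each frame.
#' @param spec An [exoskeleton_spec()].
#' @return Per-side torque in N*m.
#' @export
total_torque <- function(theta_c, ascent_speed, active_enabled, spec) {
  stopifnot(inherits(spec, "exoskeleton_spec"))
  n <- max(length(theta_c), length(ascent_speed), length(active_enabled))
  theta_c <- rep_len(theta_c, n)
  ascent_speed <- rep_len(ascent_speed, n)
  active_enabled <- rep_len(as.logical(active_enabled), n)
  tp <- passive_torque(theta_c, spec$passive_table, spec$assistance$eta_p)
  ta <- active_torque(ascent_speed, spec$active_table, spec$assistance$eta_a)
  tp + ifelse(active_enabled, ta, 0)
}

#' Complete the passive maximum-torque map from calibrated anchors
#'
#' Maximum torques are calibrated at a few percentages (typically 100, 70 and
#' 40); the remaining multiples of ten are filled by distributing the
#' difference between adjacent anchors evenly across the intermediate steps.
#' Below the lowest anchor the torque is distributed evenly down to zero at
#' 0%; above the highest anchor the last even spacing is continued.
#'
#' @param anchors Named numeric vector mapping anchor percentage to per-side
#'   maximum torque, N*m; must be non-decreasing in the percentage.
#' @return Named numeric vector over all percentages 0, 10, ..., 100.
#' @export
scale_passive_percentages <- function(anchors) {
  anchors <- check_tau_max_map(anchors, "anchors")
  pct <- as.integer(names(anchors))
  # implicit zero-assistance anchor: no torque at 0 %
  if (!0L %in% pct) {
    pct <- c(0L, pct)
    anchors <- c(0, anchors)
  }
  full <- valid_percentages()
  vals <- stats::approx(pct, anchors, xout = full, rule = 2)$y
  # continue the last segment's even spacing beyond the highest anchor
  top <- max(pct)
  if (top < 100L && length(pct) >= 2L) {
    slope <- (anchors[length(anchors)] - anchors[length(anchors) - 1L]) /
      (pct[length(pct)] - pct[length(pct) - 1L])
    above <- full > top
    vals[above] <- anchors[length(anchors)] + slope * (full[above] - top)
  }
  # anchors must round-trip bit-exactly, untouched by interpolation arithmetic
  vals[match(pct, full)] <- anchors
  stats::setNames(vals, full)
}

#' Complete the active keypoint table from calibrated anchor rows
#'
#' Saturation torques and both velocity thresholds are interpolated evenly
#' between the calibrated anchors for every multiple of ten; each generated
#' row's slope and intercept are then recomputed from its own line through
#' `(vel_lim, 0)` and `(vel_max, tau_a_max)`.
#'
#' @param anchor_rows A data.frame with columns `eta`, `tau_a_max`, `vel_lim`,
#'   `vel_max` at the calibrated percentages.
#' @return A complete [active_keypoint_table()] with one row per percentage
#'   0, 10, ..., 100.
#' @export
scale_active_percentages <- function(anchor_rows) {
  need <- c("eta", "tau_a_max", "vel_lim", "vel_max")
  if (!is.data.frame(anchor_rows) || !all(need %in% names(anchor_rows)))
    stop("anchor_rows must have columns eta, tau_a_max, vel_lim, vel_max", call. = FALSE)
  a <- anchor_rows[order(anchor_rows$eta), need]
  if (any(!(a$eta %in% valid_percentages())) || anyDuplicated(a$eta))
    stop("anchor percentages must be distinct multiples of ten", call. = FALSE)
  if (any(diff(a$tau_a_max) < 0))
    stop("tau_a_max must be non-decreasing in eta", call. = FALSE)
  if (any(a$vel_max <= a$vel_lim))
    stop("each anchor needs vel_max > vel_lim (degenerate hinge)", call. = FALSE)
  full <- valid_percentages()
  interp_even <- function(y, zero_at_0) {
    x <- a$eta
    if (!0L %in% x) {
      x <- c(0L, x)
      y <- c(if (zero_at_0) 0 else y[1L], y)
    }
    out <- stats::approx(x, y, xout = full, rule = 2)$y
    top <- max(x)
    if (top < 100L && length(x) >= 2L) {
      slope <- (y[length(y)] - y[length(y) - 1L]) / (x[length(x)] - x[length(x) - 1L])
      above <- full > top
      out[above] <- y[length(y)] + slope * (full[above] - top)
    }
    out[match(x, full)] <- y
    out
  }
  tau <- interp_even(a$tau_a_max, zero_at_0 = TRUE)
  vlim <- interp_even(a$vel_lim, zero_at_0 = FALSE)
  vmax <- interp_even(a$vel_max, zero_at_0 = FALSE)
  if (any(vmax <= vlim))
    stop("interpolated rows are degenerate (vel_max <= vel_lim)", call. = FALSE)
  slope <- ifelse(tau > 0, tau / (vmax - vlim), 0)
  rows <- data.frame(eta = full,
                     tau_a_max = tau,
                     vel_lim = vlim,
                     slope = slope,
                     intercept = -slope * vlim)
  active_keypoint_table(rows)
}

#' @export
print.exoskeleton_spec <- function(x, ...) {
  cat("Exoskeleton specification\n")
  cat(sprintf("  assistance: passive %d%% / active %d%%, activation angle %.1f deg\n",
              x$assistance$eta_p, x$assistance$eta_a, x$assistance$psi_a))
  cat(sprintf("  levers: D_TT %.3f m, D_MT %.3f m; device weight %.2f kgf\n",
              x$body$d_tt, x$body$d_mt, x$device_weight))
  cat(sprintf("  passive tau_max at 100%%: %.2f N*m; active tau_a_max at 100%%: %.2f N*m\n",
              lookup_tau_max(x$passive_table, 100),
              lookup_active_row(x$active_table, 100)$tau_a_max))
  invisible(x)
}
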