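# Ergonomic risk recomputation in the style of motion-capture risk methods:
# per-posture scores (angle, angular acceleration, force, torque, grip) are
# combined into per-posture risks whose sum, scaled by the task repetition
# rate, is the "risk per minute" percentage with green/yellow/red bands.
#
# The score functions of the underlying commercial method are not
# public; this module ships documented surrogate score maps (piecewise-linear,
# monotone, non-negative) exposed entirely through configuration. The part
# the package contributes -- recomputing force- and torque-derived scores
# under exoskeleton assistance while every other score stays fixed -- is
# independent of the particular maps.

#' Default risk scoring configuration
#'
#' Surrogate per-posture score maps and weights. Each map is a monotone
#' piecewise-linear function given as `x` (input, physical units) and `score`
#' breakpoints; inputs beyond the last breakpoint are clamped. All properties
#' the package guarantees (assistance monotonicity, fixed non-force factors)
#' hold for any monotone non-negative replacement.
#'
#' @param trunk_mass Trunk mass used by the gravitational demand surrogate, kg.
#' @param trunk_com_distance Sagittal distance from the lumbar joint to the
#'   trunk center of mass, m.
#' @param hand_load Mass carried in the hands, kg.
#' @param hand_lever Sagittal lever of the hand load about the lumbar joint, m.
#' @param repetitions_per_minute Task repetition rate used to scale the summed
#'   per-posture risks.
#' @return A list of class `risk_config`.
#' @export
risk_config <- function(trunk_mass = 35, trunk_com_distance = 0.25,
                        hand_load = 0, hand_lever = 0.4,
                        repetitions_per_minute = 1) {
  stopifnot(trunk_mass > 0, trunk_com_distance > 0, hand_load >= 0,
            hand_lever >= 0, repetitions_per_minute > 0)
  structure(list(
    trunk_mass = trunk_mass,
    trunk_com_distance = trunk_com_distance,
    hand_load = hand_load,
    hand_lever = hand_lever,
    repetitions_per_minute = repetitions_per_minute,
    # score maps: input -> dimensionless score, monotone non-decreasing
    maps = list(
      angle = list(x = c(0, 20, 45, 90, 120), score = c(0, 1, 2, 4, 6)),
      acceleration = list(x = c(0, 50, 200, 600), score = c(0, 0.5, 1.5, 3)),
      force = list(x = c(0, 25, 75, 150, 300), score = c(0, 1, 3, 6, 10)),
      torque = list(x = c(0, 25, 75, 150, 300), score = c(0, 1, 2.5, 5, 8)),
      grip = list(x = c(0, 1), score = c(0, 0))
    ),
    weights = c(angle = 1, acceleration = 1, force = 1, torque = 1, grip = 1),
    # risk-per-minute normalization: summed weighted scores per frame are
    # averaged over the capture and scaled to a percentage
    score_to_pct = 2.5
  ), class = "risk_config")
}

apply_score_map <- function(map, x) {
  stats::approx(map$x, map$score, xout = pmin(pmax(x, min(map$x)), max(map$x)),
                rule = 2)$y
}

#' Gravitational lumbar moment demand
#'
#' Static sagittal-plane surrogate for the lumbar extension moment the trunk
#' musculature must supply: trunk weight and any hand-held load acting at
#' their levers, projected by the sine of the flexion angle.
#'
#' @param capture A [capture_series()].
#' @param config A [risk_config()] (supplies anthropometrics and load).
#' @return Per-frame lumbar moment demand, N*m.
#' @export
lumbar_demand <- function(capture, config = risk_config()) {
  stopifnot(inherits(capture, "capture_series"), inherits(config, "risk_config"))
  lever_term <- config$trunk_mass * G_STANDARD * config$trunk_com_distance +
    config$hand_load * G_STANDARD * config$hand_lever
  lever_term * sin(pmax(capture$theta_c, 0) * pi / 180)
}

#' Reduce the lumbar demand by the exoskeleton's assistance
#'
#' Subtracts the total device torque from the gravitational demand frame by
#' frame, clamped at zero (the device is not modeled as loading the joint
#' beyond its demand). Only force- and torque-derived scores downstream see
#' the assisted demand; all other scores are computed from the unchanged
#' kinematics.
#'
#' @param demand Per-frame lumbar moment demand, N*m.
#' @param exo_torque Per-frame total device torque (both sides), N*m.
#' @return Assisted demand series, N*m.
#' @export
recompute_with_exo <- function(demand, exo_torque) {
  if (length(demand) != length(exo_torque))
    stop("demand and exo_torque must have equal length", call. = FALSE)
  pmax(0, demand - exo_torque)
}

#' Per-frame posture scores
#'
#' Evaluates the five score maps on a capture: angle and angular-acceleration
#' scores from the kinematics, force and torque scores from the (possibly
#' assistance-reduced) lumbar demand, and the grip score from the hand load.
#'
#' @param capture A [capture_series()].
#' @param demand Per-frame lumbar demand, N*m (assisted or unassisted).
#' @param config A [risk_config()].
#' @return A data.frame of class `posture_scores` with one row per frame and
#'   columns `angle_score`, `angular_acceleration_score`, `force_score`,
#'   `torque_score`, `grip_score`.
#' @export
posture_scores <- function(capture, demand, config = risk_config()) {
  stopifnot(inherits(capture, "capture_series"), inherits(config, "risk_config"),
            length(demand) == nrow(capture))
  fs <- attr(capture, "sample_rate")
  v <- estimate_velocity(capture)
  acc <- c(0, diff(v)) * fs
  # force surrogate: compressive-equivalent load at the lumbar lever
  f_equiv <- demand / max(config$trunk_com_distance, 1e-9)
  structure(data.frame(
    angle_score = apply_score_map(config$maps$angle, capture$theta_c),
    angular_acceleration_score = apply_score_map(config$maps$acceleration, abs(acc)),
    force_score = apply_score_map(config$maps$force, f_equiv),
    torque_score = apply_score_map(config$maps$torque, demand),
    grip_score = apply_score_map(config$maps$grip,
                                 rep(config$hand_load, nrow(capture)))
  ), class = c("posture_scores", "data.frame"))
}

#' Risk per minute from posture scores
#'
#' Per-posture risk is the weighted sum of the five scores, normalized by the
#' number of postures and scaled by the configured score-to-percent factor
#' and the task repetition rate. The capture-level risk percentage is exactly
#' the sum of the per-posture risks, then banded green/yellow/red.
#'
#' @param scores A [posture_scores()] data.frame.
#' @param config A [risk_config()].
#' @param duration Capture duration in seconds (informational; risk is
#'   per-repetition-normalized, not per-sample).
#' @return A list of class `risk_result` with `risk_per_minute` (percentage),
#'   `per_posture_risks`, and `color_band`.
#' @export
risk_per_minute <- function(scores, config = risk_config(), duration = NULL) {
  stopifnot(inherits(scores, "posture_scores"), inherits(config, "risk_config"))
  w <- config$weights
  if (any(w < 0)) stop("score weights must be non-negative", call. = FALSE)
  weighted <- w["angle"] * scores$angle_score +
    w["acceleration"] * scores$angular_acceleration_score +
    w["force"] * scores$force_score +
    w["torque"] * scores$torque_score +
    w["grip"] * scores$grip_score
  # fold normalization and repetition scaling into the per-posture risks so
  # the capture risk is exactly their sum
  per_posture <- weighted * config$score_to_pct *
    config$repetitions_per_minute / length(weighted)
  risk <- sum(per_posture)
  structure(list(risk_per_minute = unname(risk),
                 per_posture_risks = unname(per_posture),
                 color_band = color_band(risk)),
            class = "risk_result")
}

#' Traffic-light band for a risk percentage
#'
#' Green below 25, yellow from 25 up to (not including) 40, red at 40 and
#' above.
#'
#' @param risk Risk percentage(s), >= 0.
#' @return Character vector in `c("green", "yellow", "red")`.
#' @export
color_band <- function(risk) {
  stopifnot(all(is.finite(risk)), all(risk >= 0))
  ifelse(risk >= 40, "red", ifelse(risk >= 25, "yellow", "green"))
}

#' Capture-level lumbar risk, with or without the exoskeleton
#'
#' End-to-end risk evaluation of a capture: gravitational demand, optional
#' assistance reduction, posture scores and the banded risk-per-minute
#' figure. With assistance, only the force and torque scores change; the
#' angle, acceleration and grip scores are identical to the unassisted run.
#'
#' @param capture A [capture_series()].
#' @param exo_torque Optional per-frame total device torque (both sides),
#'   N*m; `NULL` evaluates the unassisted task.
#' @param config A [risk_config()].
#' @return A `risk_result` with the `posture_scores` attached as attribute
#'   `scores`.
#' @export
lumbar_risk <- function(capture, exo_torque = NULL, config = risk_config()) {
  demand <- lumbar_demand(capture, config)
  if (!is.null(exo_torque)) demand <- recompute_with_exo(demand, exo_torque)
  sc <- posture_scores(capture, demand, config)
  res <- risk_per_minute(sc, config)
  attr(res, "scores") <- sc
  res
}

#' @export
print.risk_result <- function(x, ...) {
  cat(sprintf("Lumbar risk per minute: %.2f%% [%s]\n",
              x$risk_per_minute, x$color_band))
  invisible(x)
}
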