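# Sagittal-plane statics: resolve the exoskeleton torque into the contact
# forces of the free body diagram and transfer pad forces (with their induced
# couples) to skeletal reference points.
#
# The device is treated as a bilaterally symmetric, planar force system. Per
# side the torque tau_E appears at the hip; the chest pad reacts at lever
# d_tt above the trochanter, the leg pad at d_mt below, and a pelvis push
# force closes the horizontal balance of the device.

#' Body lever-arm dimensions
#'
#' @param d_tt Distance from the trochanter to the center of the chest pad, m.
#' @param d_mt Distance from the trochanter to the leg pad, m.
#' @return An object of class `body_dimensions`.
#' @export
body_dimensions <- function(d_tt, d_mt) {
  stopifnot(is.numeric(d_tt), is.numeric(d_mt),
            length(d_tt) == 1L, length(d_mt) == 1L)
  if (!is.finite(d_tt) || !is.finite(d_mt) || d_tt <= 0 || d_mt <= 0)
    stop("lever arms d_tt and d_mt must be positive and finite", call. = FALSE)
  structure(list(d_tt = as.numeric(d_tt), d_mt = as.numeric(d_mt)),
            class = "body_dimensions")
}

#' Resolve exoskeleton torque into body contact forces
#'
#' Per side, the chest force is `tau_E / d_tt` and the leg-pad reaction
#' `tau_E / d_mt` (lever-arm division); the pelvis push force is the residual
#' that closes the horizontal force balance of the device free body,
#' `f_r = f_c + f_lg`. The device weight is split between shoulders and
#' pelvis by `shoulder_fraction`.
#'
#' @param tau_e_per_side Per-side torque(s), N*m (vectorized over frames).
#' @param body A [body_dimensions()].
#' @param device_weight Device weight, kgf.
#' @param shoulder_fraction Fraction of the weight carried at the shoulders.
#' @return An object of class `exo_force_state`: a data.frame with per-frame
#'   per-side forces `f_c`, `f_lg`, `f_r` (N), the transfer couples `t_c`,
#'   `t_k` (N*m) about the nearest skeletal reference, and the weight shares
#'   `w_e_shoulder`, `w_e_pelvis` (N) as attributes-carrying columns.
#' @export
resolve_forces <- function(tau_e_per_side, body, device_weight = 0,
                           shoulder_fraction = 0.5) {
  stopifnot(inherits(body, "body_dimensions"),
            is.numeric(tau_e_per_side), all(is.finite(tau_e_per_side)),
            is.finite(device_weight), device_weight >= 0,
            shoulder_fraction >= 0, shoulder_fraction <= 1)
  tau <- as.numeric(tau_e_per_side)
  f_c <- tau / body$d_tt
  f_lg <- tau / body$d_mt
  f_r <- f_c + f_lg
  w <- kgf_to_n(device_weight)
  st <- data.frame(tau_e_per_side = tau,
                   f_c = f_c, f_lg = f_lg, f_r = f_r,
                   t_c = f_c * 0,   # filled by transfer_to_joint when offsets known
                   t_k = f_lg * 0,
                   w_e_shoulder = rep(shoulder_fraction * w, length(tau)),
                   w_e_pelvis = rep((1 - shoulder_fraction) * w, length(tau)))
  structure(st, body = body, device_weight_n = w,
            class = c("exo_force_state", "data.frame"))
}

#' Total chest force in kilogram-force
#'
#' Sums the left and right chest-pad forces (the quantity the two load cells
#' measure together) and converts to kgf for comparison with load-cell data.
#'
#' @param state An [resolve_forces()] result.
#' @return Chest force in kgf, one value per frame.
#' @export
chest_force_total <- function(state) {
  stopifnot(inherits(state, "exo_force_state"))
  n_to_kgf(2 * state$f_c)
}

#' Transfer a pad force to a joint reference point
#'
#' Replaces a force applied at a pad by the statically equivalent system at a
#' joint: the same force plus a couple equal to the planar cross product of
#' the offset and the force. Used for the chest-to-sternum and leg-pad-to-knee
#' transfers.
#'
#' @param force Length-2 numeric `(fx, fy)` in N, or a scalar treated as a
#'   force perpendicular to the offset.
#' @param pad_offset Length-2 numeric `(ox, oy)` in m from the joint to the
#'   pad, or a scalar offset perpendicular to a scalar force.
#' @return A list with `force` (unchanged) and `couple` (N*m, scalar moment
#'   about the out-of-plane axis).
#' @export
transfer_to_joint <- function(force, pad_offset) {
  stopifnot(is.numeric(force), is.numeric(pad_offset),
            all(is.finite(force)), all(is.finite(pad_offset)))
  if (length(force) == 1L && length(pad_offset) == 1L) {
    couple <- pad_offset * force
  } else if (length(force) == 2L && length(pad_offset) == 2L) {
    couple <- pad_offset[1L] * force[2L] - pad_offset[2L] * force[1L]
  } else {
    stop("force and pad_offset must both be scalars or both length-2 vectors",
         call. = FALSE)
  }
  list(force = force, couple = couple)
}

#' Net force and moment residual of the device free body
#'
#' Rebuilds the full planar action-reaction set the body exerts on the device
#' (chest, leg-pad and pelvis reactions on both sides, shoulder and pelvis
#' weight supports, gravity) from a force state and returns the net force and
#' net moment about the trochanter. For a consistent state both are zero up to
#' floating-point error; used as the equilibrium diagnostic.
#'
#' @param state An [resolve_forces()] result (single frame or vectorized).
#' @return A data.frame with per-frame `net_fx`, `net_fy`, `net_moment`.
#' @export
equilibrium_residual <- function(state) {
  stopifnot(inherits(state, "exo_force_state"))
  body <- attr(state, "body")
  # reactions on the device, per side (x anterior, y up, moments about the
  # trochanter): chest reaction +x at (0, d_tt), leg reaction +x at
  # (0, -d_mt), pelvis reaction -x at the origin
  net_fx <- 2 * (state$f_c + state$f_lg - state$f_r)
  m_chest <- -body$d_tt * state$f_c      # r x F = (0, d_tt) x (F, 0)
  m_leg <- body$d_mt * state$f_lg
  net_moment <- 2 * (m_chest + m_leg)
  # vertical: shoulder and pelvis supports against gravity, colinear with the
  # device center of mass in this scalar model
  net_fy <- state$w_e_shoulder + state$w_e_pelvis -
    rep(attr(state, "device_weight_n"), nrow(state))
  data.frame(net_fx = net_fx, net_fy = net_fy, net_moment = net_moment)
}
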