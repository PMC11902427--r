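# Synthetic capture generation: flexion-extension motion envelopes and
# load-cell readings driven by a known ground-truth exoskeleton model. The
# generator reproduces the structure of a characterization session -- slow
# single flexion-extensions for the passive mode, repeated faster cycles for
# the active mode, mixed movements with interrupted ascents for hybrid
# validation -- together with the two instrumentation artifacts that matter
# for validation: taring at peak flexion and descent-phase contamination by
# the user's return effort.

#' Motion profile for the synthetic flexion generator
#'
#' @param n_cycles Number of flexion-extension cycles.
#' @param peak_flexion Peak lumbar flexion, degrees.
#' @param period Duration of one cycle, seconds.
#' @param hold_fraction Fraction of each period spent holding upright between
#'   cycles, in \[0, 1).
#' @param sample_rate Sampling rate, Hz.
#' @param noise_sd_angle Additive white Gaussian angle noise, degrees.
#' @param pause_fraction Fraction of the ascent at which to pause mid-way
#'   (0 disables); emulates interrupted half-ascents.
#' @param pause_duration Pause length, seconds.
#' @return A list of class `motion_profile`.
#' @export
motion_profile <- function(n_cycles = 5, peak_flexion = 70, period = 4,
                           hold_fraction = 0.15, sample_rate = 60,
                           noise_sd_angle = 0, pause_fraction = 0,
                           pause_duration = 0.5) {
  stopifnot(n_cycles >= 1, peak_flexion > 0, period > 0,
            hold_fraction >= 0, hold_fraction < 1, sample_rate > 0,
            noise_sd_angle >= 0, pause_fraction >= 0, pause_fraction < 1)
  structure(as.list(environment()), class = "motion_profile")
}

#' Load-cell simulation configuration
#'
#' @param noise_sd_force White Gaussian force noise, kgf.
#' @param tare_at_peak Tare the cells at the frame of greatest flexion
#'   (offsets the entire reading by the value there).
#' @param descent_contamination_amp Peak amplitude of the spurious force the
#'   user exerts on the cells while lowering the trunk, kgf; applied
#'   proportionally to the descent speed.
#' @param cell_capacity Rated capacity of each of the two cells, kgf.
#' @return A list of class `cell_sim_config`.
#' @export
cell_sim_config <- function(noise_sd_force = 0, tare_at_peak = FALSE,
                            descent_contamination_amp = 0, cell_capacity = 50) {
  stopifnot(noise_sd_force >= 0, descent_contamination_amp >= 0,
            cell_capacity > 0)
  structure(as.list(environment()), class = "cell_sim_config")
}

#' Generate a synthetic flexion-extension capture
#'
#' Raised-cosine flexion cycles separated by upright holds, with an optional
#' mid-ascent pause in every cycle and additive angle noise. Deterministic
#' under a fixed seed.
#'
#' @param profile A [motion_profile()].
#' @param seed Integer seed for the angle noise.
#' @return A [capture_series()] (no measured force).
#' @export
generate_motion <- function(profile, seed = 1L) {
  stopifnot(inherits(profile, "motion_profile"))
  fs <- profile$sample_rate
  dt <- 1 / fs
  move_t <- profile$period * (1 - profile$hold_fraction)
  hold_t <- profile$period * profile$hold_fraction
  one_cycle <- function() {
    n_mv <- max(5L, round(move_t * fs))
    if (n_mv %% 2L == 0L) n_mv <- n_mv + 1L   # sample the peak exactly
    ph <- seq(0, 1, length.out = n_mv)
    th <- profile$peak_flexion * 0.5 * (1 - cos(2 * pi * ph))
    if (profile$pause_fraction > 0) {
      # pause part-way through the ascent (the second half of the cycle)
      asc <- which(ph > 0.5)
      target <- profile$peak_flexion * (1 - profile$pause_fraction)
      at <- asc[which.min(abs(th[asc] - target))]
      th <- append(th, rep(th[at], round(profile$pause_duration * fs)), after = at)
    }
    c(th, rep(0, round(hold_t * fs)))
  }
  theta <- c(rep(0, round(0.5 * fs)),                 # settle upright first
             unlist(replicate(profile$n_cycles, one_cycle(), simplify = FALSE)))
  if (profile$noise_sd_angle > 0) {
    set.seed(seed)
    theta <- theta + stats::rnorm(length(theta), sd = profile$noise_sd_angle)
  }
  capture_series(time = seq_along(theta) * dt - dt, theta_c = theta,
                 sample_rate = fs)
}

#' Simulate the chest force a capture's true model would produce
#'
#' Runs the forward model -- kinematics, activation mask, total torque, force
#' resolution -- on a capture and returns the total chest force in kgf. This
#' is the noise-free "truth" channel that [generate_loadcell()] perturbs.
#'
#' @param capture A [capture_series()].
#' @param spec The [exoskeleton_spec()] acting as ground truth.
#' @return A list with per-frame `force_kgf`, `tau_e_per_side`, the
#'   `annotation` and the activation `mask`.
#' @export
simulate_chest_force <- function(capture, spec) {
  stopifnot(inherits(capture, "capture_series"), inherits(spec, "exoskeleton_spec"))
  ann <- segment_phases(capture)
  mask <- activation_mask(ann, spec$assistance$psi_a)
  tau <- total_torque(capture$theta_c, ann$ascent_speed, mask, spec)
  state <- resolve_forces(tau, spec$body, spec$device_weight, spec$shoulder_fraction)
  list(force_kgf = chest_force_total(state),
       tau_e_per_side = tau,
       annotation = ann,
       mask = mask)
}

#' Generate synthetic load-cell readings for a capture
#'
#' True chest force from the ground-truth model plus Gaussian noise, a
#' descent-phase contamination ramp proportional to descent speed, and an
#' optional taring offset fixed at the frame of greatest flexion. Readings
#' are clipped at twice the summed cell capacity (with a warning).
#'
#' @param capture A [capture_series()].
#' @param truth Ground-truth [exoskeleton_spec()].
#' @param cfg A [cell_sim_config()].
#' @param seed Integer seed for the force noise.
#' @return The capture with a `measured_force` column added (kgf).
#' @export
generate_loadcell <- function(capture, truth, cfg = cell_sim_config(), seed = 1L) {
  stopifnot(inherits(cfg, "cell_sim_config"))
  sim <- simulate_chest_force(capture, truth)
  force <- sim$force_kgf
  if (cfg$descent_contamination_amp > 0) {
    desc_speed <- pmax(0, estimate_velocity(capture))  # flexing = descending
    top <- max(desc_speed)
    if (top > 0)
      force <- force + cfg$descent_contamination_amp * desc_speed / top
  }
  if (cfg$noise_sd_force > 0) {
    set.seed(seed)
    force <- force + stats::rnorm(length(force), sd = cfg$noise_sd_force)
  }
  if (cfg$tare_at_peak) {
    force <- force - force[which.max(capture$theta_c)]
  }
  lim <- 2 * 2 * cfg$cell_capacity
  if (any(abs(force) > lim)) {
    warning("simulated load-cell reading exceeds twice the summed capacity; clipping")
    force <- pmin(pmax(force, -lim), lim)
  }
  capture_series(capture$time, capture$theta_c, measured_force = force,
                 sample_rate = attr(capture, "sample_rate"))
}

#' Generate a full capture set mirroring a characterization session
#'
#' Passive mode: slow single flexion-extensions, several repetitions per
#' percentage. Active mode: at least five faster cycles per capture. Hybrid
#' mode: two captures (full assistance and half assistance) of mixed movement
#' with interrupted ascents. Every capture carries its assistance setting and
#' simulated load-cell channel.
#'
#' @param truth Ground-truth [exoskeleton_spec()] (its tables must cover the
#'   requested percentages).
#' @param percentages Assistance percentages to record, e.g. `c(100, 70, 40)`.
#' @param reps Repetitions per percentage.
#' @param mode One of `"passive"`, `"active"`, `"hybrid"`.
#' @param cfg A [cell_sim_config()].
#' @param seed Integer master seed; each capture derives its own sub-seed.
#' @return A list of captures; each element has `capture` (with measured
#'   force), `eta_p`, `eta_a`, `mode` and `seed`.
#' @export
generate_capture_set <- function(truth, percentages = c(100, 70, 40), reps = 3,
                                 mode = c("passive", "active", "hybrid"),
                                 cfg = cell_sim_config(), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(truth, "exoskeleton_spec"))
  seed <- as.integer(seed)
  out <- list()
  if (mode == "hybrid") {
    settings <- list(c(100L, 100L), c(50L, 50L))
    for (k in seq_along(settings)) {
      s <- settings[[k]]
      sub <- (seed * 1000L + 900L + k) %% .Machine$integer.max
      prof <- motion_profile(n_cycles = 5, peak_flexion = 75, period = 3,
                             hold_fraction = 0.1,
                             pause_fraction = if (k == 1L) 0.5 else 0,
                             pause_duration = 0.8)
      cap <- generate_motion(prof, seed = sub)
      sp <- truth
      sp$assistance <- assistance_config(s[1L], s[2L], truth$assistance$psi_a)
      cap <- generate_loadcell(cap, sp, cfg, seed = sub + 1L)
      out[[length(out) + 1L]] <- list(capture = cap, eta_p = s[1L], eta_a = s[2L],
                                      mode = mode, seed = sub)
    }
    return(out)
  }
  for (i in seq_along(percentages)) {
    pct <- check_percentage(percentages[i], "percentage")
    for (r in seq_len(reps)) {
      sub <- (seed * 1000L + i * 100L + r) %% .Machine$integer.max
      prof <- if (mode == "passive") {
        # one slow, progressive flexion-extension
        motion_profile(n_cycles = 1, peak_flexion = 85, period = 12,
                       hold_fraction = 0)
      } else {
        # repeated cycles fast enough to sweep past the saturation speed
        motion_profile(n_cycles = 5, peak_flexion = 70, period = 2.2,
                       hold_fraction = 0.1)
      }
      cap <- generate_motion(prof, seed = sub)
      sp <- truth
      sp$assistance <- if (mode == "passive")
        assistance_config(pct, 0L, truth$assistance$psi_a)
      else
        assistance_config(0L, pct, truth$assistance$psi_a)
      cap <- generate_loadcell(cap, sp, cfg, seed = sub + 1L)
      out[[length(out) + 1L]] <- list(capture = cap,
                                      eta_p = sp$assistance$eta_p,
                                      eta_a = sp$assistance$eta_a,
                                      mode = mode, seed = sub)
    }
  }
  out
}
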