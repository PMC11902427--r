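# Verification of the model against measured (or synthetically measured)
# load-cell data: per-capture force deviations, the ascending-only filtering
# convention for active captures, and paired simulated-vs-experimental risk.

#' Mean absolute force difference between two series
#'
#' @param simulated Simulated chest force, kgf.
#' @param measured Measured chest force, kgf; same length and sampling.
#' @return Mean per-frame absolute difference, kgf.
#' @export
mean_abs_diff <- function(simulated, measured) {
  if (length(simulated) != length(measured))
    stop("simulated and measured series must have equal length", call. = FALSE)
  mean(abs(simulated - measured))
}

#' Keep measured force only on ascending frames
#'
#' The load cells are tared at peak flexion, so outside the ascents they
#' record the user's own return effort rather than device assistance. This
#' filter zeroes the measured force on every frame not labelled `ascend`,
#' leaving ascending frames untouched -- the convention used when validating
#' active assistance.
#'
#' @param measured Measured force series, kgf.
#' @param annotation A [segment_phases()] result aligned with the series.
#' @return Filtered series, kgf.
#' @export
active_mod_filter <- function(measured, annotation) {
  stopifnot(inherits(annotation, "phase_annotation"))
  if (length(measured) != nrow(annotation))
    stop("measured series and annotation must be aligned", call. = FALSE)
  out <- measured
  out[annotation$phase != "ascend"] <- 0
  out
}

#' Paired simulated-vs-experimental risk for one capture
#'
#' The simulated branch drives the risk pipeline with the model's device
#' torque; the experimental branch converts the measured chest force back to
#' a device torque through the chest lever arm (the measured force being the
#' reaction to the device torque) and feeds the identical pipeline.
#'
#' @param capture A [capture_series()] with a `measured_force` column.
#' @param spec An [exoskeleton_spec()].
#' @param config A [risk_config()].
#' @param use_active_mod Apply the ascending-only filter to the measured
#'   force before the experimental branch.
#' @return A list with `risk_simulated`, `risk_experimental` (both
#'   percentages), their `difference` (experimental - simulated), and the
#'   unassisted `risk_unassisted` for reference.
#' @export
compare_risk <- function(capture, spec, config = risk_config(),
                         use_active_mod = FALSE) {
  stopifnot(inherits(capture, "capture_series"), inherits(spec, "exoskeleton_spec"))
  if (!"measured_force" %in% names(capture))
    stop("capture has no measured force channel", call. = FALSE)
  sim <- simulate_chest_force(capture, spec)
  measured <- capture$measured_force
  if (use_active_mod) measured <- active_mod_filter(measured, sim$annotation)
  # measured total chest force (kgf) -> total device torque (N*m, both sides)
  tau_exp_total <- kgf_to_n(pmax(measured, 0)) * spec$body$d_tt
  tau_sim_total <- 2 * sim$tau_e_per_side
  r_sim <- lumbar_risk(capture, tau_sim_total, config)
  r_exp <- lumbar_risk(capture, tau_exp_total, config)
  r_un <- lumbar_risk(capture, NULL, config)
  list(risk_simulated = r_sim$risk_per_minute,
       risk_experimental = r_exp$risk_per_minute,
       difference = r_exp$risk_per_minute - r_sim$risk_per_minute,
       risk_unassisted = r_un$risk_per_minute,
       band_simulated = r_sim$color_band,
       band_experimental = r_exp$color_band)
}

#' Validate a capture set against a specification
#'
#' Runs the forward model on every capture of a set (as produced by
#' [generate_capture_set()] or loaded from disk), computes per-capture mean
#' absolute force deviations and paired risks, and aggregates them. Active
#' captures are reported both raw and with the ascending-only filter
#' (`active_mod`).
#'
#' @param capture_set A list of elements with `capture`, `eta_p`, `eta_a`,
#'   `mode`.
#' @param spec The [exoskeleton_spec()] to validate.
#' @param config A [risk_config()].
#' @return An object of class `validation_report`: a data.frame with one row
#'   per capture (and per filtering variant for active captures) and columns
#'   `mode`, `eta_p`, `eta_a`, `mean_abs_force_diff`, `risk_simulated`,
#'   `risk_experimental`, `risk_difference`; aggregate mean and sd in
#'   attributes `aggregate_mean` and `aggregate_sd`.
#' @export
validate_capture_set <- function(capture_set, spec, config = risk_config()) {
  stopifnot(is.list(capture_set), inherits(spec, "exoskeleton_spec"))
  rows <- list()
  for (item in capture_set) {
    cap <- item$capture
    sp <- spec
    sp$assistance <- assistance_config(item$eta_p, item$eta_a,
                                       spec$assistance$psi_a)
    sim <- simulate_chest_force(cap, sp)
    variants <- if (identical(item$mode, "active"))
      c(item$mode, "active_mod") else item$mode
    for (variant in variants) {
      measured <- cap$measured_force
      sim_force <- sim$force_kgf
      use_mod <- identical(variant, "active_mod")
      if (use_mod) {
        measured <- active_mod_filter(measured, sim$annotation)
        sim_force <- active_mod_filter(sim_force, sim$annotation)
      }
      rk <- compare_risk(cap, sp, config, use_active_mod = use_mod)
      rows[[length(rows) + 1L]] <- data.frame(
        mode = variant, eta_p = item$eta_p, eta_a = item$eta_a,
        mean_abs_force_diff = mean_abs_diff(sim_force, measured),
        risk_simulated = rk$risk_simulated,
        risk_experimental = rk$risk_experimental,
        risk_difference = rk$difference)
    }
  }
  report <- do.call(rbind, rows)
  structure(report,
            aggregate_mean = mean(report$mean_abs_force_diff),
            aggregate_sd = stats::sd(report$mean_abs_force_diff),
            class = c("validation_report", "data.frame"))
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation report: %d rows; force deviation %.4f +/- %.4f kgf\n",
              nrow(x), attr(x, "aggregate_mean"), attr(x, "aggregate_sd")))
  print.data.frame(x, digits = 4)
  invisible(x)
}
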