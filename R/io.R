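# File formats: capture CSV (time + flexion angle + optional load-cell
# channels) and the versioned YAML exoskeleton parameter file.

#' Read a capture CSV
#'
#' Expected columns: `time_s`, `theta_c_deg`, and either `force_chest_kgf` or
#' the pair `cell_left_kgf` + `cell_right_kgf` (summed on load, as the two
#' chest cells are in the rig). Header required, comma-separated, decimal
#' point.
#'
#' @param path Path to the CSV file.
#' @return A [capture_series()].
#' @export
read_capture_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "theta_c_deg") %in% names(df)))
    stop("capture CSV must have columns time_s and theta_c_deg", call. = FALSE)
  force <- NULL
  if ("force_chest_kgf" %in% names(df)) {
    force <- df$force_chest_kgf
  } else if (all(c("cell_left_kgf", "cell_right_kgf") %in% names(df))) {
    force <- df$cell_left_kgf + df$cell_right_kgf
  }
  capture_series(df$time_s, df$theta_c_deg, measured_force = force)
}

#' Write a capture CSV
#'
#' @param capture A [capture_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_capture_csv <- function(capture, path) {
  stopifnot(inherits(capture, "capture_series"))
  df <- data.frame(time_s = capture$time, theta_c_deg = capture$theta_c)
  if ("measured_force" %in% names(capture))
    df$force_chest_kgf <- capture$measured_force
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

PARAMETER_SCHEMA_VERSION <- 1L

#' Read an exoskeleton parameter file
#'
#' Loads and validates a versioned YAML parameter file with blocks `passive`
#' (characteristic angles, torque ratios, per-percentage max torques),
#' `active` (per-percentage rows and the activation angle), `body` (lever
#' arms) and `device` (weight, shoulder fraction). Every keypoint-table
#' invariant is enforced on load.
#'
#' @param path Path to the YAML file.
#' @param eta_p,eta_a Assistance percentages to select (default 100/100).
#' @return An [exoskeleton_spec()].
#' @export
read_exo_parameters <- function(path, eta_p = 100, eta_a = 100) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schema_version) || cfg$schema_version != PARAMETER_SCHEMA_VERSION)
    stop(sprintf("unsupported parameter schema version (expected %d)",
                 PARAMETER_SCHEMA_VERSION), call. = FALSE)
  for (block in c("passive", "active", "body", "device"))
    if (is.null(cfg[[block]]))
      stop(sprintf("parameter file is missing the '%s' block", block), call. = FALSE)
  tau_max <- unlist(cfg$passive$tau_max)
  passive <- passive_keypoint_table(cfg$passive$characteristic_angles,
                                    cfg$passive$torque_ratios,
                                    tau_max)
  rows <- do.call(rbind, lapply(names(cfg$active$rows), function(p) {
    r <- cfg$active$rows[[p]]
    data.frame(eta = as.integer(p), tau_a_max = r$tau_a_max,
               vel_lim = r$vel_lim, slope = r$slope, intercept = r$intercept)
  }))
  active <- active_keypoint_table(rows)
  body <- body_dimensions(cfg$body$d_tt, cfg$body$d_mt)
  assistance <- assistance_config(eta_p, eta_a, cfg$active$psi_a)
  exoskeleton_spec(passive, active, assistance, body,
                   device_weight = cfg$device$weight_kgf,
                   shoulder_fraction = cfg$device$shoulder_fraction)
}

#' Write an exoskeleton parameter file
#'
#' @param spec An [exoskeleton_spec()].
#' @param path Output path (YAML).
#' @return `path`, invisibly.
#' @export
write_exo_parameters <- function(spec, path) {
  stopifnot(inherits(spec, "exoskeleton_spec"))
  at <- spec$active_table
  rows <- stats::setNames(lapply(seq_len(nrow(at)), function(i) {
    list(tau_a_max = at$tau_a_max[i], vel_lim = at$vel_lim[i],
         slope = at$slope[i], intercept = at$intercept[i])
  }), as.character(at$eta))
  cfg <- list(
    schema_version = PARAMETER_SCHEMA_VERSION,
    passive = list(
      characteristic_angles = spec$passive_table$characteristic_angles,
      torque_ratios = spec$passive_table$torque_ratios,
      tau_max = as.list(spec$passive_table$tau_max)),
    active = list(rows = rows, psi_a = spec$assistance$psi_a),
    body = list(d_tt = spec$body$d_tt, d_mt = spec$body$d_mt),
    device = list(weight_kgf = spec$device_weight,
                  shoulder_fraction = spec$shoulder_fraction))
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

#' The bundled synthetic example device
#'
#' Loads the parameter file shipped with the package
#' (`extdata/synthetic_device.yaml`). The values are a plausible synthetic
#' stand-in for a commercial lumbar exoskeleton -- useful as ground truth for
#' simulation studies -- not measurements of any physical device.
#'
#' @param eta_p,eta_a Assistance percentages to select.
#' @return An [exoskeleton_spec()].
#' @export
synthetic_device_spec <- function(eta_p = 100, eta_a = 100) {
  path <- system.file("extdata", "synthetic_device.yaml", package = "lgabs",
                      mustWork = TRUE)
  read_exo_parameters(path, eta_p = eta_p, eta_a = eta_a)
}
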