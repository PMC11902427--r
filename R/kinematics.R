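# Kinematic preprocessing of lumbar flexion captures: velocity estimation,
# ascend/descend/hold phase labelling, cycle segmentation and the active
# assistance activation mask.
#
# Sign convention: theta_c = 0 upright, increasing with forward flexion.
# "Ascending" (trunk extension, rising back up) therefore means
# d(theta_c)/dt < 0, and the ascent speed fed to the active law is the
# magnitude max(0, -d(theta_c)/dt).

#' Motion-capture series of lumbar flexion
#'
#' A uniformly sampled time series of the lumbar flexion angle relative to the
#' global vertical, optionally with the synchronized chest force measured by
#' the load cells (sum of the two cells, kgf).
#'
#' @param time Time stamps in seconds, strictly increasing and uniform.
#' @param theta_c Lumbar flexion angle in degrees (0 = upright).
#' @param measured_force Optional chest force in kgf, same length.
#' @param sample_rate Sampling rate in Hz; inferred from `time` when missing.
#' @return An object of class `capture_series` (a data.frame with columns
#'   `time`, `theta_c` and optionally `measured_force`, plus a `sample_rate`
#'   attribute).
#' @export
capture_series <- function(time, theta_c, measured_force = NULL, sample_rate = NULL) {
  time <- as.numeric(time)
  theta_c <- as.numeric(theta_c)
  if (length(time) < 2L) stop("a capture needs at least two samples", call. = FALSE)
  if (length(theta_c) != length(time))
    stop("time and theta_c must have equal length", call. = FALSE)
  dt <- diff(time)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6)
    stop("time must be strictly increasing and uniform to within 1e-6 s", call. = FALSE)
  if (is.null(sample_rate)) sample_rate <- 1 / stats::median(dt)
  stopifnot(is.numeric(sample_rate), sample_rate > 0)
  df <- data.frame(time = time, theta_c = theta_c)
  if (!is.null(measured_force)) {
    if (length(measured_force) != length(time))
      stop("measured_force must match the capture length", call. = FALSE)
    df$measured_force <- as.numeric(measured_force)
  }
  structure(df, sample_rate = as.numeric(sample_rate),
            class = c("capture_series", "data.frame"))
}

#' @export
print.capture_series <- function(x, ...) {
  cat(sprintf("Lumbar flexion capture: %d frames at %.1f Hz (%.1f s), flexion %.1f-%.1f deg%s\n",
              nrow(x), attr(x, "sample_rate"),
              x$time[nrow(x)] - x$time[1L],
              min(x$theta_c), max(x$theta_c),
              if ("measured_force" %in% names(x)) ", with load-cell force" else ""))
  invisible(x)
}

#' Estimate angular velocity from a flexion capture
#'
#' Central finite differences of the flexion angle (one-sided at the
#' endpoints) followed by a centered moving-average smoother. Linear signals
#' pass through unchanged, so constant velocities are recovered exactly.
#'
#' @param capture A [capture_series()].
#' @param smoothing_window Smoother width in seconds (default 0.25 s);
#'   rounded to an odd number of samples, minimum covering 2 samples.
#' @return Angular velocity in deg/s (positive = flexing), one value per frame.
#' @export
estimate_velocity <- function(capture, smoothing_window = 0.25) {
  stopifnot(inherits(capture, "capture_series"))
  fs <- attr(capture, "sample_rate")
  k <- max(1L, round(smoothing_window * fs))
  if (k %% 2L == 0L) k <- k + 1L
  n <- nrow(capture)
  if (n < max(2L, k)) stop("capture shorter than the smoothing window", call. = FALSE)
  th <- capture$theta_c
  dt <- 1 / fs
  v <- numeric(n)
  v[1L] <- (th[2L] - th[1L]) / dt
  v[n] <- (th[n] - th[n - 1L]) / dt
  if (n > 2L) v[2:(n - 1L)] <- (th[3:n] - th[1:(n - 2L)]) / (2 * dt)
  if (k > 1L) {
    # moving mean with edge frames padded by replication (keeps ramps exact
    # in the interior and endpoints biased by at most half a window)
    half <- (k - 1L) %/% 2L
    padded <- c(rep(v[1L], half), v, rep(v[n], half))
    v <- stats::filter(padded, rep(1 / k, k), sides = 2)[(half + 1L):(half + n)]
    v <- as.numeric(v)
  }
  v
}

#' Label movement phases and segment flexion cycles
#'
#' Frames are labelled `descend` (flexing, velocity above +threshold),
#' `ascend` (extending, velocity below -threshold) or `hold`. Cycles are
#' delimited at upright turning points (the flexion minimum inside each
#' ascend-to-descend transition), so each cycle contains one descent into
#' flexion, its flexion peak and the ascent back up -- including interrupted
#' ascents, which stay inside their cycle. Leading and trailing partial
#' cycles are kept and flagged.
#'
#' @param capture A [capture_series()].
#' @param velocity Angular velocity in deg/s (from [estimate_velocity()]);
#'   computed with defaults when missing.
#' @param hold_threshold Velocity magnitude under which a frame counts as a
#'   hold, deg/s.
#' @return An object of class `phase_annotation`: a data.frame with per-frame
#'   `phase` (factor), `ascent_speed` (deg/s), `cycle_id` and
#'   `cycle_peak_flexion`, plus a `cycles` attribute (per-cycle summary with a
#'   `partial` flag).
#' @export
segment_phases <- function(capture, velocity = NULL, hold_threshold = 2) {
  stopifnot(inherits(capture, "capture_series"))
  if (is.null(velocity)) velocity <- estimate_velocity(capture)
  n <- nrow(capture)
  stopifnot(length(velocity) == n, hold_threshold >= 0)
  phase <- rep("hold", n)
  phase[velocity > hold_threshold] <- "descend"
  phase[velocity < -hold_threshold] <- "ascend"
  phase <- factor(phase, levels = c("descend", "ascend", "hold"))

  # cycle boundaries: the most upright frame within every ascend -> descend
  # hand-over (holds in between are absorbed into the boundary search)
  boundaries <- integer(0)
  last_moving <- NULL   # index of last non-hold frame seen
  for (i in seq_len(n)) {
    if (phase[i] == "hold") next
    if (!is.null(last_moving) &&
        phase[last_moving] == "ascend" && phase[i] == "descend") {
      span <- last_moving:i
      boundaries <- c(boundaries, span[which.min(capture$theta_c[span])])
    }
    last_moving <- i
  }
  starts <- c(1L, boundaries)
  ends <- c(boundaries - 1L, n)
  keep <- starts <= ends
  starts <- starts[keep]; ends <- ends[keep]
  cycle_id <- integer(n)
  peak <- numeric(length(starts))
  for (j in seq_along(starts)) {
    cycle_id[starts[j]:ends[j]] <- j
    peak[j] <- max(capture$theta_c[starts[j]:ends[j]])
  }
  partial <- logical(length(starts))
  if (length(starts) > 0L) {
    partial[1L] <- TRUE                      # no upright boundary on the left
    partial[length(starts)] <- TRUE          # capture may stop mid-cycle
  }
  ann <- data.frame(phase = phase,
                    ascent_speed = pmax(0, -velocity),
                    cycle_id = cycle_id,
                    cycle_peak_flexion = peak[cycle_id])
  structure(ann,
            cycles = data.frame(cycle_id = seq_along(starts),
                                start = starts, end = ends,
                                peak_flexion = peak, partial = partial),
            class = c("phase_annotation", "data.frame"))
}

#' Active-assistance activation mask
#'
#' The device's activation rule: active assistance engages exactly on
#' ascending frames whose enclosing flexion cycle peaked beyond the
#' activation angle. An interrupted ascent that resumes within the same cycle
#' re-activates, because the rule is re-evaluated every frame.
#'
#' @param annotation A [segment_phases()] result.
#' @param psi_a Activation angle, degrees of lumbar flexion.
#' @return Logical vector, one value per frame.
#' @export
activation_mask <- function(annotation, psi_a) {
  stopifnot(inherits(annotation, "phase_annotation"),
            is.numeric(psi_a), length(psi_a) == 1L, psi_a >= 0)
  annotation$phase == "ascend" & annotation$cycle_peak_flexion > psi_a
}
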