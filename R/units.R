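# Unit conventions: torques are carried internally in N*m and forces in N;
# chest loads are reported in kgf because load cells and force tables use kg.

#' Standard gravity used for kgf conversions
#'
#' Conversion constant between kilogram-force and newton
#' (1 kgf = 9.80665 N exactly).
#'
#' @format A length-one numeric.
#' @export
G_STANDARD <- 9.80665

#' Convert newtons to kilogram-force
#'
#' @param x Force in N.
#' @return Force in kgf.
#' @export
n_to_kgf <- function(x) x / G_STANDARD

#' Convert kilogram-force to newtons
#'
#' @param x Force in kgf.
#' @return Force in N.
#' @export
kgf_to_n <- function(x) x * G_STANDARD

# Internal: the assistance levels the device UI offers.
valid_percentages <- function() seq(0L, 100L, by = 10L)

check_percentage <- function(eta, what = "percentage") {
  if (length(eta) != 1L || !is.finite(eta) || !(eta %in% valid_percentages())) {
    stop(sprintf("%s must be a single value in 0, 10, ..., 100 (got %s)",
                 what, paste(format(eta), collapse = ", ")), call. = FALSE)
  }
  as.integer(eta)
}
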