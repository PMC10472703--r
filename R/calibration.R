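#' Convert log flash intensity to photoisomerizations per rod
#'
#' Scotopic flash energies in log cd.s/m2 are converted to the number of
#' photoisomerizations each rod undergoes per flash (R*/rod), using the
#' calibration 1 scot cd/m2 = 516 R*/rod/s. Intensities are treated as flash
#' energies (cd.s/m2), so the rate constant applies directly per flash.
#'
#' @param intensity_log Numeric vector of flash intensities in log cd.s/m2.
#' @param r_star_per_cd Rate constant in R*/rod per scot cd.s/m2 (default 516).
#' @return Numeric vector of photoisomerizations per rod per flash.
#' @examples
#' log_intensity_to_isomerizations(0)    # 516
#' log_intensity_to_isomerizations(1)    # 5160
#' @export
log_intensity_to_isomerizations <- function(intensity_log, r_star_per_cd = 516) {
  if (!is.numeric(intensity_log) || length(intensity_log) == 0 ||
      any(!is.finite(intensity_log))) {
    stop("`intensity_log` must be finite numeric", call. = FALSE)
  }
  10^intensity_log * r_star_per_cd
}

#' Classify a stimulus into one of the four scotopic light zones
#'
#' Murine scotopic ERG stimuli are conventionally divided into four intensity
#' zones: (1) rod threshold (scotopic threshold response), (2) rod to
#' rod-bipolar transmission, (3) mixed rod pathways, (4) cone-involved
#' responses. Only the rod-range upper edge (-0.3 log cd.s/m2) is fixed by the
#' rod operating range; the two internal boundaries are configurable.
#'
#' @param intensity_log Numeric vector, log cd.s/m2.
#' @param boundaries Increasing numeric vector of the three upper zone
#'   boundaries `c(z1, z2, z3)`; intensity `<= z1` is zone 1, `<= z2` zone 2,
#'   `<= z3` zone 3, above zone 4. Default `c(-3.8, -2.0, -0.3)`.
#' @return Integer vector of zones in 1:4.
#' @export
classify_light_zone <- function(intensity_log, boundaries = c(-3.8, -2.0, -0.3)) {
  if (any(!is.finite(intensity_log))) stop("non-finite intensity", call. = FALSE)
  if (length(boundaries) != 3 || is.unsorted(boundaries, strictly = TRUE)) {
    stop("`boundaries` must be 3 strictly increasing values", call. = FALSE)
  }
  zone <- findInterval(intensity_log, boundaries, left.open = TRUE) + 1L
  as.integer(zone)
}

#' Mask intensities falling within the rod operating range
#'
#' Returns `TRUE` for stimuli strictly below -0.3 log cd.s/m2, the upper edge
#' of the rod cells' operating range. Responses inside this range are the ones
#' fitted by the Naka-Rushton function (see [fit_naka_rushton()]).
#'
#' @param intensities Non-empty numeric vector, log cd.s/m2.
#' @param upper Exclusive upper bound in log cd.s/m2 (default -0.3).
#' @return Logical vector, same length as `intensities`.
#' @export
rod_range_mask <- function(intensities, upper = -0.3) {
  if (length(intensities) == 0) stop("empty intensity vector", call. = FALSE)
  if (any(!is.finite(intensities))) stop("non-finite intensity", call. = FALSE)
  intensities < upper
}

#' Describe a stimulus: intensity, photoisomerizations, light zone
#'
#' @param intensity_log Numeric vector, log cd.s/m2.
#' @inheritParams classify_light_zone
#' @return Data frame with columns `intensity_log`, `r_star`, `zone`.
#' @export
stimulus_spec <- function(intensity_log, boundaries = c(-3.8, -2.0, -0.3)) {
  data.frame(
    intensity_log = intensity_log,
    r_star = log_intensity_to_isomerizations(intensity_log),
    zone = classify_light_zone(intensity_log, boundaries)
  )
}
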