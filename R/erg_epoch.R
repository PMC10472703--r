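#' Construct an ERG epoch
#'
#' An `erg_epoch` is one averaged scotopic ERG sweep: a uniformly sampled
#' voltage series (microvolts) on a millisecond time grid where 0 marks
#' stimulus onset and negative times are pre-stimulus baseline.
#'
#' @param time_ms Strictly increasing, uniformly spaced time vector (ms).
#' @param voltage_uv Voltage vector (uV), same length as `time_ms`.
#' @param intensity_log Stimulus intensity, log cd.s/m2.
#' @param fs_hz Sampling rate in Hz; must agree with the grid step.
#' @param meta Named list of free-form labels (animal id, group, ...).
#' @return Object of class `erg_epoch`.
#' @export
erg_epoch <- function(time_ms, voltage_uv, intensity_log, fs_hz, meta = list()) {
  if (length(time_ms) != length(voltage_uv) || length(time_ms) < 2) {
    stop("time and voltage must have equal length >= 2", call. = FALSE)
  }
  if (any(!is.finite(voltage_uv))) stop("voltage must be finite", call. = FALSE)
  step <- diff(time_ms)
  if (any(step <= 0)) stop("time must be strictly increasing", call. = FALSE)
  expected <- 1000 / fs_hz
  if (any(abs(step - expected) > 1e-9 * expected)) {
    stop("time grid not uniform at 1000/fs_hz ms", call. = FALSE)
  }
  structure(
    list(time_ms = as.numeric(time_ms), voltage_uv = as.numeric(voltage_uv),
         intensity_log = intensity_log, fs_hz = fs_hz, meta = meta),
    class = "erg_epoch"
  )
}

#' @export
print.erg_epoch <- function(x, ...) {
  cat(sprintf(
    "<erg_epoch> %d samples @ %g Hz, %.1f..%.1f ms, intensity %g log cd.s/m2\n",
    length(x$time_ms), x$fs_hz, min(x$time_ms), max(x$time_ms), x$intensity_log))
  invisible(x)
}

#' @export
length.erg_epoch <- function(x) length(x$time_ms)

# indices of pre-stimulus samples (t < 0)
prestim_idx <- function(epoch) which(epoch$time_ms < 0)

# replace the voltage, keeping grid and metadata
with_voltage <- function(epoch, v) {
  epoch$voltage_uv <- as.numeric(v)
  epoch
}
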