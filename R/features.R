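#' Baseline-correct an ERG epoch
#'
#' Subtracts the mean of the pre-stimulus window from the whole trace, so the
#' pre-stimulus mean of the output is zero. All downstream measurements are
#' shift-invariant after this step.
#'
#' @param epoch An [erg_epoch()] with at least 10 ms of pre-stimulus samples.
#' @return Baseline-corrected [erg_epoch()].
#' @export
baseline_correct <- function(epoch) {
  pre <- prestim_idx(epoch)
  if (length(pre) == 0) stop("epoch has no pre-stimulus samples", call. = FALSE)
  if (-min(epoch$time_ms) < 10) {
    stop("need >= 10 ms of pre-stimulus baseline", call. = FALSE)
  }
  with_voltage(epoch, epoch$voltage_uv - mean(epoch$voltage_uv[pre]))
}

# Low-pass an epoch's voltage with an FFT mask whose edge is cosine-tapered
# between `cutoff` and 1.5 * cutoff; the taper suppresses the Gibbs ringing a
# hard mask would leave around the stimulus-onset discontinuity.
lowpass_voltage <- function(v, fs_hz, cutoff) {
  n <- length(v)
  f <- abs(seq(0, n - 1) * fs_hz / n)
  f <- pmin(f, fs_hz - f) # fold to physical frequency
  hi <- 1.5 * cutoff
  gain <- ifelse(f <= cutoff, 1,
                 ifelse(f >= hi, 0, 0.5 * (1 + cos(pi * (f - cutoff) / (hi - cutoff)))))
  Re(fft(fft(v) * gain, inverse = TRUE)) / n
}

window_idx <- function(epoch, win) {
  idx <- which(epoch$time_ms >= win[1] & epoch$time_ms <= win[2])
  if (length(idx) == 0) stop("measurement window outside epoch", call. = FALSE)
  idx
}

#' Measure a-wave and b-wave amplitude and implicit time
#'
#' Conventions follow standard clinical full-field ERG practice: the a-wave
#' amplitude is the depth of the trace minimum in the a-window below
#' baseline; its implicit time is the latency of that minimum from stimulus
#' onset. The b-wave amplitude is measured trough-to-peak (b-peak minus
#' a-trough) when a credible a-wave is present, and from baseline otherwise
#' (dim flashes have no measurable a-wave); its implicit time is the latency
#' of the b-peak. By default the trace is low-passed at 60 Hz before
#' measurement so oscillatory-potential wavelets neither capture the b-peak
#' nor bias the a-trough.
#'
#' @param epoch Baseline-corrected [erg_epoch()].
#' @param a_window,b_window Numeric `c(lo, hi)` search windows in ms.
#' @param smooth Logical; low-pass before measurement (default TRUE).
#' @param smooth_cutoff_hz Low-pass cutoff, Hz.
#' @param b_reference `"auto"` (trough-to-peak when the a-wave exceeds 3x the
#'   pre-stimulus noise sd, else baseline), `"trough"`, or `"baseline"`.
#' @return List of class `waveform_features` with fields `a_amp`,
#'   `a_implicit_ms`, `b_amp`, `b_implicit_ms`, `baseline_uv`, `flags`.
#' @export
measure_ab_waves <- function(epoch, a_window = c(3, 50), b_window = c(20, 150),
                             smooth = TRUE, smooth_cutoff_hz = 60,
                             b_reference = c("auto", "trough", "baseline")) {
  b_reference <- match.arg(b_reference)
  v <- if (smooth) lowpass_voltage(epoch$voltage_uv, epoch$fs_hz, smooth_cutoff_hz)
       else epoch$voltage_uv
  flags <- character()
  pre <- prestim_idx(epoch)
  baseline <- mean(v[pre])
  noise_sd <- sd(v[pre])

  ai <- window_idx(epoch, a_window)
  bi <- window_idx(epoch, b_window)
  if (diff(range(epoch$voltage_uv)) == 0) flags <- c(flags, "flat")

  ia <- ai[which.min(v[ai])]
  a_trough <- v[ia]
  a_amp <- max(0, baseline - a_trough)
  ib <- bi[which.max(v[bi])]
  b_peak <- v[ib]

  # credible a-wave: above noise and above an absolute 1 uV floor (dim
  # flashes leave sub-microvolt numerical dips that are not a-waves)
  a_present <- a_amp > max(3 * noise_sd, 1)
  use_trough <- switch(b_reference,
                       auto = a_present, trough = TRUE, baseline = FALSE)
  b_amp <- if (use_trough) b_peak - a_trough else b_peak - baseline
  if (b_amp < 0) { b_amp <- 0; flags <- c(flags, "no-b-wave") }
  if (!a_present) flags <- c(flags, "no-a-wave")

  structure(list(
    a_amp = a_amp, a_implicit_ms = epoch$time_ms[ia],
    b_amp = b_amp, b_implicit_ms = epoch$time_ms[ib],
    b_from_trough = use_trough,
    baseline_uv = baseline, noise_sd_uv = noise_sd, flags = flags
  ), class = "waveform_features")
}

#' Measure the positive scotopic threshold response
#'
#' The pSTR is read as the maximum of the (baseline-corrected) trace above
#' baseline in a late window, default 80-200 ms. Negative-only deflections
#' yield zero amplitude with a flag.
#'
#' @param epoch Baseline-corrected [erg_epoch()] at a zone-1 intensity.
#' @param window Numeric `c(lo, hi)` search window, ms.
#' @param smooth,smooth_cutoff_hz As in [measure_ab_waves()].
#' @return List with `pstr_amp`, `pstr_implicit_ms`, `flags`.
#' @export
measure_pstr <- function(epoch, window = c(80, 200),
                         smooth = TRUE, smooth_cutoff_hz = 60) {
  v <- if (smooth) lowpass_voltage(epoch$voltage_uv, epoch$fs_hz, smooth_cutoff_hz)
       else epoch$voltage_uv
  idx <- window_idx(epoch, window)
  baseline <- mean(v[prestim_idx(epoch)])
  ip <- idx[which.max(v[idx])]
  amp <- v[ip] - baseline
  flags <- character()
  if (amp <= 0) { amp <- 0; flags <- "no-positive-deflection" }
  list(pstr_amp = amp, pstr_implicit_ms = epoch$time_ms[ip], flags = flags)
}

#' Average repeated sweeps recorded at one intensity
#'
#' Pointwise arithmetic mean of the voltage traces; residual noise sd falls
#' as 1/sqrt(number of sweeps).
#'
#' @param epochs Non-empty list of [erg_epoch()] objects on identical time
#'   grids at the same intensity.
#' @return An [erg_epoch()]; `meta$n_sweeps_averaged` records the count.
#' @export
average_sweeps <- function(epochs) {
  if (length(epochs) == 0) stop("no epochs", call. = FALSE)
  ref <- epochs[[1]]
  for (e in epochs[-1]) {
    if (length(e$time_ms) != length(ref$time_ms) ||
        any(abs(e$time_ms - ref$time_ms) > 1e-9) ||
        !isTRUE(all.equal(e$intensity_log, ref$intensity_log))) {
      stop("epochs differ in time grid or intensity", call. = FALSE)
    }
  }
  v <- rowMeans(vapply(epochs, function(e) e$voltage_uv,
                       numeric(length(ref$voltage_uv))))
  out <- with_voltage(ref, v)
  out$meta$n_sweeps_averaged <- length(epochs)
  out
}

#' Extract the full feature set from a list of epochs
#'
#' Convenience wrapper: baseline-corrects each epoch, measures a/b waves at
#' every intensity and the pSTR at zone-1 intensities, and returns one tidy
#' row per epoch.
#'
#' @param epochs List of [erg_epoch()] objects.
#' @param ... Passed to [measure_ab_waves()].
#' @return Data frame, one row per epoch.
#' @export
extract_features <- function(epochs, ...) {
  rows <- lapply(seq_along(epochs), function(i) {
    ep <- baseline_correct(epochs[[i]])
    ab <- measure_ab_waves(ep, ...)
    zone <- classify_light_zone(ep$intensity_log)
    ps <- if (zone == 1L) measure_pstr(ep) else
      list(pstr_amp = NA_real_, pstr_implicit_ms = NA_real_)
    data.frame(
      epoch = i, intensity_log = ep$intensity_log, zone = zone,
      a_amp = ab$a_amp, a_implicit_ms = ab$a_implicit_ms,
      b_amp = ab$b_amp, b_implicit_ms = ab$b_implicit_ms,
      pstr_amp = ps$pstr_amp, pstr_implicit_ms = ps$pstr_implicit_ms,
      animal = if (!is.null(ep$meta$animal)) ep$meta$animal else NA_character_,
      group = if (!is.null(ep$meta$group)) ep$meta$group else NA_character_
    )
  })
  do.call(rbind, rows)
}
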