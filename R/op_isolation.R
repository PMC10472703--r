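#' Isolate oscillatory potentials by hard spectral band-pass filtering
#'
#' Implements the FFT / inverse-FFT isolation of oscillatory potentials: the
#' voltage series is discrete-Fourier transformed, every frequency bin whose
#' physical frequency lies outside `[lo_hz, hi_hz]` is zeroed (hard
#' rectangular mask, band edges inclusive -- components beyond the cut-offs
#' are eliminated, the cut-offs themselves survive), and the series is
#' inverse transformed. No zero-padding is applied: the mask acts on the
#' epoch's native frequency grid. An optional raised-cosine taper of the
#' mask edges is available for users who prefer reduced ringing over the
#' literal hard mask.
#'
#' @param epoch An [erg_epoch()] with at least 8 samples.
#' @param lo_hz,hi_hz Pass-band edges in Hz, `0 < lo < hi <= fs/2`.
#'   Defaults 65 and 300 Hz, the conventional murine OP band.
#' @param taper_hz Optional one-sided raised-cosine transition width in Hz
#'   (default 0 = hard mask).
#' @return The filtered [erg_epoch()] on the same time grid.
#' @export
spectral_bandpass <- function(epoch, lo_hz = 65, hi_hz = 300, taper_hz = 0) {
  n <- length(epoch$voltage_uv)
  if (n < 8) stop("epoch too short to filter (need >= 8 samples)", call. = FALSE)
  if (lo_hz <= 0 || lo_hz >= hi_hz) stop("need 0 < lo_hz < hi_hz", call. = FALSE)
  if (hi_hz > epoch$fs_hz / 2) stop("hi_hz exceeds Nyquist", call. = FALSE)
  f <- seq(0, n - 1) * epoch$fs_hz / n
  f <- pmin(f, epoch$fs_hz - f)
  if (taper_hz > 0) {
    ramp <- function(x) ifelse(x <= 0, 0, ifelse(x >= 1, 1, 0.5 * (1 - cos(pi * x))))
    gain <- ramp((f - (lo_hz - taper_hz)) / taper_hz) *
      (1 - ramp((f - hi_hz) / taper_hz))
  } else {
    gain <- as.numeric(f >= lo_hz & f <= hi_hz)
  }
  spec <- fft(epoch$voltage_uv) * gain
  out <- fft(spec, inverse = TRUE) / n
  # real input, symmetric mask => imaginary residue is numerical only
  with_voltage(epoch, Re(out))
}

#' Detect and quantify oscillatory-potential wavelets
#'
#' Scans the band-passed trace for local maxima inside the search window
#' whose height exceeds a threshold (default 3x the filtered pre-stimulus
#' sd), orders them by time, and keeps the first `k`. For each wavelet the
#' implicit time is the latency of the peak from stimulus onset and the
#' amplitude is the peak value minus the value at the adjacent trough --
#' resolved as the next local minimum after the peak; when the peak is the
#' last extremum, the preceding minimum is used and the result flagged.
#'
#' @param filtered Band-passed [erg_epoch()] from [spectral_bandpass()].
#' @param search_window_ms Numeric `c(lo, hi)` window, ms (default 10-100).
#' @param k Number of wavelets to keep (default 4).
#' @param threshold Peak-height threshold in uV, or `NULL` for the default
#'   `max(3 * prestim_sd, 1e-3 * max(trace))`.
#' @param trough `"following"` (default) or `"preceding"` convention for the
#'   adjacent trough.
#' @return List of class `op_result`: `peak_times_ms`, `implicit_ms`,
#'   `amplitudes_uv`, `sum_amp_uv` (sum over the retained wavelets),
#'   `band_hz`, `flags`.
#' @export
detect_op_wavelets <- function(filtered, search_window_ms = c(10, 100), k = 4,
                               threshold = NULL,
                               trough = c("following", "preceding")) {
  trough <- match.arg(trough)
  v <- filtered$voltage_uv
  t <- filtered$time_ms
  idx <- window_idx(filtered, search_window_ms)
  pre <- prestim_idx(filtered)
  if (is.null(threshold)) {
    threshold <- max(3 * sd(v[pre]), 1e-3 * max(abs(v[idx]), 0))
  }
  flags <- character()

  inner <- idx[idx > 1 & idx < length(v)]
  is_max <- v[inner] > v[inner - 1] & v[inner] >= v[inner + 1]
  peaks <- inner[is_max & v[inner] >= threshold]
  if (length(peaks) == 0) stop("no qualifying OP peaks found", call. = FALSE)
  if (length(peaks) < k) flags <- c(flags, "fewer-peaks-than-requested")
  peaks <- peaks[seq_len(min(k, length(peaks)))]

  amp <- numeric(length(peaks))
  for (j in seq_along(peaks)) {
    p <- peaks[j]
    nxt <- next_local_min(v, p)
    prv <- prev_local_min(v, p)
    use <- if (trough == "following") nxt else prv
    if (is.na(use)) {
      use <- if (trough == "following") prv else nxt
      flags <- c(flags, sprintf("wavelet-%d-fallback-trough", j))
    }
    if (is.na(use)) stop("no adjacent trough for OP wavelet", call. = FALSE)
    amp[j] <- v[p] - v[use]
  }
  structure(list(
    peak_times_ms = t[peaks], implicit_ms = t[peaks],
    amplitudes_uv = amp, sum_amp_uv = sum(amp),
    band_hz = c(lo = NA_real_, hi = NA_real_), flags = unique(flags)
  ), class = "op_result")
}

next_local_min <- function(v, p) {
  i <- p
  n <- length(v)
  while (i < n && v[i + 1] <= v[i]) i <- i + 1
  if (i == p || i == n && v[n] > v[n - 1]) NA_integer_ else i
}

prev_local_min <- function(v, p) {
  i <- p
  while (i > 1 && v[i - 1] <= v[i]) i <- i - 1
  if (i == p) NA_integer_ else i
}

#' Sum of oscillatory-potential amplitudes
#'
#' The summed-OP statistic: arithmetic sum of the amplitudes of the first
#' (up to) four wavelets.
#'
#' @param result An `op_result` from [detect_op_wavelets()], or a bare
#'   numeric vector of amplitudes.
#' @param k Number of leading wavelets to include (default 4).
#' @return Sum of amplitudes, uV.
#' @export
sum_op_amplitudes <- function(result, k = 4) {
  amps <- if (is.numeric(result)) result else result$amplitudes_uv
  if (length(amps) == 0) stop("no OP amplitudes to sum", call. = FALSE)
  sum(amps[seq_len(min(k, length(amps)))])
}

#' Full OP analysis of a raw epoch
#'
#' Baseline-corrects, band-passes (65-300 Hz by default), and quantifies the
#' first `k` OP wavelets.
#'
#' @inheritParams spectral_bandpass
#' @inheritParams detect_op_wavelets
#' @return `op_result` with `band_hz` filled in.
#' @export
analyze_ops <- function(epoch, lo_hz = 65, hi_hz = 300,
                        search_window_ms = c(10, 100), k = 4) {
  filt <- spectral_bandpass(baseline_correct(epoch), lo_hz, hi_hz)
  res <- detect_op_wavelets(filt, search_window_ms, k)
  res$band_hz <- c(lo = lo_hz, hi = hi_hz)
  res
}
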