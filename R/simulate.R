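#' Parameters for the synthetic scotopic ERG generator
#'
#' Defaults describe a typical murine scotopic recording: 2 kHz sampling,
#' 350 ms epoch with 50 ms pre-stimulus baseline, a-wave trough at 15 ms,
#' b-wave peak at 70 ms with a saturating (Naka-Rushton) intensity-response,
#' four oscillatory-potential wavelets at 110 Hz riding the b-wave rising
#' limb, a small positive scotopic threshold response near 130 ms, and
#' Gaussian noise reduced by sweep averaging (40 sweeps).
#'
#' @param a_amp a-wave trough depth, uV (present in zones 3-4).
#' @param a_peak_ms a-wave trough time, ms.
#' @param a_shape Gamma-lobe sharpness of the a-wave (dimensionless).
#' @param b_amp_max True maximum b-wave amplitude (Bmax), uV.
#' @param b_peak_ms b-wave peak time, ms.
#' @param b_shape Gamma-lobe sharpness of the b-wave (dimensionless).
#' @param nr_semisat Naka-Rushton semisaturation intensity, linear cd.s/m2.
#' @param nr_slope Naka-Rushton exponent, dimensionless.
#' @param op_gain Oscillatory-potential amplitude as a fraction of the
#'   epoch's b-wave amplitude.
#' @param op_freq_hz OP carrier frequency, Hz (must lie in (65, 300)).
#' @param op_onset_ms Center of the first OP wavelet, ms.
#' @param op_decay Per-wavelet geometric amplitude decay.
#' @param n_wavelets Number of OP wavelets.
#' @param pstr_amp Positive scotopic threshold response amplitude, uV.
#' @param pstr_peak_ms pSTR peak time, ms.
#' @param pstr_sigma_ms pSTR Gaussian half-width, ms.
#' @param noise_sd Per-sweep noise standard deviation, uV.
#' @param n_sweeps Number of averaged sweeps (noise sd scales as 1/sqrt).
#' @param fs_hz Sampling rate, Hz (>= 600 so the OP band is below Nyquist).
#' @param epoch_ms Total epoch duration, ms.
#' @param pre_stim_ms Pre-stimulus baseline duration, ms.
#' @param response_floor_log Absolute scotopic floor: stimuli below this
#'   intensity (log cd.s/m2) elicit no response at all.
#' @return List of class `erg_sim_params`.
#' @export
erg_sim_params <- function(a_amp = 150, a_peak_ms = 15, a_shape = 3,
                           b_amp_max = 600, b_peak_ms = 70, b_shape = 10,
                           nr_semisat = 1e-2, nr_slope = 1,
                           op_gain = 0.12, op_freq_hz = 110, op_onset_ms = 15,
                           op_decay = 0.85, n_wavelets = 4L,
                           pstr_amp = 20, pstr_peak_ms = 130, pstr_sigma_ms = 20,
                           noise_sd = 10, n_sweeps = 40L,
                           fs_hz = 2000, epoch_ms = 350, pre_stim_ms = 50,
                           response_floor_log = -5) {
  p <- as.list(environment())
  validate_erg_sim_params(p)
  structure(p, class = "erg_sim_params")
}

validate_erg_sim_params <- function(p) {
  num <- unlist(p[vapply(p, is.numeric, TRUE)])
  if (any(!is.finite(num))) stop("non-finite simulation parameter", call. = FALSE)
  stopifnot(
    p$a_amp >= 0, p$b_amp_max >= 0, p$pstr_amp >= 0, p$noise_sd >= 0,
    p$nr_semisat > 0, p$nr_slope > 0, p$op_gain >= 0,
    p$n_wavelets >= 1, p$n_sweeps >= 1,
    p$epoch_ms > p$pre_stim_ms, p$pre_stim_ms >= 0
  )
  if (p$op_freq_hz <= 65 || p$op_freq_hz >= 300) {
    stop("op_freq_hz must lie inside (65, 300)", call. = FALSE)
  }
  if (p$fs_hz < 2 * 300) stop("fs_hz must be >= 600 (Nyquist over OP band)", call. = FALSE)
  invisible(p)
}

# time grid for an epoch: first sample at -pre_stim_ms, step 1000/fs
sim_time_grid <- function(p) {
  n <- round(p$epoch_ms * p$fs_hz / 1000)
  (seq_len(n) - 1) * 1000 / p$fs_hz - p$pre_stim_ms
}

#' Noise-free stimulus-driven ERG components
#'
#' Returns the individual waveform components (a-wave, b-wave, oscillatory
#' potentials, pSTR) evaluated on the epoch grid, so feature extractors can
#' be tested against exact ground truth. All components are identically zero
#' before stimulus onset and below the scotopic floor.
#'
#' @param params An [erg_sim_params()] object.
#' @param intensity_log Stimulus intensity, log cd.s/m2.
#' @return List with `time_ms` and numeric vectors `a`, `b`, `op`, `pstr`,
#'   plus the epoch's true b-wave amplitude `b_amp`.
#' @export
erg_components <- function(params, intensity_log) {
  validate_erg_sim_params(params)
  t <- sim_time_grid(params)
  zero <- numeric(length(t))
  out <- list(time_ms = t, a = zero, b = zero, op = zero, pstr = zero, b_amp = 0)
  if (intensity_log < params$response_floor_log) return(out)

  on <- t > 0
  tp <- t[on]
  zone <- classify_light_zone(intensity_log)
  b_amp <- naka_rushton(10^intensity_log, params$b_amp_max,
                        params$nr_semisat, params$nr_slope)
  out$b_amp <- b_amp

  # b-wave: gamma-shaped lobe, unit peak at b_peak_ms
  k <- params$b_shape
  tb <- params$b_peak_ms
  out$b[on] <- b_amp * (tp / tb)^k * exp(k * (1 - tp / tb))

  # a-wave: negative gamma-shaped lobe (smooth from onset, trough exactly at
  # a_peak_ms), only at mixed/cone intensities
  if (zone >= 3 && params$a_amp > 0) {
    ka <- params$a_shape
    ta <- params$a_peak_ms
    out$a[on] <- -params$a_amp * (tp / ta)^ka * exp(ka * (1 - tp / ta))
  }

  # oscillatory potentials: decaying Gabor wavelets on the rising limb
  if (params$op_gain > 0 && b_amp > 0) {
    period_ms <- 1000 / params$op_freq_hz
    # envelope width balances separable wavelet peaks against spectral
    # compactness (narrow envelopes leak below the 65 Hz band edge)
    sg <- 0.75 * period_ms
    op <- numeric(length(tp))
    for (j in seq_len(params$n_wavelets)) {
      cj <- params$op_onset_ms + (j - 1) * period_ms
      aj <- params$op_gain * b_amp * params$op_decay^(j - 1)
      op <- op + aj * cos(2 * pi * params$op_freq_hz * (tp - cj) / 1000) *
        exp(-(tp - cj)^2 / (2 * sg^2))
    }
    out$op[on] <- op
  }

  # pSTR: small late positive lobe; dominates near threshold where the
  # b-wave has collapsed
  if (params$pstr_amp > 0) {
    out$pstr[on] <- params$pstr_amp *
      exp(-(tp - params$pstr_peak_ms)^2 / (2 * params$pstr_sigma_ms^2))
  }
  out
}

#' Simulate one averaged scotopic ERG epoch
#'
#' Sums the noise-free components from [erg_components()] and adds i.i.d.
#' Gaussian noise with standard deviation `noise_sd / sqrt(n_sweeps)`,
#' emulating sweep averaging. Deterministic for a fixed seed.
#'
#' @inheritParams erg_components
#' @param seed Integer seed.
#' @param meta Optional metadata list attached to the epoch.
#' @return An [erg_epoch()].
#' @export
simulate_erg_epoch <- function(params, intensity_log, seed, meta = list()) {
  if (!is.finite(intensity_log)) stop("non-finite intensity", call. = FALSE)
  comp <- erg_components(params, intensity_log)
  v <- comp$a + comp$b + comp$op + comp$pstr
  if (params$noise_sd > 0) {
    v <- v + withr::with_seed(as.integer(seed),
      rnorm(length(v), 0, params$noise_sd / sqrt(params$n_sweeps)))
  }
  erg_epoch(comp$time_ms, v, intensity_log, params$fs_hz,
            meta = c(meta, list(n_sweeps = params$n_sweeps, seed = seed)))
}

#' Derive a child seed from a master seed
#'
#' Deterministic scheme used by all list-generating simulators: element `i`
#' of a series uses `split_seed(seed, i)`, a multiplicative-congruential mix
#' that stays inside the 32-bit integer range.
#'
#' @param seed Master integer seed.
#' @param index 1-based element index.
#' @return Integer child seed in \[1, 2^31 - 2\].
#' @export
split_seed <- function(seed, index) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + index) %% 2147483646 + 1)
}

#' Simulate an intensity ladder of ERG epochs
#'
#' One epoch per intensity, child seeds split deterministically from the
#' master seed ([split_seed()]), input order preserved.
#'
#' @inheritParams simulate_erg_epoch
#' @param intensities Non-empty numeric vector, log cd.s/m2.
#' @return List of [erg_epoch()] objects.
#' @export
simulate_intensity_series <- function(params, intensities, seed, meta = list()) {
  if (length(intensities) == 0) stop("empty intensity list", call. = FALSE)
  lapply(seq_along(intensities), function(i) {
    simulate_erg_epoch(params, intensities[i], split_seed(seed, i), meta = meta)
  })
}

#' Generate a raw sample matching a published mean and SEM exactly
#'
#' Inverts the "mean +/- SEM, n" reporting convention: a seeded normal draw
#' is affinely rescaled so the returned sample has arithmetic mean exactly
#' `mean` and sample SEM (sd with n-1 denominator, divided by sqrt(n))
#' exactly `sem`. Any two-sample statistic computed from such samples equals
#' the corresponding summary-statistic formula exactly.
#'
#' @param mean Target sample mean.
#' @param sem Target standard error of the mean (>= 0).
#' @param n Sample size (>= 2 when `sem > 0`).
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
make_group_samples <- function(mean, sem, n, seed) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (sem < 0) stop("sem must be >= 0", call. = FALSE)
  if (sem == 0) return(rep(mean, n))
  if (n < 2) stop("sem > 0 requires n >= 2 (SEM undefined for n = 1)", call. = FALSE)
  z <- withr::with_seed(as.integer(seed), rnorm(n))
  while (sd(z) == 0) z <- z + seq_len(n) # unreachable for continuous draws
  target_sd <- sem * sqrt(n)
  mean + (z - base::mean(z)) / sd(z) * target_sd
}

#' Parameters for the synthetic oxygen-consumption-rate generator
#'
#' Levels describe the three phases of a mitochondrial stress assay on
#' retinal punches: basal respiration, the FCCP-uncoupled maximum, and the
#' rotenone/antimycin-A floor (non-mitochondrial consumption).
#'
#' @param basal_level,fccp_plateau,nonmito_level Phase OCR levels, pmol/min.
#' @param n_basal,n_fccp,n_rotaa Measurements per phase.
#' @param interval_min Minutes between successive measurements.
#' @param noise_sd Measurement noise sd, pmol/min.
#' @param protein_mg Punch protein content, mg (> 0), for normalization.
#' @return List of class `ocr_sim_params`.
#' @export
ocr_sim_params <- function(basal_level = 120, fccp_plateau = 150,
                           nonmito_level = 25,
                           n_basal = 3L, n_fccp = 3L, n_rotaa = 3L,
                           interval_min = 6.5, noise_sd = 0,
                           protein_mg = 0.05) {
  p <- as.list(environment())
  stopifnot(p$basal_level >= 0, p$fccp_plateau >= 0, p$nonmito_level >= 0,
            p$n_basal >= 1, p$n_fccp >= 1, p$n_rotaa >= 1,
            p$interval_min > 0, p$noise_sd >= 0, p$protein_mg > 0)
  if (any(!is.finite(unlist(p)))) stop("non-finite OCR parameter", call. = FALSE)
  structure(p, class = "ocr_sim_params")
}

#' Simulate a three-phase OCR trace
#'
#' @param params An [ocr_sim_params()] object.
#' @param seed Integer seed.
#' @param well_id Well label.
#' @return Data frame with columns `well_id`, `time_min`, `ocr_pmol_min`,
#'   `phase` (factor basal/fccp/rotaa).
#' @export
simulate_ocr_trace <- function(params, seed, well_id = "A1") {
  n <- c(params$n_basal, params$n_fccp, params$n_rotaa)
  level <- rep(c(params$basal_level, params$fccp_plateau, params$nonmito_level), n)
  phase <- rep(c("basal", "fccp", "rotaa"), n)
  ocr <- level
  if (params$noise_sd > 0) {
    ocr <- ocr + withr::with_seed(as.integer(seed),
                                  rnorm(sum(n), 0, params$noise_sd))
  }
  data.frame(
    well_id = well_id,
    time_min = seq_len(sum(n)) * params$interval_min,
    ocr_pmol_min = ocr,
    phase = factor(phase, levels = c("basal", "fccp", "rotaa"))
  )
}

#' Simulate a longitudinal cohort table from per-cell summary targets
#'
#' Builds a long-format table (animal, group, week, variable, value) whose
#' per-group, per-week, per-variable mean and SEM match the supplied targets
#' exactly (via [make_group_samples()]). Emulates the glucose / body-weight /
#' HbA1c longitudinal tables of a diabetic-mouse study design.
#'
#' @param design List with elements `groups` (named integer vector of group
#'   sizes) and `targets` (data frame with columns `group`, `week`,
#'   `variable`, `mean`, `sem`); every group must appear in `targets` with a
#'   complete set of (week, variable) cells.
#' @param seed Integer seed.
#' @return Long data frame (animal, group, week, variable, value).
#' @export
simulate_cohort <- function(design, seed) {
  if (is.null(design$groups) || is.null(design$targets)) {
    stop("design needs `groups` and `targets`", call. = FALSE)
  }
  tg <- design$targets
  need <- c("group", "week", "variable", "mean", "sem")
  if (!all(need %in% names(tg))) stop("targets missing columns", call. = FALSE)
  cells <- unique(tg[c("week", "variable")])
  out <- list(); idx <- 0L
  for (g in names(design$groups)) {
    n <- design$groups[[g]]
    sub <- tg[tg$group == g, ]
    if (nrow(merge(cells, sub[c("week", "variable")])) != nrow(cells)) {
      stop(sprintf("design has missing cells for group '%s'", g), call. = FALSE)
    }
    animals <- sprintf("%s_%02d", g, seq_len(n))
    for (r in seq_len(nrow(sub))) {
      idx <- idx + 1L
      vals <- make_group_samples(sub$mean[r], sub$sem[r], n, split_seed(seed, idx))
      out[[idx]] <- data.frame(
        animal = animals, group = g,
        week = sub$week[r], variable = sub$variable[r], value = vals
      )
    }
  }
  do.call(rbind, out)
}

#' Flag animals meeting the diabetic-inclusion criterion
#'
#' An animal is included when its week-9 fasting blood glucose is at least
#' the threshold (inclusive boundary): >= 13.9 mmol/L.
#'
#' @param cohort Long table from [simulate_cohort()].
#' @param threshold Inclusion threshold, mmol/L (default 13.9).
#' @param week Week of the qualifying measurement (default 9).
#' @param variable Variable name holding glucose (default "glucose").
#' @return Data frame (animal, group, glucose, included).
#' @export
apply_inclusion_filter <- function(cohort, threshold = 13.9, week = 9,
                                   variable = "glucose") {
  g9 <- cohort[cohort$week == week & cohort$variable == variable, ]
  if (nrow(g9) == 0) stop("no qualifying measurements found", call. = FALSE)
  data.frame(
    animal = g9$animal, group = g9$group, glucose = g9$value,
    included = g9$value >= threshold
  )
}
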