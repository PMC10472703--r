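test_that("epochs are deterministic in (params, seed) and zero pre-stimulus", {
  p <- erg_sim_params()
  e1 <- simulate_erg_epoch(p, 0.3, seed = 11)
  e2 <- simulate_erg_epoch(p, 0.3, seed = 11)
  expect_identical(e1$voltage_uv, e2$voltage_uv)
  e3 <- simulate_erg_epoch(p, 0.3, seed = 12)
  expect_false(identical(e1$voltage_uv, e3$voltage_uv))
  # noise-free: all stimulus-driven energy after t = 0
  q <- noise_free_params()
  ep <- simulate_erg_epoch(q, 0.3, 1)
  expect_identical(ep$voltage_uv[ep$time_ms < 0], rep(0, sum(ep$time_ms < 0)))
})

test_that("far-below-threshold stimulus yields an identically zero trace", {
  p <- noise_free_params(op_gain = 0)
  ep <- simulate_erg_epoch(p, -6, seed = 1)
  expect_identical(ep$voltage_uv, rep(0, length(ep)))
})

test_that("invalid simulator parameters are rejected", {
  expect_error(erg_sim_params(nr_semisat = -1))
  expect_error(erg_sim_params(op_freq_hz = 400), "65, 300")
  expect_error(erg_sim_params(fs_hz = 500), "Nyquist")
  expect_error(erg_sim_params(noise_sd = NaN), "finite")
  expect_error(erg_sim_params(epoch_ms = 40, pre_stim_ms = 50))
})

test_that("intensity series preserves order and splits seeds deterministically", {
  p <- erg_sim_params()
  ints <- c(-4.32, -3.3, -1.3, 0.3, 1.3)
  s1 <- simulate_intensity_series(p, ints, seed = 5)
  expect_length(s1, 5)
  expect_equal(vapply(s1, function(e) e$intensity_log, 1), ints)
  s2 <- simulate_intensity_series(p, ints, seed = 5)
  for (i in seq_along(s1)) expect_identical(s1[[i]]$voltage_uv, s2[[i]]$voltage_uv)
  expect_length(simulate_intensity_series(p, -1.3, seed = 1), 1)
  expect_error(simulate_intensity_series(p, numeric(0), seed = 1), "empty")
})

test_that("noise-free b-wave amplitudes are non-decreasing along the ladder", {
  p <- noise_free_params()
  ints <- c(-3.3, -2.8, -2.3, -1.8, -1.3, -0.8, -0.3, 0.3, 1.3)
  eps <- simulate_intensity_series(p, ints, seed = 1)
  b <- extract_features(eps)$b_amp
  expect_true(all(diff(b) >= -1e-9))
})

test_that("make_group_samples matches the target mean and SEM exactly", {
  cases <- list(c(10, 2, 5), c(65.78, 2.72, 7), c(-3.4, 0.01, 12), c(0, 5, 30))
  for (cs in cases) {
    x <- make_group_samples(cs[1], cs[2], cs[3], seed = 99)
    expect_equal(mean(x), cs[1], tolerance = 1e-12)
    expect_equal(sd(x) / sqrt(length(x)), cs[2], tolerance = 1e-10)
  }
  # n = 2 is forced: the two points are mean +/- sem
  expect_equal(sort(make_group_samples(10, 2, 2, seed = 1)), c(8, 12))
  expect_identical(make_group_samples(7, 0, 4, seed = 1), rep(7, 4))
  expect_error(make_group_samples(1, 1, 1, seed = 1), "n >= 2")
})

test_that("sweep averaging reduces noise sd by sqrt(n_sweeps)", {
  p <- erg_sim_params(noise_sd = 20, n_sweeps = 40)
  sds <- vapply(1:200, function(s) sd(simulate_erg_epoch(p, -6, s)$voltage_uv), 1)
  expect_equal(mean(sds), 20 / sqrt(40), tolerance = 0.1)
})

test_that("OCR trace simulation hits configured phase levels", {
  prm <- ocr_sim_params(basal_level = 120, fccp_plateau = 150, nonmito_level = 25)
  tr <- simulate_ocr_trace(prm, seed = 1)
  expect_equal(nrow(tr), 9)
  expect_identical(as.character(tr$phase), rep(c("basal", "fccp", "rotaa"), each = 3))
  expect_true(all(tr$ocr_pmol_min[tr$phase == "basal"] == 120))
  expect_identical(tr, simulate_ocr_trace(prm, seed = 1))
  noisy <- simulate_ocr_trace(ocr_sim_params(noise_sd = 5), seed = 2)
  expect_false(all(noisy$ocr_pmol_min[noisy$phase == "basal"] == 120))
})

test_that("cohort simulation honours targets and the inclusion rule", {
  design <- list(
    groups = c(ctrl = 6L, db = 5L),
    targets = data.frame(
      group = c("ctrl", "db"), week = 9, variable = "glucose",
      mean = c(7, 20), sem = c(0.3, 1.2))
  )
  coh <- simulate_cohort(design, seed = 3)
  expect_setequal(names(coh), c("animal", "group", "week", "variable", "value"))
  db <- coh$value[coh$group == "db"]
  expect_equal(mean(db), 20, tolerance = 1e-10)
  flags <- apply_inclusion_filter(coh)
  expect_identical(flags$included, flags$glucose >= 13.9)
  # boundary is inclusive as printed; just below is excluded
  coh2 <- coh
  coh2$value[1] <- 13.9
  coh2$value[2] <- 13.89
  f2 <- apply_inclusion_filter(coh2)
  expect_true(f2$included[f2$animal == coh2$animal[1]])
  expect_false(f2$included[f2$animal == coh2$animal[2]])
  # missing cells are an error
  bad <- design
  bad$targets <- bad$targets[bad$targets$group == "ctrl", ]
  expect_error(simulate_cohort(bad, seed = 1), "missing cells")
})

test_that("cohort summaries round-trip into matching summary t-tests", {
  x <- make_group_samples(65.78, 2.72, 7, seed = 21)
  y <- make_group_samples(53.60, 2.02, 6, seed = 22)
  raw <- t_test_raw(x, y)
  summ <- pooled_t_from_summary(c(65.78, 2.72, 7), c(53.60, 2.02, 6))
  expect_equal(raw$t, summ$t, tolerance = 1e-9)
  expect_identical(raw$df, summ$df)
})
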