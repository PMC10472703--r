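test_that("pooled t from summaries reproduces hand-checked published pairs", {
  r1 <- pooled_t_from_summary(group_summary(65.78, 2.72, 7),
                              group_summary(53.60, 2.02, 6))
  expect_equal(r1$t, -3.488, tolerance = 0.002)
  expect_identical(r1$df, 11L)
  r2 <- pooled_t_from_summary(c(126.31, 4.42, 14), c(83.89, 7.92, 11))
  expect_equal(r2$t, -4.939, tolerance = 0.002)
  expect_identical(r2$df, 23L)
  # equal groups: t is exactly zero
  expect_equal(pooled_t_from_summary(c(5, 1, 8), c(5, 1, 8))$t, 0)
  # zero variance, unequal means: infinite-t flag
  expect_identical(pooled_t_from_summary(c(1, 0, 5), c(2, 0, 5))$t, Inf)
})

test_that("raw-sample t delegates exactly to the summary formulas", {
  x <- make_group_samples(122.76, 7.93, 5, seed = 31)
  y <- make_group_samples(75.29, 6.75, 7, seed = 32)
  raw <- t_test_raw(x, y)
  summ <- pooled_t_from_summary(c(122.76, 7.93, 5), c(75.29, 6.75, 7))
  expect_equal(raw$t, summ$t, tolerance = 1e-9)
  expect_identical(raw$df, summ$df)
  # independent oracle: base R t.test on the same samples
  tt <- t.test(y, x, var.equal = TRUE)
  expect_equal(raw$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(raw$p, tt$p.value, tolerance = 1e-12)
  tw <- t.test(y, x)
  ww <- t_test_raw(x, y, welch = TRUE)
  expect_equal(ww$t, unname(tw$statistic), tolerance = 1e-12)
  expect_equal(ww$df, unname(tw$parameter), tolerance = 1e-9)
  expect_equal(t_test_raw(x, x)$t, 0)
  expect_error(t_test_raw(x, 1), "n >= 2")
})

test_that("group swap negates t and keeps df", {
  g1 <- c(126.31, 4.42, 14); g2 <- c(83.89, 7.92, 11)
  a <- pooled_t_from_summary(g1, g2); b <- pooled_t_from_summary(g2, g1)
  expect_equal(a$t, -b$t, tolerance = 1e-12)
  expect_identical(a$df, b$df)
  aw <- welch_t_from_summary(g1, g2); bw <- welch_t_from_summary(g2, g1)
  expect_equal(aw$t, -bw$t, tolerance = 1e-12)
  expect_equal(aw$df, bw$df, tolerance = 1e-12)
})

test_that("Welch reduces to pooled for equal n and sem, never exceeds its df", {
  w <- welch_t_from_summary(c(10, 2, 8), c(13, 2, 8))
  p <- pooled_t_from_summary(c(10, 2, 8), c(13, 2, 8))
  expect_equal(w$t, p$t, tolerance = 1e-12)
  expect_lte(w$df, p$df)
  # one group with sem 0: limit equals a one-sample comparison against mean1
  w0 <- welch_t_from_summary(c(10, 0, 6), c(14, 1.5, 9))
  expect_equal(w0$t, (14 - 10) / 1.5, tolerance = 1e-12)
  expect_equal(w0$df, 8, tolerance = 1e-9)
})

test_that("Shapiro-Wilk gates normality as expected", {
  lin <- qnorm(((1:100) - 3/8) / (100 + 1/4)) # perfectly normal quantiles
  sw <- shapiro_wilk(lin)
  expect_gt(sw$W, 0.999)
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  heavy <- rep(c(-5, 5), 25) + withr::with_seed(4, rnorm(50, 0, 0.1))
  expect_lt(shapiro_wilk(heavy)$p, 0.01)
  # agrees with the reference implementation
  x <- withr::with_seed(8, rexp(40))
  expect_equal(shapiro_wilk(x)$W, unname(shapiro.test(x)$statistic))
})

test_that("mixed ANOVA matches the definitional sums-of-squares oracle", {
  d <- make_long_table(n_per_group = 4, times = c(1, 2, 3))
  got <- mixed_anova(d)
  want <- splitplot_oracle(d)
  expect_equal(got$f_group, want$f_group, tolerance = 1e-9)
  expect_equal(got$f_time, want$f_time, tolerance = 1e-9)
  expect_equal(got$f_interaction, want$f_int, tolerance = 1e-9)
  expect_identical(got$df$group, c(1, 6))
  expect_identical(got$df$time, c(2, 12))
  # cross-check against base R's split-plot aov
  fit <- summary(aov(value ~ group * factor(time) + Error(factor(subject)),
                     data = d))
  btab <- fit[["Error: factor(subject)"]][[1]]
  wtab <- fit[["Error: Within"]][[1]]
  expect_equal(got$f_group, btab["group", "F value"], tolerance = 1e-9)
  expect_equal(got$f_time, wtab["factor(time)", "F value"], tolerance = 1e-9)
  expect_equal(got$f_interaction, wtab["group:factor(time)", "F value"],
               tolerance = 1e-9)
})

test_that("ANOVA handles unequal group sizes and degenerate inputs", {
  d <- make_long_table(n_per_group = 5, times = c(9, 13, 17, 25))
  d <- d[d$subject != "s01", ] # 4 vs 5 subjects
  got <- mixed_anova(d)
  want <- splitplot_oracle(d)
  expect_equal(got$f_group, want$f_group, tolerance = 1e-9)
  expect_equal(got$f_time, want$f_time, tolerance = 1e-9)
  expect_equal(got$f_interaction, want$f_int, tolerance = 1e-9)
  # all values equal: every F is zero
  flat <- make_long_table()
  flat$value <- 3
  ff <- mixed_anova(flat)
  expect_equal(ff$f_group, 0)
  expect_equal(ff$f_time, 0)
  expect_equal(ff$f_interaction, 0)
  # missing cell is refused, single timepoint is refused
  broken <- make_long_table()[-1, ]
  expect_error(mixed_anova(broken), "incomplete")
  one_t <- make_long_table(times = 1)
  expect_error(mixed_anova(one_t), "single timepoint")
})

test_that("total SS decomposes orthogonally on random inputs", {
  for (s in 1:20) {
    d <- make_long_table(n_per_group = 2 + s %% 4, times = seq_len(2 + s %% 3),
                         seed = 100 + s)
    m <- mixed_anova(d)
    parts <- m$ss["group"] + m$ss["subj_error"] + m$ss["time"] +
      m$ss["interaction"] + m$ss["within_error"]
    expect_equal(unname(parts), unname(m$ss["total"]), tolerance = 1e-9)
    expect_gte(m$epsilon_gg, 1 / (m$n_times - 1))
    expect_lte(m$epsilon_gg, 1)
  }
})

test_that("GG epsilon approaches 1 for exchangeable (compound symmetric) data", {
  ns <- 200; k <- 4
  Y <- withr::with_seed(9, outer(rnorm(ns), rep(1, k)) + matrix(rnorm(ns * k), ns, k))
  d <- data.frame(subject = rep(sprintf("s%03d", 1:ns), k),
                  group = rep(rep(c("A", "B"), each = ns / 2), k),
                  time = rep(1:k, each = ns), value = as.vector(Y))
  expect_equal(mixed_anova(d)$epsilon_gg, 1, tolerance = 0.05)
})

test_that("simple main effects equal squared pooled t for two groups", {
  d <- make_long_table(n_per_group = 5, times = c(9, 13, 17, 25))
  sme <- simple_main_effects(d, at = 13)
  x <- d$value[d$time == 13 & d$group == "A"]
  y <- d$value[d$time == 13 & d$group == "B"]
  expect_equal(sme$f, t_test_raw(x, y)$t^2, tolerance = 1e-9)
  # brute-force one-way ANOVA oracle at that timepoint
  vals <- c(x, y); grp <- rep(c("A", "B"), c(length(x), length(y)))
  gm <- tapply(vals, grp, mean)
  ssb <- sum(table(grp) * (gm - mean(vals))^2)
  ssw <- sum((vals - gm[grp])^2)
  f_oracle <- (ssb / 1) / (ssw / (length(vals) - 2))
  expect_equal(sme$f, f_oracle, tolerance = 1e-9)
  # equal group means: F = 0
  d0 <- d
  d0$value[d0$time == 9] <- rep(c(1, 2, 3, 4, 5), 2)
  expect_equal(simple_main_effects(d0, at = 9)$f, 0, tolerance = 1e-12)
  expect_error(simple_main_effects(d, at = 99), "unknown timepoint")
  # omnibus error term uses the between-subjects df
  so <- simple_main_effects(d, at = 13, error = "omnibus")
  expect_identical(so$df2, mixed_anova(d)$df$group[2])
})

test_that("pooled t keeps its nominal type-I error under the null", {
  nrep <- 1e4; n <- 10
  X <- withr::with_seed(1, matrix(rnorm(nrep * n), n))
  Y <- withr::with_seed(2, matrix(rnorm(nrep * n), n))
  mx <- colMeans(X); my <- colMeans(Y)
  vx <- colSums((X - rep(mx, each = n))^2)
  vy <- colSums((Y - rep(my, each = n))^2)
  tv <- (my - mx) / sqrt((vx + vy) / (2 * n - 2) * 2 / n)
  pv <- 2 * pt(-abs(tv), 2 * n - 2)
  expect_gte(mean(pv < 0.05), 0.04)
  expect_lte(mean(pv < 0.05), 0.06)
  # the vectorized null machinery agrees with t_test_raw on spot checks
  for (i in c(1, 500, 9999)) {
    expect_equal(t_test_raw(X[, i], Y[, i])$t, tv[i], tolerance = 1e-12)
  }
})

test_that("every bundled published comparison is reproduced", {
  rep_tab <- reproduce_reported_t()
  expect_identical(nrow(rep_tab), 12L)
  expect_true(all(rep_tab$df_match))
  expect_true(all(abs(rep_tab$delta_t) <= 0.05))
  expect_true(attr(rep_tab, "all_pass"))
})
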