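#' Group summary (mean, SEM, n)
#'
#' Container for a published group-level summary. The sample sd is
#' recoverable as `sem * sqrt(n)`.
#'
#' @param mean Group mean.
#' @param sem Standard error of the mean (>= 0).
#' @param n Sample size (>= 2).
#' @param label Optional group label.
#' @return List of class `group_summary`.
#' @export
group_summary <- function(mean, sem, n, label = "") {
  if (!is.finite(mean) || !is.finite(sem) || sem < 0) {
    stop("mean must be finite and sem >= 0", call. = FALSE)
  }
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  structure(list(label = label, mean = mean, sem = sem, n = as.integer(n)),
            class = "group_summary")
}

as_group_summary <- function(x) {
  if (inherits(x, "group_summary")) return(x)
  if (is.numeric(x) && length(x) >= 3) return(group_summary(x[1], x[2], x[3]))
  stop("cannot interpret as group summary", call. = FALSE)
}

summarize_sample <- function(x, label = "") {
  group_summary(mean(x), sd(x) / sqrt(length(x)), length(x), label)
}

t_result <- function(t, df, mean_diff, pooled) {
  p <- if (is.finite(t)) 2 * pt(-abs(t), df) else 0
  structure(list(t = t, df = df, p = p, pooled = pooled, mean_diff = mean_diff),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("%s two-sample t: t = %.3f, df = %s, p = %.4g (diff %.3f)\n",
              if (x$pooled) "Pooled" else "Welch", x$t,
              format(x$df, digits = 4), x$p, x$mean_diff))
  invisible(x)
}

#' Pooled two-sample t-test from published summaries
#'
#' Student's t with pooled variance computed directly from (mean, SEM, n)
#' pairs. Orientation is fixed as second group minus first, so with the
#' control group first a deficit in the second group yields a negative t --
#' matching the sign convention of printed comparisons in the diabetic-mouse
#' literature this package accompanies. df = n1 + n2 - 2.
#'
#' @param g1,g2 [group_summary()] objects (or numeric `c(mean, sem, n)`).
#' @return `t_test_result` with `t`, `df`, `p` (two-sided), `mean_diff`.
#' @export
pooled_t_from_summary <- function(g1, g2) {
  g1 <- as_group_summary(g1); g2 <- as_group_summary(g2)
  sd1 <- g1$sem * sqrt(g1$n); sd2 <- g2$sem * sqrt(g2$n)
  df <- g1$n + g2$n - 2L
  sp2 <- ((g1$n - 1) * sd1^2 + (g2$n - 1) * sd2^2) / df
  diff <- g2$mean - g1$mean
  se <- sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  t <- if (se > 0) diff / se else if (diff == 0) 0 else sign(diff) * Inf
  t_result(t, df, diff, pooled = TRUE)
}

#' Welch two-sample t-test from published summaries
#'
#' Unequal-variance t with Welch-Satterthwaite degrees of freedom, computed
#' from (mean, SEM, n) pairs: t = (m2 - m1) / sqrt(sem1^2 + sem2^2).
#'
#' @inheritParams pooled_t_from_summary
#' @return `t_test_result`.
#' @export
welch_t_from_summary <- function(g1, g2) {
  g1 <- as_group_summary(g1); g2 <- as_group_summary(g2)
  v1 <- g1$sem^2; v2 <- g2$sem^2
  diff <- g2$mean - g1$mean
  se2 <- v1 + v2
  if (se2 == 0) {
    return(t_result(if (diff == 0) 0 else sign(diff) * Inf,
                    g1$n + g2$n - 2L, diff, pooled = FALSE))
  }
  df <- se2^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  t_result(diff / sqrt(se2), df, diff, pooled = FALSE)
}

#' Two-sample t-test on raw samples
#'
#' Computes each sample's (mean, SEM, n) and delegates to the corresponding
#' summary-statistic formula, so raw and summary routes agree exactly.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param welch Use the Welch correction (default FALSE = pooled).
#' @return `t_test_result`.
#' @export
t_test_raw <- function(x, y, welch = FALSE) {
  if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per group", call. = FALSE)
  g1 <- summarize_sample(x); g2 <- summarize_sample(y)
  if (welch) welch_t_from_summary(g1, g2) else pooled_t_from_summary(g1, g2)
}

#' Shapiro-Wilk normality test
#'
#' Normality gate applied before parametric comparisons; wraps the standard
#' Royston approximation. Requires 3 <= n <= 5000 and non-constant data.
#'
#' @param x Numeric sample.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || length(x) > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  }
  if (sd(x) == 0) stop("W undefined for a constant sample", call. = FALSE)
  res <- shapiro.test(x)
  list(W = unname(res$statistic), p = res$p.value)
}

check_long_table <- function(data) {
  need <- c("subject", "group", "time", "value")
  if (!all(need %in% names(data))) {
    stop("need columns subject, group, time, value", call. = FALSE)
  }
  data$subject <- as.character(data$subject)
  data$group <- as.character(data$group)
  tab <- table(data$subject, data$time)
  if (any(tab != 1)) {
    stop("design incomplete: every subject must appear exactly once per time",
         call. = FALSE)
  }
  if (length(unique(data$time)) < 2) {
    stop("within-subject effects undefined with a single timepoint", call. = FALSE)
  }
  if (any(table(unique(data[c("subject", "group")])$group) < 2)) {
    stop("need >= 2 subjects per group", call. = FALSE)
  }
  data
}

#' Two-way mixed (split-plot) ANOVA with Greenhouse-Geisser correction
#'
#' One between-subjects factor (group) crossed with one within-subjects
#' factor (time), every subject measured at every timepoint. Sums of squares
#' are the definitional split-plot decomposition: the group effect is tested
#' against subject-within-group variation; time and the time-by-group
#' interaction against the time-by-subject-within-group residual. Because
#' each subject contributes every timepoint, the decomposition is orthogonal
#' even with unequal group sizes (time marginals weighted by group size).
#' The Greenhouse-Geisser epsilon is computed from the eigenvalues of the
#' double-centered pooled within-group covariance of the timepoints and
#' multiplies the within-effect degrees of freedom.
#'
#' @param data Long data frame with columns `subject`, `group`, `time`,
#'   `value`; balanced complete design, no missing cells.
#' @return List of class `mixed_anova`: per-effect F, raw and
#'   Greenhouse-Geisser-corrected dfs and p-values, `epsilon_gg`, and the
#'   full SS table.
#' @export
mixed_anova <- function(data) {
  data <- check_long_table(data)
  times <- sort(unique(data$time))
  k <- length(times)
  subj <- unique(data[c("subject", "group")])
  a <- length(unique(subj$group))
  if (a < 2) stop("need >= 2 groups", call. = FALSE)
  N <- nrow(subj)

  # subjects x times response matrix
  Y <- matrix(NA_real_, N, k, dimnames = list(subj$subject, as.character(times)))
  for (r in seq_len(nrow(data))) {
    Y[data$subject[r], as.character(data$time[r])] <- data$value[r]
  }
  grp <- subj$group
  n_g <- table(grp)

  grand <- mean(Y)
  M_s <- rowMeans(Y)                               # subject means
  M_g <- tapply(M_s, grp, mean)                    # group means
  M_t <- colMeans(Y)                               # time means (weighted)
  M_gt <- apply(Y, 2, function(col) tapply(col, grp, mean))  # a x k cell means
  if (a == 2 && is.null(dim(M_gt))) M_gt <- matrix(M_gt, nrow = a)

  ss_total <- sum((Y - grand)^2)
  ss_between_subj <- k * sum((M_s - grand)^2)
  ss_group <- k * sum(n_g * (M_g - grand)^2)
  ss_subj_err <- ss_between_subj - ss_group
  ss_time <- N * sum((M_t - grand)^2)
  e_gt <- sweep(sweep(M_gt, 1, M_g, "-"), 2, M_t, "-") + grand
  ss_int <- sum(sweep(e_gt^2, 1, as.numeric(n_g), "*"))
  ss_werr <- ss_total - ss_between_subj - ss_time - ss_int

  df_group <- a - 1; df_subj <- N - a
  df_time <- k - 1; df_int <- (a - 1) * (k - 1); df_werr <- (N - a) * (k - 1)

  # zero-SS numerators give F = 0 even when the error SS is also zero
  fratio <- function(ssn, dfn, ssd, dfd) {
    if (ssn <= 0) 0 else (ssn / dfn) / (ssd / dfd)
  }
  f_group <- fratio(ss_group, df_group, ss_subj_err, df_subj)
  f_time <- fratio(ss_time, df_time, ss_werr, df_werr)
  f_int <- fratio(ss_int, df_int, ss_werr, df_werr)

  # GG epsilon from the pooled within-group covariance, double-centered
  resid <- Y
  for (g in names(n_g)) {
    rows <- grp == g
    resid[rows, ] <- sweep(Y[rows, , drop = FALSE], 2,
                           colMeans(Y[rows, , drop = FALSE]), "-")
  }
  S <- crossprod(resid) / (N - a)
  Sc <- sweep(sweep(S, 1, rowMeans(S), "-"), 2, colMeans(S), "-") + mean(S)
  eps <- if (sum(Sc^2) == 0) 1 else sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
  eps <- min(1, max(1 / (k - 1), eps))

  pvals <- c(
    group = pf(f_group, df_group, df_subj, lower.tail = FALSE),
    time = pf(f_time, df_time, df_werr, lower.tail = FALSE),
    interaction = pf(f_int, df_int, df_werr, lower.tail = FALSE)
  )
  pvals_gg <- c(
    time = pf(f_time, df_time * eps, df_werr * eps, lower.tail = FALSE),
    interaction = pf(f_int, df_int * eps, df_werr * eps, lower.tail = FALSE)
  )
  structure(list(
    f_group = f_group, f_time = f_time, f_interaction = f_int,
    df = list(group = c(df_group, df_subj),
              time = c(df_time, df_werr),
              interaction = c(df_int, df_werr)),
    df_gg = list(time = c(df_time, df_werr) * eps,
                 interaction = c(df_int, df_werr) * eps),
    epsilon_gg = eps, p = pvals, p_gg = pvals_gg,
    ss = c(group = ss_group, subj_error = ss_subj_err, time = ss_time,
           interaction = ss_int, within_error = ss_werr, total = ss_total),
    n_subjects = N, n_times = k, n_groups = a
  ), class = "mixed_anova")
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat(sprintf("<mixed_anova> %d groups x %d times, %d subjects\n",
              x$n_groups, x$n_times, x$n_subjects))
  cat(sprintf("  group: F = %.3f, df = (%d, %d), p = %.4g\n",
              x$f_group, x$df$group[1], x$df$group[2], x$p["group"]))
  cat(sprintf("  time:  F = %.3f, df = (%.2f, %.2f) GG, p = %.4g (eps = %.3f)\n",
              x$f_time, x$df_gg$time[1], x$df_gg$time[2], x$p_gg["time"],
              x$epsilon_gg))
  cat(sprintf("  time x group: F = %.3f, df = (%.2f, %.2f) GG, p = %.4g\n",
              x$f_interaction, x$df_gg$interaction[1], x$df_gg$interaction[2],
              x$p_gg["interaction"]))
  invisible(x)
}

#' Simple main effect of group at one timepoint
#'
#' Default (`error = "per-timepoint"`): one-way between-groups ANOVA using
#' only that timepoint's data; with two groups, F equals the square of the
#' pooled t. `error = "omnibus"` keeps the same numerator but tests it
#' against the omnibus between-subjects error mean square from the full
#' mixed ANOVA.
#'
#' @param data Long table as for [mixed_anova()].
#' @param at Timepoint at which to test.
#' @param error Error-term convention.
#' @return List with `f`, `df1`, `df2`, `p`.
#' @export
simple_main_effects <- function(data, at, error = c("per-timepoint", "omnibus")) {
  error <- match.arg(error)
  data <- check_long_table(data)
  if (!at %in% data$time) stop("unknown timepoint", call. = FALSE)
  slice <- data[data$time == at, ]
  vals <- slice$value
  grp <- slice$group
  a <- length(unique(grp)); N <- length(vals)
  gm <- tapply(vals, grp, mean)
  n_g <- table(grp)
  ss_b <- sum(n_g * (gm - mean(vals))^2)
  ms_b <- ss_b / (a - 1)
  if (error == "per-timepoint") {
    ss_w <- sum((vals - gm[grp])^2)
    df2 <- N - a
    ms_e <- ss_w / df2
  } else {
    om <- mixed_anova(data)
    df2 <- om$df$group[2]
    ms_e <- om$ss["subj_error"] / df2
  }
  f <- if (ss_b <= 0) 0 else ms_b / ms_e
  list(f = unname(f), df1 = a - 1, df2 = unname(df2),
       p = unname(pf(f, a - 1, df2, lower.tail = FALSE)))
}
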