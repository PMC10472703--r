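# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: the DFT oracle is the O(n^2) transform written
# from its definition, and the split-plot oracle accumulates sums of squares
# with explicit loops over cells.

# Direct DFT band-pass from the transform definition (no fft()).
direct_dft_bandpass <- function(v, fs, lo, hi) {
  n <- length(v)
  j <- 0:(n - 1)
  X <- vapply(j, function(m) sum(v * exp(-2i * pi * m * j / n)), complex(1))
  f <- j * fs / n
  f <- pmin(f, fs - f)
  X[f < lo | f > hi] <- 0
  out <- vapply(j, function(m) sum(X * exp(2i * pi * m * j / n)) / n, complex(1))
  Re(out)
}

# Definitional split-plot sums of squares via explicit loops.
splitplot_oracle <- function(data) {
  data$subject <- as.character(data$subject)
  subs <- unique(data[c("subject", "group")])
  times <- sort(unique(data$time))
  grps <- sort(unique(subs$group))
  get <- function(s, t) data$value[data$subject == s & data$time == t]
  grand <- mean(data$value)

  ss_group <- 0; ss_subj <- 0; ss_time <- 0; ss_int <- 0; ss_werr <- 0
  for (g in grps) {
    sg <- subs$subject[subs$group == g]
    mg <- mean(data$value[data$group == g])
    ss_group <- ss_group + length(sg) * length(times) * (mg - grand)^2
    for (s in sg) {
      ms <- mean(data$value[data$subject == s])
      ss_subj <- ss_subj + length(times) * (ms - mg)^2
    }
  }
  for (t in times) {
    mt <- mean(data$value[data$time == t])
    ss_time <- ss_time + nrow(subs) * (mt - grand)^2
  }
  for (g in grps) for (t in times) {
    sg <- subs$subject[subs$group == g]
    mgt <- mean(data$value[data$group == g & data$time == t])
    mg <- mean(data$value[data$group == g])
    mt <- mean(data$value[data$time == t])
    ss_int <- ss_int + length(sg) * (mgt - mg - mt + grand)^2
    for (s in sg) {
      ms <- mean(data$value[data$subject == s])
      ss_werr <- ss_werr + (get(s, t) - ms - mgt + mg)^2
    }
  }
  a <- length(grps); k <- length(times); N <- nrow(subs)
  list(
    f_group = (ss_group / (a - 1)) / (ss_subj / (N - a)),
    f_time = (ss_time / (k - 1)) / (ss_werr / ((N - a) * (k - 1))),
    f_int = (ss_int / ((a - 1) * (k - 1))) / (ss_werr / ((N - a) * (k - 1))),
    ss = c(group = ss_group, subj = ss_subj, time = ss_time,
           int = ss_int, werr = ss_werr)
  )
}

# Balanced toy long table for ANOVA tests.
make_long_table <- function(n_per_group = 4, times = c(1, 2, 3), seed = 42,
                            group_effect = 1, time_slope = 0.5) {
  withr::with_seed(seed, {
    subs <- sprintf("s%02d", seq_len(2 * n_per_group))
    grp <- rep(c("A", "B"), each = n_per_group)
    d <- expand.grid(subject = subs, time = times, stringsAsFactors = FALSE)
    d$group <- grp[match(d$subject, subs)]
    d$value <- rnorm(nrow(d)) + time_slope * d$time +
      group_effect * (d$group == "B")
    d
  })
}

noise_free_params <- function(...) erg_sim_params(noise_sd = 0, ...)
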