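#' Load the bundled table of published group comparisons
#'
#' Twelve group-level comparisons between control (db/+) and diabetic
#' (db/db) mice -- oscillatory-potential amplitudes, retinal layer
#' thicknesses, cell and synapse counts, and respiration parameters --
#' transcribed as (mean, SEM, n) per group together with the t statistic
#' and degrees of freedom reported alongside them. Used to validate the
#' summary-statistic t-test implementation against published values.
#'
#' @param path CSV path; defaults to the bundled table.
#' @return Data frame, one comparison per row.
#' @export
reported_group_summaries <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reported_group_summaries.csv",
                        package = "scoterg", mustWork = TRUE)
  }
  read.csv(path, stringsAsFactors = FALSE)
}

#' Recompute published t statistics from their printed summaries
#'
#' For every row of the bundled comparison table, applies
#' [pooled_t_from_summary()] to the two (mean, SEM, n) summaries (control
#' group first, so t is oriented diabetic minus control) and reports the
#' recomputed t and df next to the published values. A row passes when
#' |recomputed t - reported t| <= `tol_t` and the df matches exactly.
#'
#' @param table Comparison table as from [reported_group_summaries()].
#' @param tol_t Tolerance on |delta t| (default 0.05).
#' @return Data frame with columns `comparison`, `t`, `df`, `t_reported`,
#'   `df_reported`, `delta_t`, `df_match`, `pass`; attribute `all_pass`.
#' @export
reproduce_reported_t <- function(table = reported_group_summaries(),
                                 tol_t = 0.05) {
  rows <- lapply(seq_len(nrow(table)), function(i) {
    r <- table[i, ]
    tt <- pooled_t_from_summary(
      group_summary(r$mean_ctrl, r$sem_ctrl, r$n_ctrl, "ctrl"),
      group_summary(r$mean_db, r$sem_db, r$n_db, "db"))
    data.frame(comparison = r$comparison, t = tt$t, df = tt$df,
               t_reported = r$t_reported, df_reported = r$df_reported,
               delta_t = tt$t - r$t_reported,
               df_match = tt$df == r$df_reported)
  })
  out <- do.call(rbind, rows)
  out$pass <- abs(out$delta_t) <= tol_t & out$df_match
  attr(out, "all_pass") <- all(out$pass)
  out
}
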