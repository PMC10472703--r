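#' Segment an annotated OCR trace into assay phases
#'
#' Orders rows by time and validates the injection sequence of a
#' mitochondrial stress assay without oligomycin: basal measurements, then
#' FCCP-uncoupled measurements, then rotenone/antimycin-A measurements.
#' All three phases must be present, non-empty, and in order.
#'
#' @param rows Data frame with columns `time_min`, `ocr_pmol_min`, `phase`
#'   (values among basal/fccp/rotaa), and optionally `well_id`.
#' @return Validated data frame sorted by time, `phase` as ordered factor.
#' @export
segment_phases <- function(rows) {
  need <- c("time_min", "ocr_pmol_min", "phase")
  if (!all(need %in% names(rows))) {
    stop("trace needs columns time_min, ocr_pmol_min, phase", call. = FALSE)
  }
  rows <- rows[order(rows$time_min), , drop = FALSE]
  ph <- as.character(rows$phase)
  levels_ok <- c("basal", "fccp", "rotaa")
  if (!all(ph %in% levels_ok)) stop("unknown phase label", call. = FALSE)
  if (!all(levels_ok %in% ph)) {
    stop(sprintf("missing phase(s): %s",
                 paste(setdiff(levels_ok, ph), collapse = ", ")), call. = FALSE)
  }
  runs <- rle(ph)$values
  if (!identical(runs, levels_ok)) {
    stop("phases out of order; expected basal -> fccp -> rotaa", call. = FALSE)
  }
  if (any(!is.finite(rows$ocr_pmol_min))) stop("non-finite OCR", call. = FALSE)
  rows$phase <- factor(ph, levels = levels_ok)
  rownames(rows) <- NULL
  rows
}

#' Derive respiration parameters from a three-phase OCR trace
#'
#' Standard flux-analyzer definitions for a protocol without oligomycin:
#' non-mitochondrial consumption is the mean OCR after rotenone/antimycin A;
#' basal respiration is the last pre-injection measurement minus the
#' non-mitochondrial floor; maximal respiration is the highest FCCP-phase
#' measurement minus the floor; spare respiratory capacity is maximal minus
#' basal (an identity, by construction). Negative basal or spare values
#' (e.g. failed uncoupling) are flagged, not clamped. Mean-of-phase
#' alternatives for basal and maximal are available.
#'
#' @param trace Data frame accepted by [segment_phases()].
#' @param basal_stat `"last"` (default) or `"mean"` of the basal phase.
#' @param maximal_stat `"max"` (default) or `"mean"` of the FCCP phase.
#' @return List of class `bioenergetics_params`: `basal`, `maximal`,
#'   `spare`, `nonmito` (pmol/min) and `flags`.
#' @export
compute_respiration_params <- function(trace,
                                       basal_stat = c("last", "mean"),
                                       maximal_stat = c("max", "mean")) {
  basal_stat <- match.arg(basal_stat)
  maximal_stat <- match.arg(maximal_stat)
  trace <- segment_phases(trace)
  ocr <- split(trace$ocr_pmol_min, trace$phase)
  nonmito <- mean(ocr$rotaa)
  basal_raw <- if (basal_stat == "last") ocr$basal[length(ocr$basal)]
               else mean(ocr$basal)
  maximal_raw <- if (maximal_stat == "max") max(ocr$fccp) else mean(ocr$fccp)
  basal <- basal_raw - nonmito
  maximal <- maximal_raw - nonmito
  spare <- maximal - basal
  flags <- character()
  if (basal < 0) flags <- c(flags, "negative-basal")
  if (spare < 0) flags <- c(flags, "negative-spare")
  structure(list(basal = basal, maximal = maximal, spare = spare,
                 nonmito = nonmito, flags = flags),
            class = "bioenergetics_params")
}

#' @export
print.bioenergetics_params <- function(x, ...) {
  cat(sprintf(
    "<bioenergetics> basal %.2f | maximal %.2f | spare %.2f | non-mito %.2f pmol/min\n",
    x$basal, x$maximal, x$spare, x$nonmito))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  if (!is.null(x$normalized)) {
    n <- x$normalized
    cat(sprintf("  per mg protein: basal %.1f | maximal %.1f | spare %.1f | non-mito %.1f\n",
                n$basal, n$maximal, n$spare, n$nonmito))
  }
  invisible(x)
}

#' Normalize respiration parameters by protein content
#'
#' Divides the four raw parameters by the punch's protein mass, yielding
#' pmol/min/mg, and attaches them as `$normalized`.
#'
#' @param params A `bioenergetics_params` object.
#' @param protein_mg Protein mass in mg (> 0).
#' @return The input with a `normalized` element added.
#' @export
normalize_by_protein <- function(params, protein_mg) {
  if (!is.numeric(protein_mg) || length(protein_mg) != 1 || !is.finite(protein_mg) ||
      protein_mg <= 0) {
    stop("protein_mg must be a single value > 0", call. = FALSE)
  }
  params$normalized <- lapply(
    params[c("basal", "maximal", "spare", "nonmito")],
    function(v) v / protein_mg)
  params$protein_mg <- protein_mg
  params
}
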