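# Calibrated qPCR relative copy-number assignment for the RCCX modular
# locus (C4A/C4B, C4L/C4S, TNXA anchored on single-copy RP1) and the
# internal-validation identity C4A+C4B == C4L+C4S == TNXA+2.

RCCX_GENES <- c("C4A", "C4B", "C4L", "C4S", "TNXA")

#' Relative copy number from replicate Ct values
#'
#' With the anchor present at one copy per chromosome (two per genome),
#' relative copies are `2 * 2^-(mean(ct_target) - mean(ct_anchor))`,
#' assuming 100% amplification efficiency (`efficiency = 2` per cycle,
#' configurable). A target recorded entirely as the no-amplification
#' sentinel (`NA`) has 0 copies; a sentinel anchor is an error.
#'
#' @param ct_target,ct_rp1 Replicate Ct values (cycles).
#' @param efficiency Per-cycle amplification factor (default 2).
#' @return Continuous relative copy number.
#' @export
relative_copy <- function(ct_target, ct_rp1, efficiency = 2) {
  if (length(ct_target) < 1 || length(ct_rp1) < 1)
    stop("need at least one replicate each")
  if (all(is.na(ct_rp1))) stop("anchor gene (RP1) did not amplify")
  if (all(is.na(ct_target))) return(0)
  dct <- mean(ct_target, na.rm = TRUE) - mean(ct_rp1, na.rm = TRUE)
  2 * efficiency^(-dct)
}

#' Fit the copy-number calibration map
#'
#' Least-squares fit of known true copies on measured relative copies
#' across reference samples, `true = a * measured + b`, correcting the
#' intrinsic underestimation of the relative-quantification step. One
#' shared linear map across genes.
#'
#' @param measured Numeric vector of measured relative copies.
#' @param true_copies Known integer copies of the same references (>= 2
#'   distinct values).
#' @return An object of class `CopyCalibration`: `a`, `b`, `fit` (the lm),
#'   `r_squared`, `residual_sd`.
#' @export
fit_calibration <- function(measured, true_copies) {
  stopifnot(length(measured) == length(true_copies), length(measured) >= 2)
  if (length(unique(true_copies)) < 2)
    stop("calibration needs at least two distinct known copy values")
  fit <- stats::lm(true_copies ~ measured)
  # noiseless reference panels fit perfectly; the summary warning about
  # unreliable diagnostics is expected there
  sm <- suppressWarnings(summary(fit))
  structure(list(a = unname(stats::coef(fit)[2]),
                 b = unname(stats::coef(fit)[1]), fit = fit,
                 r_squared = sm$r.squared,
                 residual_sd = sm$sigma),
            class = "CopyCalibration")
}

#' Apply a calibration map
#' @param calibration A [fit_calibration()] result (or `NULL` for the
#'   identity map).
#' @param measured Numeric vector of measured relative copies.
#' @return Calibrated continuous copies.
#' @export
apply_calibration <- function(calibration, measured) {
  if (is.null(calibration)) return(measured)
  calibration$a * measured + calibration$b
}

#' Assign integer copy numbers and run the internal validation
#'
#' Calibrated continuous copies are rounded to the nearest non-negative
#' integer (ties at .5 round up). When `validate` is `TRUE` the three
#' module counts `C4A + C4B`, `C4L + C4S` and `TNXA + 2` are compared; the
#' call is valid only when all three agree, in which case `modules_total`
#' is their common value.
#'
#' @param calibrated Named numeric vector with entries `C4A`, `C4B`,
#'   `C4L`, `C4S`, `TNXA`.
#' @param validate Run the internal-validation identity (default TRUE)?
#' @return An object of class `CopyNumberCall`: `raw`, `assigned` (named
#'   integer), `totals` (the three counts), `valid`, `modules_total`.
#' @export
assign_copies <- function(calibrated, validate = TRUE) {
  stopifnot(all(RCCX_GENES %in% names(calibrated)))
  assigned <- pmax(0L, as.integer(floor(calibrated[RCCX_GENES] + 0.5)))
  names(assigned) <- RCCX_GENES
  totals <- c(C4A_C4B = assigned[["C4A"]] + assigned[["C4B"]],
              C4L_C4S = assigned[["C4L"]] + assigned[["C4S"]],
              TNXA_2 = assigned[["TNXA"]] + 2L)
  valid <- if (validate) length(unique(totals)) == 1L else NA
  structure(list(raw = calibrated, assigned = assigned, totals = totals,
                 valid = valid,
                 modules_total = if (isTRUE(valid)) totals[[1]] else
                   NA_integer_),
            class = "CopyNumberCall")
}

#' @export
print.CopyNumberCall <- function(x, ...) {
  cat("<CopyNumberCall>",
      paste(names(x$assigned), x$assigned, sep = "=", collapse = " "),
      sprintf(" totals (%s)%s\n", paste(x$totals, collapse = ","),
              if (isTRUE(x$valid)) " valid" else
                if (isFALSE(x$valid)) " INVALID" else ""))
  invisible(x)
}

#' End-to-end RCCX copy-number calling from a Ct table
#'
#' For every sample in a long-format Ct table, computes relative copies of
#' each RCCX gene against the RP1 anchor, applies the calibration map, and
#' assigns validated integer copies.
#'
#' @param ct_table data.frame (`sample`, `gene`, `replicate`, `ct`)
#'   including `RP1` rows.
#' @param calibration Optional [fit_calibration()] map.
#' @param genes Target genes (default the five RCCX genes).
#' @return data.frame with one row per sample: per-gene integer copies,
#'   the three totals and `valid`; the full `CopyNumberCall` objects are
#'   attached as the `calls` attribute.
#' @export
call_rccx <- function(ct_table, calibration = NULL, genes = RCCX_GENES) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(ct_table)))
  samples <- unique(ct_table$sample)
  calls <- lapply(samples, function(s) {
    tab <- ct_table[ct_table$sample == s, ]
    ct_ref <- tab$ct[tab$gene == "RP1"]
    raw <- vapply(genes, function(g)
      relative_copy(tab$ct[tab$gene == g], ct_ref), numeric(1))
    assign_copies(apply_calibration(calibration, raw))
  })
  names(calls) <- samples
  out <- data.frame(sample = samples)
  for (g in genes)
    out[[g]] <- vapply(calls, function(x) x$assigned[[g]], integer(1))
  out$modules_total <- vapply(calls, function(x)
    if (isTRUE(x$valid)) x$modules_total else NA_integer_, integer(1))
  out$valid <- vapply(calls, function(x) isTRUE(x$valid), logical(1))
  attr(out, "calls") <- calls
  out
}

#' Read a long-format Ct table
#' @param path TSV with header `sample`, `gene`, `replicate`, `ct`
#'   (`NA` = no amplification).
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
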