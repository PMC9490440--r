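# The Spectrum container: a wavenumber-ordered absorbance trace.

#' Construct a spectrum
#'
#' @param wavenumbers Numeric, cm-1, strictly monotone after sorting.
#' @param absorbance Numeric, same length, finite.
#' @param sample_id Optional identifier.
#' @param state Declared state: `"unburnt"`, `"burnt"` or `"unknown"`.
#' @param pmi_days Known postmortem interval in days, or `NA`.
#' @param baseline_corrected Logical flag maintained by
#'   [baseline_correct()].
#' @return Object of class `ftir_spectrum`.
#' @export
ftir_spectrum <- function(wavenumbers, absorbance, sample_id = NA_character_,
                          state = "unknown", pmi_days = NA_real_,
                          baseline_corrected = FALSE) {
  if (length(wavenumbers) != length(absorbance))
    abort_ba("wavenumbers and absorbance must have equal length", "format_error")
  if (length(wavenumbers) == 0L)
    abort_ba("empty spectrum", "empty_input_error")
  o <- order(wavenumbers)
  wavenumbers <- wavenumbers[o]
  absorbance <- absorbance[o]
  if (any(duplicated(wavenumbers))) {
    # collapse duplicate wavenumbers by mean
    absorbance <- as.numeric(tapply(absorbance, wavenumbers, mean))
    wavenumbers <- sort(unique(wavenumbers))
  }
  if (any(!is.finite(absorbance)))
    abort_ba("non-finite absorbance values", "format_error")
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance,
                 sample_id = sample_id, state = state, pmi_days = pmi_days,
                 baseline_corrected = baseline_corrected),
            class = "ftir_spectrum")
}

#' @export
print.ftir_spectrum <- function(x, ...) {
  cat(sprintf("<ftir_spectrum> %s: %d points, %.0f-%.0f cm-1, state=%s%s\n",
              x$sample_id %||% "?", length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers), x$state,
              if (isTRUE(x$baseline_corrected)) ", baseline-corrected" else ""))
  invisible(x)
}

#' @export
as.data.frame.ftir_spectrum <- function(x, ...) {
  data.frame(wavenumber_cm1 = x$wavenumbers, absorbance = x$absorbance)
}
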