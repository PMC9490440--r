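# Baseline correction by local-minimum anchoring.

#' Default baseline anchor wavenumbers
#'
#' The four instrument-protocol anchors (450, 800, 900, 1200 cm-1) plus
#' extra anchors at 1300, 1800, 2200 and 3800 cm-1 so the carbonate/amide,
#' cyanamide and OH regions sit between anchored segments rather than on an
#' extrapolated one.
#'
#' @return Numeric vector of anchor positions, cm-1.
#' @export
default_anchors <- function() c(450, 800, 900, 1200, 1300, 1800, 2200, 3800)

#' Baseline-correct a spectrum
#'
#' For each anchor the local minimum of absorbance within +/-10 cm-1 is
#' located; the piecewise-linear interpolant through those minima is
#' subtracted and negative residuals are clipped at 0. Beyond the outermost
#' anchors the nearest segment is extended linearly. Because the knots sit
#' on actual spectrum minima, the corrected trace is exactly zero at each
#' knot, which makes the operation idempotent.
#'
#' @param spectrum An `ftir_spectrum`.
#' @param anchors Anchor wavenumbers (>= 2), each within the spectrum
#'   range.
#' @param window Half-width of the local-minimum search window, cm-1.
#' @return A new, baseline-corrected `ftir_spectrum`; the input is not
#'   modified.
#' @export
baseline_correct <- function(spectrum, anchors = default_anchors(),
                             window = 10) {
  wn <- spectrum$wavenumbers
  ab <- spectrum$absorbance
  anchors <- sort(anchors)
  if (length(anchors) < 2)
    abort_ba("need at least 2 baseline anchors", "anchor_error")
  if (any(anchors < min(wn) | anchors > max(wn)))
    abort_ba("baseline anchor outside spectrum range", "anchor_error")
  knot_x <- numeric(length(anchors))
  knot_y <- numeric(length(anchors))
  for (i in seq_along(anchors)) {
    in_win <- which(wn >= anchors[i] - window & wn <= anchors[i] + window)
    if (!length(in_win))
      abort_ba(sprintf("no grid points near anchor %g", anchors[i]), "anchor_error")
    j <- in_win[which.min(ab[in_win])]
    knot_x[i] <- wn[j]
    knot_y[i] <- ab[j]
  }
  # piecewise-linear through the knots, nearest segment extended outward
  baseline <- stats::approx(knot_x, knot_y, xout = wn, rule = 2)$y
  n <- length(knot_x)
  lo <- wn < knot_x[1]
  if (any(lo)) {
    s <- (knot_y[2] - knot_y[1]) / (knot_x[2] - knot_x[1])
    baseline[lo] <- knot_y[1] + s * (wn[lo] - knot_x[1])
  }
  hi <- wn > knot_x[n]
  if (any(hi)) {
    s <- (knot_y[n] - knot_y[n - 1]) / (knot_x[n] - knot_x[n - 1])
    baseline[hi] <- knot_y[n] + s * (wn[hi] - knot_x[n])
  }
  ftir_spectrum(wn, pmax(ab - baseline, 0),
                sample_id = spectrum$sample_id, state = spectrum$state,
                pmi_days = spectrum$pmi_days, baseline_corrected = TRUE)
}
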