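# Peak-height extraction: maxima, minima and shoulders within tolerance
# windows, following the protocol of recording the window maximum when a
# slight frequency shift (+/-5 cm-1) is present, together with the shift.

#' Construct a feature query
#'
#' @param center Nominal band position, cm-1.
#' @param tolerance Search half-window, cm-1 (protocol default 5).
#' @param mode `"peak"`, `"valley"` or `"shoulder"`.
#' @return Object of class `feature_query`.
#' @export
feature_query <- function(center, tolerance = 5, mode = c("peak", "valley", "shoulder")) {
  mode <- match.arg(mode)
  if (tolerance < 0) abort_ba("tolerance must be >= 0", "window_error")
  structure(list(center = center, tolerance = tolerance, mode = mode),
            class = "feature_query")
}

sg_smooth <- function(y, n = 11, p = 3) {
  if (length(y) < n) return(y)
  signal::sgolayfilt(y, p = p, n = n, m = 0)
}

sg_second_derivative <- function(y, n = 11, p = 3) {
  if (length(y) < n) return(rep(NA_real_, length(y)))
  signal::sgolayfilt(y, p = p, n = n, m = 2)
}

local_max_idx <- function(y) {
  n <- length(y)
  if (n < 3) return(integer())
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1L
}

local_min_idx <- function(y) local_max_idx(-y)

# curvature-dip detector: smoothed second derivative has an interior local
# minimum in the window whose depth below the chord through the window-end
# values exceeds dip_floor, and (for a true shoulder) the smoothed
# absorbance has no interior local maximum there
curvature_dip <- function(wn, ab_s, d2, idx, dip_floor, forbid_max = TRUE) {
  if (length(idx) < 5 || any(is.na(d2[idx]))) return(NULL)
  dips <- idx[local_min_idx(d2[idx])]
  if (!length(dips)) return(NULL)
  if (forbid_max && length(local_max_idx(ab_s[idx]))) return(NULL)
  chord <- stats::approx(wn[range(idx)], d2[range(idx)], xout = wn[dips])$y
  depth <- chord - d2[dips]
  ok <- depth >= dip_floor
  if (!any(ok)) return(NULL)
  j <- dips[ok][which.max(depth[ok])]
  list(index = j, depth = max(depth[ok]))
}

#' Measure a spectral feature
#'
#' Peak mode returns the maximum absorbance within
#' `[center - tol, center + tol]` and its wavenumber; valley mode the
#' minimum. Shoulder mode decides presence from a dip in the
#' Savitzky-Golay-smoothed second derivative (localised extra negative
#' curvature) inside the window with no full local maximum of smoothed
#' absorbance there, returning the absorbance at the dip. The reported
#' `shift` is `observed_center - center`.
#'
#' @param spectrum A baseline-corrected `ftir_spectrum`.
#' @param query A `feature_query`.
#' @param sg_window,sg_order Savitzky-Golay parameters (points, polynomial
#'   order) used for shoulder detection.
#' @param dip_floor Minimum curvature-dip depth (absorbance per cm-1
#'   squared) for a shoulder to count.
#' @return List with `height`, `observed_center`, `shift` and `present`
#'   (always `TRUE` for peak/valley; the shoulder verdict otherwise).
#' @export
feature_height <- function(spectrum, query, sg_window = 11, sg_order = 3,
                           dip_floor = 2e-4) {
  wn <- spectrum$wavenumbers
  ab <- spectrum$absorbance
  lo <- query$center - query$tolerance
  hi <- query$center + query$tolerance
  if (lo < min(wn) || hi > max(wn))
    abort_ba(sprintf("query window [%g, %g] outside spectrum range", lo, hi),
             "window_error")
  idx <- which(wn >= lo & wn <= hi)
  if (!length(idx))
    abort_ba("no grid points in query window", "window_error")
  if (query$mode == "peak") {
    j <- idx[which.max(ab[idx])]
    return(list(height = ab[j], observed_center = wn[j],
                shift = wn[j] - query$center, present = TRUE))
  }
  if (query$mode == "valley") {
    j <- idx[which.min(ab[idx])]
    return(list(height = ab[j], observed_center = wn[j],
                shift = wn[j] - query$center, present = TRUE))
  }
  ab_s <- sg_smooth(ab, n = sg_window, p = sg_order)
  d2 <- sg_second_derivative(ab_s, n = sg_window, p = sg_order)
  hit <- curvature_dip(wn, ab_s, d2, idx, dip_floor)
  if (is.null(hit))
    return(list(height = NA_real_, observed_center = NA_real_,
                shift = NA_real_, present = FALSE))
  list(height = ab[hit$index], observed_center = wn[hit$index],
       shift = wn[hit$index] - query$center, present = TRUE)
}
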