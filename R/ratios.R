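# The infrared ratio battery and categorical heat markers.

#' Construct a ratio definition
#'
#' @param name Unique ratio name within a battery.
#' @param numerator,denominator Lists of [feature_query()] objects; heights
#'   are summed within each side.
#' @param applicability `"both"`, `"unburnt-only"` or `"burnt-only"`.
#' @return Object of class `ratio_definition`.
#' @export
ratio_definition <- function(name, numerator, denominator,
                             applicability = c("both", "unburnt-only", "burnt-only")) {
  applicability <- match.arg(applicability)
  if (!length(denominator))
    abort_ba(sprintf("ratio %s has empty denominator", name), "configuration_error")
  if (inherits(numerator, "feature_query")) numerator <- list(numerator)
  if (inherits(denominator, "feature_query")) denominator <- list(denominator)
  structure(list(name = name, numerator = numerator, denominator = denominator,
                 applicability = applicability),
            class = "ratio_definition")
}

#' The default ten-ratio battery
#'
#' Literature-standard peak-height indices, with band centers in editable
#' positions (build a custom battery to change them):
#' \itemize{
#'   \item IRSF = (565 + 605) / valley in [575, 600] (crystallinity index)
#'   \item C/P = 1415/1035 (type-B carbonate to phosphate)
#'   \item BPI = 1415/605, API = 1540/605 (burnt only), C/C = 1415/1540
#'     (burnt only)
#'   \item CN/P = 2010/1035 (cyanamide), CO/CO3 = 1740/1415 (carbonyl)
#'   \item N/P = 1660/1035 and APR = 1640/1035 (amide indices, unburnt
#'     only; the A-carbonate band overlaps amide II in unburnt bone, which
#'     is also why API/C-C are burnt-only)
#'   \item PHT = 625/610 (high-temperature phosphate reordering)
#' }
#'
#' @param tolerance Peak search half-window, cm-1.
#' @return Named list of `ratio_definition` objects.
#' @export
default_ratio_battery <- function(tolerance = 5) {
  pk <- function(center, tol = tolerance) feature_query(center, tol, "peak")
  defs <- list(
    ratio_definition("IRSF", list(pk(565), pk(605)),
                     list(feature_query(587.5, 12.5, "valley"))),
    ratio_definition("C/P", pk(1415), pk(1035)),
    ratio_definition("BPI", pk(1415), pk(605)),
    ratio_definition("API", pk(1540), pk(605), "burnt-only"),
    ratio_definition("C/C", pk(1415), pk(1540), "burnt-only"),
    ratio_definition("CN/P", pk(2010), pk(1035)),
    ratio_definition("CO/CO3", pk(1740), pk(1415)),
    ratio_definition("N/P", pk(1660), pk(1035), "unburnt-only"),
    ratio_definition("APR", pk(1640), pk(1035), "unburnt-only"),
    ratio_definition("PHT", pk(625), pk(610))
  )
  setNames(defs, vapply(defs, `[[`, "", "name"))
}

#' Compute the ratio battery for one spectrum
#'
#' Each applicable ratio is the sum of numerator heights over the sum of
#' denominator heights, with the observed shift of every queried feature
#' recorded. Ratios whose applicability excludes the declared state, and
#' ratios with a zero denominator (warned, not an error), are reported as
#' not-applicable (`NA`).
#'
#' @param spectrum A baseline-corrected `ftir_spectrum`.
#' @param battery List of `ratio_definition`s; duplicate names rejected.
#' @param state Declared state; defaults to the spectrum metadata.
#' @return Object of class `ftir_ratio_record`: fields `ratios` (named
#'   numeric), `shifts` (named numeric, one per queried feature),
#'   `sample_id`, `state`, `pmi_days`.
#' @export
compute_ratios <- function(spectrum, battery = default_ratio_battery(),
                           state = spectrum$state) {
  nms <- vapply(battery, `[[`, "", "name")
  if (anyDuplicated(nms))
    abort_ba("duplicate ratio names in battery", "configuration_error")
  ratios <- setNames(rep(NA_real_, length(battery)), nms)
  shifts <- c()
  for (def in battery) {
    excluded <- (def$applicability == "unburnt-only" && state == "burnt") ||
      (def$applicability == "burnt-only" && state != "burnt")
    num <- 0; den <- 0
    for (q in def$numerator) {
      f <- feature_height(spectrum, q)
      num <- num + f$height
      shifts[sprintf("%s:num:%g", def$name, q$center)] <- f$shift
    }
    for (q in def$denominator) {
      f <- feature_height(spectrum, q)
      den <- den + f$height
      shifts[sprintf("%s:den:%g", def$name, q$center)] <- f$shift
    }
    if (excluded) next
    if (!is.finite(den) || den == 0) {
      warning(sprintf("ratio %s: zero denominator, reported as not-applicable",
                      def$name))
      next
    }
    ratios[def$name] <- num / den
  }
  structure(list(ratios = ratios, shifts = shifts,
                 sample_id = spectrum$sample_id, state = state,
                 pmi_days = spectrum$pmi_days),
            class = "ftir_ratio_record")
}

#' @export
print.ftir_ratio_record <- function(x, ...) {
  cat(sprintf("<ftir_ratio_record> %s (%s, PMI %s d)\n",
              x$sample_id %||% "?", x$state,
              format(x$pmi_days)))
  print(round(x$ratios, 4))
  invisible(x)
}

#' Flatten ratio records into a data frame
#'
#' @param records List of `ftir_ratio_record`s.
#' @return Data frame with one row per record: metadata plus one column
#'   per ratio.
#' @export
ratio_records_to_df <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    cbind(data.frame(sample_id = r$sample_id, state = r$state,
                     pmi_days = r$pmi_days),
          as.data.frame(as.list(r$ratios), check.names = FALSE))
  }))
}

#' Detect categorical heat markers
#'
#' Scans a baseline-corrected spectrum for: the beta-TCP peak at
#' 1123 cm-1 (a local maximum of the smoothed trace within +/-5 cm-1 with
#' prominence above the floor), the 547 cm-1 shoulder (curvature-dip
#' criterion), the extra peak in the 1080-1100 cm-1 range (local maximum
#' or, because it usually rides the flank of the main phosphate band, a
#' curvature dip), and the OH-Cl band (default 3494 cm-1; the position is
#' configurable because reported values vary across the apatite
#' literature). Absent markers are valid results, not errors.
#'
#' @param spectrum A baseline-corrected `ftir_spectrum`.
#' @param floor Minimum prominence (absorbance above the flanking minima)
#'   for a peak to count.
#' @param dip_floor Curvature-dip depth floor for shoulder-type markers.
#' @param ohcl_center Center of the OH-Cl query, cm-1.
#' @param sg_window,sg_order Savitzky-Golay smoothing parameters.
#' @return Object of class `marker_report`: named list of
#'   `list(present, height, observed_center)` entries `btcp_peak_1123`,
#'   `shoulder_547`, `extra_peak_1080_1100`, `oh_cl_peak`.
#' @export
detect_markers <- function(spectrum, floor = 0.02, dip_floor = 2e-4,
                           ohcl_center = 3494, sg_window = 11, sg_order = 3) {
  wn <- spectrum$wavenumbers
  ab <- spectrum$absorbance
  ab_s <- sg_smooth(ab, n = sg_window, p = sg_order)
  d2 <- sg_second_derivative(ab_s, n = sg_window, p = sg_order)
  absent <- list(present = FALSE, height = NA_real_, observed_center = NA_real_)

  # prominence: height of the smoothed local maximum above the higher of
  # the minima on its two flanks, searched out to `margin` cm-1
  scan_local_max <- function(lo, hi, margin = 15) {
    idx <- which(wn >= lo & wn <= hi)
    if (length(idx) < 3) return(absent)
    lm <- idx[local_max_idx(ab_s[idx])]
    if (!length(lm)) return(absent)
    prom <- vapply(lm, function(j) {
      left <- which(wn >= wn[j] - margin & wn <= wn[j])
      right <- which(wn >= wn[j] & wn <= wn[j] + margin)
      ab_s[j] - max(min(ab_s[left]), min(ab_s[right]))
    }, numeric(1))
    lm <- lm[prom >= floor]
    if (!length(lm)) return(absent)
    j <- lm[which.max(ab_s[lm])]
    list(present = TRUE, height = ab[j], observed_center = wn[j])
  }

  scan_dip <- function(lo, hi) {
    idx <- which(wn >= lo & wn <= hi)
    hit <- curvature_dip(wn, ab_s, d2, idx, dip_floor, forbid_max = FALSE)
    if (is.null(hit)) return(absent)
    list(present = TRUE, height = ab[hit$index], observed_center = wn[hit$index])
  }

  extra <- scan_local_max(1080, 1100)
  if (!extra$present) extra <- scan_dip(1080, 1100)

  sh <- feature_height(spectrum, feature_query(547, 5, "shoulder"),
                       sg_window = sg_window, sg_order = sg_order,
                       dip_floor = dip_floor)
  structure(list(
    btcp_peak_1123 = scan_local_max(1123 - 5, 1123 + 5),
    shoulder_547 = list(present = sh$present, height = sh$height,
                        observed_center = sh$observed_center),
    extra_peak_1080_1100 = extra,
    oh_cl_peak = scan_local_max(ohcl_center - 8, ohcl_center + 8)
  ), class = "marker_report")
}
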