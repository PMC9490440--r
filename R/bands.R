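# Band specifications for the spectral forward model.

#' Construct a band table
#'
#' @param center Numeric vector of band centers, cm-1, within [400, 4000].
#' @param width Gaussian half-width parameter (sigma), cm-1, > 0.
#' @param amplitude Peak absorbance, >= 0.
#' @param label Optional band assignment labels.
#' @return A `band_spec` data frame.
#' @export
band_spec <- function(center, width, amplitude, label = NULL) {
  if (any(center < 400 | center > 4000))
    abort_ba("band centers must lie within [400, 4000] cm-1", "invalid_design_error")
  if (any(width <= 0)) abort_ba("band widths must be > 0", "invalid_design_error")
  if (any(amplitude < 0)) abort_ba("band amplitudes must be >= 0", "invalid_design_error")
  out <- data.frame(center = center, width = width, amplitude = amplitude,
                    label = label %||% rep(NA_character_, length(center)))
  class(out) <- c("band_spec", "data.frame")
  out
}

#' Default band model for a given state and postmortem interval
#'
#' Builds the Gaussian band list the spectral generator uses: the phosphate
#' nu4 doublet (565/605 cm-1) whose width narrows as crystallinity rises,
#' nu1/nu3 phosphate (962, 1035 cm-1), the B-type carbonate envelope (875,
#' 1415, 1455 cm-1), and state-specific features -- amide I/II, carbonyl
#' and the 547 cm-1 Mg-substitution shoulder in unburnt bone; cyanamide
#' (2010 cm-1), A-type carbonate (1540 cm-1), the 1080-1100 cm-1 extra
#' peak, the 625 cm-1 high-temperature phosphate shoulder and the OH-Cl
#' band in burnt bone. Amplitudes and widths are drawn from the trend
#' model, so they move with PMI as the study conditions prescribe.
#'
#' @param state `"unburnt"` or `"burnt"`.
#' @param pmi_days Postmortem interval in days.
#' @param trends A `trend_model`; defaults to [make_default_trends()].
#' @return A `band_spec` data frame.
#' @export
default_bands <- function(state, pmi_days, trends = make_default_trends()) {
  check_state(state)
  tv <- function(analyte) trend_value(trends, analyte, state, "ALL", pmi_days)
  w4 <- tv("nu4_width")
  band_spec(
    center = c(565, 605, 585, 625, 547, 962, 1035, 875, 1415, 1455, 1540,
               1550, 1660, 1740, 2010, 1090, 3400, 3494),
    width = c(w4, w4, 12, 8, 6, 7, 40, 12, 30, 25, 18, 25, 28, 15, 12, 15,
              150, 12),
    amplitude = c(1.0, 1.0, tv("valley_fill"), tv("pht625_amp"),
                  tv("shoulder547_amp"), 0.25,
                  1.60, 0.4 * tv("co3_amp"), tv("co3_amp"),
                  0.8 * tv("co3_amp"), tv("api1540_amp"), tv("amide2_amp"),
                  tv("amide1_amp"), tv("carbonyl_amp"), tv("cn_amp"),
                  tv("extra1090_amp"), tv("water_amp"), tv("ohcl_amp")),
    label = c("nu4 PO4", "nu4 PO4", "nu4 valley fill", "PHT shoulder",
              "Mg-OH shoulder",
              "nu1 PO4", "nu3 PO4", "nu2 CO3", "nu3 CO3 (B)", "nu3 CO3 (B)",
              "CO3 (A)", "amide II", "amide I", "carbonyl", "cyanamide",
              "extra 1080-1100", "water/OH", "OH-Cl")
  )
}
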