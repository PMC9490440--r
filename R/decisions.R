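# Interpretive decision rules: burnt/unburnt discrimination, heat-marker
# temperature banding, and the potassium-threshold inference of the
# postmortem interval preceding burning.

PMI_CATEGORIES <- c("peri-mortem burn plausible (<= ~2 weeks)",
                    "delayed burn (>= ~3 months surface exposure)",
                    "long delay (>= 1 year; K below detection in MC)",
                    "borderline", "indeterminate")

#' Classify burnt vs unburnt from a ratio record
#'
#' With a fitted LDA (trained on ratio battery columns), returns its
#' prediction with the posterior as the confidence. Without one, a
#' rule-based fallback declares "burnt" when CN/P exceeds a floor (the
#' cyanamide band only appears in bone burnt under reducing conditions);
#' when CN/P is not applicable it falls back to an IRSF crystallinity cut
#' (a weaker criterion, since diagenesis alone can raise IRSF).
#' Confidence reflects the margin over the deciding threshold.
#'
#' @param record An `ftir_ratio_record`.
#' @param model Optional `lda_result` fitted on ratio columns.
#' @param cn_p_floor CN/P threshold for the fallback rule.
#' @param irsf_cut IRSF threshold for the fallback rule.
#' @return List of class `burn_assessment`: `label`, `confidence`,
#'   `evidence` (named values used).
#' @export
classify_state <- function(record, model = NULL, cn_p_floor = 0.02,
                           irsf_cut = 3.8) {
  key <- record$ratios[c("C/P", "PHT", "CN/P")]
  if (all(is.na(key)))
    abort_ba("C/P, PHT and CN/P all not-applicable: cannot classify",
             "indeterminate_input_error")
  if (!is.null(model)) {
    feats <- record$ratios[colnames(model$means)]
    feats[is.na(feats)] <- 0
    pr <- predict_lda(model, matrix(feats, nrow = 1,
                                    dimnames = list(NULL, colnames(model$means))))
    conf <- max(pr$posterior[1, ])
    return(structure(list(label = pr$predicted[1], confidence = conf,
                          evidence = c(record$ratios[colnames(model$means)])),
                     class = "burn_assessment"))
  }
  cn_p <- record$ratios[["CN/P"]]
  irsf <- record$ratios[["IRSF"]]
  if (!is.na(cn_p)) {
    label <- if (cn_p > cn_p_floor) "burnt" else "unburnt"
    margin <- abs(cn_p - cn_p_floor) / cn_p_floor
  } else {
    label <- if (!is.na(irsf) && irsf > irsf_cut) "burnt" else "unburnt"
    margin <- if (!is.na(irsf)) abs(irsf - irsf_cut) / irsf_cut else 0
  }
  structure(list(label = label,
                 confidence = min(1, 0.5 + margin / 2),
                 evidence = c(`CN/P` = cn_p, IRSF = irsf,
                              `C/P` = record$ratios[["C/P"]],
                              PHT = record$ratios[["PHT"]])),
            class = "burn_assessment")
}

#' Temperature banding from heat markers
#'
#' Both beta-TCP signals (1123 cm-1 peak AND 547 cm-1 shoulder) together
#' indicate > 700 degrees C; an OH-Cl band indicates > 600 degrees C
#' (chlorine substitution into the hydroxyl channel starts above that).
#' A 1123 peak without the 547 shoulder is ambiguous: it may be a shifted
#' phosphate feature rather than beta-TCP. The rule is defined for burnt
#' bone only; in unburnt bone a 547 shoulder means Mg substitution, not
#' beta-TCP.
#'
#' @param markers A `marker_report`.
#' @param state Declared state; must be `"burnt"`.
#' @return List of class `heat_assessment`: `band` (character statement),
#'   `notes` (character vector).
#' @export
assess_heat_markers <- function(markers, state) {
  if (state != "burnt")
    abort_ba("heat-marker banding applies to burnt bone only (in unburnt bone the 547 cm-1 shoulder indicates Mg substitution)",
             "rule_inapplicable_error")
  notes <- character()
  btcp <- markers$btcp_peak_1123$present
  sh547 <- markers$shoulder_547$present
  ohcl <- markers$oh_cl_peak$present
  if (btcp && sh547) {
    band <- "> 700 degrees C reached (beta-TCP: 1123 cm-1 peak + 547 cm-1 shoulder)"
  } else if (ohcl) {
    band <- "> 600 degrees C reached (OH-Cl substitution band)"
  } else {
    band <- "no high-temperature marker"
  }
  if (btcp && !sh547)
    notes <- c(notes, paste("1123 cm-1 peak present without the 547 cm-1",
                            "shoulder: ambiguous, possibly a shifted phosphate",
                            "feature rather than beta-TCP; no > 700 C claim"))
  if (markers$extra_peak_1080_1100$present)
    notes <- c(notes, "extra 1080-1100 cm-1 peak present (common in burnt bone)")
  structure(list(band = band, notes = notes), class = "heat_assessment")
}

#' Potassium-threshold inference of PMI before burning
#'
#' For a burnt specimen, compares mean elemental potassium (wt%) in the
#' inner (IC) and mid-cortical (MC) zones to the decision threshold
#' (default 0.07 +/- 0.01 wt%):
#' \itemize{
#'   \item MC potassium below its detection limit: long delay (>= 1 year).
#'   \item IC and MC both below threshold - band: delayed burn (>= ~3
#'     months surface exposure).
#'   \item IC and MC both >= 0.20 wt%: peri-mortem burn plausible (an
#'     inference from the fresh-burnt observation floor, flagged as an
#'     extension in the caveats).
#'   \item Either value inside [threshold - band, threshold + band]:
#'     borderline.
#'   \item Otherwise (including conflicting IC/MC evidence):
#'     indeterminate.
#' }
#' Outer-cortical values never drive the category (soil potassium uptake
#' can raise them); HC is reported as supporting evidence only. A
#' burial-slows-dehydration caveat is always attached.
#'
#' @param k_by_zone Named numeric vector of mean elemental K wt% per zone
#'   (needs `IC` and `MC`; `OC`/`HC` optional), or a `zone_summary` from
#'   which the specimen's K means are taken.
#' @param state Must be `"burnt"`; the rule is undefined for unburnt bone.
#' @param limits Detection limits (oxide wt%); the K2O limit is converted
#'   to elemental K internally.
#' @param threshold Decision threshold, elemental wt%.
#' @param band Borderline half-width, wt%. The headline value is +/-0.01;
#'   a +/-0.001 variant also circulates and can be set here.
#' @param fresh_floor Fresh-burnt K floor, wt%.
#' @return List of class `pmi_assessment`: `category`, `threshold`,
#'   `band`, `zone_values`, `detection_limit_K`, `caveats`, `evidence`.
#' @export
k_pmi_rule <- function(k_by_zone, state, limits = default_detection_limits(),
                       threshold = 0.07, band = 0.01, fresh_floor = 0.20) {
  if (state != "burnt")
    abort_ba("the potassium PMI rule is defined for burnt bone only",
             "rule_inapplicable_error")
  if (inherits(k_by_zone, "zone_summary")) {
    kz <- k_by_zone[k_by_zone$analyte == "K", ]
    k_by_zone <- setNames(kz$mean, kz$zone)
  }
  if (!all(c("IC", "MC") %in% names(k_by_zone)) ||
      any(is.na(k_by_zone[c("IC", "MC")])))
    abort_ba("IC and MC potassium values are required", "indeterminate_input_error")
  dl_k <- limits[["K2O"]] * oxide_conversion_factor("K2O")
  ic <- k_by_zone[["IC"]]; mc <- k_by_zone[["MC"]]
  caveats <- c(
    "burial slows dehydration: with a buried (not surface-exposed) specimen the same K level implies a longer interval",
    "OC values are not decisive: the outer cortex can take up potassium from soil")
  in_band <- function(v) v >= threshold - band & v <= threshold + band
  if (mc < dl_k) {
    category <- PMI_CATEGORIES[3]
    caveats <- c(caveats,
                 "endogenous K below detection in mid-cortical bone: depletion essentially complete before burning")
  } else if (ic < threshold - band && mc < threshold - band) {
    category <- PMI_CATEGORIES[2]
  } else if (ic >= fresh_floor && mc >= fresh_floor) {
    category <- PMI_CATEGORIES[1]
    caveats <- c(caveats,
                 sprintf("the >= %.2f wt%% fresh-burnt floor is an inference from the day-0 observation, not a stated rule", fresh_floor))
  } else if (in_band(ic) || in_band(mc)) {
    category <- PMI_CATEGORIES[4]
  } else {
    category <- PMI_CATEGORIES[5]
    if ((ic < threshold - band) != (mc < threshold - band))
      caveats <- c(caveats,
                   "conflicting IC vs MC evidence (one above, one below threshold)")
  }
  structure(list(category = category, threshold = threshold, band = band,
                 zone_values = k_by_zone, detection_limit_K = dl_k,
                 caveats = caveats,
                 evidence = list(IC = ic, MC = mc,
                                 HC = if ("HC" %in% names(k_by_zone)) k_by_zone[["HC"]] else NA_real_,
                                 OC = if ("OC" %in% names(k_by_zone)) k_by_zone[["OC"]] else NA_real_)),
            class = "pmi_assessment")
}

#' @export
print.pmi_assessment <- function(x, ...) {
  cat(sprintf("<pmi_assessment> %s\n", x$category))
  cat(sprintf("  K wt%%: %s (threshold %.3f +/- %.3f)\n",
              paste(sprintf("%s=%.3f", names(x$zone_values), x$zone_values),
                    collapse = " "), x$threshold, x$band))
  for (cv in x$caveats) cat("  caveat:", cv, "\n")
  invisible(x)
}
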