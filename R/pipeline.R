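# End-to-end orchestration: configuration, the staged pipeline and the
# collated report.

RUN_CONFIG_KEYS <- c("seed", "out_dir", "anchors", "tolerance",
                     "detection_limits", "thresholds", "stats", "design",
                     "low_total_fraction", "spectrum_noise_sd")

#' Build a run configuration
#'
#' Every under-specified default (detection limits, band centers,
#' thresholds) lives here so a run can override and echo them. Unknown
#' keys are rejected rather than ignored.
#'
#' @param ... Overrides for any of: `seed`, `out_dir`, `anchors`,
#'   `tolerance`, `detection_limits`, `thresholds` (list with
#'   `k_threshold`, `k_band`, `fresh_floor`, `cn_p_floor`, `irsf_cut`),
#'   `stats` (list with `alternative`, `p_adjust`), `design` (list with
#'   `points_per_zone`), `low_total_fraction`, `spectrum_noise_sd`.
#' @return List of class `run_config`.
#' @export
run_config <- function(...) {
  overrides <- list(...)
  unknown <- setdiff(names(overrides), RUN_CONFIG_KEYS)
  if (length(unknown))
    abort_ba(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
             "configuration_error")
  cfg <- list(
    seed = 1L,
    out_dir = NULL,
    anchors = default_anchors(),
    tolerance = 5,
    detection_limits = as.list(default_detection_limits()),
    thresholds = list(k_threshold = 0.07, k_band = 0.01, fresh_floor = 0.20,
                      cn_p_floor = 0.02, irsf_cut = 3.8),
    stats = list(alternative = "two.sided", p_adjust = "holm"),
    design = list(points_per_zone = 3L),
    low_total_fraction = 82 / 699,
    spectrum_noise_sd = 0.004
  )
  for (k in names(overrides)) {
    if (is.list(cfg[[k]]) && is.list(overrides[[k]])) {
      sub_unknown <- setdiff(names(overrides[[k]]), names(cfg[[k]]))
      if (length(sub_unknown))
        abort_ba(sprintf("unknown config key(s) under %s: %s", k,
                         paste(sub_unknown, collapse = ", ")),
                 "configuration_error")
      cfg[[k]][names(overrides[[k]])] <- overrides[[k]]
    } else {
      cfg[[k]] <- overrides[[k]]
    }
  }
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file; top-level keys must be known config keys.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path))
    abort_ba(sprintf("config file not found: %s", path), "missing_input_error")
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the staged analysis pipeline on a synthetic study
#'
#' Stages: `simulate` (generate the study bundle), `ftir` (baseline
#' correction, ratio battery and markers per spectrum), `empa`
#' (censor/QC/summarise the point table), `stats` (regression vs PMI,
#' PCA, LDA, MANOVA + MCT on both data sets), `classify` (burn state per
#' specimen and the potassium PMI rule for burnt specimens), `report`.
#' Identical config (including seed) reproduces every artifact.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory for artifacts; `NULL` for none.
#' @return List with the stage outputs (`study`, `ftir`, `empa`, `stats`,
#'   `decisions`, `report`).
#' @export
run_pipeline <- function(config = run_config(), out_dir = config$out_dir) {
  design <- default_study_design(seed = config$seed)
  design$points_per_zone <- as.integer(config$design$points_per_zone)
  trends <- make_default_trends()
  study <- simulate_study(design, trends, seed = config$seed,
                          spectrum_noise_sd = config$spectrum_noise_sd,
                          low_total_fraction = config$low_total_fraction)

  battery <- default_ratio_battery(tolerance = config$tolerance)
  corrected <- lapply(study$spectra, baseline_correct, anchors = config$anchors)
  records <- lapply(corrected, compute_ratios, battery = battery)
  markers <- lapply(corrected, detect_markers)
  ftir_df <- ratio_records_to_df(records)

  limits <- unlist(config$detection_limits)
  empa_clean <- clean_empa(study$empa, limits = limits)
  empa_elem <- oxide_to_element(empa_clean)
  empa_elem$ca_p_molar <- ca_p_molar_ratio(empa_clean)
  zone_summary <- summarize_empa(empa_elem, analytes = trend_elements())

  stats_out <- pipeline_stats(ftir_df, empa_elem, config)

  decisions <- pipeline_decisions(records, empa_elem, study$truth, config,
                                  limits)

  results <- list(config = config, study = study,
                  ftir = list(records = records, table = ftir_df,
                              markers = markers),
                  empa = list(clean = empa_clean, elemental = empa_elem,
                              summary = zone_summary,
                              qc = qc_log(empa_clean)),
                  stats = stats_out, decisions = decisions)
  if (!is.null(out_dir)) results$report <- write_report(results, out_dir)
  results
}

pipeline_stats <- function(ftir_df, empa_elem, config) {
  ratio_cols <- intersect(names(default_ratio_battery()), names(ftir_df))
  reg <- list()
  for (st in bone_states()) {
    sub <- ftir_df[ftir_df$state == st, ]
    for (rc in ratio_cols) {
      y <- sub[[rc]]
      if (sum(is.finite(y)) < 3) next
      reg[[sprintf("%s|%s", st, rc)]] <-
        regress_vs_pmi(sub$pmi_days, y,
                       alternative = config$stats$alternative)
    }
  }
  reg_table <- do.call(rbind, lapply(names(reg), function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    data.frame(state = parts[1], parameter = parts[2],
               slope = reg[[k]]$slope, r = reg[[k]]$r, p = reg[[k]]$p,
               n = reg[[k]]$n)
  }))

  ftir_mat <- as.matrix(ftir_df[ratio_cols])
  ftir_mat[is.na(ftir_mat)] <- 0
  elem_cols <- intersect(trend_elements(), names(empa_elem))
  empa_mat <- as.matrix(empa_elem[elem_cols])

  ftir_scaled <- suppressWarnings(zscore_scale(ftir_mat))
  empa_scaled <- suppressWarnings(zscore_scale(empa_mat))

  list(
    regression = reg_table,
    pca_ftir = pca_scaled(ftir_scaled, scale. = FALSE),
    pca_empa = pca_scaled(empa_scaled, scale. = FALSE),
    lda_state_ftir = lda_fit(ftir_scaled, ftir_df$state),
    lda_state_empa = lda_fit(empa_scaled, empa_elem$state),
    lda_pmi_ftir = lda_fit(ftir_scaled, ftir_df$pmi_days),
    manova_ftir = manova_with_mct(ftir_scaled, ftir_df$pmi_days,
                                  p_adjust = config$stats$p_adjust),
    manova_empa = manova_with_mct(empa_scaled, empa_elem$pmi_days,
                                  p_adjust = config$stats$p_adjust)
  )
}

pipeline_decisions <- function(records, empa_elem, truth, config, limits) {
  th <- config$thresholds
  burn <- lapply(records, classify_state, cn_p_floor = th$cn_p_floor,
                 irsf_cut = th$irsf_cut)
  burn_labels <- vapply(burn, `[[`, "", "label")
  truth_states <- truth$state[match(names(burn), truth$sample_id)]
  state_accuracy <- mean(burn_labels == truth_states)

  pmi <- list()
  burnt_ids <- unique(empa_elem$sample_id[empa_elem$state == "burnt"])
  for (sid in burnt_ids) {
    sub <- empa_elem[empa_elem$sample_id == sid, ]
    kz <- tapply(sub$K, sub$zone, mean)
    if (!all(c("IC", "MC") %in% names(kz))) next
    pmi[[sid]] <- k_pmi_rule(kz, "burnt", limits = limits,
                             threshold = th$k_threshold, band = th$k_band,
                             fresh_floor = th$fresh_floor)
  }
  list(burn = burn, state_accuracy = state_accuracy, pmi = pmi)
}

#' Write the collated report
#'
#' Emits `report.json` (machine-readable: regression table, PCA variance,
#' LDA accuracies, MANOVA results, decision outcomes with caveats, QC
#' counts, config echo) and `report.md` (the same, human-readable).
#' Serialization is deterministic: unchanged results give byte-identical
#' files.
#'
#' @param results Output of [run_pipeline()] (any subset of stages).
#' @param out_dir Directory to write into (created if needed).
#' @return Invisibly, the parsed report list.
#' @export
write_report <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rep <- list(config = unclass(results$config))
  if (!is.null(results$ftir))
    rep$ftir <- list(n_spectra = nrow(results$ftir$table),
                     ratio_means_by_group = aggregate_ratios(results$ftir$table))
  if (!is.null(results$empa))
    rep$empa <- list(n_retained = nrow(results$empa$clean),
                     n_removed = nrow(results$empa$qc),
                     summary = results$empa$summary)
  if (!is.null(results$stats))
    rep$stats <- list(
      regression = results$stats$regression,
      pca_ftir_explained = results$stats$pca_ftir$explained,
      pca_empa_explained = results$stats$pca_empa$explained,
      lda_state_accuracy_ftir = results$stats$lda_state_ftir$accuracy,
      lda_state_accuracy_empa = results$stats$lda_state_empa$accuracy,
      lda_pmi_accuracy_ftir = results$stats$lda_pmi_ftir$accuracy,
      manova_ftir = results$stats$manova_ftir[c("wilks_lambda", "p")],
      manova_empa = results$stats$manova_empa[c("wilks_lambda", "p")])
  if (!is.null(results$decisions))
    rep$decisions <- list(
      state_accuracy = results$decisions$state_accuracy,
      pmi = lapply(results$decisions$pmi, function(a)
        list(category = a$category, zone_values = as.list(a$zone_values),
             threshold = a$threshold, band = a$band, caveats = a$caveats)))
  if (!length(setdiff(names(rep), "config")))
    abort_ba("no stage outputs to report", "missing_input_error")
  jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  writeLines(render_report_md(rep), file.path(out_dir, "report.md"))
  invisible(rep)
}

aggregate_ratios <- function(ftir_df) {
  ratio_cols <- setdiff(names(ftir_df), c("sample_id", "state", "pmi_days"))
  stats::aggregate(ftir_df[ratio_cols],
                   by = ftir_df[c("state", "pmi_days")],
                   FUN = function(v) mean(v, na.rm = TRUE))
}

render_report_md <- function(rep) {
  out <- c("# Bioapatite pipeline report", "")
  if (!is.null(rep$ftir)) {
    out <- c(out, "## FT-IR ratios (group means)", "",
             utils::capture.output(print(rep$ftir$ratio_means_by_group,
                                         digits = 4)), "")
  }
  if (!is.null(rep$empa)) {
    out <- c(out, "## EMPA",
             sprintf("- points retained: %d, removed by QC: %d",
                     rep$empa$n_retained, rep$empa$n_removed), "")
  }
  if (!is.null(rep$stats)) {
    out <- c(out, "## Statistics", "",
             sprintf("- FT-IR PCA PC1/PC2 explained: %.2f%% / %.2f%%",
                     rep$stats$pca_ftir_explained[1],
                     rep$stats$pca_ftir_explained[2]),
             sprintf("- EMPA PCA PC1/PC2 explained: %.2f%% / %.2f%%",
                     rep$stats$pca_empa_explained[1],
                     rep$stats$pca_empa_explained[2]),
             sprintf("- LDA state accuracy (FT-IR / EMPA): %.3f / %.3f",
                     rep$stats$lda_state_accuracy_ftir,
                     rep$stats$lda_state_accuracy_empa),
             sprintf("- MANOVA vs PMI: FT-IR Wilks %.4f (p=%.3g), EMPA Wilks %.4f (p=%.3g)",
                     rep$stats$manova_ftir$wilks_lambda, rep$stats$manova_ftir$p,
                     rep$stats$manova_empa$wilks_lambda, rep$stats$manova_empa$p),
             "", "### Regression vs PMI", "",
             utils::capture.output(print(rep$stats$regression, digits = 3)), "")
  }
  if (!is.null(rep$decisions)) {
    out <- c(out, "## Decisions",
             sprintf("- burnt/unburnt agreement with truth: %.3f",
                     rep$decisions$state_accuracy),
             "", "### Potassium PMI rule (burnt specimens)", "")
    for (sid in names(rep$decisions$pmi))
      out <- c(out, sprintf("- %s: %s", sid, rep$decisions$pmi[[sid]]$category))
  }
  out
}
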