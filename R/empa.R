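# EMPA point tables: ingestion, detection-limit censoring, QC filtering
# and zonal summaries.

EMPA_SCHEMA <- function() c("sample_id", "state", "pmi_days", "zone",
                            empa_analytes(), "total")

#' Construct an EMPA table
#'
#' @param df Data frame matching the documented schema: `sample_id`,
#'   `state`, `pmi_days`, `zone`, one column per oxide analyte, `total`.
#' @param qc_log Data frame of removed points with reasons (maintained by
#'   [clean_empa()]).
#' @return Object of class `empa_table` (a data frame).
#' @export
empa_table <- function(df, qc_log = NULL) {
  missing <- setdiff(EMPA_SCHEMA(), names(df))
  if (length(missing))
    abort_ba(sprintf("EMPA table missing column(s): %s",
                     paste(missing, collapse = ", ")), "format_error")
  bad_zone <- setdiff(unique(df$zone), empa_zones())
  if (length(bad_zone))
    abort_ba(sprintf("unknown zone code(s): %s", paste(bad_zone, collapse = ", ")),
             "format_error")
  for (a in empa_analytes()) {
    if (any(is.na(df[[a]])))
      abort_ba(sprintf("missing values in analyte column %s", a), "format_error")
    if (any(df[[a]] < 0))
      abort_ba(sprintf("negative wt%% in analyte column %s", a), "format_error")
  }
  df <- as.data.frame(df)[, EMPA_SCHEMA()]
  attr(df, "qc_log") <- qc_log %||% data.frame(sample_id = character(),
                                               zone = character(),
                                               reason = character(),
                                               total = numeric())
  class(df) <- c("empa_table", "data.frame")
  df
}

#' QC log of an EMPA table
#' @param table An `empa_table`.
#' @return Data frame of removed points and reasons.
#' @export
qc_log <- function(table) attr(table, "qc_log")

#' Read an EMPA CSV
#'
#' Expects the documented header
#' `sample_id,state,pmi_days,zone,P2O5,...,MnO,total`. Unknown zone codes
#' and missing analyte cells are rejected, never silently zeroed.
#'
#' @param source Path to a CSV file.
#' @return An `empa_table`.
#' @export
read_empa_csv <- function(source) {
  df <- utils::read.csv(source, stringsAsFactors = FALSE)
  missing <- setdiff(EMPA_SCHEMA(), names(df))
  if (length(missing))
    abort_ba(sprintf("EMPA CSV %s lacks column(s): %s", source,
                     paste(missing, collapse = ", ")), "format_error")
  empa_table(df)
}

#' Write an EMPA table to CSV
#' @param table An `empa_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_empa_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Default per-analyte detection limits (wt\%)
#'
#' Conservative placeholder values for wavelength-dispersive microprobe
#' work on apatite: 0.01 wt% for the trace oxides and 0.05 wt% for the
#' majors. Instrument-specific limits should replace these via the
#' `detection_limits` config entry when available.
#'
#' @return Named numeric vector over the analyte columns.
#' @export
default_detection_limits <- function() {
  dl <- setNames(rep(0.01, length(empa_analytes())), empa_analytes())
  dl[c("CaO", "P2O5")] <- 0.05
  dl
}

#' Censor below-detection values and remove low-total points
#'
#' Two rules, applied in order: (i) analyte values strictly below their
#' detection limit are set to exactly 0.00 and flagged; (ii) points whose
#' original analytical total is below 50 wt% are removed and logged (the
#' sum of elements is then less than plausible for bone, indicating a
#' mislocated beam). The filter uses the total as measured, before
#' censoring changes it.
#'
#' @param table An `empa_table`.
#' @param limits Named numeric vector of detection limits covering every
#'   analyte; see [default_detection_limits()].
#' @param total_floor QC threshold on the analytical total, wt%.
#' @return A cleaned `empa_table`; removed points are in [qc_log()], and a
#'   logical matrix attribute `"below_dl"` marks censored cells.
#' @export
clean_empa <- function(table, limits = default_detection_limits(),
                       total_floor = 50) {
  missing <- setdiff(empa_analytes(), names(limits))
  if (length(missing))
    abort_ba(sprintf("detection limits missing for: %s",
                     paste(missing, collapse = ", ")), "configuration_error")
  if (any(limits[empa_analytes()] <= 0))
    abort_ba("detection limits must be > 0", "configuration_error")
  df <- as.data.frame(table)
  below <- matrix(FALSE, nrow(df), length(empa_analytes()),
                  dimnames = list(NULL, empa_analytes()))
  for (a in empa_analytes()) {
    below[, a] <- df[[a]] < limits[[a]]
    df[[a]][below[, a]] <- 0
  }
  keep <- df$total >= total_floor
  removed <- df[!keep, , drop = FALSE]
  log <- data.frame(sample_id = removed$sample_id, zone = removed$zone,
                    reason = sprintf("total %.2f wt%% < %g wt%%",
                                     removed$total, total_floor),
                    total = removed$total)
  out <- empa_table(df[keep, , drop = FALSE],
                    qc_log = rbind(qc_log(table), log))
  attr(out, "below_dl") <- below[keep, , drop = FALSE]
  out
}

#' Zonal summary statistics
#'
#' Per (analyte x grouping cell): n, mean, twice the standard error
#' (SE = SD/sqrt(n), SD with the n-1 denominator) and the coefficient of
#' variation (SD/mean). Cells with n = 1 report `NA` for 2SE and CV; a
#' zero mean reports `NA` CV.
#'
#' @param table A cleaned `empa_table` (or any data frame with the analyte
#'   columns).
#' @param group_keys Character vector of grouping columns, default
#'   `c("state", "pmi_days", "zone")`.
#' @param analytes Columns to summarise; defaults to every analyte present.
#' @return Long-format data frame of class `zone_summary` with columns
#'   `analyte`, the group keys, `n`, `mean`, `se2`, `cv`.
#' @export
summarize_empa <- function(table, group_keys = c("state", "pmi_days", "zone"),
                           analytes = NULL) {
  df <- as.data.frame(table)
  if (nrow(df) == 0L) {
    out <- data.frame(analyte = character())
    class(out) <- c("zone_summary", "data.frame")
    return(out)
  }
  analytes <- analytes %||% intersect(c(empa_analytes(), trend_elements()),
                                      names(df))
  key <- interaction(df[group_keys], drop = TRUE, lex.order = TRUE)
  cells <- split(seq_len(nrow(df)), key)
  rows <- lapply(cells, function(idx) {
    head_row <- df[idx[1], group_keys, drop = FALSE]
    do.call(rbind, lapply(analytes, function(a) {
      v <- df[[a]][idx]
      n <- length(v)
      m <- mean(v)
      s <- if (n > 1) stats::sd(v) else NA_real_
      cbind(data.frame(analyte = a), head_row,
            data.frame(n = n, mean = m,
                       se2 = if (n > 1) 2 * s / sqrt(n) else NA_real_,
                       cv = if (n > 1 && m > 0) s / m else NA_real_))
    }))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("zone_summary", "data.frame")
  out
}
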