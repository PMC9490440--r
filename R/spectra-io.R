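# Spectrum I/O: two-column CSV and a minimal JCAMP-DX (XYDATA) dialect.

parse_meta_comments <- function(lines) {
  meta <- list()
  for (ln in grep("^#", lines, value = TRUE)) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*[:=]\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  meta
}

#' Read a spectrum from CSV or minimal JCAMP-DX
#'
#' CSV input is two numeric columns (wavenumber cm-1, absorbance), with an
#' optional header row and optional `# key: value` comment lines carrying
#' metadata (`sample_id`, `state`, `pmi_days`). JCAMP input is the
#' `##XYDATA=(XY..XY)` form. Wavenumbers are sorted ascending and duplicate
#' wavenumbers collapsed by mean.
#'
#' @param source Path to a file, or a character vector of lines.
#' @param format `"csv"` or `"jcamp"`; guessed from the file extension when
#'   omitted.
#' @return An `ftir_spectrum`.
#' @export
read_spectrum <- function(source, format = NULL) {
  lines <- if (length(source) == 1L && file.exists(source))
    readLines(source, warn = FALSE) else as.character(source)
  if (length(lines) == 0L || all(!nzchar(trimws(lines))))
    abort_ba("empty spectrum input", "empty_input_error")
  if (is.null(format)) {
    format <- if (any(grepl("^##", lines))) "jcamp" else "csv"
  }
  switch(format,
         csv = read_spectrum_csv_lines(lines),
         jcamp = read_spectrum_jcamp_lines(lines),
         abort_ba(sprintf("unknown spectrum format '%s'", format), "format_error"))
}

read_spectrum_csv_lines <- function(lines) {
  meta <- parse_meta_comments(lines)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (!length(keep)) abort_ba("no data rows in spectrum input", "empty_input_error")
  first <- strsplit(trimws(lines[keep[1]]), "[,;\t]")[[1]]
  has_header <- suppressWarnings(any(is.na(as.numeric(first))))
  data_idx <- if (has_header) keep[-1] else keep
  if (!length(data_idx)) abort_ba("no data rows in spectrum input", "empty_input_error")
  wn <- numeric(length(data_idx)); ab <- numeric(length(data_idx))
  for (i in seq_along(data_idx)) {
    parts <- strsplit(trimws(lines[data_idx[i]]), "[,;\t]")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) < 2 || any(is.na(vals[1:2])))
      abort_ba(sprintf("unparseable spectrum line %d: '%s'", data_idx[i],
                       lines[data_idx[i]]), "format_error")
    wn[i] <- vals[1]; ab[i] <- vals[2]
  }
  ftir_spectrum(wn, ab,
                sample_id = meta$sample_id %||% NA_character_,
                state = meta$state %||% "unknown",
                pmi_days = as.numeric(meta$pmi_days %||% NA))
}

read_spectrum_jcamp_lines <- function(lines) {
  start <- grep("^##XYDATA", lines)
  if (!length(start)) abort_ba("no ##XYDATA block found", "format_error")
  end <- grep("^##END", lines)
  end <- if (length(end)) end[end > start[1]][1] else length(lines) + 1L
  body <- lines[(start[1] + 1L):(end - 1L)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) abort_ba("empty ##XYDATA block", "empty_input_error")
  title <- sub("^##TITLE=\\s*", "", grep("^##TITLE=", lines, value = TRUE))
  pairs <- do.call(rbind, lapply(seq_along(body), function(i) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "[,;\\s]+")[[1]]))
    if (length(vals) < 2 || any(is.na(vals)))
      abort_ba(sprintf("unparseable XYDATA line %d: '%s'", start[1] + i, body[i]),
               "format_error")
    matrix(vals, ncol = 2, byrow = TRUE)
  }))
  ftir_spectrum(pairs[, 1], pairs[, 2],
                sample_id = if (length(title)) title[1] else NA_character_)
}

#' Write a spectrum as two-column CSV
#'
#' Emits `# key: value` metadata comments, the
#' `wavenumber_cm-1,absorbance` header, then one row per point in
#' descending wavenumber (instrument scan order).
#'
#' @param spectrum An `ftir_spectrum`.
#' @param path Output path.
#' @param digits Significant digits written.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path, digits = 10) {
  o <- order(spectrum$wavenumbers, decreasing = TRUE)
  meta <- c(
    if (!is.na(spectrum$sample_id)) sprintf("# sample_id: %s", spectrum$sample_id),
    sprintf("# state: %s", spectrum$state),
    if (!is.na(spectrum$pmi_days)) sprintf("# pmi_days: %g", spectrum$pmi_days)
  )
  writeLines(c(meta, "wavenumber_cm-1,absorbance",
               sprintf("%.10g,%s", spectrum$wavenumbers[o],
                       formatC(spectrum$absorbance[o], digits = digits,
                               format = "g"))),
             path)
  invisible(path)
}

#' Write a spectrum as minimal JCAMP-DX
#'
#' `(XY..XY)` XYDATA form, one x,y pair per line.
#'
#' @inheritParams write_spectrum_csv
#' @return `path`, invisibly.
#' @export
write_spectrum_jcamp <- function(spectrum, path, digits = 10) {
  o <- order(spectrum$wavenumbers, decreasing = TRUE)
  writeLines(c(
    sprintf("##TITLE=%s", spectrum$sample_id %||% ""),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=INFRARED SPECTRUM",
    "##XUNITS=1/CM",
    "##YUNITS=ABSORBANCE",
    sprintf("##NPOINTS=%d", length(spectrum$wavenumbers)),
    "##XYDATA=(XY..XY)",
    sprintf("%.10g, %s", spectrum$wavenumbers[o],
            formatC(spectrum$absorbance[o], digits = digits, format = "g")),
    "##END="), path)
  invisible(path)
}
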