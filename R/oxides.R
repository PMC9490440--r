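# Oxide <-> element conversions for WDS-EMPA analytes.
#
# Microprobe software reports cations as oxide weight percent; the
# interpretive thresholds in this package (notably the potassium rule) are
# stated in elemental wt%, so both directions are needed.

# 2021 IUPAC standard atomic weights (conventional values)
ATOMIC_MASS <- c(
  Ca = 40.078, P = 30.973762, K = 39.0983, Na = 22.98977, Mg = 24.305,
  Al = 26.981538, Si = 28.0855, Sr = 87.62, Fe = 55.845, Mn = 54.938045,
  O = 15.999, Cl = 35.453
)

# oxide column -> (element, cations per formula unit)
OXIDE_INFO <- list(
  P2O5  = list(element = "P",  n_cat = 2L, n_o = 5L),
  Al2O3 = list(element = "Al", n_cat = 2L, n_o = 3L),
  Na2O  = list(element = "Na", n_cat = 2L, n_o = 1L),
  SiO2  = list(element = "Si", n_cat = 1L, n_o = 2L),
  K2O   = list(element = "K",  n_cat = 2L, n_o = 1L),
  CaO   = list(element = "Ca", n_cat = 1L, n_o = 1L),
  Cl    = list(element = "Cl", n_cat = 1L, n_o = 0L),
  MgO   = list(element = "Mg", n_cat = 1L, n_o = 1L),
  SrO   = list(element = "Sr", n_cat = 1L, n_o = 1L),
  FeO   = list(element = "Fe", n_cat = 1L, n_o = 1L),
  MnO   = list(element = "Mn", n_cat = 1L, n_o = 1L)
)

#' Analyte (oxide) columns of an EMPA table
#' @return Character vector of the eleven oxide column names.
#' @export
empa_analytes <- function() names(OXIDE_INFO)

oxide_molar_mass <- function(oxide) {
  info <- OXIDE_INFO[[oxide]]
  if (is.null(info)) abort_ba(sprintf("unknown oxide '%s'", oxide), "configuration_error")
  info$n_cat * ATOMIC_MASS[[info$element]] + info$n_o * ATOMIC_MASS[["O"]]
}

#' Gravimetric conversion factor from oxide to element
#'
#' @param oxide Oxide column name, e.g. `"CaO"`; `"Cl"` passes through with
#'   factor 1.
#' @return Fraction of the oxide mass carried by the cation.
#' @examples
#' oxide_conversion_factor("CaO")  # 0.7147
#' @export
oxide_conversion_factor <- function(oxide) {
  info <- OXIDE_INFO[[oxide]]
  if (is.null(info)) abort_ba(sprintf("unknown oxide '%s'", oxide), "configuration_error")
  if (info$n_o == 0L) return(1)
  info$n_cat * ATOMIC_MASS[[info$element]] / oxide_molar_mass(oxide)
}

#' Convert EMPA oxide wt\% to elemental wt\%
#'
#' Applies the standard gravimetric factors (e.g. CaO -> Ca multiplies by
#' 40.078/56.077). Chlorine is measured as the element and passes through
#' unchanged. Columns other than the analytes (ids, zone, total, ...) are
#' preserved; converted columns are renamed to the element symbol.
#'
#' @param x An `empa_table` or a data frame with the oxide analyte columns.
#' @return Same shape with elemental wt\% columns named by element symbol.
#' @export
oxide_to_element <- function(x) {
  df <- as.data.frame(x)
  for (ox in empa_analytes()) {
    if (!ox %in% names(df)) next
    info <- OXIDE_INFO[[ox]]
    df[[ox]] <- df[[ox]] * oxide_conversion_factor(ox)
    names(df)[names(df) == ox] <- info$element
  }
  df
}

#' Invert [oxide_to_element()]
#'
#' @param x Data frame with elemental wt\% columns named by element symbol.
#' @return Data frame with oxide columns restored.
#' @export
element_to_oxide <- function(x) {
  df <- as.data.frame(x)
  for (ox in empa_analytes()) {
    el <- OXIDE_INFO[[ox]]$element
    if (!el %in% names(df)) next
    df[[el]] <- df[[el]] / oxide_conversion_factor(ox)
    names(df)[names(df) == el] <- ox
  }
  df
}

#' Ca/P molar ratio from oxide wt\%
#'
#' Computes (mol Ca)/(mol P) from CaO and P2O5 weight percent:
#' (CaO/M_CaO) / (2 P2O5/M_P2O5). Stoichiometric hydroxyapatite
#' Ca10(PO4)6(OH)2 gives 5/3 = 1.67. A zero P2O5 yields `NA` with a
#' warning rather than an infinity.
#'
#' @param x Data frame (or `empa_table`) with `CaO` and `P2O5` columns, or a
#'   numeric vector `c(CaO = ..., P2O5 = ...)`.
#' @return Numeric vector of molar ratios, one per row/point.
#' @export
ca_p_molar_ratio <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) x <- as.data.frame(as.list(x))
  df <- as.data.frame(x)
  if (!all(c("CaO", "P2O5") %in% names(df)))
    abort_ba("ca_p_molar_ratio needs CaO and P2O5 columns", "configuration_error")
  mol_ca <- df$CaO / oxide_molar_mass("CaO")
  mol_p <- 2 * df$P2O5 / oxide_molar_mass("P2O5")
  out <- ifelse(mol_p == 0 & df$CaO == 0, 0, mol_ca / mol_p)
  if (any(mol_p == 0 & df$CaO > 0)) {
    warning("P2O5 = 0 with nonzero CaO: Ca/P molar ratio not applicable (NA)")
    out[mol_p == 0 & df$CaO > 0] <- NA_real_
  }
  out
}

#' Oxide wt\% of stoichiometric hydroxyapatite
#'
#' The CaO and P2O5 weight fractions implied by Ca10(PO4)6(OH)2, used as the
#' analytic check of the oxide-to-molar pipeline.
#'
#' @return Named numeric vector with `CaO` and `P2O5` in wt\%.
#' @export
hydroxyapatite_reference <- function() {
  m_ca <- ATOMIC_MASS[["Ca"]]; m_p <- ATOMIC_MASS[["P"]]
  m_o <- ATOMIC_MASS[["O"]]; m_h <- 1.008
  m_hap <- 10 * m_ca + 6 * (m_p + 4 * m_o) + 2 * (m_o + m_h)
  c(CaO = 10 * oxide_molar_mass("CaO") / m_hap * 100,
    P2O5 = 3 * oxide_molar_mass("P2O5") / m_hap * 100)
}
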