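# Synthetic-data generator: forward models for the FT-IR and EMPA inputs.
#
# The generator exists so every downstream stage is testable without the
# original specimen data: group trajectories follow the calibrated trend
# model and all randomness is controlled by explicit seeds.

#' Describe a study design
#'
#' @param groups Data frame with columns `state`, `pmi_days`,
#'   `n_specimens`.
#' @param points_per_zone EMPA points measured per zone per specimen.
#' @param grid Wavenumber grid as `c(start, stop, step)` in cm-1; start >
#'   stop (instrument convention is a descending scan).
#' @param seed Master seed (integer).
#' @return Object of class `study_design`.
#' @export
study_design <- function(groups, points_per_zone = 3L,
                         grid = c(4000, 400, 1), seed = 1L) {
  if (!all(c("state", "pmi_days", "n_specimens") %in% names(groups)))
    abort_ba("groups needs state, pmi_days, n_specimens columns", "invalid_design_error")
  if (!all(groups$state %in% bone_states()))
    abort_ba("unknown state in design", "invalid_design_error")
  if (any(groups$n_specimens < 1))
    abort_ba("n_specimens must be >= 1", "invalid_design_error")
  if (grid[1] <= grid[2] || grid[3] <= 0)
    abort_ba("grid must be c(start, stop, step) with start > stop, step > 0",
             "invalid_design_error")
  if (grid[1] > 4000 || grid[2] < 400)
    abort_ba("grid must lie within [400, 4000] cm-1", "invalid_design_error")
  if (points_per_zone < 1)
    abort_ba("points_per_zone must be >= 1", "invalid_design_error")
  structure(list(groups = as.data.frame(groups),
                 points_per_zone = as.integer(points_per_zone),
                 grid = grid, seed = as.integer(seed)),
            class = "study_design")
}

#' The default (study-shaped) design
#'
#' Fresh controls (n = 10) plus exposure groups at 14, 34, 91 and 180 days
#' (n = 5 each) and 365 days (n = 2), in both unburnt and burnt state:
#' 32 specimens per state.
#'
#' @param seed Master seed.
#' @return A `study_design`.
#' @export
default_study_design <- function(seed = 1L) {
  g <- expand.grid(state = bone_states(),
                   pmi_days = PMI_ANCHOR_DAYS, stringsAsFactors = FALSE)
  g$n_specimens <- rep(c(10L, 5L, 5L, 5L, 5L, 2L), each = 2L)
  study_design(g, seed = seed)
}

grid_wavenumbers <- function(grid) {
  # internal representation is ascending; writers honour the scan order
  seq(grid[2], grid[1], by = grid[3])
}

gaussian_profile <- function(wn, center, width, amplitude) {
  amplitude * exp(-(wn - center)^2 / (2 * width^2))
}

#' Simulate one ATR FT-IR spectrum
#'
#' Absorbance is the sum of Gaussian band profiles plus a polynomial
#' baseline plus i.i.d. Gaussian noise.
#'
#' @param bands A `band_spec` (see [default_bands()]).
#' @param state Declared state stored in the spectrum metadata.
#' @param pmi_days PMI label stored in the metadata.
#' @param grid Wavenumber grid `c(start, stop, step)`.
#' @param baseline_coef Polynomial coefficients (intercept first) evaluated
#'   on the wavenumber axis and added to the trace.
#' @param noise_sd SD of additive absorbance noise; >= 0.
#' @param sample_id Identifier stored in the metadata.
#' @param seed Optional integer; when given, the draw is reproducible.
#' @return An `ftir_spectrum` (not baseline-corrected).
#' @export
simulate_spectrum <- function(bands, state = "unknown", pmi_days = NA_real_,
                              grid = c(4000, 400, 1),
                              baseline_coef = c(0.02, 2e-6), noise_sd = 0.004,
                              sample_id = NA_character_, seed = NULL) {
  if (grid[1] > 4000 || grid[2] < 400 || grid[1] <= grid[2])
    abort_ba("grid must lie within [400, 4000] cm-1, start > stop",
             "invalid_design_error")
  if (noise_sd < 0) abort_ba("noise_sd must be >= 0", "invalid_design_error")
  if (!is.null(seed)) set.seed(seed)
  wn <- grid_wavenumbers(grid)
  absorb <- rep(0, length(wn))
  for (i in seq_len(nrow(bands)))
    absorb <- absorb + gaussian_profile(wn, bands$center[i], bands$width[i],
                                        bands$amplitude[i])
  baseline <- rep(0, length(wn))
  for (k in seq_along(baseline_coef))
    baseline <- baseline + baseline_coef[k] * wn^(k - 1)
  absorb <- absorb + baseline
  if (noise_sd > 0) absorb <- absorb + stats::rnorm(length(wn), 0, noise_sd)
  ftir_spectrum(wn, absorb, sample_id = sample_id, state = state,
                pmi_days = pmi_days)
}

#' Simulate a zonal EMPA point table
#'
#' Each point draws elemental wt% per analyte from the trend mean plus
#' Gaussian noise (truncated at 0), converted to oxide wt% for emission. A
#' configurable fraction of points is rescaled to an analytical total below
#' 50 wt%, emulating mislocated beam spots, so the downstream QC filter has
#' something to remove. Censoring at detection limits is deliberately NOT
#' applied here; that is [clean_empa()]'s job.
#'
#' @param design A `study_design`.
#' @param trends A `trend_model`.
#' @param seed Integer seed (defaults to the design's master seed).
#' @param low_total_fraction Probability that a point is emitted with total
#'   < 50 wt%. The default reproduces the study's removal rate (82 of 699
#'   points).
#' @return An `empa_table` with one row per point.
#' @export
simulate_empa_table <- function(design, trends = make_default_trends(),
                                seed = design$seed,
                                low_total_fraction = 82 / 699) {
  set.seed(seed)
  groups <- design$groups
  rows <- vector("list", 0L)
  elements <- trend_elements()
  for (g in seq_len(nrow(groups))) {
    state <- groups$state[g]
    pmi <- groups$pmi_days[g]
    for (s in seq_len(groups$n_specimens[g])) {
      sid <- sprintf("%s-%03d-%02d", toupper(substr(state, 1, 1)), pmi, s)
      for (zone in empa_zones()) {
        zmult <- c(OC = 1.6, MC = 0.95, IC = 1.05, HC = 1.25)[[zone]]
        for (p in seq_len(design$points_per_zone)) {
          vals <- vapply(elements, function(el) {
            mu <- trend_value(trends, el, state, zone, pmi)
            max(0, stats::rnorm(1, mu, zmult * trends$noise_sd[[el]]))
          }, numeric(1))
          rows[[length(rows) + 1L]] <-
            c(list(sample_id = sid, state = state, pmi_days = pmi, zone = zone),
              as.list(vals))
        }
      }
    }
  }
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  ox <- element_to_oxide(df)
  ox$total <- rowSums(ox[, empa_analytes()])
  # degrade a random subset to sub-50% totals (beam-placement failures)
  low <- stats::runif(nrow(ox)) < low_total_fraction
  if (any(low)) {
    target <- stats::runif(sum(low), 25, 49.5)
    f <- target / ox$total[low]
    ox[low, empa_analytes()] <- ox[low, empa_analytes()] * f
    ox$total[low] <- rowSums(ox[low, empa_analytes(), drop = FALSE])
  }
  empa_table(ox)
}

#' Simulate a complete study bundle
#'
#' One spectrum and one set of zonal EMPA points per specimen, with truth
#' labels. Deterministic under the seed: identical (design, trends, seed)
#' give bit-identical output.
#'
#' @param design A `study_design`.
#' @param trends A `trend_model`.
#' @param seed Integer; defaults to the design's master seed.
#' @param spectrum_noise_sd Absorbance noise SD for the spectra.
#' @param low_total_fraction Passed to [simulate_empa_table()].
#' @return List with elements `spectra` (named list of `ftir_spectrum`),
#'   `empa` (an `empa_table`) and `truth` (data frame of labels).
#' @export
simulate_study <- function(design = default_study_design(),
                           trends = make_default_trends(),
                           seed = design$seed, spectrum_noise_sd = 0.004,
                           low_total_fraction = 82 / 699) {
  groups <- design$groups
  spectra <- list()
  truth <- list()
  set.seed(seed)
  spec_seeds <- sample.int(2^31 - 2, sum(groups$n_specimens) + 1L)
  idx <- 0L
  for (g in seq_len(nrow(groups))) {
    state <- groups$state[g]
    pmi <- groups$pmi_days[g]
    bands <- default_bands(state, pmi, trends)
    for (s in seq_len(groups$n_specimens[g])) {
      idx <- idx + 1L
      sid <- sprintf("%s-%03d-%02d", toupper(substr(state, 1, 1)), pmi, s)
      spectra[[sid]] <- simulate_spectrum(
        bands, state = state, pmi_days = pmi, grid = design$grid,
        noise_sd = spectrum_noise_sd, sample_id = sid, seed = spec_seeds[idx])
      truth[[sid]] <- data.frame(sample_id = sid, state = state,
                                 pmi_days = pmi)
    }
  }
  empa <- simulate_empa_table(design, trends, seed = spec_seeds[idx + 1L],
                              low_total_fraction = low_total_fraction)
  list(spectra = spectra, empa = empa,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}
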