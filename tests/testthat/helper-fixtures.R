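# Shared fixtures, built in code.

# single Gaussian band on the default grid, no baseline, no noise
gaussian_spectrum <- function(center = 1035, amp = 1, sigma = 10,
                              state = "unknown") {
  simulate_spectrum(band_spec(center, sigma, amp), state = state,
                    baseline_coef = 0, noise_sd = 0)
}

# minimal valid EMPA data frame with overridable analytes
toy_empa_df <- function(n = 1, ...) {
  base <- list(P2O5 = 37, Al2O3 = 0.1, Na2O = 0.6, SiO2 = 0.17, K2O = 0.19,
               CaO = 37, Cl = 0.2, MgO = 0.17, SrO = 0.05, FeO = 0.05,
               MnO = 0.01)
  over <- list(...)
  base[names(over)] <- over
  df <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                   state = rep("burnt", n), pmi_days = rep(0, n),
                   zone = rep("MC", n))
  for (a in names(base)) df[[a]] <- rep_len(base[[a]], n)
  df$total <- rowSums(df[empa_analytes()])
  df
}

# a cached default-study pipeline run shared across test files
.pipeline_cache <- new.env(parent = emptyenv())
cached_pipeline <- function(seed = 101) {
  key <- as.character(seed)
  if (is.null(.pipeline_cache[[key]]))
    .pipeline_cache[[key]] <- run_pipeline(run_config(seed = seed))
  .pipeline_cache[[key]]
}
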