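# Spectrum I/O, baseline correction, feature extraction, the ratio battery
# and marker detection.

test_that("CSV spectra parse, collapse duplicates, and round-trip", {
  sp <- read_spectrum(c("1035,1.0", "1036,0.9"), format = "csv")
  expect_length(sp$wavenumbers, 2)
  expect_equal(sp$absorbance, c(1.0, 0.9))

  dup <- read_spectrum(c("1035,1.0", "1035,0.8", "1040,0.5"), format = "csv")
  expect_length(dup$wavenumbers, 2)
  expect_equal(dup$absorbance[dup$wavenumbers == 1035], 0.9)

  sim <- simulate_spectrum(default_bands("burnt", 14), state = "burnt",
                           pmi_days = 14, sample_id = "B-014-01",
                           noise_sd = 0.004, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(sim, path)
  back <- read_spectrum(path)
  expect_equal(back$wavenumbers, sim$wavenumbers)
  expect_equal(back$absorbance, sim$absorbance, tolerance = 1e-8)
  expect_equal(back$sample_id, "B-014-01")
  expect_equal(back$state, "burnt")
  expect_equal(back$pmi_days, 14)

  jpath <- withr::local_tempfile(fileext = ".jdx")
  write_spectrum_jcamp(sim, jpath)
  jback <- read_spectrum(jpath)
  expect_equal(jback$absorbance, sim$absorbance, tolerance = 1e-8)
})

test_that("malformed spectrum input fails with a located error", {
  expect_error(read_spectrum(character(0)), class = "empty_input_error")
  expect_error(read_spectrum(c("1035,1.0", "oops,x"), format = "csv"),
               regexp = "line 2", class = "format_error")
})

test_that("baseline correction is exact on null input and recovers known baselines", {
  flat <- ftir_spectrum(seq(400, 4000), rep(0, 3601))
  corr <- baseline_correct(flat)
  expect_equal(corr$absorbance, rep(0, 3601))

  # single Gaussian plus a known linear ramp: corrected height within 1%
  wn <- seq(400, 4000)
  ab <- exp(-(wn - 1035)^2 / (2 * 10^2)) + 1e-4 * (4000 - wn)
  sp <- ftir_spectrum(wn, ab)
  corr <- baseline_correct(sp)
  expect_equal(corr$absorbance[wn == 1035], 1.0, tolerance = 0.01)

  expect_error(baseline_correct(sp, anchors = c(100, 800)),
               class = "anchor_error")
  expect_error(baseline_correct(sp, anchors = 800), class = "anchor_error")
})

test_that("baseline correction is idempotent", {
  sp <- simulate_spectrum(default_bands("unburnt", 91), noise_sd = 0.004,
                          seed = 17)
  once <- baseline_correct(sp)
  twice <- baseline_correct(once)
  expect_lt(max(abs(twice$absorbance - once$absorbance)), 1e-12)
})

test_that("feature heights match the analytic band and the brute-force window maximum", {
  sp <- gaussian_spectrum(center = 1035, amp = 1, sigma = 10)
  f <- feature_height(sp, feature_query(1035, 5, "peak"))
  expect_equal(f$height, 1.0)
  expect_equal(f$observed_center, 1035)
  expect_equal(f$shift, 0)

  # query offset from the true band: window max sits at the near edge
  f2 <- feature_height(sp, feature_query(1043, 5, "peak"))
  expect_equal(f2$observed_center, 1038)
  expect_equal(f2$height, exp(-9 / 200), tolerance = 1e-10)

  # valley between two bands equals the brute-force scan of the profile
  two <- simulate_spectrum(band_spec(c(565, 605), c(10, 10), c(1, 1)),
                           baseline_coef = 0, noise_sd = 0)
  v <- feature_height(two, feature_query(587.5, 12.5, "valley"))
  idx <- two$wavenumbers >= 575 & two$wavenumbers <= 600
  expect_equal(v$height, min(two$absorbance[idx]))
  expect_lt(v$height, 1)

  expect_error(feature_height(sp, feature_query(395, 5, "peak")),
               class = "window_error")
})

test_that("peak extraction equals brute-force argmax on randomized spectra", {
  set.seed(42)
  for (i in 1:40) {
    n <- sample(50:200, 1)
    wn <- sort(runif(n, 400, 4000))
    sp <- ftir_spectrum(wn, runif(n))
    center <- runif(1, min(wn) + 60, max(wn) - 60)
    tol <- runif(1, 5, 50)
    idx <- which(wn >= center - tol & wn <= center + tol)
    if (!length(idx)) {
      expect_error(feature_height(sp, feature_query(center, tol, "peak")),
                   class = "window_error")
      next
    }
    f <- feature_height(sp, feature_query(center, tol, "peak"))
    expect_identical(f$height, max(sp$absorbance[idx]))
    expect_lte(abs(f$shift), tol)
  }
})

test_that("the ratio battery follows the stated composition rules", {
  # flat unit spectrum: every queried height is 1, so IRSF = (1+1)/1 = 2
  flat <- ftir_spectrum(seq(400, 4000), rep(1, 3601))
  rec <- compute_ratios(flat, state = "unburnt")
  expect_equal(rec$ratios[["IRSF"]], 2.0)
  # applicability: A-carbonate indices are NA for unburnt, amide indices
  # for burnt
  expect_true(is.na(rec$ratios[["API"]]))
  expect_true(is.na(rec$ratios[["C/C"]]))
  rec_b <- compute_ratios(flat, state = "burnt")
  expect_false(is.na(rec_b$ratios[["API"]]))
  expect_true(is.na(rec_b$ratios[["N/P"]]))
  expect_true(is.na(rec_b$ratios[["APR"]]))

  # zero denominator warns (one warning per affected ratio) and yields NA,
  # not infinity
  zero <- ftir_spectrum(seq(400, 4000), rep(0, 3601))
  warns <- capture_warnings(rz <- compute_ratios(zero, state = "unburnt"))
  expect_true(all(grepl("zero denominator", warns)))
  expect_gt(length(warns), 0)
  expect_true(all(is.na(rz$ratios)))

  dup <- c(default_ratio_battery(), default_ratio_battery()[1])
  expect_error(compute_ratios(flat, battery = dup),
               class = "configuration_error")
})

test_that("all ten ratios are exactly invariant under positive scaling", {
  sp <- baseline_correct(simulate_spectrum(default_bands("burnt", 0),
                                           state = "burnt", noise_sd = 0.004,
                                           seed = 11))
  base <- compute_ratios(sp, state = "burnt")$ratios
  for (c_scale in c(3, 0.25, 17.5)) {
    scaled <- ftir_spectrum(sp$wavenumbers, c_scale * sp$absorbance,
                            state = "burnt")
    expect_equal(compute_ratios(scaled, state = "burnt")$ratios, base,
                 tolerance = 1e-12)
  }
})

test_that("reported shifts never exceed the query tolerance", {
  sp <- baseline_correct(simulate_spectrum(default_bands("unburnt", 180),
                                           noise_sd = 0.004, seed = 23))
  rec <- compute_ratios(sp, state = "unburnt")
  expect_true(all(abs(rec$shifts) <= 12.5 + 1e-9))
})

test_that("ratios on noiseless synthetic spectra match band-parameter arithmetic", {
  tr <- make_default_trends()
  bands <- default_bands("unburnt", 0, tr)
  sp <- simulate_spectrum(bands, noise_sd = 0, baseline_coef = 0)
  rec <- compute_ratios(sp, state = "unburnt")
  # analytic oracle: band-sum maximised over the same +/-5 cm-1 window
  h_win <- function(center, tol = 5) {
    grid <- seq(center - tol, center + tol, by = 1)
    max(vapply(grid, function(x)
      sum(bands$amplitude * exp(-(x - bands$center)^2 /
                                  (2 * bands$width^2))), numeric(1)))
  }
  expect_equal(rec$ratios[["C/P"]], h_win(1415) / h_win(1035),
               tolerance = 0.01)
  expect_equal(rec$ratios[["N/P"]], h_win(1660) / h_win(1035),
               tolerance = 0.01)
  expect_equal(rec$ratios[["BPI"]], h_win(1415) / h_win(605),
               tolerance = 0.01)
})

test_that("heat markers are detected per state and PMI group", {
  mk <- function(state, pmi, seed = 7)
    detect_markers(baseline_correct(simulate_spectrum(
      default_bands(state, pmi), state = state, noise_sd = 0.004, seed = seed)))

  u <- mk("unburnt", 91)
  expect_false(u$btcp_peak_1123$present)   # nothing in 1110-1140 by default
  expect_false(u$extra_peak_1080_1100$present)
  expect_false(u$oh_cl_peak$present)
  expect_true(u$shoulder_547$present)      # Mg-substitution shoulder

  b <- mk("burnt", 91)
  expect_true(b$extra_peak_1080_1100$present)
  expect_true(b$oh_cl_peak$present)
  expect_false(b$shoulder_547$present)
  # the 34-day burnt group is the configured exception for the extra peak
  expect_false(mk("burnt", 34)$extra_peak_1080_1100$present)

  # an added band at 1123 cm-1 above the floor is reported with its height
  bands <- rbind(default_bands("burnt", 91),
                 band_spec(1123, 8, 0.30, "beta-TCP"))
  m <- detect_markers(baseline_correct(simulate_spectrum(
    bands, noise_sd = 0.004, seed = 7)))
  expect_true(m$btcp_peak_1123$present)
  expect_lte(abs(m$btcp_peak_1123$observed_center - 1123), 5)
  expect_gt(m$btcp_peak_1123$height, 0.25)
})
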