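# The generator: calibrated trends, determinism, and the statistical
# structure downstream stages rely on.

test_that("default trends encode the calibrated potassium and sodium anchors", {
  tr <- make_default_trends()
  expect_gte(trend_value(tr, "K", "burnt", "ALL", 0), 0.20)
  expect_equal(trend_value(tr, "K", "unburnt", "ALL", 0), 0.16)
  expect_equal(trend_value(tr, "K", "unburnt", "ALL", 14), 0.06)
  expect_equal(trend_value(tr, "Na", "burnt", "ALL", 14), 0.46)
  expect_lt(trend_value(tr, "K", "burnt", "ALL", 14), 0.14)
  # IC/MC/HC at or below 0.06 wt% from three months
  expect_lte(trend_value(tr, "K", "burnt", "IC", 91), 0.06)
  # OC stays below its 0.12 wt% ceiling from three months on
  expect_lt(trend_value(tr, "K", "burnt", "OC", 91), 0.12)
  # burnt Na plateau after the two-week drop
  plateau <- trend_value(tr, "Na", "burnt", "ALL", c(34, 91, 180, 365))
  expect_true(all(plateau >= 0.45 & plateau <= 0.48))
  # zone falls back to ALL when no zone-specific entry exists
  expect_identical(trend_value(tr, "Na", "burnt", "IC", 14),
                   trend_value(tr, "Na", "burnt", "ALL", 14))
})

test_that("trend model validates anchors", {
  expect_error(trend_model(list(K = list(unburnt = list(ALL = c(1, 2)))),
                           c(K = 0.01)),
               class = "invalid_design_error")
  expect_error(trend_model(list(K = list(unburnt = list(ALL = rep(-1, 6)))),
                           c(K = 0.01)),
               class = "invalid_design_error")
  expect_error(trend_value(make_default_trends(), "Xx", "burnt", "ALL", 0),
               class = "invalid_design_error")
})

test_that("simulated spectra are deterministic under seed and respect the grid", {
  b <- default_bands("unburnt", 0)
  s1 <- simulate_spectrum(b, noise_sd = 0.01, seed = 5)
  s2 <- simulate_spectrum(b, noise_sd = 0.01, seed = 5)
  expect_identical(s1$absorbance, s2$absorbance)
  s3 <- simulate_spectrum(b, noise_sd = 0.01, seed = 6)
  expect_false(identical(s1$absorbance, s3$absorbance))
  expect_error(simulate_spectrum(b, grid = c(5000, 400, 1)),
               class = "invalid_design_error")
  # noiseless single band: maximum 1.0 exactly at the band center
  sp <- gaussian_spectrum(center = 1035, amp = 1)
  expect_equal(max(sp$absorbance), 1.0)
  expect_equal(sp$wavenumbers[which.max(sp$absorbance)], 1035)
})

test_that("the study-shaped design yields 32 specimens per state", {
  d <- default_study_design()
  n_per_state <- tapply(d$groups$n_specimens, d$groups$state, sum)
  expect_equal(unname(n_per_state[["unburnt"]]), 32)
  expect_equal(unname(n_per_state[["burnt"]]), 32)
  study <- simulate_study(d, seed = 3)
  expect_length(study$spectra, 64)
  expect_equal(nrow(study$truth), 64)
  expect_equal(sum(study$truth$state == "burnt"), 32)
})

test_that("a minimal design produces one spectrum, points and a label", {
  d <- study_design(data.frame(state = "burnt", pmi_days = 0, n_specimens = 1),
                    points_per_zone = 1, seed = 2)
  study <- simulate_study(d, low_total_fraction = 0)
  expect_length(study$spectra, 1)
  expect_gte(nrow(study$empa), 1)
  expect_equal(nrow(study$truth), 1)
})

test_that("identical design and seed give bit-identical bundles; seeds only change noise", {
  d <- study_design(data.frame(state = bone_states(), pmi_days = 14,
                               n_specimens = 2), seed = 9)
  a <- simulate_study(d)
  b <- simulate_study(d)
  expect_identical(a$spectra[[1]]$absorbance, b$spectra[[1]]$absorbance)
  expect_identical(as.data.frame(a$empa), as.data.frame(b$empa))
  c2 <- simulate_study(d, seed = 10)
  expect_identical(a$truth, c2$truth)
  expect_false(identical(a$spectra[[1]]$absorbance, c2$spectra[[1]]$absorbance))
})

test_that("zero noise makes every point in a cell identical; values stay non-negative", {
  tr <- make_default_trends()
  tr$noise_sd[trend_elements()] <- 0
  d <- study_design(data.frame(state = "unburnt", pmi_days = 34, n_specimens = 2),
                    points_per_zone = 3, seed = 4)
  tab <- simulate_empa_table(d, tr, low_total_fraction = 0)
  for (zone in empa_zones()) {
    cell <- tab[tab$zone == zone, "K2O"]
    expect_equal(length(unique(round(cell, 12))), 1)
  }
  tab2 <- simulate_empa_table(d, seed = 8)
  expect_true(all(as.matrix(tab2[empa_analytes()]) >= 0))
})

test_that("cell sample means recover the configured trend means (3 SE)", {
  tr <- make_default_trends()
  d <- study_design(data.frame(state = "burnt", pmi_days = 91, n_specimens = 1),
                    points_per_zone = 200, seed = 12)
  tab <- simulate_empa_table(d, tr, low_total_fraction = 0)
  elem <- oxide_to_element(tab)
  for (zone in c("IC", "MC")) {
    v <- elem$K[elem$zone == zone]
    mu <- trend_value(tr, "K", "burnt", zone, 91)
    expect_lt(abs(mean(v) - mu), 3 * sd(v) / sqrt(length(v)))
  }
  # K trajectory monotone non-increasing in IC and MC (empirical means)
  d2 <- study_design(data.frame(state = "burnt",
                                pmi_days = c(0, 14, 34, 91, 180, 365),
                                n_specimens = 1),
                     points_per_zone = 50, seed = 13)
  tab2 <- oxide_to_element(simulate_empa_table(d2, tr, low_total_fraction = 0))
  for (zone in c("IC", "MC")) {
    m <- tapply(tab2$K[tab2$zone == zone], tab2$pmi_days[tab2$zone == zone], mean)
    m <- m[order(as.numeric(names(m)))]
    expect_true(all(diff(m) < 3 * 0.01 / sqrt(50)))
  }
})

test_that("the low-total fraction is reproduced to binomial accuracy", {
  d <- study_design(data.frame(state = "unburnt", pmi_days = 0, n_specimens = 5),
                    points_per_zone = 25, seed = 21)  # 500 points
  tab <- simulate_empa_table(d, low_total_fraction = 0.2)
  n_low <- sum(tab$total < 50)
  ci <- qbinom(c(0.005, 0.995), 500, 0.2)
  expect_gte(n_low, ci[1])
  expect_lte(n_low, ci[2])
})

test_that("unknown states and zones are rejected at design time", {
  expect_error(study_design(data.frame(state = "charred", pmi_days = 0,
                                       n_specimens = 1)),
               class = "invalid_design_error")
  expect_error(study_design(data.frame(state = "burnt", pmi_days = 0,
                                       n_specimens = 0)),
               class = "invalid_design_error")
})
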