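test_that("band assignment finds nearest entries within tolerance", {
  tab <- band_table()
  hit <- assign_band(2953, tab)
  expect_match(hit$mode, "CH3 asymmetric stretching")

  hit2 <- assign_band(1651, tab)
  expect_match(hit2$assignment, "alpha-helices")

  expect_null(assign_band(2500, tab))

  # tie between two entries breaks toward the lower wavenumber
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("center_cm1,mode,assignment,note",
               "1000,low mode,low,", "1008,high mode,high,"), tmp)
  t2 <- band_table(tmp, match_tolerance = 8)
  expect_equal(assign_band(1004, t2)$assignment, "low")
})

test_that("band table validates its inputs", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("center_cm1,mode,assignment,note", tmp)
  expect_error(band_table(tmp), class = "ftirfp_format_error")
  expect_error(band_table(match_tolerance = 0), class = "ftirfp_validation_error")
})

test_that("peak intensity matches the analytic Gaussian second derivative", {
  grid <- seq(2800, 3050, by = 1)
  d <- sg_second_derivative(gaussian_spectrum(grid, 2922, 8, 2))
  pk <- peak_intensity(d, 2922)
  expect_equal(pk$intensity, 2 / 64, tolerance = 0.01)
  expect_equal(pk$wavenumber, 2922)

  # linear in amplitude, <= 1% relative error against the analytic value
  for (amp in c(0.5, 1, 2)) {
    da <- sg_second_derivative(gaussian_spectrum(grid, 2922, 8, amp))
    expect_equal(peak_intensity(da, 2922)$intensity, amp / 64, tolerance = 0.01)
  }

  # doubling the spectrum doubles the magnitude
  d2 <- d; d2$absorbance <- 2 * d$absorbance
  expect_equal(peak_intensity(d2, 2922)$intensity,
               2 * pk$intensity, tolerance = 1e-10)
})

test_that("flat spectra and uncovered windows raise the right errors", {
  flat <- spectrum(seq(2900, 2950), rep(0, 51))
  expect_error(peak_intensity(flat, 2922), class = "ftirfp_no_peak_error")
  s <- spectrum(seq(2900, 2950), rnorm(51))
  expect_error(peak_intensity(s, 2940, search_halfwidth = 15),
               class = "ftirfp_range_error")
})

test_that("intensity ratios recover analytic amplitude ratios", {
  grid <- seq(1700, 3050, by = 1)
  mk <- function(a2922, a2959 = 1, a2851 = 0, a1747 = 0, a3013 = 0) {
    sg_second_derivative(gaussian_spectrum(
      grid, c(2922, 2959, 2851, 1747, 3013), rep(8, 5),
      c(a2922, a2959, a2851, a1747, a3013)))
  }
  expect_equal(ch2_ch3_ratio(mk(1)), 1, tolerance = 1e-3)
  expect_equal(ch2_ch3_ratio(mk(2)), 2, tolerance = 1e-2)
  # missing CH2 band
  expect_error(ch2_ch3_ratio(mk(0)), class = "ftirfp_no_peak_error")

  expect_equal(carbonyl_total_lipid_ratio(mk(1, 1, 1, 1)), 0.5, tolerance = 1e-2)
  expect_error(carbonyl_total_lipid_ratio(mk(1, 1, 1, 0)),
               class = "ftirfp_no_peak_error")
  expect_equal(carbonyl_total_lipid_ratio(mk(1, 1, 1, 0), allow_zero = TRUE), 0)

  expect_equal(unsat_sat_ratio(mk(1, 1, 1, 0, 1)), 0.5, tolerance = 1e-2)
  expect_equal(unsat_sat_ratio(mk(1, 1, 1, 0, 0.2)), 0.1, tolerance = 1e-2)

  # olefinic band lies above 3000: a 3000-2800 crop cannot support the ratio
  cropped <- select_region(mk(1, 1, 1, 0, 1), 2800, 3000)
  expect_error(unsat_sat_ratio(cropped), class = "ftirfp_range_error")
})

test_that("ratios are invariant under positive scaling of the spectrum", {
  grid <- seq(1700, 3050, by = 1)
  d <- sg_second_derivative(gaussian_spectrum(
    grid, c(2922, 2959, 2851, 1747, 3013), rep(8, 5), c(1, 0.6, 0.8, 0.3, 0.1)))
  ref <- c(ch2_ch3_ratio(d), carbonyl_total_lipid_ratio(d), unsat_sat_ratio(d))
  for (c in c(0.1, 10)) {
    ds <- d; ds$absorbance <- c * d$absorbance
    expect_equal(c(ch2_ch3_ratio(ds), carbonyl_total_lipid_ratio(ds),
                   unsat_sat_ratio(ds)), ref, tolerance = 1e-10)
  }
})

test_that("batch ratio computation records failures without aborting", {
  grid <- seq(600, 4000, by = 2)
  good <- gaussian_spectrum(grid, c(2922, 2959, 2851, 1747, 3013),
                            rep(8, 5), c(1, 0.6, 0.8, 0.3, 0.1))$absorbance
  mat <- rbind(good, good, good, good, good, 0 * good)
  set <- spectra_set(grid, mat, sample_ids = sprintf("s%d", 1:6),
                     groups = rep(c("a", "b"), 3))
  cfg <- preprocess_config(baseline = "none", normalization = "none")
  # flat row survives preprocessing only without area normalization
  deriv <- preprocess_pipeline(set, cfg)
  out <- compute_ratios(deriv)
  expect_equal(nrow(out), 6)
  expect_equal(sum(is.na(out$error)), 5)
  expect_true(all(is.finite(out$ch2_ch3[is.na(out$error)])))
  expect_true(is.na(out$ch2_ch3[!is.na(out$error)]))
})

test_that("ratio estimates track generator ground truth at zero noise", {
  cfg <- default_profiles("coriell", noise_sd = 0)
  for (g in names(cfg$groups)) cfg$groups[[g]]$amplitude_cv <- 0
  sim <- simulate_cohort(cfg, seed = 1)
  deriv <- preprocess_pipeline(sim$set)
  est <- compute_ratios(deriv)
  for (g in names(cfg$groups)) {
    truth <- sim$truth$group_ratios[sim$truth$group_ratios$group == g, ]
    e <- est[est$group == g, ][1, ]
    expect_equal(e$ch2_ch3, truth$ch2_ch3, tolerance = 0.02)
    expect_equal(e$carbonyl_total_lipid, truth$carbonyl_total_lipid,
                 tolerance = 0.02)
    expect_equal(e$unsat_sat, truth$unsat_sat, tolerance = 0.02)
  }
})

test_that("an elevated carbonyl amplitude raises the estimated group ratio", {
  cfg <- default_profiles("coriell", n_samples_per_group = 2)
  higher <- 0
  for (s in 1:20) {
    sim <- simulate_cohort(cfg, seed = s, ground_truth = FALSE)
    est <- compute_ratios(preprocess_pipeline(sim$set))
    med <- tapply(est$carbonyl_total_lipid, est$group, stats::median)
    higher <- higher + (med["DM1_1000"] > med["control"])
  }
  expect_gte(higher, 19)
})
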