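test_that("baseline correction handles flat, sloped and tented spectra", {
  flat <- spectrum(c(0, 1, 2), c(1, 1, 1))
  expect_equal(baseline_correct(flat, "rubberband")$absorbance, c(0, 0, 0))

  slope <- spectrum(c(0, 1, 2), c(0, 5, 10))
  expect_equal(baseline_correct(slope, "linear")$absorbance, c(0, 0, 0))

  # hull of a tent is the chord through the endpoints: peak survives intact
  tent <- spectrum(c(0, 1, 2), c(0, 5, 0))
  expect_equal(baseline_correct(tent, "rubberband")$absorbance, c(0, 5, 0))

  expect_identical(baseline_correct(tent, "none"), tent)
  expect_error(baseline_correct(spectrum(c(0, 1), c(1, 2)), "rubberband"),
               class = "ftirfp_validation_error")
})

test_that("rubberband output is nonnegative and invariant to affine offsets", {
  set.seed(11)
  grid <- seq(600, 1600, by = 5)
  for (i in 1:5) {
    y <- abs(rnorm(length(grid))) + sin(grid / 50)
    s <- spectrum(grid, y)
    corrected <- baseline_correct(s, "rubberband")$absorbance
    expect_true(all(corrected >= -1e-9))
    # adding an affine function of wavenumber changes nothing
    s2 <- spectrum(grid, y + 3.7 - 0.002 * grid)
    corrected2 <- baseline_correct(s2, "rubberband")$absorbance
    expect_equal(corrected2, corrected, tolerance = 1e-9)
  }
})

test_that("area normalization scales |A| integral to 1 and is idempotent", {
  s <- spectrum(0:10, rep(5, 11))           # |A| area 50 -> constant 0.1
  n1 <- area_normalize(s)
  expect_equal(n1$absorbance, rep(5 / 50, 11))
  expect_equal(sum((abs(n1$absorbance)[-1] + abs(n1$absorbance)[-11]) / 2), 1)

  n2 <- area_normalize(n1)
  expect_equal(n2$absorbance, n1$absorbance, tolerance = 1e-12)

  neg <- spectrum(0:10, rep(-5, 11))
  expect_equal(area_normalize(neg)$absorbance, rep(-5 / 50, 11))

  expect_error(area_normalize(spectrum(0:10, rep(0, 11))),
               class = "ftirfp_degenerate_error")

  # scale invariance: normalize(c * s) == normalize(s) for c > 0
  set.seed(3)
  y <- rnorm(50)
  g <- seq_len(50)
  for (c in c(0.1, 1, 10)) {
    expect_equal(area_normalize(spectrum(g, c * y))$absorbance,
                 area_normalize(spectrum(g, y))$absorbance, tolerance = 1e-12)
  }
})

test_that("SG second derivative is exact on low-order polynomials", {
  grid <- seq(1000, 1200, by = 2)
  for (coef in list(c(4, 0, 0), c(7, 3, 0), c(1, -2, 0.5))) {
    y <- coef[1] + coef[2] * grid + coef[3] * grid^2
    d <- sg_second_derivative(spectrum(grid, y))
    expect_equal(d$absorbance, rep(2 * coef[3], length(d$absorbance)),
                 tolerance = 1e-8)
  }
  # trimming: output loses half_width points per side
  d <- sg_second_derivative(spectrum(grid, grid^2), half_width = 3)
  expect_length(d$wavenumbers, length(grid) - 6)
  expect_equal(d$wavenumbers[1], grid[4])
})

test_that("SG second derivative tracks the analytic Gaussian derivative", {
  grid <- seq(2800, 3050, by = 1)
  s <- gaussian_spectrum(grid, 2922, 8, 1)
  d <- sg_second_derivative(s)
  at_center <- d$absorbance[d$wavenumbers == 2922]
  expect_equal(at_center, -1 / 64, tolerance = 0.01)
  # whole profile within 1% of the analytic curve (relative to its max)
  truth <- gaussian_d2(d$wavenumbers, 2922, 8, 1)
  expect_lt(max(abs(d$absorbance - truth)) / max(abs(truth)), 0.01)
})

test_that("SG operator is linear and demands a uniform grid", {
  grid <- seq(1000, 1100, by = 1)
  set.seed(5)
  y1 <- rnorm(length(grid)); y2 <- rnorm(length(grid))
  d1 <- sg_second_derivative(spectrum(grid, y1))$absorbance
  d2 <- sg_second_derivative(spectrum(grid, y2))$absorbance
  d12 <- sg_second_derivative(spectrum(grid, 2 * y1 - 3 * y2))$absorbance
  expect_equal(d12, 2 * d1 - 3 * d2, tolerance = 1e-10)

  bad <- spectrum(c(1, 2, 4, 8, 16, 32, 64, 70), rnorm(8))
  expect_error(sg_second_derivative(bad), class = "ftirfp_validation_error")
})

test_that("region selection keeps the closed interval", {
  grid <- seq(600, 4000, by = 2)
  s <- spectrum(grid, sin(grid))
  r <- select_region(s, 3000, 2800)   # bounds in either order
  expect_length(r$wavenumbers, 101)
  expect_equal(range(r$wavenumbers), c(2800, 3000))

  one <- select_region(s, 1500, 1501)
  expect_length(one$wavenumbers, 1)

  expect_error(select_region(s, 5000, 6000), class = "ftirfp_range_error")
})

test_that("preprocess pipeline applies stages in order and records provenance", {
  grid <- seq(600, 4000, by = 2)
  set.seed(9)
  mat <- rbind(gaussian_spectrum(grid, c(2922, 1651), c(8, 18), c(0.3, 1))$absorbance,
               gaussian_spectrum(grid, c(2922, 1651), c(8, 18), c(0.3, 1))$absorbance)
  set <- spectra_set(grid, mat, sample_ids = c("a", "b"))

  # all-"none" config: identity on values (no derivative, no crop here)
  cfg0 <- preprocess_config(baseline = "none", normalization = "none")
  cfg0$derivative_order <- 0L
  out0 <- preprocess_pipeline(set, cfg0)
  expect_equal(out0$matrix, set$matrix)

  # identical input rows give identical output rows
  out <- preprocess_pipeline(set, preprocess_config())
  expect_equal(out$matrix[1, ], out$matrix[2, ])
  expect_equal(out$provenance$preprocess$baseline, "rubberband")

  # mid-pipeline invariant: |A| integrates to 1 after normalization,
  # before derivatization
  cfg_nd <- preprocess_config()
  cfg_nd$derivative_order <- 0L
  norm <- preprocess_pipeline(set, cfg_nd)
  for (i in 1:2) {
    a <- norm$matrix[i, ]
    expect_equal(sum((abs(a)[-1] + abs(a)[-length(a)]) * diff(grid)) / 2, 1,
                 tolerance = 1e-9)
  }
})

test_that("region selection commutes with derivative-only preprocessing", {
  grid <- seq(600, 4000, by = 2)
  s <- gaussian_spectrum(grid, c(2922, 2959), c(8, 9), c(1, 0.5))
  full <- sg_second_derivative(s)
  inner <- select_region(full, 2850, 2990)
  # derivative of the cropped spectrum agrees on the shared support
  cropped <- sg_second_derivative(select_region(s, 2800, 3040))
  shared <- select_region(cropped, 2850, 2990)
  expect_equal(inner$absorbance, shared$absorbance, tolerance = 1e-12)
})

test_that("invalid SG configurations are rejected", {
  expect_error(preprocess_config(sg_half_width = 0),
               class = "ftirfp_validation_error")
  expect_error(preprocess_config(sg_half_width = 1, sg_polyorder = 4),
               class = "ftirfp_validation_error")
  expect_error(preprocess_config(regions = list(c(100, 100))),
               class = "ftirfp_validation_error")
})
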