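test_that("wavelength grids have exact bin structure and reject bad inputs", {
  g <- wavelength_grid(300, 800, 5)
  expect_equal(g$n_bins, 100L)
  expect_equal(wl_centers(g)[1], 302.5)
  expect_equal(wl_centers(g)[100], 797.5)
  expect_equal(wl_bin(g, 302.5), 1L)
  expect_equal(wl_bin(g, 799.99), 100L)
  expect_true(is.na(wl_bin(g, 800)))
  expect_error(wavelength_grid(500, 400, 5), "start_nm")
  expect_error(wavelength_grid(300, 800, -1), "step_nm")
  expect_error(wavelength_grid(300, 801, 5), "integer multiple")
})

test_that("gaussian emission line is a unit-mass normal density", {
  peak <- gaussian_emission(509, 509, 20)
  expect_equal(peak, 1 / (sqrt(2 * pi) * 20), tolerance = 1e-12)
  lam <- seq(300.25, 800, by = 0.5)
  expect_equal(sum(gaussian_emission(lam, 509, 20)) * 0.5, 1, tolerance = 1e-3)
  expect_equal(gaussian_emission(509 + 20, 509, 20), peak * exp(-0.5),
               tolerance = 1e-12)
  expect_equal(gaussian_emission(509 - 20, 509, 20), peak * exp(-0.5),
               tolerance = 1e-12)
  expect_error(gaussian_emission(500, 509, 0), "lambda_sigma")
})

test_that("binary absorption window is 1 strictly inside 370-690 nm", {
  expect_equal(cerezo_absorption(c(500, 371, 689.9)), c(1, 1, 1))
  expect_equal(cerezo_absorption(c(700, 370, 690, 300)), c(0, 0, 0, 0))
  expect_error(cerezo_absorption(-5), "wavelengths")
})

test_that("baseline wavelength redistribution composes window, line and yield", {
  # outside the absorption window the product is annihilated
  lam <- seq(400, 700, by = 25)
  expect_equal(cerezo_redistribution(700, lam, 509, 20, 0.8), rep(0, length(lam)))
  expect_equal(cerezo_redistribution(488, lam, 509, 20, 0), rep(0, length(lam)))
  # independent closed form via dnorm
  expect_equal(cerezo_redistribution(488, 509, 509, 20, 0.8),
               0.8 * (488 / 509) * dnorm(509, 509, 20), tolerance = 1e-12)
  expect_error(cerezo_redistribution(-1, 509, 509, 20, 0.8), "wavelengths")
})

test_that("fluorescence efficiency follows the tabulated spectra", {
  fl <- quick_fluo(phi = 0.7)
  exp_pk <- excitation_peak(fl)
  em_pk <- emission_peak(fl)
  expect_equal(fluorescence_efficiency(fl, exp_pk, em_pk),
               0.7 * max(fl$f_em$values), tolerance = 1e-12)
  # excitation outside the grid support reads as zero
  expect_equal(fluorescence_efficiency(fl, 299, em_pk), 0)
  expect_equal(fluorescence_efficiency(fl, exp_pk, 299), 0)
  # summing over all emission bins collapses the unit-integral emission
  lam <- wl_centers(fl$f_em$grid)
  for (lex in c(450, 488, 520)) {
    s <- sum(fluorescence_efficiency(fl, lex, lam)) * fl$f_em$grid$step_nm
    expect_equal(s, 0.7 * spd_value_at(fl$f_ex, lex), tolerance = 1e-9)
  }
})

test_that("fluorescence efficiency is separable in excitation and emission", {
  fl <- quick_fluo()
  l1 <- 505; l2 <- 540
  ratios <- vapply(c(430, 470, 488, 510), function(lex) {
    a <- fluorescence_efficiency(fl, lex, l1)
    b <- fluorescence_efficiency(fl, lex, l2)
    a / b
  }, numeric(1))
  expect_true(max(ratios) - min(ratios) < 1e-9 * max(ratios))
})

test_that("spectral integration is the midpoint rule and is linear", {
  g <- wavelength_grid(400, 500, 1)
  expect_equal(spd_integrate(spectral_distribution(g, rep(0, 100))), 0)
  expect_equal(spd_integrate(spectral_distribution(g, rep(2, 100))), 200)
  set.seed(11)
  x <- spectral_distribution(g, runif(100))
  y <- spectral_distribution(g, runif(100))
  z <- spectral_distribution(g, 3 * x$values + 0.5 * y$values)
  expect_equal(spd_integrate(z), 3 * spd_integrate(x) + 0.5 * spd_integrate(y),
               tolerance = 1e-12)
  # a unit-normalized emission spectrum integrates to one by construction
  expect_equal(spd_integrate(quick_fluo()$f_em), 1, tolerance = 1e-9)
})

test_that("spectrum CSV reading interpolates, clamps, and validates", {
  g <- wavelength_grid(300, 800, 5)
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,value", "400,0", "500,1"), p)
  spd <- read_spectrum_csv(p, g)
  expect_equal(spd_value_at(spd, 450), 0.5, tolerance = 1e-9)
  expect_equal(spd_value_at(spd, 350), 0)   # outside tabulated support
  expect_equal(spd_value_at(spd, 600), 0)

  writeLines(c("lambda,value", "400,0"), p)
  expect_error(read_spectrum_csv(p, g), "header")
  writeLines(c("wavelength_nm,value", "400,0", "x,1"), p)
  expect_error(read_spectrum_csv(p, g), "line 3")
  writeLines(c("wavelength_nm,value", "400,0", "390,1"), p)
  expect_error(read_spectrum_csv(p, g), "not strictly increasing")
  writeLines(c("wavelength_nm,value", "400,-0.1"), p)
  expect_error(read_spectrum_csv(p, g), "negative")
  expect_error(read_spectrum_csv(file.path(tempdir(), "nope.csv"), g),
               "not found")
})

test_that("spectrum write-read round trip is exact on grid-aligned data", {
  fl <- fluorophore_fixture("gfp")
  p <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(fl$f_em, p)
  back <- read_spectrum_csv(p, fl$f_em$grid)
  expect_lt(max(abs(back$values - fl$f_em$values)), 1e-9)
})

test_that("fluorophore constructor enforces the normalization conventions", {
  fl <- quick_fluo()
  expect_equal(max(fl$f_ex$values), 1)
  expect_equal(spd_integrate(fl$f_em), 1, tolerance = 1e-9)
  g <- wavelength_grid()
  s <- spectral_distribution(g, dnorm(wl_centers(g), 500, 20))
  expect_error(fluorophore("x", s, s, phi = 1.2, sigma_cm2 = 1e-16), "phi")
  expect_error(fluorophore("x", s, s, phi = 0.5, sigma_cm2 = 0), "sigma_cm2")
  # bundled fixtures load and carry plausible peaks
  for (w in c("gfp", "rfp", "cfp")) {
    f <- fluorophore_fixture(w)
    expect_s3_class(f, "fluorophore")
    expect_true(emission_peak(f) > excitation_peak(f))  # Stokes shift
  }
  expect_error(fluorophore_table(fl, fl), "unique")
})
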