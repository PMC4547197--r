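test_that("transmittance is 1 in vacuum and exact for uniform extinction", {
  fl <- quick_fluo()
  empty <- make_homogeneous_cube(4, 0, 0.5)
  sheet <- light_sheet(10, 10, 488, 1e12)
  sc0 <- lsfm_scene(empty, fluorophore_table(fl), sheet)
  expect_equal(transmittance(c(-5, 0, 0), c(5, 0, 0), 488, sc0), 1)

  med <- make_homogeneous_cube(4, 1, 0.5, sigma_s_elastic = 80)
  sc <- lsfm_scene(med, fluorophore_table(quick_fluo(sigma = 1e-22)), sheet)
  # a 3 um path fully inside the uniform medium
  got <- transmittance(c(-1.5, 0, 0), c(1.5, 0, 0), 488, sc, step_um = 0.1)
  expect_equal(got, exp(-80 * 3e-4), tolerance = 1e-6)
  # multiplicative over concatenated segments
  t1 <- transmittance(c(-1.5, 0, 0), c(0.3, 0, 0), 488, sc, step_um = 0.1)
  t2 <- transmittance(c(0.3, 0, 0), c(1.5, 0, 0), 488, sc, step_um = 0.1)
  expect_equal(t1 * t2, got, tolerance = 1e-6)
})

test_that("marched transmittance matches adaptive quadrature on a gradient", {
  # density ramp along x; absorption at the laser line dominates extinction
  fl <- quick_fluo(sigma = 3e-16)
  nx <- 40L
  dens <- array(rep((1:nx) * 5e16, times = 8 * 8), dim = c(nx, 8, 8))
  grid <- fluor_volume(c(nx, 8L, 8L), 0.5, origin_um = c(-10, -2, -2),
                       density = dens, dye_index = 0L)
  sheet <- light_sheet(10, 10, excitation_peak(fl), 1e12)
  sc <- lsfm_scene(grid, fluorophore_table(fl), sheet)
  p0 <- c(-6, 0.1, 0.1); p1 <- c(7, 0.1, 0.1)
  lam <- excitation_peak(fl)
  fex <- spd_value_at(fl$f_ex, lam)
  seg_len <- p1[1] - p0[1]
  sigma_line <- function(s) {
    pts <- cbind(p0[1] + s, p0[2], p0[3])
    3e-16 * fex * sample_density(grid, pts)
  }
  tau_ref <- integrate(sigma_line, 0, seg_len, rel.tol = 1e-10)$value * 1e-4
  got <- transmittance(p0, p1, lam, sc, step_um = 0.25)
  expect_equal(got, exp(-tau_ref), tolerance = 5e-3)
})

test_that("phase functions are normalized over the sphere", {
  expect_equal(phase_isotropic(), 1 / (4 * pi), tolerance = 1e-12)
  dirs <- fibonacci_sphere(10000)
  w_in <- c(0, 0, 1)
  for (g in c(0, 0.3, 0.7, -0.5)) {
    vals <- vapply(seq_len(nrow(dirs)), function(i)
      phase_hg(w_in, dirs[i, ], g), numeric(1))
    expect_equal(mean(vals) * 4 * pi, 1, tolerance = 1e-3)
  }
  # HG reduces to isotropic at g = 0
  for (i in c(1, 500, 9999))
    expect_equal(phase_hg(w_in, dirs[i, ], 0), 1 / (4 * pi), tolerance = 1e-12)
  expect_error(phase_hg(w_in, w_in, 1), "g")
})

test_that("the source term collapses correctly at fluorescent points", {
  fl <- quick_fluo(phi = 0.8, sigma = 3e-16)
  sc <- cube_scene(fluo = fl)
  # non-fluorescent point, no elastic scattering: zero everywhere
  s0 <- source_term(c(10, 10, 10), c(0, 0, 1), sc)
  expect_true(all(s0$values == 0))
  # fluorescent point: negligible far outside the emission band (Gaussian
  # tails never reach exact zero), zero beyond the grid
  s1 <- source_term(c(0, 0, 0), c(0, 0, 1), sc)
  expect_lt(s1$values[wl_bin(sc$spectral_grid, 350)], 1e-12 * max(s1$values))
  expect_gt(s1$values[wl_bin(sc$spectral_grid, emission_peak(fl))], 0)
  # 4 pi x sum over emission bins recovers the volume emission coefficient
  flux <- sheet_flux_density(sc$sheet, c(0, 0, 0))
  tot <- sum(s1$values) * sc$spectral_grid$step_nm * 4 * pi
  want <- 3e-16 * 1e18 * 0.8 * spd_value_at(fl$f_ex, sc$sheet$lambda_ex_nm) * flux
  expect_equal(tot, want, tolerance = 1e-9)
})

test_that("ray integration matches the single-scatter slab closed form", {
  fl <- quick_fluo(phi = 0.8, sigma = 3e-16)
  sc <- cube_scene(side = 2, N = 1e18, vs = 0.1, fluo = fl)
  ray <- make_ray(c(0.2, -0.3, 10), c(0, 0, -1))
  L <- integrate_ray(ray, sc)
  flux <- sheet_flux_density(sc$sheet, c(0, 0, 0))
  fex <- spd_value_at(fl$f_ex, sc$sheet$lambda_ex_nm)
  want_total <- (1 / (4 * pi)) * 3e-16 * 1e18 * 0.8 * fex * flux * 2e-4
  expect_equal(spd_integrate(L), want_total, tolerance = 0.01)
  # per-bin shape equals the emission spectrum
  shp <- L$values / max(L$values)
  fem <- fl$f_em$values / max(fl$f_em$values)
  expect_lt(max(abs(shp - fem)), 1e-6)
  # rays that miss the specimen return an all-zero spectrum
  miss <- integrate_ray(make_ray(c(50, 0, 10), c(0, 0, -1)), sc)
  expect_true(all(miss$values == 0))
})

test_that("halving the marching step changes the slab radiance by < 0.5%", {
  sc <- cube_scene(vs = 0.1)
  ray <- make_ray(c(0.2, -0.3, 10), c(0, 0, -1))
  L1 <- spd_integrate(integrate_ray(ray, sc, march_settings(0.1, jitter = FALSE)))
  L2 <- spd_integrate(integrate_ray(ray, sc, march_settings(0.05, jitter = FALSE)))
  expect_lt(abs(L2 - L1) / L2, 0.005)
})

test_that("with fluorescence off the integrator reduces to elastic scattering", {
  # phi = 0 kills the inelastic term; a uniform elastic slab remains
  fl <- quick_fluo(phi = 0, sigma = 1e-22)
  grid <- make_homogeneous_cube(2, 1, 0.1, sigma_s_elastic = 40)
  sheet <- light_sheet(8, 8, excitation_peak(fl), 1e12)
  sc <- lsfm_scene(grid, fluorophore_table(fl), sheet,
                   march_settings(0.05, jitter = FALSE), attenuation = "none")
  ray <- make_ray(c(0, 0, 10), c(0, 0, -1))
  L <- integrate_ray(ray, sc)
  exbin <- wl_bin(sc$spectral_grid, sheet$lambda_ex_nm)
  # all the light is at the laser line
  expect_equal(sum(L$values[-exbin]), 0)
  # closed form: sigma_s * phase(90 deg) * flux * medium path; the clamped
  # medium mask spans the grid inflated by half a voxel (2.1 um)
  flux <- sheet_flux_density(sheet, c(0, 0, 0))
  want <- 40 * (1 / (4 * pi)) * flux * 2.1e-4
  expect_equal(L$values[exbin] * sc$spectral_grid$step_nm, want,
               tolerance = 0.01)
})

test_that("emitted wavelengths never stray outside the emission support", {
  # a dye with exactly compact emission support: 500-550 nm only
  g <- wavelength_grid()
  ctr <- wl_centers(g)
  em <- spectral_distribution(g, ifelse(ctr >= 500 & ctr <= 550,
                                        dnorm(ctr, 525, 12), 0))
  ex <- spectral_distribution(g, exp(-0.5 * ((ctr - 488) / 22)^2))
  fl <- fluorophore("COMPACT", ex, em, phi = 0.8, sigma_cm2 = 3e-16)
  sc <- cube_scene(fluo = fl)
  film <- render_section(sc, ortho_camera(4, 4, resolution = c(16, 16),
                                          samples_per_pixel = 2), seed = 1)
  support <- fl$f_em$values > 0
  off_band <- apply(film$spd, 3, sum)[!support]
  expect_true(all(off_band == 0))
  expect_gt(sum(apply(film$spd, 3, sum)[support]), 0)
})

test_that("film response is exactly linear in the photon budget", {
  fl <- quick_fluo()
  sc1 <- cube_scene(photons = 1e12, fluo = fl, jitter = TRUE)
  sc2 <- cube_scene(photons = 2e12, fluo = fl, jitter = TRUE)
  cam <- ortho_camera(4, 4, resolution = c(16, 16), samples_per_pixel = 2)
  f1 <- render_section(sc1, cam, seed = 9)
  f2 <- render_section(sc2, cam, seed = 9)
  expect_equal(f2$spd, 2 * f1$spd, tolerance = 1e-12)
})

test_that("simulated emission conserves the photon budget of the volume", {
  # sheet covering the whole (taper-smeared) specimen, no attenuation:
  # 4 pi x detected photons = Phi * sigma * phi * f_ex * total molecules
  fl <- quick_fluo(phi = 0.8, sigma = 3e-16)
  sc <- cube_scene(side = 2, N = 1e18, vs = 0.1, fluo = fl, jitter = TRUE)
  cam <- ortho_camera(4, 4, resolution = c(64, 64), samples_per_pixel = 4)
  film <- render_section(sc, cam, seed = 2)
  flux <- sheet_flux_density(sc$sheet, c(0, 0, 0))
  fex <- spd_value_at(fl$f_ex, sc$sheet$lambda_ex_nm)
  want <- flux * 3e-16 * 0.8 * fex * total_molecules(sc$grid) / (4 * pi)
  expect_equal(detect_photons(film), want, tolerance = 0.01)
})
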