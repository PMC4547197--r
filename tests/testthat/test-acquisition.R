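test_that("pinhole rays are orthographic and ignore the focal plane", {
  cam <- ortho_camera(100, 100, resolution = c(10, 10), aperture_radius_um = 0)
  r <- generate_camera_ray(cam, cbind(5, 5))   # film center
  expect_equal(r$direction, matrix(c(0, 0, -1), 1))
  expect_equal(r$origin[1, 1:2], c(0, 0))
  r2 <- generate_camera_ray(cam, cbind(0.5, 9.5))
  expect_equal(r2$origin[1, 1:2], c(-45, 45))
  # focal plane position is irrelevant at aperture zero
  cam_a <- cam; cam_a$focal_plane_z_um <- -30
  cam_b <- cam; cam_b$focal_plane_z_um <- 12
  s <- cbind(runif(5, 0, 10), runif(5, 0, 10))
  ra <- generate_camera_ray(cam_a, s, origin_z_um = 50)
  rb <- generate_camera_ray(cam_b, s, origin_z_um = 50)
  expect_identical(ra, rb)
})

test_that("thin-lens rays focus on-plane points and blur off-plane points", {
  cam <- ortho_camera(100, 100, resolution = c(10, 10),
                      aperture_radius_um = 4, focus_scale_um = 25,
                      focal_plane_z_um = -7)
  set.seed(21)
  lens <- cbind(runif(1000), runif(1000))
  px <- cbind(rep(5, 1000), rep(5, 1000))
  r <- generate_camera_ray(cam, px, lens, origin_z_um = 60)
  # every ray passes through the film point on the focal plane
  t_f <- (-7 - r$origin[, 3]) / r$direction[, 3]
  at_f <- r$origin[, 1:2] + r$direction[, 1:2] * t_f
  expect_lt(max(abs(at_f)), 1e-9)
  # 10 um off-plane: circle of confusion of radius aperture * dz / scale
  t_o <- (3 - r$origin[, 3]) / r$direction[, 3]
  at_o <- r$origin[, 1:2] + r$direction[, 1:2] * t_o
  rad <- sqrt(rowSums(at_o^2))
  want_r <- 4 * 10 / 25
  expect_lt(max(rad), want_r * 1.001)
  expect_gt(max(rad), want_r * 0.97)
  # concentric disk sampling fills the disk (mean radius of uniform disk: 2R/3)
  expect_equal(mean(rad), 2 / 3 * want_r, tolerance = 0.05)
})

test_that("emission filters act bin-wise with grid checks", {
  g <- wavelength_grid()
  fl <- quick_fluo()
  spd <- fl$f_em
  expect_equal(apply_emission_filter(spd, unity_filter(g))$values, spd$values)
  nf <- notch_filter(g, lambda_ex_nm = 488)
  blocked <- which(nf$transmission$values == 0)
  expect_equal(blocked, wl_bin(g, 488) + (-1:1))   # laser bin plus one each side
  out <- apply_emission_filter(spd, nf)
  expect_true(all(out$values[blocked] == 0))
  expect_equal(out$values[-blocked], spd$values[-blocked])
  bp <- bandpass_filter(g, 500, 550)
  inband <- wl_centers(g) >= 500 & wl_centers(g) <= 550
  expect_equal(spd_integrate(apply_emission_filter(spd, bp)),
               sum(spd$values[inband]) * g$step_nm)
  g2 <- wavelength_grid(400, 700, 5)
  expect_error(apply_emission_filter(spd, unity_filter(g2)), "grids differ")
})

test_that("a notch filter removes the laser line from a scattering scene", {
  fl <- quick_fluo(phi = 0.6, sigma = 3e-16)
  grid <- make_homogeneous_cube(2, 1e18, 0.1, sigma_s_elastic = 30)
  sheet <- light_sheet(4, 4, excitation_peak(fl), 1e12)
  sc <- lsfm_scene(grid, fluorophore_table(fl), sheet, attenuation = "none")
  cam <- ortho_camera(4, 4, resolution = c(16, 16), samples_per_pixel = 2)
  raw <- render_section(sc, cam, seed = 3)
  exbin <- wl_bin(sc$spectral_grid, sheet$lambda_ex_nm)
  expect_gt(sum(raw$spd[, , exbin]), 0)   # elastic light reaches the film
  filtered <- render_section(sc, cam, seed = 3,
                             filter = notch_filter(sc$spectral_grid,
                                                   sheet$lambda_ex_nm))
  expect_equal(sum(filtered$spd[, , exbin]), 0)
})

test_that("renders are seed-deterministic and symmetric for a centered cube", {
  sc <- cube_scene(jitter = TRUE)
  cam <- ortho_camera(4, 4, resolution = c(32, 32), samples_per_pixel = 4)
  f1 <- render_section(sc, cam, seed = 5)
  f2 <- render_section(sc, cam, seed = 5)
  expect_identical(f1$spd, f2$spd)
  f3 <- render_section(sc, cam, seed = 6)
  expect_false(identical(f1$spd, f3$spd))
  img <- film_photon_image(f1)
  # bright square centered in the field of view; reflection symmetry holds up
  # to pixel-sampling noise in the half-voxel boundary taper, and exactly for
  # the mirrored photon totals
  expect_lt(sum(abs(img - img[, 32:1])) / sum(img), 0.1)
  expect_lt(sum(abs(img - img[32:1, ])) / sum(img), 0.1)
  expect_equal(sum(img[1:16, ]), sum(img[17:32, ]), tolerance = 0.01)
  expect_equal(sum(img[, 1:16]), sum(img[, 17:32]), tolerance = 0.01)
  ctr <- img[14:19, 14:19]
  expect_true(all(ctr > 0.9 * max(img)))
})

test_that("opposing cameras detect matching photon counts (reciprocity)", {
  sc <- cube_scene(jitter = TRUE, attenuation = "camera")
  mk <- function(axis) ortho_camera(4, 4, resolution = c(32, 32),
                                    samples_per_pixel = 4, axis = axis)
  f_down <- render_section(sc, mk("-z"), seed = 11)
  f_up <- render_section(sc, mk("+z"), seed = 12)
  expect_equal(detect_photons(f_up) / detect_photons(f_down), 1,
               tolerance = 0.01)
})

test_that("Monte Carlo noise shrinks roughly as one over sqrt(samples)", {
  grid <- make_rod_phantom(n_rods = 10, seed = 2, half_span_um = 10,
                           z_half_um = 6, voxel_size_um = 0.5)
  fl <- quick_fluo()
  sheet <- light_sheet(10, 22, excitation_peak(fl), 1e12)
  sc <- lsfm_scene(grid, fluorophore_table(fl), sheet)
  mk <- function(spp) ortho_camera(20, 20, resolution = c(24, 24),
                                   aperture_radius_um = 5,
                                   samples_per_pixel = spp)
  pix_sd <- function(spp) {
    imgs <- vapply(1:6, function(s)
      film_photon_image(render_section(sc, mk(spp), seed = 100 + s)),
      matrix(0, 24, 24))
    mean(apply(imgs, c(1, 2), sd))
  }
  ratio <- pix_sd(4) / pix_sd(32)
  expect_gt(ratio, 1.6)     # ideal sqrt(8) = 2.83
  expect_lt(ratio, 5)
})

test_that("developed images carry invertible scaling metadata", {
  sc <- cube_scene(jitter = TRUE)
  cam <- ortho_camera(4, 4, resolution = c(16, 16), samples_per_pixel = 2)
  film <- render_section(sc, cam, seed = 4)
  img <- develop_image(film)
  expect_equal(dim(img), c(16, 16))
  expect_true(all(img >= 0 & img <= 1))
  expect_lt(max(abs(img * attr(img, "scale") - film_photon_image(film))),
            1e-9 * attr(img, "scale"))
  # two films differing 2x in photons develop 2:1 under a shared scale
  sc2 <- cube_scene(photons = 2e12, jitter = TRUE)
  film2 <- render_section(sc2, cam, seed = 4)
  shared <- max(film_photon_image(film2))
  i1 <- develop_image(film, max_value = shared)
  i2 <- develop_image(film2, max_value = shared)
  expect_equal(2 * as.vector(i1), as.vector(i2), tolerance = 1e-12)
  # pseudocolor mode keeps dimensions and hue channels
  pc <- develop_image(film2, mode = "pseudocolor")
  expect_equal(dim(pc), c(16, 16, 3))
  # an unilluminated specimen develops to an all-zero raster
  dark <- render_section(cube_scene(N = 0), cam, seed = 4)
  expect_true(all(develop_image(dark) == 0))
  expect_equal(detect_photons(dark), 0)
})
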