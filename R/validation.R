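#' Expected photon count from the fluorescence brightness equation
#'
#' Closed-form fluorescent photon yield at one detection plane under
#' isotropic emission and uniform excitation of an optically thin volume:
#' \deqn{F = \frac{1}{4\pi} I \sigma N \phi l}
#' with \eqn{I} the sheet photon budget, \eqn{\sigma} the molecular
#' absorption cross section (cm^2), \eqn{N} the fluorophore concentration
#' (cm^-3), \eqn{\phi} the quantum yield and \eqn{l} the excitation path
#' length through the volume (cm).
#'
#' @param I photons delivered by the sheet.
#' @param sigma_cm2 absorption cross section (cm^2).
#' @param N_cm3 concentration (cm^-3).
#' @param phi quantum yield.
#' @param l_cm path length (cm).
#' @return expected photons at one detection plane.
#' @export
fbe_expected_photons <- function(I, sigma_cm2, N_cm3, phi, l_cm) {
  stopifnot(all(I >= 0), sigma_cm2 >= 0, N_cm3 >= 0, phi >= 0, l_cm >= 0)
  (1 / (4 * pi)) * I * sigma_cm2 * N_cm3 * phi * l_cm
}

#' Configuration of the brightness-validation experiment
#'
#' The canonical setup: a homogeneous fluorescent cube centered at the
#' intersection of the illumination and detection axes, a sheet sized to
#' illuminate the entire cube (cross-section = cube face), and two opposing
#' detection cameras along the z axis. Defaults: 2 um cube with
#' sigma = 3e-16 cm^2, N = 1e18 cm^-3, phi = 0.8, photon budgets
#' (1-10) x 1e12. The optical depth sigma*N*l is asserted small so that the
#' uniform-excitation assumption behind the closed form holds.
#'
#' @param cube_side_um cube edge (um).
#' @param sigma_cm2 absorption cross section (cm^2).
#' @param N_cm3 fluorophore concentration (cm^-3).
#' @param phi quantum yield.
#' @param intensities photon budgets to sweep.
#' @param voxel_size_um voxelization of the cube (um).
#' @param resolution film pixels per side.
#' @param spp samples per pixel.
#' @param film_width_um film side (um); must cover the cube face.
#' @return a list of class \code{fbe_config}.
#' @export
fbe_experiment_config <- function(cube_side_um = 2, sigma_cm2 = 3e-16,
                                  N_cm3 = 1e18, phi = 0.8,
                                  intensities = (1:10) * 1e12,
                                  voxel_size_um = 0.1, resolution = 128,
                                  spp = 64, film_width_um = 4) {
  stopifnot(film_width_um >= cube_side_um)
  structure(list(cube_side_um = cube_side_um, sigma_cm2 = sigma_cm2,
                 N_cm3 = N_cm3, phi = phi, intensities = intensities,
                 voxel_size_um = voxel_size_um, resolution = resolution,
                 spp = spp, film_width_um = film_width_um),
            class = "fbe_config")
}

# a single-dye scene for the FBE cube; excitation at the dye's f_ex peak so
# the relative excitation efficiency is exactly 1, as the closed form assumes
fbe_scene <- function(cfg, photons, fluo = NULL) {
  if (is.null(fluo)) fluo <- fluorophore_fixture("gfp")
  fluo$phi <- cfg$phi
  fluo$sigma_cm2 <- cfg$sigma_cm2
  grid <- make_homogeneous_cube(cfg$cube_side_um, cfg$N_cm3, cfg$voxel_size_um)
  sheet <- light_sheet(thickness_um = cfg$cube_side_um,
                       height_um = cfg$cube_side_um,
                       lambda_ex_nm = excitation_peak(fluo),
                       photons = photons, z_um = 0)
  lsfm_scene(grid, fluorophore_table(fluo), sheet)
}

#' Run the fluorescence-brightness validation experiment
#'
#' For each photon budget, renders the cube from the two opposing cameras,
#' integrates the detected photons over each virtual sensor and pairs them
#' with the closed-form prediction. The simulated-to-analytic ratio per row
#' is the headline validation figure.
#'
#' @param cfg an \code{\link{fbe_experiment_config}}.
#' @param seed RNG seed.
#' @param fluo optional fluorophore to label the cube with (default: the
#'   GFP-like fixture, with \code{cfg}'s phi and sigma substituted).
#' @return data.frame with columns \code{I}, \code{F_analytic},
#'   \code{F_cam1}, \code{F_cam2}, \code{ratio1}, \code{ratio2}.
#' @export
run_fbe_experiment <- function(cfg = fbe_experiment_config(), seed = 1L,
                               fluo = NULL) {
  depth <- cfg$sigma_cm2 * cfg$N_cm3 * um_to_cm(cfg$cube_side_um)
  if (depth > 0.1)
    warning(sprintf(
      "run_fbe_experiment: optical depth %.3g not << 1; uniform excitation is doubtful",
      depth))
  l_cm <- um_to_cm(cfg$cube_side_um)
  cam <- function(axis) ortho_camera(cfg$film_width_um, cfg$film_width_um,
                                     resolution = rep(cfg$resolution, 2),
                                     samples_per_pixel = cfg$spp, axis = axis)
  rows <- lapply(seq_along(cfg$intensities), function(i) {
    I <- cfg$intensities[i]
    scene <- fbe_scene(cfg, I, fluo)
    f1 <- render_section(scene, cam("-z"), seed = seed + 2L * i)
    f2 <- render_section(scene, cam("+z"), seed = seed + 2L * i + 1L)
    fa <- fbe_expected_photons(I, cfg$sigma_cm2, cfg$N_cm3, cfg$phi, l_cm)
    data.frame(I = I, F_analytic = fa,
               F_cam1 = detect_photons(f1), F_cam2 = detect_photons(f2))
  })
  out <- do.call(rbind, rows)
  out$ratio1 <- out$F_cam1 / out$F_analytic
  out$ratio2 <- out$F_cam2 / out$F_analytic
  out
}

#' Measure detected emission spectra across excitation wavelengths
#'
#' Renders a small uniformly labeled specimen of one fluorophore at each
#' excitation wavelength, sums the film SPD over all pixels, and normalizes
#' every curve to the peak of the curve obtained at the maximum-excitation
#' wavelength (the laser line with the highest \eqn{f_{ex}}). The recovered
#' curve shapes follow the emission spectrum; their relative amplitudes
#' follow the excitation spectrum.
#'
#' @param fluo a \code{\link{fluorophore}}.
#' @param lambda_ex_nm excitation wavelengths to sweep (nm).
#' @param photons sheet photon budget per exposure.
#' @param cube_side_um,voxel_size_um,N_cm3 specimen parameters.
#' @param resolution,spp render scale.
#' @param seed RNG seed.
#' @return list of class \code{spd_measurement}: \code{lambda_ex_nm},
#'   \code{detected} (matrix, one normalized SPD row per excitation),
#'   \code{grid}, \code{fluo}, \code{reference_lambda_ex}.
#' @export
measure_emission_spd <- function(fluo, lambda_ex_nm = c(355, 405, 488, 561),
                                 photons = 1e12, cube_side_um = 2,
                                 voxel_size_um = 0.1, N_cm3 = 1e18,
                                 resolution = 128, spp = 8, seed = 1L) {
  grid <- make_homogeneous_cube(cube_side_um, N_cm3, voxel_size_um)
  tab <- fluorophore_table(fluo)
  wg <- fluo$f_em$grid
  detected <- matrix(0, length(lambda_ex_nm), wg$n_bins)
  for (i in seq_along(lambda_ex_nm)) {
    sheet <- light_sheet(cube_side_um, cube_side_um, lambda_ex_nm[i],
                         photons, z_um = 0)
    scene <- lsfm_scene(grid, tab, sheet)
    film <- render_section(scene,
                           ortho_camera(2 * cube_side_um, 2 * cube_side_um,
                                        resolution = rep(resolution, 2),
                                        samples_per_pixel = spp),
                           seed = seed + i)
    detected[i, ] <- film_spd(film)$values
  }
  ref <- which.max(spd_value_at(fluo$f_ex, lambda_ex_nm))
  scale <- max(detected[ref, ])
  if (scale > 0) detected <- detected / scale
  structure(list(lambda_ex_nm = lambda_ex_nm, detected = detected,
                 grid = wg, fluo = fluo, reference_lambda_ex = lambda_ex_nm[ref]),
            class = "spd_measurement")
}

#' Sharpness of an image
#'
#' Mean squared finite-difference gradient normalized by the squared mean
#' intensity. Scale-invariant, so pure photon-count rescaling leaves it
#' unchanged; defocus blur lowers it.
#'
#' @param img numeric matrix.
#' @return scalar sharpness.
#' @export
sharpness_metric <- function(img) {
  m <- mean(img)
  if (m <= 0) return(0)
  gx <- img[-1, ] - img[-nrow(img), ]
  gy <- img[, -1] - img[, -ncol(img)]
  (mean(gx^2) + mean(gy^2)) / m^2
}

#' Default phantom for the sheet-thickness blur study
#'
#' Fluorescent rods aligned with the detection axis and spanning the full
#' axial extent, so that at zero aperture every sheet thickness images the
#' same pattern (thicker sheets trade per-area flux for illuminated column
#' length exactly), while at finite aperture the extra out-of-focus column
#' sections blur the image.
#'
#' @param n_rods number of rods.
#' @param seed placement seed.
#' @param half_span_um lateral half extent of the phantom (um).
#' @param z_half_um axial half extent (um); should exceed the largest half
#'   sheet thickness studied.
#' @param rod_radius_um rod radius (um).
#' @param voxel_size_um voxel edge (um).
#' @param density_cm3 concentration inside rods (cm^-3).
#' @return a \code{\link{fluor_volume}}.
#' @export
make_rod_phantom <- function(n_rods = 25, seed = 7L, half_span_um = 15,
                             z_half_um = 8, rod_radius_um = 0.8,
                             voxel_size_um = 0.5, density_cm3 = 1e18) {
  shapes <- with_seed(seed, {
    lapply(seq_len(n_rods), function(i) {
      cx <- stats::runif(1, -half_span_um + rod_radius_um,
                         half_span_um - rod_radius_um)
      cy <- stats::runif(1, -half_span_um + rod_radius_um,
                         half_span_um - rod_radius_um)
      cylinder_shape(c(cx, cy, -z_half_um), c(cx, cy, z_half_um),
                     rod_radius_um, density_cm3, 0L)
    })
  })
  voxelize_primitives(shapes, voxel_size_um,
                      bounds = list(min = c(-half_span_um, -half_span_um, -z_half_um),
                                    max = c(half_span_um, half_span_um, z_half_um)))
}

#' Sheet-thickness blur study
#'
#' Renders the same optical section at several sheet thicknesses with a
#' finite-aperture camera and reports the sharpness of each image. Thicker
#' sheets admit more out-of-focus light, so sharpness decreases with
#' thickness; at zero aperture (infinite depth of field) it stays flat.
#'
#' @param thicknesses_um sheet thicknesses to sweep (um).
#' @param aperture_radius_um camera aperture (um).
#' @param focus_scale_um telecentric blur growth constant (um).
#' @param grid specimen (default: \code{\link{make_rod_phantom}}).
#' @param fluo fluorophore labeling the phantom.
#' @param photons sheet photon budget.
#' @param resolution,spp render scale.
#' @param seed RNG seed (shared across thicknesses).
#' @return data.frame with \code{thickness_um}, \code{sharpness},
#'   \code{mean_photons}.
#' @export
blur_vs_thickness <- function(thicknesses_um = c(5, 7.5, 10, 12.5),
                              aperture_radius_um = 5, focus_scale_um = 25,
                              grid = make_rod_phantom(), fluo = NULL,
                              photons = 1e12, resolution = 128, spp = 8,
                              seed = 1L) {
  if (is.null(fluo)) fluo <- fluorophore_fixture("gfp")
  tab <- fluorophore_table(fluo)
  span <- min(grid$dims[1:2]) * grid$voxel_size_um
  rows <- lapply(thicknesses_um, function(th) {
    sheet <- light_sheet(th, height_um = span + 2, excitation_peak(fluo),
                         photons = photons, z_um = 0)
    scene <- lsfm_scene(grid, tab, sheet)
    camera <- ortho_camera(span, span, resolution = rep(resolution, 2),
                           aperture_radius_um = aperture_radius_um,
                           focus_scale_um = focus_scale_um,
                           samples_per_pixel = spp)
    film <- render_section(scene, camera, seed = seed)
    img <- film_photon_image(film)
    data.frame(thickness_um = th, sharpness = sharpness_metric(img),
               mean_photons = mean(img))
  })
  do.call(rbind, rows)
}
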