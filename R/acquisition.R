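#' Orthographic thin-lens camera
#'
#' Models the telecentric detection train (objective + tube lens) of the
#' microscope: an orthographic view along the detection axis z, with a finite
#' aperture for depth of field. A point on the focal plane images sharply;
#' a point \eqn{\Delta z} off the plane blurs into a circle of confusion of
#' radius \code{aperture_radius_um * |dz| / focus_scale_um}, independent of
#' magnification (telecentric blur). \code{aperture_radius_um = 0} is the
#' ideal pinhole-orthographic camera with infinite depth of field.
#'
#' @param film_width_um,film_height_um physical extent of the imaged field of
#'   view (um), centered on the detection axis.
#' @param resolution pixel counts \code{c(nx, ny)}.
#' @param aperture_radius_um lens radius (um); 0 = pinhole.
#' @param focus_scale_um lens parameter setting the blur growth rate per um
#'   of defocus (no lens prescription is modeled; this single constant stands
#'   in for it).
#' @param focal_plane_z_um focus distance; overwritten with the sheet z at
#'   render time (illumination/detection synchronization).
#' @param samples_per_pixel stratified pixel/lens samples per pixel.
#' @param axis \code{"-z"}: camera above the specimen looking down (rays
#'   travel toward -z); \code{"+z"}: the opposing camera.
#' @return an object of class \code{ortho_camera}.
#' @export
ortho_camera <- function(film_width_um, film_height_um, resolution = c(128, 128),
                         aperture_radius_um = 0, focus_scale_um = 25,
                         focal_plane_z_um = 0, samples_per_pixel = 8,
                         axis = c("-z", "+z")) {
  axis <- match.arg(axis)
  resolution <- as.integer(resolution)
  stopifnot(film_width_um > 0, film_height_um > 0, all(resolution >= 1),
            aperture_radius_um >= 0, focus_scale_um > 0, samples_per_pixel >= 1)
  structure(list(film_width_um = film_width_um, film_height_um = film_height_um,
                 resolution = resolution,
                 aperture_radius_um = aperture_radius_um,
                 focus_scale_um = focus_scale_um,
                 focal_plane_z_um = focal_plane_z_um,
                 samples_per_pixel = as.integer(samples_per_pixel),
                 axis = axis),
            class = "ortho_camera")
}

#' @export
print.ortho_camera <- function(x, ...) {
  cat(sprintf("<ortho_camera> %gx%g um film, %dx%d px, aperture %g um, %d spp, axis %s\n",
              x$film_width_um, x$film_height_um, x$resolution[1], x$resolution[2],
              x$aperture_radius_um, x$samples_per_pixel, x$axis))
  invisible(x)
}

camera_sign <- function(camera) if (camera$axis == "-z") -1 else 1

# world (x, y) of continuous pixel coordinates (0..nx, 0..ny)
pixel_to_world <- function(camera, px, py) {
  cbind(-camera$film_width_um / 2 + px / camera$resolution[1] * camera$film_width_um,
        -camera$film_height_um / 2 + py / camera$resolution[2] * camera$film_height_um)
}

#' Generate camera rays
#'
#' Base rays are orthographic: from the film point along the view axis. With
#' a finite aperture, the origin is displaced laterally by a concentric-disk
#' mapped lens sample and the ray is redirected through the base ray's
#' intersection with the focal plane, so on-plane points stay sharp and
#' off-plane points blur with the telecentric circle-of-confusion rule.
#'
#' @param camera an \code{\link{ortho_camera}}.
#' @param pixel_sample n x 2 continuous pixel coordinates in
#'   [0, nx) x [0, ny).
#' @param lens_sample n x 2 unit-square points driving the lens position.
#' @param origin_z_um world z of the ray origins (defaults to the focal plane
#'   plus/minus a fixed standoff along the axis).
#' @return list with \code{origin} (n x 3) and \code{direction} (n x 3, unit).
#' @export
generate_camera_ray <- function(camera, pixel_sample, lens_sample = NULL,
                                origin_z_um = NULL) {
  if (is.null(dim(pixel_sample))) pixel_sample <- matrix(pixel_sample, ncol = 2)
  n <- nrow(pixel_sample)
  sgn <- camera_sign(camera)
  if (is.null(origin_z_um))
    origin_z_um <- camera$focal_plane_z_um - sgn * 1e4   # 1 cm standoff
  fp <- pixel_to_world(camera, pixel_sample[, 1], pixel_sample[, 2])
  if (camera$aperture_radius_um > 0) {
    if (is.null(lens_sample)) lens_sample <- matrix(0.5, n, 2)
    lens <- concentric_disk(lens_sample[, 1], lens_sample[, 2]) *
      camera$aperture_radius_um
    # lateral slope per um of defocus; at z = focal plane the ray passes
    # through the film point exactly
    slope <- lens / camera$focus_scale_um
    dzo <- origin_z_um - camera$focal_plane_z_um
    o <- cbind(fp[, 1] + slope[, 1] * dzo, fp[, 2] + slope[, 2] * dzo,
               rep(origin_z_um, n))
    # the ray is p(z) = focal_point + slope * (z - z_f); travel along the
    # view axis means z changes by sgn per unit axial step
    dirn <- cbind(slope[, 1] * sgn, slope[, 2] * sgn, rep(sgn, n))
    dirn <- dirn / sqrt(rowSums(dirn^2))
  } else {
    o <- cbind(fp[, 1], fp[, 2], rep(origin_z_um, n))
    dirn <- matrix(rep(c(0, 0, sgn), each = n), n, 3)
  }
  list(origin = o, direction = dirn)
}

#' Emission filters
#'
#' Per-bin transmission in [0, 1] applied in front of the film, standing in
#' for the microscope's filter cubes. The notch filter blocks the laser line
#' (one bin plus \code{halfwidth_nm} to each side) to eliminate elastically
#' scattered excitation light; the band-pass passes [lo, hi] nm; the unity
#' filter is the identity.
#'
#' @param grid a \code{\link{wavelength_grid}}.
#' @return an object of class \code{emission_filter}.
#' @export
unity_filter <- function(grid = wavelength_grid()) {
  structure(list(transmission = spectral_distribution(grid, rep(1, grid$n_bins))),
            class = "emission_filter")
}

#' @param lambda_ex_nm laser line to block.
#' @param halfwidth_nm extra blocked width to each side of the laser bin.
#' @rdname unity_filter
#' @export
notch_filter <- function(grid = wavelength_grid(), lambda_ex_nm,
                         halfwidth_nm = grid$step_nm) {
  v <- rep(1, grid$n_bins)
  ctr <- wl_centers(grid)
  v[abs(ctr - lambda_ex_nm) <= halfwidth_nm + grid$step_nm / 2 - 1e-9] <- 0
  structure(list(transmission = spectral_distribution(grid, v)),
            class = "emission_filter")
}

#' @param lo_nm,hi_nm passband edges (nm).
#' @rdname unity_filter
#' @export
bandpass_filter <- function(grid = wavelength_grid(), lo_nm, hi_nm) {
  stopifnot(lo_nm < hi_nm)
  ctr <- wl_centers(grid)
  v <- as.numeric(ctr >= lo_nm & ctr <= hi_nm)
  structure(list(transmission = spectral_distribution(grid, v)),
            class = "emission_filter")
}

#' Apply an emission filter
#'
#' Bin-wise product of a spectral distribution (or every pixel of a spectral
#' film) with the filter transmission.
#'
#' @param x a \code{\link{spectral_distribution}} or \code{spectral_film}.
#' @param filter an \code{emission_filter}.
#' @return object of the same class as \code{x}.
#' @export
apply_emission_filter <- function(x, filter) {
  stopifnot(inherits(filter, "emission_filter"))
  tv <- filter$transmission
  if (inherits(x, "spectral_distribution")) {
    if (!same_grid(x$grid, tv$grid))
      stop("apply_emission_filter: wavelength grids differ")
    return(spectral_distribution(x$grid, x$values * tv$values))
  }
  if (inherits(x, "spectral_film")) {
    if (!same_grid(x$spectral_grid, tv$grid))
      stop("apply_emission_filter: wavelength grids differ")
    x$spd <- sweep(x$spd, 3, tv$values, `*`)
    return(x)
  }
  stop("apply_emission_filter: unsupported input")
}

new_spectral_film <- function(camera, spectral_grid, spd, meta = list()) {
  pixel_area_cm2 <- um_to_cm(camera$film_width_um / camera$resolution[1]) *
    um_to_cm(camera$film_height_um / camera$resolution[2])
  structure(list(spd = spd, spectral_grid = spectral_grid,
                 resolution = camera$resolution,
                 film_width_um = camera$film_width_um,
                 film_height_um = camera$film_height_um,
                 pixel_area_cm2 = pixel_area_cm2, meta = meta),
            class = "spectral_film")
}

#' @export
print.spectral_film <- function(x, ...) {
  cat(sprintf("<spectral_film> %dx%d px, %d bins; %.4g photons detected\n",
              x$resolution[1], x$resolution[2], x$spectral_grid$n_bins,
              detect_photons(x)))
  invisible(x)
}

#' Render one optical section
#'
#' Simulates the optical sectioning process: the camera focal plane is locked
#' to the sheet position, and for every pixel the spectral radiance of
#' stratified pixel/lens sample rays is averaged, filtered, and accumulated
#' on the film. The film stores the per-pixel spectral photon flux so that
#' \code{\link{detect_photons}} integrates to photon counts. Deterministic
#' for a fixed seed.
#'
#' @param scene an \code{\link{lsfm_scene}}.
#' @param camera an \code{\link{ortho_camera}}.
#' @param filter an emission filter (default: unity -- purely fluorescent
#'   scenes have no elastic light to block).
#' @param seed RNG seed for the render.
#' @return a \code{spectral_film}.
#' @export
render_section <- function(scene, camera, filter = NULL, seed = 1L) {
  camera$focal_plane_z_um <- scene$sheet$z_um   # illumination/detection sync
  nx <- camera$resolution[1]; ny <- camera$resolution[2]
  npix <- nx * ny
  spp <- camera$samples_per_pixel
  nd <- length(scene$fluos$entries)
  base_px <- rep(seq_len(nx) - 1, times = ny)
  base_py <- rep(seq_len(ny) - 1, each = nx)
  sgn <- camera_sign(camera)
  mb <- march_bounds(scene$grid)
  origin_z <- if (sgn < 0) mb$hi[3] + scene$grid$voxel_size_um
              else mb$lo[3] - scene$grid$voxel_size_um
  Wsum <- matrix(0, npix, nd)
  Welsum <- numeric(npix)
  with_seed(seed, {
    for (s in seq_len(spp)) {
      px <- base_px + stats::runif(npix)
      py <- base_py + stats::runif(npix)
      lens <- if (camera$aperture_radius_um > 0)
        cbind(stats::runif(npix), stats::runif(npix)) else NULL
      rays <- generate_camera_ray(camera, cbind(px, py), lens,
                                  origin_z_um = origin_z)
      ju <- if (scene$settings$jitter) stats::runif(npix) else rep(0.5, npix)
      res <- march_rays(rays$origin, rays$direction, scene,
                        jitter_u = ju)
      Wsum <- Wsum + res$W
      Welsum <- Welsum + res$Wel
    }
  })
  vals <- weights_to_spd_values(scene, Wsum / spp, Welsum / spp)
  spd <- array(vals, dim = c(nx, ny, scene$spectral_grid$n_bins))
  film <- new_spectral_film(camera, scene$spectral_grid, spd,
                            meta = list(seed = seed, spp = spp,
                                        lambda_ex_nm = scene$sheet$lambda_ex_nm,
                                        sheet_z_um = scene$sheet$z_um,
                                        photons = scene$sheet$photons,
                                        axis = camera$axis))
  if (!is.null(filter)) film <- apply_emission_filter(film, filter)
  film
}

#' Total detected photons on the film
#'
#' The double midpoint sum over the detector surface and the visible
#' wavelength range: per-pixel spectral values times pixel area (cm^2) times
#' bin width (nm), summed. Linear in the film values.
#'
#' @param film a \code{spectral_film}.
#' @return photon count.
#' @export
detect_photons <- function(film) {
  sum(film$spd) * film$pixel_area_cm2 * film$spectral_grid$step_nm
}

#' Per-pixel photon image
#'
#' Collapses the spectral film to a pixel matrix of photon counts
#' (spectral integral times pixel area).
#'
#' @param film a \code{spectral_film}.
#' @return nx x ny numeric matrix.
#' @export
film_photon_image <- function(film) {
  apply(film$spd, c(1, 2), sum) * film$pixel_area_cm2 * film$spectral_grid$step_nm
}

#' Pixel-summed spectral distribution of a film
#'
#' The SPD measured over the whole detector: per-bin sum across pixels times
#' pixel area, in photons per nm.
#'
#' @param film a \code{spectral_film}.
#' @return a \code{\link{spectral_distribution}}.
#' @export
film_spd <- function(film) {
  spectral_distribution(film$spectral_grid,
                        apply(film$spd, 3, sum) * film$pixel_area_cm2)
}

# crude emission-peak wavelength (nm) to RGB lookup for pseudocolor previews;
# piecewise-linear visible-spectrum ramp, not colorimetric
wavelength_to_rgb <- function(lambda_nm) {
  r <- g <- b <- numeric(length(lambda_nm))
  l <- lambda_nm
  i <- l >= 380 & l < 440; r[i] <- (440 - l[i]) / 60; b[i] <- 1
  i <- l >= 440 & l < 490; g[i] <- (l[i] - 440) / 50; b[i] <- 1
  i <- l >= 490 & l < 510; g[i] <- 1; b[i] <- (510 - l[i]) / 20
  i <- l >= 510 & l < 580; r[i] <- (l[i] - 510) / 70; g[i] <- 1
  i <- l >= 580 & l < 645; r[i] <- 1; g[i] <- (645 - l[i]) / 65
  i <- l >= 645 & l <= 780; r[i] <- 1
  cbind(r, g, b)
}

#' Develop a spectral film into a raster image
#'
#' \code{"photon_sum_gray16"}: the per-pixel photon integral linearly scaled
#' into [0, 1] by \code{max_value} (recorded in the \code{scale} attribute,
#' so \code{gray * scale} recovers photons up to 16-bit quantization when
#' written). \code{"pseudocolor"}: intensity times an RGB hue from the
#' per-pixel mean detected wavelength.
#'
#' @param film a \code{spectral_film}.
#' @param mode \code{"photon_sum_gray16"} or \code{"pseudocolor"}.
#' @param max_value scaling maximum (default: the film's max pixel photons).
#' @return a matrix (gray) or nx x ny x 3 array (pseudocolor) in [0, 1], with
#'   attributes \code{scale} and \code{mode}.
#' @export
develop_image <- function(film, mode = c("photon_sum_gray16", "pseudocolor"),
                          max_value = NULL) {
  mode <- match.arg(mode)
  img <- film_photon_image(film)
  if (is.null(max_value)) max_value <- max(img, 1e-300)
  out <- pmin(img / max_value, 1)
  if (mode == "pseudocolor") {
    ctr <- wl_centers(film$spectral_grid)
    tot <- apply(film$spd, c(1, 2), sum)
    wmean <- apply(sweep(film$spd, 3, ctr, `*`), c(1, 2), sum) / pmax(tot, 1e-300)
    rgbv <- wavelength_to_rgb(as.vector(wmean))
    out <- array(as.vector(out) * rgbv, dim = c(dim(img), 3))
  }
  attr(out, "scale") <- max_value
  attr(out, "mode") <- mode
  out
}
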