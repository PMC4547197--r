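#' Light sheet model
#'
#' The illumination unit is modeled directly by its product: a thin
#' rectangular directional slab of single-wavelength light propagating along
#' +x, uniform across its cross-section (the rectangular approximation of a
#' focused Gaussian beam near its waist). The slab is bounded in z (thickness,
#' centered on \code{z_um}, which doubles as the focal plane of the detection
#' camera) and in y (height, centered on y = 0); \code{photons} is the photon
#' budget delivered during one exposure (one rendered optical section).
#'
#' @param thickness_um slab extent along the detection axis z (um).
#' @param height_um slab extent along y (um).
#' @param lambda_ex_nm excitation (laser line) wavelength (nm).
#' @param photons photon budget per exposure.
#' @param z_um world z of the sheet center = camera focal plane (um).
#' @param attenuate if \code{TRUE}, apply Beer-Lambert attenuation of the
#'   sheet along +x through the specimen (off by default: validation assumes
#'   uniform, maximal excitation of an optically thin specimen).
#' @return an object of class \code{light_sheet}.
#' @export
light_sheet <- function(thickness_um, height_um, lambda_ex_nm, photons,
                        z_um = 0, attenuate = FALSE) {
  stopifnot(thickness_um > 0, height_um > 0, lambda_ex_nm > 0, photons >= 0)
  structure(list(thickness_um = thickness_um, height_um = height_um,
                 lambda_ex_nm = lambda_ex_nm, photons = photons,
                 z_um = z_um, attenuate = isTRUE(attenuate),
                 direction = c(1, 0, 0)),
            class = "light_sheet")
}

#' @export
print.light_sheet <- function(x, ...) {
  cat(sprintf("<light_sheet> %g um thick x %g um high, %g nm, %.3g photons, z = %g um%s\n",
              x$thickness_um, x$height_um, x$lambda_ex_nm, x$photons, x$z_um,
              if (x$attenuate) " (attenuated)" else ""))
  invisible(x)
}

#' Photon flux density of the sheet at world points
#'
#' Inside the slab the flux density is \code{photons / A} with
#' \code{A = thickness x height} in cm^2 (uniform illumination profile);
#' outside it is 0. With \code{attenuate = TRUE} the flux is reduced by
#' Beer-Lambert attenuation \code{exp(-integral of sigma_t ds)} accumulated
#' along +x from the specimen entry face to the point, at the excitation
#' wavelength.
#'
#' @param sheet a \code{\link{light_sheet}}.
#' @param pts n x 3 matrix (or length-3 vector) of world points (um).
#' @param scene optional \code{\link{lsfm_scene}}; required when
#'   \code{sheet$attenuate} is \code{TRUE}.
#' @param step_um marching step for the attenuation line integral (um).
#' @return photon flux density (photons cm^-2) per point.
#' @export
sheet_flux_density <- function(sheet, pts, scene = NULL, step_um = NULL) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  area_cm2 <- um_to_cm(sheet$thickness_um) * um_to_cm(sheet$height_um)
  inside <- abs(pts[, 3] - sheet$z_um) <= sheet$thickness_um / 2 &
            abs(pts[, 2]) <= sheet$height_um / 2
  flux <- ifelse(inside, sheet$photons / area_cm2, 0)
  if (sheet$attenuate && any(inside)) {
    if (is.null(scene)) stop("sheet_flux_density: attenuation requires a scene")
    if (is.null(step_um)) step_um <- scene$settings$step_um
    x0 <- scene$grid$origin_um[1] - scene$grid$voxel_size_um / 2
    tr <- rep(1, nrow(pts))
    idx <- which(inside & pts[, 1] > x0)
    if (length(idx)) {
      p1 <- pts[idx, , drop = FALSE]
      p0 <- p1; p0[, 1] <- x0
      tr[idx] <- transmittance_batch(p0, p1, sheet$lambda_ex_nm, scene,
                                     step_um, path = "excitation")
    }
    flux <- flux * tr
  }
  flux
}

#' Gaussian beam thickness profile
#'
#' The hyperbolic half-thickness of a focused Gaussian beam,
#' \eqn{w(x) = w_0 \sqrt{1 + (x/x_R)^2}}, with Rayleigh range
#' \eqn{x_R = \pi w_0^2 n / \lambda} (n = 1). Quantifies how quickly the
#' sheet diverges away from its waist: one Rayleigh range out, the beam is
#' \eqn{\sqrt 2} (41\%) thicker.
#'
#' @param w0_um beam waist half-thickness (um).
#' @param lambda_nm wavelength (nm).
#' @return an object of class \code{gaussian_beam} with the derived
#'   \code{rayleigh_range_um}.
#' @export
gaussian_beam <- function(w0_um, lambda_nm) {
  stopifnot(w0_um > 0, lambda_nm > 0)
  structure(list(w0_um = w0_um, lambda_nm = lambda_nm,
                 rayleigh_range_um = pi * w0_um^2 / (lambda_nm * 1e-3)),
            class = "gaussian_beam")
}

#' @param beam a \code{\link{gaussian_beam}}.
#' @param x_um distance from the waist along propagation (um), vectorized.
#' @return half-thickness w(x) in um.
#' @rdname gaussian_beam
#' @export
gaussian_thickness <- function(beam, x_um) {
  beam$w0_um * sqrt(1 + (x_um / beam$rayleigh_range_um)^2)
}

#' Error of the uniform-slab approximation over a field of view
#'
#' Maximum relative thickness deviation of the real Gaussian profile from the
#' waist thickness over |x| <= fov/2: \code{(w(fov/2) - w0) / w0}. Reaches
#' the characteristic 41\% (sqrt(2) - 1) when the field of view spans two
#' Rayleigh ranges; beyond that the rectangular sheet model is a poor stand-in
#' for the diverging beam.
#'
#' @param beam a \code{\link{gaussian_beam}}.
#' @param fov_um field of view along propagation (um), > 0.
#' @return maximum relative thickness deviation (dimensionless).
#' @export
rectangular_approximation_error <- function(beam, fov_um) {
  stopifnot(fov_um > 0)
  (gaussian_thickness(beam, fov_um / 2) - beam$w0_um) / beam$w0_um
}
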