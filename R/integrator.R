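#' Ray and marching settings
#'
#' @param origin world point (um).
#' @param direction direction vector (normalized internally).
#' @param tmin,tmax parametric interval (um along the ray), half-open.
#' @return an object of class \code{lsfm_ray}.
#' @export
make_ray <- function(origin, direction, tmin = 0, tmax = Inf) {
  stopifnot(length(origin) == 3, length(direction) == 3, tmin < tmax)
  if (sum(direction^2) == 0) stop("make_ray: zero direction")
  structure(list(origin = as.numeric(origin), direction = norm_vec(direction),
                 tmin = tmin, tmax = tmax), class = "lsfm_ray")
}

#' @param step_um base marching step (um); the grid default is half a voxel.
#' @param jitter stratified per-ray offset of the march samples (decorrelates
#'   banding); when off, midpoint sampling is used.
#' @param seed RNG seed used when jitter is drawn outside a render loop.
#' @rdname make_ray
#' @export
march_settings <- function(step_um, jitter = TRUE, seed = 1L) {
  stopifnot(step_um > 0)
  structure(list(step_um = step_um, jitter = isTRUE(jitter),
                 seed = as.integer(seed)), class = "march_settings")
}

#' Assemble a renderable scene
#'
#' Binds a specimen grid, its fluorophore table, the light sheet and the
#' marching settings, and precomputes the per-dye quantities the integrator
#' consumes: the excitation efficiency at the laser line
#' \eqn{f_{ex}(\lambda_{ex})}, the emission spectrum values per bin, and the
#' effective reabsorption factor
#' \eqn{\kappa = \int f_{ex,rel}(\lambda) f_{em}(\lambda) d\lambda}
#' used for wavelength-flat camera-path extinction (emission mostly lies
#' red of the absorption band, so \eqn{\kappa} is well below 1).
#'
#' @param grid a \code{\link{fluor_volume}}.
#' @param fluos a \code{\link{fluorophore_table}}; every dye index used by the
#'   grid must resolve into it.
#' @param sheet a \code{\link{light_sheet}}.
#' @param settings \code{\link{march_settings}}; default step is half a voxel.
#' @param attenuation \code{"camera"} (default) applies Beer-Lambert
#'   extinction along the detection path; \code{"none"} disables it (the
#'   closed-form oracles assume a non-attenuating medium).
#' @param spectral_grid wavelength grid for film accumulation; defaults to
#'   the fluorophore grid.
#' @return an object of class \code{lsfm_scene}.
#' @export
lsfm_scene <- function(grid, fluos, sheet,
                       settings = march_settings(grid$voxel_size_um / 2),
                       attenuation = c("camera", "none"),
                       spectral_grid = NULL) {
  stopifnot(inherits(grid, "fluor_volume"), inherits(fluos, "fluorophore_table"),
            inherits(sheet, "light_sheet"))
  attenuation <- match.arg(attenuation)
  used <- sort(unique(grid$dye_index[grid$dye_index >= 0]))
  if (length(used) && max(used) >= length(fluos$entries))
    stop(sprintf("lsfm_scene: grid references dye index %d but table has %d entries",
                 max(used), length(fluos$entries)))
  wg <- if (is.null(spectral_grid)) fluos$entries[[1]]$f_em$grid else spectral_grid
  nd <- length(fluos$entries)
  dye <- list(
    sigma_cm2 = vapply(fluos$entries, function(e) e$sigma_cm2, numeric(1)),
    phi       = vapply(fluos$entries, function(e) e$phi, numeric(1)),
    fex_at_ex = vapply(fluos$entries, function(e)
      spd_value_at(e$f_ex, sheet$lambda_ex_nm), numeric(1)),
    kappa     = vapply(fluos$entries, function(e)
      sum(e$f_ex$values * e$f_em$values) * e$f_em$grid$step_nm, numeric(1)),
    f_em      = t(vapply(fluos$entries, function(e)
      spd_value_at(e$f_em, wl_centers(wg)), numeric(wg$n_bins))))
  dim(dye$f_em) <- c(nd, wg$n_bins)
  # zero-padded density corner array: lets the marching sampler interpolate
  # without per-corner bounds checks (padding realizes the zero boundary)
  pd <- grid$dims + 2L
  pad <- array(0, dim = pd)
  pad[2:(pd[1] - 1), 2:(pd[2] - 1), 2:(pd[3] - 1)] <- grid$density
  structure(list(grid = grid, fluos = fluos, sheet = sheet,
                 settings = settings, attenuation = attenuation,
                 spectral_grid = wg, dye = dye,
                 pad_density = as.vector(pad), pad_dims = pd),
            class = "lsfm_scene")
}

#' @export
print.lsfm_scene <- function(x, ...) {
  cat("<lsfm_scene>\n")
  print(x$grid); print(x$fluos); print(x$sheet)
  cat(sprintf("  marching step %g um (jitter %s); %s-path attenuation\n",
              x$settings$step_um, x$settings$jitter, x$attenuation))
  invisible(x)
}

#' Isotropic and Henyey-Greenstein phase functions
#'
#' Angular distributions of scattered light, normalized to 1 over the sphere.
#' Fluorescence emission is isotropic (constant 1/4pi); the elastic term uses
#' Henyey-Greenstein with anisotropy g, which reduces to isotropic at g = 0.
#'
#' @param omega_in,omega_out unit vectors: incoming propagation and outgoing
#'   scattering directions.
#' @return phase function value (sr^-1).
#' @export
phase_isotropic <- function(omega_in = NULL, omega_out = NULL) 1 / (4 * pi)

#' @param g Henyey-Greenstein anisotropy, |g| < 1.
#' @rdname phase_isotropic
#' @export
phase_hg <- function(omega_in, omega_out, g) {
  if (abs(g) >= 1) stop("phase_hg: |g| must be < 1")
  hg_phase(sum(norm_vec(omega_in) * norm_vec(omega_out)), g)
}

hg_phase <- function(cos_theta, g) {
  (1 - g^2) / (4 * pi * (1 + g^2 - 2 * g * cos_theta)^1.5)
}

# --- extinction model -------------------------------------------------------

# sigma_t (cm^-1) at world points. path = "excitation": elastic scattering
# plus fluorophore absorption sigma * N * f_ex,rel(lambda). path = "camera":
# elastic scattering plus the wavelength-flat effective reabsorption
# sigma * N * kappa (see lsfm_scene).
extinction_at <- function(scene, pts, lambda_nm, path = c("excitation", "camera")) {
  path <- match.arg(path)
  if (scene$attenuation == "none" && path == "camera")
    return(numeric(nrow(pts)))
  dens <- trilinear_sample(scene$grid, pts)
  dyei <- clamped_dye(scene$grid, pts)
  medium <- dyei >= 0
  sig <- scene$grid$sigma_s_elastic * as.numeric(medium)
  idx <- which(medium & dens > 0)
  if (length(idx)) {
    d1 <- dyei[idx] + 1L
    absfac <- if (path == "camera") {
      scene$dye$kappa[d1]
    } else {
      fex_l <- vapply(scene$fluos$entries, function(e)
        spd_value_at(e$f_ex, lambda_nm), numeric(1))
      fex_l[d1]
    }
    sig[idx] <- sig[idx] + scene$dye$sigma_cm2[d1] * dens[idx] * absfac
  }
  sig
}

# --- ray / AABB intersection (vectorized) -----------------------------------

# marching domain: the grid AABB inflated by half a voxel, so that the
# zero-padded trilinear density profile is integrated over its full support
# and line integrals of voxelized solids are exact
march_bounds <- function(grid) {
  h <- grid$voxel_size_um / 2
  list(lo = grid$origin_um - h, hi = grid_max_um(grid) + h)
}

intersect_aabb <- function(o, d, lo, hi, tmin = 0, tmax = Inf) {
  t0 <- rep(tmin, nrow(o)); t1 <- rep(tmax, nrow(o))
  for (k in 1:3) {
    dk <- d[, k]; ok <- o[, k]
    par <- abs(dk) < 1e-12
    inv <- ifelse(par, Inf, 1 / dk)
    ta <- (lo[k] - ok) * inv
    tb <- (hi[k] - ok) * inv
    near <- pmin(ta, tb); far <- pmax(ta, tb)
    # parallel rays: inside the slab -> no constraint, outside -> miss
    miss_par <- par & (ok < lo[k] | ok > hi[k])
    near[par] <- -Inf; far[par] <- Inf
    t0 <- pmax(t0, near); t1 <- pmin(t1, far)
    t1[miss_par] <- -Inf
  }
  list(t0 = t0, t1 = t1, hit = t1 > t0)
}

# --- the marching engine ----------------------------------------------------

# fused specimen lookup for points guaranteed inside the marching domain:
# trilinear density from the zero-padded corner array (no bounds checks) and
# the clamped containing-voxel dye index
march_sample <- function(scene, px, py, pz) {
  g <- scene$grid
  vs <- g$voxel_size_um
  d <- g$dims
  ux <- (px - g$origin_um[1]) / vs
  uy <- (py - g$origin_um[2]) / vs
  uz <- (pz - g$origin_um[3]) / vs
  i1 <- pmin.int(pmax.int(floor(ux), 0), d[1] - 1L)
  i2 <- pmin.int(pmax.int(floor(uy), 0), d[2] - 1L)
  i3 <- pmin.int(pmax.int(floor(uz), 0), d[3] - 1L)
  dye <- g$dye_index[i1 + i2 * d[1] + i3 * (d[1] * d[2]) + 1]
  cx <- ux - 0.5; j1 <- floor(cx); f1 <- cx - j1
  cy <- uy - 0.5; j2 <- floor(cy); f2 <- cy - j2
  cz <- uz - 0.5; j3 <- floor(cz); f3 <- cz - j3
  s2 <- scene$pad_dims[1]
  s3 <- scene$pad_dims[1] * scene$pad_dims[2]
  # corner j (0-based grid voxel) sits at padded 1-based index j + 2
  l0 <- (j1 + 2) + (j2 + 1) * s2 + (j3 + 1) * s3
  P <- scene$pad_density
  g1 <- 1 - f1; g2 <- 1 - f2; g3 <- 1 - f3
  dens <-
    g3 * (g2 * (g1 * P[l0]           + f1 * P[l0 + 1]) +
          f2 * (g1 * P[l0 + s2]      + f1 * P[l0 + s2 + 1])) +
    f3 * (g2 * (g1 * P[l0 + s3]      + f1 * P[l0 + s3 + 1]) +
          f2 * (g1 * P[l0 + s3 + s2] + f1 * P[l0 + s3 + s2 + 1]))
  list(dens = dens, dye = dye)
}

# Batch single-scattering march. o, d: n x 3 matrices (d unit rows).
# Returns per-ray per-dye fluorescence path weights W (n x n_dyes) such that
# the spectral radiance is W %*% f_em, plus the elastic weight Wel (n) carried
# at the excitation wavelength. Weight units: photons cm^-2 sr^-1 (the per-nm
# factor enters through f_em).
march_rays <- function(o, d, scene, settings = scene$settings,
                       jitter_u = NULL, tmin = 0, tmax = Inf) {
  n <- nrow(o)
  nd <- length(scene$fluos$entries)
  W <- matrix(0, n, nd)
  Wel <- numeric(n)
  mb <- march_bounds(scene$grid)
  hit <- intersect_aabb(o, d, mb$lo, mb$hi, tmin, tmax)
  idx <- which(hit$hit)
  if (!length(idx)) return(list(W = W, Wel = Wel))
  if (is.null(jitter_u))
    jitter_u <- if (settings$jitter) stats::runif(n) else rep(0.5, n)
  # work only on rays that intersect the marching domain
  ox <- o[idx, 1]; oy <- o[idx, 2]; oz <- o[idx, 3]
  dx <- d[idx, 1]; dy <- d[idx, 2]; dz <- d[idx, 3]
  t0 <- hit$t0[idx]
  len <- hit$t1[idx] - t0
  nsteps <- pmax.int(1, ceiling(len / settings$step_um))
  dt <- len / nsteps
  ju <- jitter_u[idx]
  dt_cm <- um_to_cm(dt)
  sheet <- scene$sheet
  g <- scene$grid
  sheet_flux0 <- sheet$photons /
    (um_to_cm(sheet$thickness_um) * um_to_cm(sheet$height_um))
  half_t <- sheet$thickness_um / 2
  half_h <- sheet$height_um / 2
  atten_cam <- scene$attenuation == "camera"
  # cosine between sheet propagation (+x) and the outgoing (toward-camera)
  # direction -omega for the elastic phase term
  phase_el <- hg_phase(-dx, g$phase_g)
  sse <- g$sigma_s_elastic
  na <- length(idx)
  Wa <- matrix(0, na, nd)
  Wela <- numeric(na)
  tau <- numeric(na)
  inv4pi <- 1 / (4 * pi)
  sig_d <- scene$dye$sigma_cm2
  kap_d <- scene$dye$kappa
  amp_d <- inv4pi * scene$dye$sigma_cm2 * scene$dye$phi * scene$dye$fex_at_ex
  for (k in seq_len(max(nsteps))) {
    run <- k <= nsteps
    # rays whose march has ended stay clamped inside the domain; their
    # contribution is zeroed through `run`
    t_k <- t0 + pmin((k - 1 + ju) * dt, len * (1 - 1e-12))
    px <- ox + dx * t_k; py <- oy + dy * t_k; pz <- oz + dz * t_k
    smp <- march_sample(scene, px, py, pz)
    dens <- smp$dens
    dyei <- smp$dye
    if (sheet$attenuate) {
      flux <- sheet_flux_density(sheet, cbind(px, py, pz), scene = scene)
    } else {
      flux <- sheet_flux0 *
        ((abs(pz - sheet$z_um) <= half_t) & (abs(py) <= half_h))
    }
    inmed <- dyei >= 0L
    if (atten_cam) {
      i1 <- pmax.int(dyei, 0L) + 1L
      sig <- (sse + sig_d[i1] * kap_d[i1] * dens) * inmed
      seg_tau <- sig * dt_cm * run
      Tcam <- exp(-(tau + 0.5 * seg_tau))
      tau <- tau + seg_tau
      base <- Tcam * flux * dt_cm * run
    } else {
      base <- flux * dt_cm * run
    }
    lum <- which(inmed & dens > 0 & base > 0)
    if (length(lum)) {
      d1 <- dyei[lum] + 1L
      w <- amp_d[d1] * dens[lum] * base[lum]
      if (nd == 1L) Wa[lum, 1L] <- Wa[lum, 1L] + w
      else {
        ij <- cbind(lum, d1)
        Wa[ij] <- Wa[ij] + w
      }
    }
    if (sse > 0) {
      el <- which(inmed & base > 0)
      if (length(el))
        Wela[el] <- Wela[el] + sse * phase_el[el] * base[el]
    }
  }
  W[idx, ] <- Wa
  Wel[idx] <- Wela
  list(W = W, Wel = Wel)
}

# expand marching weights into per-bin spectral values (photons cm^-2 sr^-1
# nm^-1): fluorescence distributes over f_em; the monochromatic elastic
# weight is bin-averaged into the excitation bin
weights_to_spd_values <- function(scene, W, Wel) {
  vals <- W %*% scene$dye$f_em
  exbin <- wl_bin(scene$spectral_grid, scene$sheet$lambda_ex_nm)
  if (!is.na(exbin) && any(Wel > 0))
    vals[, exbin] <- vals[, exbin] + Wel / scene$spectral_grid$step_nm
  vals
}

#' Beer-Lambert transmittance along a segment
#'
#' \code{exp(-integral of sigma_t ds)} between two world points, evaluated by
#' midpoint ray marching of the scene's extinction coefficient at the given
#' wavelength; 1 in vacuum, multiplicative over concatenated segments up to
#' quadrature tolerance.
#'
#' @param p0,p1 world points (um).
#' @param lambda_nm wavelength (nm).
#' @param scene an \code{\link{lsfm_scene}}.
#' @param step_um marching step (default: scene setting).
#' @param path \code{"excitation"} or \code{"camera"} extinction model.
#' @return transmittance in [0, 1].
#' @export
transmittance <- function(p0, p1, lambda_nm, scene, step_um = NULL,
                          path = "excitation") {
  transmittance_batch(matrix(p0, ncol = 3), matrix(p1, ncol = 3),
                      lambda_nm, scene, step_um, path)
}

transmittance_batch <- function(p0, p1, lambda_nm, scene, step_um = NULL,
                                path = "excitation") {
  if (is.null(step_um)) step_um <- scene$settings$step_um
  seg <- p1 - p0
  len <- sqrt(rowSums(seg^2))
  tau <- numeric(nrow(p0))
  pos <- len > 0
  if (any(pos)) {
    nsteps <- pmax(1, ceiling(len / step_um))
    dt <- ifelse(pos, len / nsteps, 0)
    dirn <- seg / ifelse(len > 0, len, 1)
    for (k in seq_len(max(nsteps))) {
      act <- pos & k <= nsteps
      if (!any(act)) break
      p <- p0 + dirn * (k - 0.5) * dt
      sig <- extinction_at(scene, p, lambda_nm, path = path)
      tau <- tau + ifelse(act, sig * um_to_cm(dt), 0)
    }
  }
  exp(-tau)
}

#' Source term of the fluorescence-extended transfer equation
#'
#' The radiant source at a point for light leaving along \code{omega},
#' specialized to the monochromatic directional sheet: at a fluorescent point
#' the inelastic term is
#' \deqn{\frac{1}{4\pi}\,\sigma N(p)\,\phi\,f_{ex}(\lambda_{ex})\,
#'       f_{em}(\lambda)\,\Phi(p)}
#' with \eqn{\Phi} the sheet flux density; at a non-fluorescent medium point
#' the elastic term contributes \eqn{\sigma_s\,p(\omega',\omega)\,\Phi(p)} at
#' the excitation wavelength only (bin-averaged into the excitation bin).
#' Self-emission is zero (no self-emissive media).
#'
#' @param p world point (um).
#' @param omega outgoing direction (toward the detector).
#' @param scene an \code{\link{lsfm_scene}}.
#' @return a \code{\link{spectral_distribution}} of the source
#'   (photons cm^-3 sr^-1 nm^-1).
#' @export
source_term <- function(p, omega, scene) {
  p <- matrix(p, ncol = 3)
  omega <- norm_vec(omega)
  dens <- trilinear_sample(scene$grid, p)
  dyei <- sample_dye(scene$grid, p)
  flux <- sheet_flux_density(scene$sheet, p, scene = scene)
  vals <- numeric(scene$spectral_grid$n_bins)
  if (dyei[1] >= 0 && dens[1] > 0 && flux[1] > 0) {
    d1 <- dyei[1] + 1L
    vals <- vals + (1 / (4 * pi)) * scene$dye$sigma_cm2[d1] * dens[1] *
      scene$dye$phi[d1] * scene$dye$fex_at_ex[d1] * flux[1] *
      scene$dye$f_em[d1, ]
  }
  if (dyei[1] >= 0 && scene$grid$sigma_s_elastic > 0 && flux[1] > 0) {
    cos_el <- sum(scene$sheet$direction * omega)
    exbin <- wl_bin(scene$spectral_grid, scene$sheet$lambda_ex_nm)
    if (!is.na(exbin))
      vals[exbin] <- vals[exbin] + scene$grid$sigma_s_elastic *
        hg_phase(cos_el, scene$grid$phase_g) * flux[1] /
        scene$spectral_grid$step_nm
  }
  spectral_distribution(scene$spectral_grid, vals)
}

#' Integrate the transfer equation along one camera ray
#'
#' Single-scattering ray marching: at each step the source term is attenuated
#' by the transmittance back to the ray origin and accumulated,
#' \eqn{L(\lambda) = \sum_i T(p_i) S(p_i, \omega, \lambda) \Delta s}.
#' Deterministic for a fixed seed; converges to the continuous line integral
#' as the step shrinks.
#'
#' @param ray a \code{\link{make_ray}}.
#' @param scene an \code{\link{lsfm_scene}}.
#' @param settings optional \code{\link{march_settings}} override.
#' @return a \code{\link{spectral_distribution}}: spectral radiance arriving
#'   at the ray origin from along the ray (photons cm^-2 sr^-1 nm^-1).
#' @export
integrate_ray <- function(ray, scene, settings = scene$settings) {
  u <- if (settings$jitter) with_seed(settings$seed, stats::runif(1)) else NULL
  res <- march_rays(matrix(ray$origin, 1), matrix(ray$direction, 1), scene,
                    settings, jitter_u = u, tmin = ray$tmin, tmax = ray$tmax)
  spectral_distribution(scene$spectral_grid,
                        weights_to_spd_values(scene, res$W, res$Wel)[1, ])
}
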