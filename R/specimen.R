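#' Annotated fluorescent volume grid
#'
#' The virtual specimen: an axis-aligned voxel grid storing at each voxel the
#' fluorophore concentration (molecules cm^-3) and an integer dye index into a
#' \code{\link{fluorophore_table}} (-1 = non-fluorescent). Geometry is in
#' micrometres in a right-handed world frame: the light sheet propagates
#' along +x, spans y, and the detection axis is z. Voxel i (0-based) covers
#' the half-open interval [origin + i*voxel_size, origin + (i+1)*voxel_size).
#'
#' @param dims integer voxel counts \code{c(nx, ny, nz)}.
#' @param voxel_size_um isotropic voxel edge length (um).
#' @param origin_um world position (um) of the grid's minimum corner.
#' @param density 3-d array \code{dims} of concentrations (cm^-3), or a scalar.
#' @param dye_index 3-d integer array of dye indices (-1 = none), or a scalar.
#' @param sigma_s_elastic global elastic scattering coefficient of the medium
#'   (cm^-1), applied wherever the specimen is present.
#' @param phase_g Henyey-Greenstein anisotropy of the elastic term, |g| < 1.
#' @return an object of class \code{fluor_volume}.
#' @export
fluor_volume <- function(dims, voxel_size_um, origin_um = -dims * voxel_size_um / 2,
                         density = 0, dye_index = -1L,
                         sigma_s_elastic = 0, phase_g = 0) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1), voxel_size_um > 0,
            length(origin_um) == 3, sigma_s_elastic >= 0, abs(phase_g) < 1)
  if (length(density) == 1) density <- array(density, dim = dims)
  if (length(dye_index) == 1) dye_index <- array(as.integer(dye_index), dim = dims)
  storage.mode(dye_index) <- "integer"
  if (!identical(dim(density), dims) || !identical(dim(dye_index), dims))
    stop("fluor_volume: density and dye_index must have dim = dims")
  if (any(density < 0)) stop("fluor_volume: density must be non-negative")
  if (any(density > 0 & dye_index < 0))
    stop("fluor_volume: fluorescent voxels (density > 0) must carry a dye index >= 0")
  structure(list(dims = dims, voxel_size_um = voxel_size_um,
                 origin_um = as.numeric(origin_um),
                 density = density, dye_index = dye_index,
                 sigma_s_elastic = sigma_s_elastic, phase_g = phase_g),
            class = "fluor_volume")
}

#' @export
print.fluor_volume <- function(x, ...) {
  cat(sprintf("<fluor_volume> %dx%dx%d voxels @ %g um, origin (%g, %g, %g) um\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size_um,
              x$origin_um[1], x$origin_um[2], x$origin_um[3]))
  cat(sprintf("  fluorescent fill: %.3g%%; dyes used: %s; sigma_s_elastic = %g cm^-1\n",
              100 * mean(x$dye_index >= 0),
              paste(sort(unique(x$dye_index[x$dye_index >= 0])), collapse = ","),
              x$sigma_s_elastic))
  invisible(x)
}

grid_max_um <- function(grid) grid$origin_um + grid$dims * grid$voxel_size_um

#' Homogeneous cube phantom
#'
#' A uniformly labeled cube centered at the world origin (the intersection of
#' the illumination and detection axes) -- the specimen used by the
#' fluorescence-brightness validation experiment.
#'
#' @param side_um cube edge length (um); must be an integer multiple of
#'   \code{voxel_size_um}.
#' @param density_cm3 fluorophore concentration (cm^-3).
#' @param voxel_size_um voxel edge (um).
#' @param dye_index dye table index for every voxel (default 0).
#' @param sigma_s_elastic elastic scattering coefficient (cm^-1).
#' @return a \code{\link{fluor_volume}}.
#' @export
make_homogeneous_cube <- function(side_um, density_cm3, voxel_size_um,
                                  dye_index = 0L, sigma_s_elastic = 0) {
  stopifnot(side_um > 0, density_cm3 >= 0, voxel_size_um > 0)
  n <- side_um / voxel_size_um
  if (abs(n - round(n)) > 1e-9)
    stop("make_homogeneous_cube: voxel_size_um must divide side_um")
  n <- as.integer(round(n))
  dye <- if (density_cm3 > 0) as.integer(dye_index) else -1L
  fluor_volume(c(n, n, n), voxel_size_um, origin_um = rep(-side_um / 2, 3),
               density = density_cm3, dye_index = dye,
               sigma_s_elastic = sigma_s_elastic)
}

#' Primitive shapes for solid voxelization
#'
#' @param center,radius sphere center (um, length-3) and radius (um).
#' @param density concentration contributed by the shape (cm^-3).
#' @param dye dye table index.
#' @return a shape description list.
#' @export
sphere_shape <- function(center, radius, density, dye = 0L) {
  stopifnot(length(center) == 3, radius > 0, density >= 0)
  list(type = "sphere", center = as.numeric(center), radius = radius,
       density = density, dye = as.integer(dye))
}

#' @param p0,p1 cylinder end points (um); \code{radius} its radius (um).
#' @rdname sphere_shape
#' @export
cylinder_shape <- function(p0, p1, radius, density, dye = 0L) {
  stopifnot(length(p0) == 3, length(p1) == 3, radius > 0, density >= 0)
  if (sum((p1 - p0)^2) == 0) stop("cylinder_shape: p0 and p1 must differ")
  list(type = "cylinder", p0 = as.numeric(p0), p1 = as.numeric(p1),
       radius = radius, density = density, dye = as.integer(dye))
}

shape_contains <- function(shape, X, Y, Z) {
  if (shape$type == "sphere") {
    (X - shape$center[1])^2 + (Y - shape$center[2])^2 + (Z - shape$center[3])^2 <=
      shape$radius^2
  } else {
    a <- shape$p0; d <- shape$p1 - shape$p0
    len2 <- sum(d^2)
    t <- ((X - a[1]) * d[1] + (Y - a[2]) * d[2] + (Z - a[3]) * d[3]) / len2
    px <- a[1] + t * d[1]; py <- a[2] + t * d[2]; pz <- a[3] + t * d[3]
    t >= 0 & t <= 1 &
      (X - px)^2 + (Y - py)^2 + (Z - pz)^2 <= shape$radius^2
  }
}

#' Solid voxelization of primitive shapes
#'
#' Converts spheres and capped cylinders into an annotated fluorescent volume
#' grid by the voxel-center inclusion test: a voxel is fluorescent iff its
#' center lies inside at least one shape. Overlaps: densities sum, the
#' last-listed shape wins the dye index.
#'
#' @param shapes list of \code{\link{sphere_shape}} / \code{cylinder_shape}.
#' @param voxel_size_um voxel edge (um).
#' @param bounds list with \code{min}, \code{max} world corners (um, length-3).
#' @param sigma_s_elastic elastic scattering coefficient (cm^-1).
#' @return a \code{\link{fluor_volume}}; an empty shape list yields an
#'   all-non-fluorescent grid.
#' @export
voxelize_primitives <- function(shapes, voxel_size_um, bounds,
                                sigma_s_elastic = 0) {
  lo <- as.numeric(bounds$min); hi <- as.numeric(bounds$max)
  stopifnot(length(lo) == 3, length(hi) == 3, all(hi > lo), voxel_size_um > 0)
  dims <- as.integer(ceiling((hi - lo) / voxel_size_um - 1e-9))
  ctr <- lapply(1:3, function(k) lo[k] + (seq_len(dims[k]) - 0.5) * voxel_size_um)
  X <- array(rep(ctr[[1]], times = dims[2] * dims[3]), dim = dims)
  Y <- array(rep(rep(ctr[[2]], each = dims[1]), times = dims[3]), dim = dims)
  Z <- array(rep(ctr[[3]], each = dims[1] * dims[2]), dim = dims)
  dens <- array(0, dim = dims)
  dye <- array(-1L, dim = dims)
  for (s in shapes) {
    inside <- shape_contains(s, X, Y, Z)
    dens[inside] <- dens[inside] + s$density
    dye[inside] <- s$dye
  }
  fluor_volume(dims, voxel_size_um, origin_um = lo, density = dens,
               dye_index = dye, sigma_s_elastic = sigma_s_elastic)
}

#' Synthetic neuron phantom
#'
#' A primitive-based stand-in for fluorescent-tagged neural tissue: each cell
#' is one soma sphere (radius drawn uniformly in 5--10 um) plus 3--8 neurites
#' modeled as chains of tapering capped cylinders following a random walk.
#' One dye is assigned per cell (cycling through \code{n_dyes}), mirroring
#' per-neuron fluorescent tagging. Deterministic for a fixed seed.
#'
#' @param n_cells number of cells, >= 1.
#' @param seed RNG seed.
#' @param bounds list with \code{min}, \code{max} world corners (um).
#' @param voxel_size_um voxel edge (um).
#' @param n_dyes number of dye indices to cycle over.
#' @param density_cm3 fluorophore concentration inside labeled structures.
#' @param sigma_s_elastic elastic scattering coefficient (cm^-1).
#' @return a \code{\link{fluor_volume}}.
#' @export
make_synthetic_neurons <- function(n_cells, seed, bounds, voxel_size_um = 1,
                                   n_dyes = 1L, density_cm3 = 1e18,
                                   sigma_s_elastic = 0) {
  stopifnot(n_cells >= 1)
  lo <- as.numeric(bounds$min); hi <- as.numeric(bounds$max)
  if (any(hi - lo < 2 * 10))
    stop("make_synthetic_neurons: bounds too small to place 10 um somata")
  shapes <- with_seed(seed, {
    out <- list()
    for (cell in seq_len(n_cells)) {
      dye <- (cell - 1L) %% as.integer(n_dyes)
      r_soma <- stats::runif(1, 5, 10)
      center <- vapply(1:3, function(k)
        stats::runif(1, lo[k] + r_soma, hi[k] - r_soma), numeric(1))
      out[[length(out) + 1L]] <- sphere_shape(center, r_soma, density_cm3, dye)
      for (nrt in seq_len(sample(3:8, 1))) {
        p <- center
        dir <- rand_unit_vector()
        r <- stats::runif(1, 1.0, 1.8)
        for (seg in seq_len(sample(4:10, 1))) {
          step <- stats::runif(1, 3, 6)
          q <- pmin(pmax(p + dir * step, lo + r), hi - r)
          if (sum((q - p)^2) > 1e-12)
            out[[length(out) + 1L]] <- cylinder_shape(p, q, r, density_cm3, dye)
          p <- q
          dir <- norm_vec(dir + 0.6 * rand_unit_vector())
          r <- max(0.4, r * stats::runif(1, 0.75, 0.95))
        }
      }
    }
    out
  })
  voxelize_primitives(shapes, voxel_size_um, bounds,
                      sigma_s_elastic = sigma_s_elastic)
}

# trilinear interpolation of voxel-center values with zero padding outside;
# pts is an n x 3 matrix of world positions (um)
trilinear_sample <- function(grid, pts) {
  vs <- grid$voxel_size_um
  d <- grid$dims
  u <- sweep(pts, 2, grid$origin_um) / vs - 0.5    # voxel-center coordinates
  i0 <- floor(u)
  f <- u - i0
  acc <- numeric(nrow(pts))
  strides <- c(1, d[1], d[1] * d[2])
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- i0[, 1] + dx; iy <- i0[, 2] + dy; iz <- i0[, 3] + dz
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    ok <- ix >= 0 & ix < d[1] & iy >= 0 & iy < d[2] & iz >= 0 & iz < d[3] & w > 0
    if (any(ok)) {
      lin <- ix[ok] + iy[ok] * strides[2] + iz[ok] * strides[3] + 1
      acc[ok] <- acc[ok] + w[ok] * grid$density[lin]
    }
  }
  acc
}

# nearest-voxel dye lookup clamped to the marching domain (grid AABB inflated
# by half a voxel, the support of the zero-padded trilinear density): points
# in the inflated shell read the boundary voxel's dye, points beyond read -1
clamped_dye <- function(grid, pts) {
  vs <- grid$voxel_size_um
  d <- grid$dims
  u <- sweep(pts, 2, grid$origin_um) / vs
  inside <- u[, 1] >= -0.5 & u[, 1] <= d[1] + 0.5 &
            u[, 2] >= -0.5 & u[, 2] <= d[2] + 0.5 &
            u[, 3] >= -0.5 & u[, 3] <= d[3] + 0.5
  i1 <- pmin(pmax(floor(u[, 1]), 0), d[1] - 1)
  i2 <- pmin(pmax(floor(u[, 2]), 0), d[2] - 1)
  i3 <- pmin(pmax(floor(u[, 3]), 0), d[3] - 1)
  out <- rep(-1L, nrow(pts))
  ok <- which(inside)
  if (length(ok))
    out[ok] <- grid$dye_index[i1[ok] + i2[ok] * d[1] + i3[ok] * d[1] * d[2] + 1]
  out
}

nearest_voxel_index <- function(grid, pts) {
  vs <- grid$voxel_size_um
  d <- grid$dims
  i <- floor(sweep(pts, 2, grid$origin_um) / vs)
  ok <- i[, 1] >= 0 & i[, 1] < d[1] & i[, 2] >= 0 & i[, 2] < d[2] &
        i[, 3] >= 0 & i[, 3] < d[3]
  lin <- rep(NA_integer_, nrow(pts))
  lin[ok] <- as.integer(i[ok, 1] + i[ok, 2] * d[1] + i[ok, 3] * d[1] * d[2] + 1)
  lin
}

#' Sample concentration and dye index at world points
#'
#' \code{sample_density} interpolates voxel-center concentrations trilinearly
#' (zero-padded outside the grid, so the profile tapers to 0 over half a voxel
#' beyond the boundary); \code{sample_dye} uses the nearest (containing)
#' voxel. Points outside the grid return density 0 and dye -1.
#'
#' @param grid a \code{\link{fluor_volume}}.
#' @param pts n x 3 matrix (or length-3 vector) of world points (um).
#' @return \code{sample_density}: concentrations (cm^-3);
#'   \code{sample_dye}: integer dye indices.
#' @export
sample_density <- function(grid, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  trilinear_sample(grid, pts)
}

#' @rdname sample_density
#' @export
sample_dye <- function(grid, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  lin <- nearest_voxel_index(grid, pts)
  out <- rep(-1L, nrow(pts))
  ok <- !is.na(lin)
  out[ok] <- grid$dye_index[lin[ok]]
  out
}

#' Total number of fluorophore molecules in a grid
#'
#' Sum of voxel concentration times voxel volume (with the um-to-cm unit
#' bridge); invariant under re-voxelization of the same solid.
#'
#' @param grid a \code{\link{fluor_volume}}.
#' @return molecule count.
#' @export
total_molecules <- function(grid) {
  sum(grid$density) * (grid$voxel_size_um * 1e-4)^3
}
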