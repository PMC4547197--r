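#' Wavelength grid
#'
#' A uniform wavelength discretization with bin centers at
#' \code{start_nm + (i - 0.5) * step_nm}. All spectral quantities in the
#' package (spectra, filters, film accumulators) live on a shared grid so that
#' bin-wise arithmetic is well defined. The default 300--800 nm range at 5 nm
#' resolution covers common laser lines (355--561 nm) and all visible
#' fluorescence emission.
#'
#' @param start_nm lower edge of the first bin (nm).
#' @param stop_nm upper edge of the last bin (nm); \code{stop_nm - start_nm}
#'   must be an integer multiple of \code{step_nm}.
#' @param step_nm bin width (nm).
#' @return an object of class \code{wavelength_grid} with fields
#'   \code{start_nm}, \code{stop_nm}, \code{step_nm}, \code{n_bins}.
#' @examples
#' g <- wavelength_grid(300, 800, 5)
#' g$n_bins          # 100
#' head(wl_centers(g))
#' @export
wavelength_grid <- function(start_nm = 300, stop_nm = 800, step_nm = 5) {
  if (!is.numeric(start_nm) || !is.numeric(stop_nm) || !is.numeric(step_nm))
    stop("wavelength_grid: numeric arguments required")
  if (step_nm <= 0) stop("wavelength_grid: step_nm must be > 0")
  if (start_nm >= stop_nm) stop("wavelength_grid: start_nm must be < stop_nm")
  n <- (stop_nm - start_nm) / step_nm
  if (abs(n - round(n)) > 1e-9)
    stop("wavelength_grid: (stop_nm - start_nm) must be an integer multiple of step_nm")
  structure(list(start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm,
                 n_bins = as.integer(round(n))),
            class = "wavelength_grid")
}

#' Bin center wavelengths of a grid
#' @param grid a \code{wavelength_grid}.
#' @return numeric vector of bin-center wavelengths (nm).
#' @export
wl_centers <- function(grid) {
  grid$start_nm + (seq_len(grid$n_bins) - 0.5) * grid$step_nm
}

#' Index of the bin containing a wavelength
#' @param grid a \code{wavelength_grid}.
#' @param lambda_nm wavelength (nm), vectorized.
#' @return integer bin indices; \code{NA} outside the grid.
#' @export
wl_bin <- function(grid, lambda_nm) {
  i <- floor((lambda_nm - grid$start_nm) / grid$step_nm) + 1
  i[lambda_nm < grid$start_nm | lambda_nm >= grid$stop_nm] <- NA_integer_
  as.integer(i)
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g-%g nm, step %g nm (%d bins)\n",
              x$start_nm, x$stop_nm, x$step_nm, x$n_bins))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(c(a$start_nm, a$stop_nm, a$step_nm),
                   c(b$start_nm, b$stop_nm, b$step_nm)))
}

#' Spectral distribution
#'
#' Per-wavelength-bin values on a \code{\link{wavelength_grid}}: the universal
#' currency for light in the simulator. Units are context dependent (photons,
#' photons per nm, or a dimensionless relative weight); integration is by the
#' midpoint rule, \code{sum(values) * step_nm}.
#'
#' @param grid a \code{wavelength_grid}.
#' @param values numeric vector of length \code{grid$n_bins}, all finite and
#'   non-negative.
#' @return an object of class \code{spectral_distribution}.
#' @export
spectral_distribution <- function(grid, values) {
  if (!inherits(grid, "wavelength_grid")) stop("spectral_distribution: grid must be a wavelength_grid")
  values <- as.numeric(values)
  if (length(values) != grid$n_bins)
    stop(sprintf("spectral_distribution: need %d values, got %d", grid$n_bins, length(values)))
  if (any(!is.finite(values))) stop("spectral_distribution: values must be finite")
  if (any(values < 0)) stop("spectral_distribution: values must be non-negative")
  structure(list(grid = grid, values = values), class = "spectral_distribution")
}

#' Integrate a spectral distribution over wavelength
#'
#' Midpoint-rule integral \code{sum(values) * step_nm}; linear in the values.
#'
#' @param spd a \code{spectral_distribution}.
#' @return scalar, in units of value x nm.
#' @export
spd_integrate <- function(spd) {
  sum(spd$values) * spd$grid$step_nm
}

#' Evaluate a spectral distribution at arbitrary wavelengths
#'
#' Linear interpolation between bin-center values; reads as 0 outside the
#' grid's center range (spectra are physically zero far from their bands).
#'
#' @param spd a \code{spectral_distribution}.
#' @param lambda_nm wavelengths (nm), vectorized.
#' @return interpolated values.
#' @export
spd_value_at <- function(spd, lambda_nm) {
  ctr <- wl_centers(spd$grid)
  out <- stats::approx(ctr, spd$values, xout = lambda_nm, rule = 1)$y
  out[is.na(out)] <- 0
  out
}

#' Normalize a spectral distribution
#'
#' \code{mode = "peak"} scales the maximum to 1 (excitation-spectrum
#' convention); \code{mode = "integral"} scales the wavelength integral to 1
#' (emission-spectrum convention, a probability density per nm).
#'
#' @param spd a \code{spectral_distribution}.
#' @param mode \code{"peak"} or \code{"integral"}.
#' @return normalized \code{spectral_distribution}.
#' @export
spd_normalize <- function(spd, mode = c("peak", "integral")) {
  mode <- match.arg(mode)
  s <- if (mode == "peak") max(spd$values) else spd_integrate(spd)
  if (s <= 0) stop("spd_normalize: cannot normalize an all-zero spectrum")
  spectral_distribution(spd$grid, spd$values / s)
}

#' @export
print.spectral_distribution <- function(x, ...) {
  cat(sprintf("<spectral_distribution> %d bins on %g-%g nm; integral = %.6g\n",
              x$grid$n_bins, x$grid$start_nm, x$grid$stop_nm, spd_integrate(x)))
  invisible(x)
}
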