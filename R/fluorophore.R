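#' Fluorophore definition
#'
#' Bundles the intrinsic photophysical characteristics a fluorescent dye
#' contributes to the source term: the relative excitation spectrum
#' \eqn{f_{ex}} (peak-normalized to 1, dimensionless efficiency), the emission
#' spectrum \eqn{f_{em}} (normalized to unit wavelength integral, a density
#' per nm), the quantum yield \eqn{\phi \in [0,1]} (emitted photons per
#' absorbed photon), and the molecular absorption cross section \eqn{\sigma}
#' in cm\eqn{^2} (with concentration N, the volume absorption coefficient is
#' \eqn{\sigma N} in cm\eqn{^{-1}}).
#'
#' @param name label, unique within a \code{\link{fluorophore_table}}.
#' @param f_ex excitation \code{\link{spectral_distribution}}.
#' @param f_em emission \code{\link{spectral_distribution}}.
#' @param phi quantum yield in [0, 1].
#' @param sigma_cm2 absorption cross section at the excitation peak (cm^2).
#' @param normalize if \code{TRUE} (default) apply the package conventions:
#'   peak-normalize \code{f_ex}, integral-normalize \code{f_em}.
#' @return an object of class \code{fluorophore}.
#' @export
fluorophore <- function(name, f_ex, f_em, phi, sigma_cm2, normalize = TRUE) {
  stopifnot(inherits(f_ex, "spectral_distribution"),
            inherits(f_em, "spectral_distribution"))
  if (!same_grid(f_ex$grid, f_em$grid))
    stop("fluorophore: f_ex and f_em must share one wavelength grid")
  if (!is.numeric(phi) || phi < 0 || phi > 1)
    stop("fluorophore: quantum yield phi must be in [0, 1]")
  if (!is.numeric(sigma_cm2) || sigma_cm2 <= 0)
    stop("fluorophore: sigma_cm2 must be > 0")
  if (normalize) {
    f_ex <- spd_normalize(f_ex, "peak")
    f_em <- spd_normalize(f_em, "integral")
  }
  if (max(f_ex$values) > 1 + 1e-9 || min(f_ex$values) < 0)
    stop("fluorophore: f_ex values must lie in [0, 1]")
  if (abs(spd_integrate(f_em) - 1) > 1e-6)
    stop("fluorophore: f_em must integrate to 1")
  structure(list(name = name, f_ex = f_ex, f_em = f_em,
                 phi = phi, sigma_cm2 = sigma_cm2),
            class = "fluorophore")
}

#' @export
print.fluorophore <- function(x, ...) {
  ctr <- wl_centers(x$f_ex$grid)
  cat(sprintf("<fluorophore> %s: ex peak %g nm, em peak %g nm, phi = %g, sigma = %g cm^2\n",
              x$name, ctr[which.max(x$f_ex$values)], ctr[which.max(x$f_em$values)],
              x$phi, x$sigma_cm2))
  invisible(x)
}

#' Excitation-peak wavelength of a fluorophore
#' @param fluo a \code{fluorophore}.
#' @return bin-center wavelength (nm) where \code{f_ex} is maximal.
#' @export
excitation_peak <- function(fluo) {
  wl_centers(fluo$f_ex$grid)[which.max(fluo$f_ex$values)]
}

#' Emission-peak wavelength of a fluorophore
#' @param fluo a \code{fluorophore}.
#' @return bin-center wavelength (nm) where \code{f_em} is maximal.
#' @export
emission_peak <- function(fluo) {
  wl_centers(fluo$f_em$grid)[which.max(fluo$f_em$values)]
}

#' Build a fluorophore from Gaussian mixture spectra
#'
#' Convenience generator for synthetic dyes: excitation and emission spectra
#' are sums of Gaussians (peak nm, width nm, relative weight), evaluated on
#' the grid and normalized per the package conventions.
#'
#' @param name label.
#' @param ex_peaks,ex_widths,ex_weights excitation mixture parameters (nm, nm,
#'   relative).
#' @param em_peaks,em_widths,em_weights emission mixture parameters.
#' @param phi quantum yield.
#' @param sigma_cm2 absorption cross section (cm^2).
#' @param grid wavelength grid.
#' @return a \code{\link{fluorophore}}.
#' @export
synthetic_fluorophore <- function(name, ex_peaks, ex_widths, ex_weights = 1,
                                  em_peaks, em_widths, em_weights = 1,
                                  phi, sigma_cm2, grid = wavelength_grid()) {
  mix <- function(peaks, widths, weights) {
    weights <- rep_len(weights, length(peaks))
    widths <- rep_len(widths, length(peaks))
    ctr <- wl_centers(grid)
    v <- numeric(grid$n_bins)
    for (i in seq_along(peaks))
      v <- v + weights[i] * exp(-0.5 * ((ctr - peaks[i]) / widths[i])^2)
    spectral_distribution(grid, v)
  }
  fluorophore(name,
              f_ex = mix(ex_peaks, ex_widths, ex_weights),
              f_em = mix(em_peaks, em_widths, em_weights),
              phi = phi, sigma_cm2 = sigma_cm2)
}

#' Bundled synthetic fluorophore fixtures
#'
#' GFP-, RFP- and CFP-like dyes assembled from the Gaussian-mixture spectrum
#' CSVs shipped under \code{inst/extdata}. These are synthetic
#' approximations with literature-plausible peak positions, quantum yields
#' and cross sections -- not measured database spectra -- and are intended as
#' self-contained test subjects; all experiments in the package are written
#' against whatever spectra are loaded, not against these shapes.
#'
#' @param which one of \code{"gfp"}, \code{"rfp"}, \code{"cfp"}.
#' @param grid wavelength grid to resample onto.
#' @return a \code{\link{fluorophore}}.
#' @export
fluorophore_fixture <- function(which = c("gfp", "rfp", "cfp"),
                                grid = wavelength_grid()) {
  which <- match.arg(which)
  pars <- list(
    gfp = list(phi = 0.60, sigma = 2.1e-16),
    rfp = list(phi = 0.25, sigma = 2.9e-16),
    cfp = list(phi = 0.40, sigma = 1.2e-16))
  exf <- system.file("extdata", sprintf("synthetic_%s_like_excitation.csv", which),
                     package = "lsfmsim", mustWork = TRUE)
  emf <- system.file("extdata", sprintf("synthetic_%s_like_emission.csv", which),
                     package = "lsfmsim", mustWork = TRUE)
  fluorophore(toupper(which),
              f_ex = read_spectrum_csv(exf, grid),
              f_em = read_spectrum_csv(emf, grid),
              phi = pars[[which]]$phi, sigma_cm2 = pars[[which]]$sigma)
}

#' Fluorophore lookup table
#'
#' Ordered list of fluorophores referenced by the per-voxel dye index of an
#' annotated fluorescent volume grid (index 0 = first entry).
#'
#' @param ... \code{\link{fluorophore}} objects (or a single list of them).
#' @return an object of class \code{fluorophore_table}.
#' @export
fluorophore_table <- function(...) {
  entries <- list(...)
  if (length(entries) == 1 && !inherits(entries[[1]], "fluorophore"))
    entries <- entries[[1]]
  if (!length(entries)) stop("fluorophore_table: at least one fluorophore required")
  for (e in entries)
    if (!inherits(e, "fluorophore")) stop("fluorophore_table: all entries must be fluorophores")
  nm <- vapply(entries, function(e) e$name, character(1))
  if (anyDuplicated(nm)) stop("fluorophore_table: fluorophore names must be unique")
  g <- entries[[1]]$f_em$grid
  for (e in entries)
    if (!same_grid(e$f_em$grid, g)) stop("fluorophore_table: all entries must share one grid")
  structure(list(entries = entries), class = "fluorophore_table")
}

#' @export
length.fluorophore_table <- function(x) length(x$entries)

#' @export
print.fluorophore_table <- function(x, ...) {
  cat(sprintf("<fluorophore_table> %d dye(s): %s\n", length(x$entries),
              paste(vapply(x$entries, function(e) e$name, character(1)), collapse = ", ")))
  invisible(x)
}
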