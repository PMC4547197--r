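#' Gaussian emission-line model (historical baseline)
#'
#' The normal-density emission function used by early ocean-water fluorescence
#' renderers: emission concentrated around a peak wavelength with a single
#' spectral width. Kept as the baseline the spectrum-driven model replaces.
#'
#' @param lambda_nm emission wavelength (nm), vectorized.
#' @param lambda0 peak emission wavelength (nm).
#' @param lambda_sigma spectral standard deviation (nm), > 0.
#' @return density value (nm^-1); integrates to 1 over the real line.
#' @export
gaussian_emission <- function(lambda_nm, lambda0, lambda_sigma) {
  if (!is.numeric(lambda_sigma) || lambda_sigma <= 0)
    stop("gaussian_emission: lambda_sigma must be > 0")
  stats::dnorm(lambda_nm, mean = lambda0, sd = lambda_sigma)
}

#' Binary absorption window (historical baseline)
#'
#' Absorption modeled as an all-or-nothing window: 1 for excitation strictly
#' inside 370--690 nm, 0 otherwise (boundaries excluded).
#'
#' @param lambda_ex excitation wavelength (nm), vectorized, > 0.
#' @return 0/1 per wavelength.
#' @export
cerezo_absorption <- function(lambda_ex) {
  if (any(lambda_ex <= 0)) stop("cerezo_absorption: wavelengths must be > 0")
  as.numeric(lambda_ex > 370 & lambda_ex < 690)
}

#' Wavelength redistribution function (historical baseline)
#'
#' Energy-transfer efficiency between an excitation and an emission
#' wavelength in the binary-window/Gaussian-line model:
#' \deqn{f(\lambda_{ex}, \lambda) = g(\lambda_{ex}) \, h(\lambda) \, \phi \,
#'       \lambda_{ex} / \lambda}
#' with \eqn{g} the binary absorption window and \eqn{h} the Gaussian emission
#' density. The \eqn{\lambda_{ex}/\lambda} factor converts energy to the
#' red-shifted emission wavelength.
#'
#' @param lambda_ex excitation wavelength (nm), > 0.
#' @param lambda_nm emission wavelength (nm), > 0.
#' @param lambda0 peak emission wavelength (nm).
#' @param lambda_sigma emission spectral width (nm).
#' @param phi quantum yield.
#' @return redistribution efficiency (dimensionless per nm).
#' @export
cerezo_redistribution <- function(lambda_ex, lambda_nm, lambda0, lambda_sigma, phi) {
  if (any(lambda_ex <= 0) || any(lambda_nm <= 0))
    stop("cerezo_redistribution: wavelengths must be > 0")
  cerezo_absorption(lambda_ex) *
    gaussian_emission(lambda_nm, lambda0, lambda_sigma) *
    phi * lambda_ex / lambda_nm
}

#' Fluorescence efficiency from tabulated spectra
#'
#' The spectrum-driven energy redistribution at the heart of the simulator:
#' \deqn{P_f(\lambda \leftarrow \lambda_{ex}) =
#'       f_{ex}(\lambda_{ex}) \, f_{em}(\lambda) \, \phi}
#' The relative excitation efficiency at the laser line scales how much light
#' is absorbed; the emission spectrum distributes the re-emitted photons over
#' wavelength; the quantum yield converts absorbed to emitted photons.
#' Separable by construction: the emission shape is independent of the
#' excitation wavelength. Wavelengths outside a spectrum's support read as 0.
#'
#' @param fluo a \code{\link{fluorophore}}.
#' @param lambda_ex excitation wavelength (nm).
#' @param lambda_nm emission wavelength (nm), vectorized.
#' @return efficiency (dimensionless per nm of emission bandwidth).
#' @export
fluorescence_efficiency <- function(fluo, lambda_ex, lambda_nm) {
  spd_value_at(fluo$f_ex, lambda_ex) * spd_value_at(fluo$f_em, lambda_nm) * fluo$phi
}
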