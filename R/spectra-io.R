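#' Read a tabulated spectrum from CSV
#'
#' Expects a two-column UTF-8 CSV with header \code{wavelength_nm,value},
#' strictly increasing wavelengths and non-negative values. The tabulated
#' curve is resampled onto \code{grid} bin centers by linear interpolation and
#' clamped to 0 outside the tabulated support.
#'
#' @param path CSV file path.
#' @param grid target \code{\link{wavelength_grid}}.
#' @return a \code{\link{spectral_distribution}} on \code{grid}.
#' @export
read_spectrum_csv <- function(path, grid = wavelength_grid()) {
  if (!file.exists(path)) stop(sprintf("read_spectrum_csv: file not found: %s", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(raw)[1:2], c("wavelength_nm", "value")))
    stop(sprintf("read_spectrum_csv: %s line 1: header must be 'wavelength_nm,value'", path))
  wl <- suppressWarnings(as.numeric(raw$wavelength_nm))
  v  <- suppressWarnings(as.numeric(raw$value))
  bad <- which(!is.finite(wl) | !is.finite(v))
  if (length(bad))
    stop(sprintf("read_spectrum_csv: %s line %d: malformed row", path, bad[1] + 1L))
  neg <- which(v < 0)
  if (length(neg))
    stop(sprintf("read_spectrum_csv: %s line %d: negative value", path, neg[1] + 1L))
  nonmono <- which(diff(wl) <= 0)
  if (length(nonmono))
    stop(sprintf("read_spectrum_csv: %s line %d: wavelengths not strictly increasing",
                 path, nonmono[1] + 2L))
  out <- stats::approx(wl, v, xout = wl_centers(grid), rule = 1)$y
  out[is.na(out)] <- 0
  spectral_distribution(grid, out)
}

#' Write a spectral distribution to CSV
#'
#' Writes bin centers and values with the \code{wavelength_nm,value} header;
#' a write-then-read round trip on the same grid reproduces the values.
#'
#' @param spd a \code{\link{spectral_distribution}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_spectrum_csv <- function(spd, path) {
  df <- data.frame(wavelength_nm = wl_centers(spd$grid), value = spd$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
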