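# shared builders for test scenes; everything is generated in code

# a single-Gaussian dye defined analytically (no file I/O), handy for oracles
quick_fluo <- function(name = "DYE", ex_peak = 488, em_peak = 510,
                       ex_width = 22, em_width = 16, phi = 0.8,
                       sigma = 3e-16, grid = wavelength_grid()) {
  synthetic_fluorophore(name, ex_peaks = ex_peak, ex_widths = ex_width,
                        em_peaks = em_peak, em_widths = em_width,
                        phi = phi, sigma_cm2 = sigma, grid = grid)
}

# homogeneous cube scene; sheet sized generously so the full (taper-smeared)
# specimen is illuminated unless cover_cube_only = TRUE
cube_scene <- function(side = 2, N = 1e18, vs = 0.1, photons = 1e12,
                       fluo = quick_fluo(), cover_cube_only = FALSE,
                       sigma_s_elastic = 0, attenuation = "none",
                       jitter = FALSE) {
  grid <- make_homogeneous_cube(side, N, vs, sigma_s_elastic = sigma_s_elastic)
  extent <- if (cover_cube_only) side else 2 * side
  sheet <- light_sheet(extent, extent, excitation_peak(fluo), photons)
  lsfm_scene(grid, fluorophore_table(fluo), sheet,
             march_settings(vs / 2, jitter = jitter),
             attenuation = attenuation)
}

# evenly distributed directions for sphere quadrature (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  th <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(th), r * sin(th), z)
}
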