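## Synthetic emission spectra built from asymmetric lognormal bands.

#' Asymmetric lognormal spectral band
#'
#' Siano-Metzler lognormal lineshape used to model solvatochromic emission
#' bands. `width` is the full width at half maximum and `asym` the asymmetry
#' ratio (1 = Gaussian limit, > 1 skews to the red).
#'
#' @param wavelength wavelengths (nm).
#' @param center peak position (nm).
#' @param width FWHM (nm).
#' @param asym asymmetry parameter (> 0, 1 = symmetric).
#' @param amplitude peak height.
#' @return intensity vector, zero outside the band support.
#' @export
lognormal_band <- function(wavelength, center, width, asym = 1.3,
                           amplitude = 1) {
  assert_scalar_num(width, "width", 0, strict_lower = TRUE)
  assert_scalar_num(asym, "asym", 0, strict_lower = TRUE)
  if (abs(asym - 1) < 1e-6) {
    return(amplitude * exp(-4 * log(2) * ((wavelength - center) / width)^2))
  }
  rho <- asym
  arg <- 1 + (wavelength - center) * (rho^2 - 1) / (rho * width)
  out <- numeric(length(wavelength))
  ok <- arg > 0
  out[ok] <- amplitude * exp(-log(2) / log(rho)^2 * log(arg[ok])^2)
  out
}

#' Specify a synthetic emission spectrum
#'
#' @param components list of numeric vectors `c(center_nm, width_nm, asym,
#'   amplitude)`, one per band. Three bands emulate the apolar (~425 nm),
#'   polar-aprotic (~450-470 nm) and polar-protic (~480-510 nm) contributions
#'   of a membrane-embedded solvatochromic probe.
#' @param noise_sd relative (multiplicative) Gaussian noise level.
#' @param wavelength_grid ascending wavelengths (nm).
#' @param seed integer seed.
#' @return `spectrum_sim_spec` object.
#' @export
spectrum_sim_spec <- function(components, noise_sd = 0.01,
                              wavelength_grid = seq(400, 560, by = 0.5),
                              seed = 1L) {
  if (any(diff(wavelength_grid) <= 0))
    stop_ox("wavelength_grid must be strictly ascending")
  comp <- do.call(rbind, lapply(components, function(cc) {
    if (length(cc) != 4) stop_ox("each component is c(center, width, asym, amplitude)")
    cc
  }))
  colnames(comp) <- c("center", "width", "asym", "amplitude")
  if (any(comp[, "amplitude"] < 0)) stop_ox("amplitudes must be >= 0")
  rng <- range(wavelength_grid)
  if (any(comp[, "center"] < rng[1] | comp[, "center"] > rng[2]))
    stop_ox("component centers must lie within the wavelength grid")
  assert_scalar_num(noise_sd, "noise_sd", 0)
  structure(list(components = comp, noise_sd = noise_sd,
                 wavelength_grid = as.numeric(wavelength_grid),
                 seed = as.integer(seed)),
            class = "spectrum_sim_spec")
}

#' Construct an emission spectrum
#'
#' @param wavelengths ascending wavelengths (nm).
#' @param intensities non-negative intensities.
#' @param temperature optional temperature (degC).
#' @param metadata optional list.
#' @return `emission_spectrum` object.
#' @export
emission_spectrum <- function(wavelengths, intensities, temperature = NULL,
                              metadata = list()) {
  if (length(wavelengths) != length(intensities))
    stop_ox("wavelengths and intensities must have equal length")
  if (any(diff(wavelengths) <= 0)) stop_ox("wavelengths must be ascending")
  if (any(intensities < 0)) stop_ox("negative intensities")
  structure(list(wavelengths = as.numeric(wavelengths),
                 intensities = as.numeric(intensities),
                 temperature = temperature, metadata = metadata),
            class = "emission_spectrum")
}

#' Generate a synthetic emission spectrum
#'
#' Sum of lognormal bands with multiplicative Gaussian noise; the generating
#' components are recorded as ground truth in the metadata.
#'
#' @param spec a [spectrum_sim_spec()].
#' @return An [emission_spectrum()].
#' @export
gen_spectrum <- function(spec) {
  if (!inherits(spec, "spectrum_sim_spec")) stop_ox("spec must be a spectrum_sim_spec")
  wl <- spec$wavelength_grid
  intensity <- rowSums(vapply(seq_len(nrow(spec$components)), function(i) {
    p <- spec$components[i, ]
    lognormal_band(wl, p["center"], p["width"], p["asym"], p["amplitude"])
  }, numeric(length(wl))))
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    intensity <- intensity * (1 + stats::rnorm(length(wl), 0, spec$noise_sd))
  }
  intensity[intensity < 0] <- 0
  emission_spectrum(wl, intensity,
                    metadata = list(truth = spec))
}
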