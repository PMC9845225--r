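## Synthetic 1-D X-ray scattering profiles: lamellar Bragg series + WAXS peak.

#' Specify a synthetic scattering profile
#'
#' Lamellar Bragg peaks at `q_n = 2*pi*n/d` with order-dependent broadening
#' (FWHM growing with n^2, the smectic-fluctuation signature), a Lorentzian
#' wide-angle chain-packing peak, a smooth polynomial background and
#' multiplicative noise.
#'
#' @param d_spacing lamellar repeat distance (Angstrom).
#' @param n_orders number of Bragg orders.
#' @param peak_fwhm first-order Bragg FWHM (1/Angstrom).
#' @param peak_width_growth per-order broadening factor: FWHM(n) =
#'   `peak_fwhm * (1 + peak_width_growth * (n^2 - 1))`.
#' @param peak_intensity_decay power-law decay of order intensities
#'   (I_n = I_1 / n^decay).
#' @param waxs_center,waxs_hwhm,waxs_amplitude Lorentzian wide-angle peak
#'   parameters (1/Angstrom; amplitude relative to first Bragg peak).
#' @param background polynomial coefficients in q (constant first).
#' @param noise_sd relative Gaussian noise.
#' @param q_grid ascending q values (1/Angstrom).
#' @param seed integer seed.
#' @return `scatter_sim_spec` object.
#' @export
scatter_sim_spec <- function(d_spacing = 62.8, n_orders = 3L,
                             peak_fwhm = 0.004, peak_width_growth = 0,
                             peak_intensity_decay = 2,
                             waxs_center = 1.396, waxs_hwhm = 0.08,
                             waxs_amplitude = 0, background = c(0.01),
                             noise_sd = 0,
                             q_grid = seq(0.02, 0.45, by = 5e-4),
                             seed = 1L) {
  assert_scalar_num(d_spacing, "d_spacing", 0, strict_lower = TRUE)
  assert_scalar_num(n_orders, "n_orders", 1)
  assert_scalar_num(peak_fwhm, "peak_fwhm", 0, strict_lower = TRUE)
  assert_scalar_num(peak_width_growth, "peak_width_growth", 0)
  assert_scalar_num(waxs_hwhm, "waxs_hwhm", 0, strict_lower = TRUE)
  assert_scalar_num(noise_sd, "noise_sd", 0)
  if (any(diff(q_grid) <= 0)) stop_ox("q_grid must be strictly ascending")
  structure(list(d_spacing = d_spacing, n_orders = as.integer(n_orders),
                 peak_fwhm = peak_fwhm, peak_width_growth = peak_width_growth,
                 peak_intensity_decay = peak_intensity_decay,
                 waxs_center = waxs_center, waxs_hwhm = waxs_hwhm,
                 waxs_amplitude = waxs_amplitude,
                 background = as.numeric(background),
                 noise_sd = noise_sd, q_grid = as.numeric(q_grid),
                 seed = as.integer(seed)),
            class = "scatter_sim_spec")
}

#' Construct a scattering profile
#'
#' @param q ascending positive scattering vector (1/Angstrom).
#' @param intensity intensities.
#' @param uncertainty optional per-point sigma.
#' @param metadata optional list.
#' @return `scattering_profile` object.
#' @export
scattering_profile <- function(q, intensity, uncertainty = NULL,
                               metadata = list()) {
  if (length(q) != length(intensity)) stop_ox("q and intensity lengths differ")
  if (any(q <= 0)) stop_ox("q must be positive")
  if (any(diff(q) <= 0)) stop_ox("q must be ascending")
  if (!is.null(uncertainty) && length(uncertainty) != length(q))
    stop_ox("uncertainty length mismatch")
  structure(list(q = as.numeric(q), intensity = as.numeric(intensity),
                 uncertainty = uncertainty, metadata = metadata),
            class = "scattering_profile")
}

## analytic noiseless model for a scatter_sim_spec
scatter_model <- function(spec, q = spec$q_grid) {
  intensity <- drop(outer(q, seq_along(spec$background) - 1, `^`) %*%
                      spec$background)
  for (n in seq_len(spec$n_orders)) {
    qn <- 2 * pi * n / spec$d_spacing
    fwhm <- spec$peak_fwhm * (1 + spec$peak_width_growth * (n^2 - 1))
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    amp <- 1 / n^spec$peak_intensity_decay
    intensity <- intensity + amp * exp(-(q - qn)^2 / (2 * sigma^2))
  }
  if (spec$waxs_amplitude > 0) {
    intensity <- intensity + spec$waxs_amplitude /
      (1 + ((q - spec$waxs_center) / spec$waxs_hwhm)^2)
  }
  intensity
}

#' Generate a synthetic scattering profile
#'
#' @param spec a [scatter_sim_spec()].
#' @return A [scattering_profile()] with generating truth in metadata. Peaks
#'   whose position falls outside the q grid trigger a warning but are still
#'   part of the analytic model.
#' @export
gen_scatter <- function(spec) {
  if (!inherits(spec, "scatter_sim_spec")) stop_ox("spec must be a scatter_sim_spec")
  q <- spec$q_grid
  q_peaks <- 2 * pi * seq_len(spec$n_orders) / spec$d_spacing
  if (any(q_peaks < min(q) | q_peaks > max(q)))
    warn_ox("some Bragg orders fall outside the q grid")
  intensity <- scatter_model(spec)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    intensity <- intensity * (1 + stats::rnorm(length(q), 0, spec$noise_sd))
    intensity[intensity < 0] <- 0
  }
  scattering_profile(q, intensity, metadata = list(truth = spec))
}
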