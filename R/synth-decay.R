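## Synthetic TCSPC decay traces and FLIM stacks with known ground truth.

#' Specify a synthetic TCSPC decay
#'
#' Describes a multi-exponential fluorescence decay convolved with a Gaussian
#' instrument response function (IRF) and counted with Poisson statistics, the
#' way a TCSPC instrument records a cuvette trace (typically acquired until the
#' peak channel holds ~10^4 counts).
#'
#' @param lifetimes numeric vector of positive lifetimes (ns).
#' @param amplitudes non-negative fractional amplitudes summing to 1.
#' @param irf_center IRF peak position (ns).
#' @param irf_fwhm IRF full width at half maximum (ns); 0 gives a delta IRF.
#' @param n_channels number of time channels.
#' @param channel_width channel width (ns).
#' @param peak_counts expected counts in the peak channel (excluding
#'   background).
#' @param background_rate expected background counts per channel.
#' @param seed integer seed for the Poisson draw.
#' @return An object of class `decay_sim_spec`.
#' @export
decay_sim_spec <- function(lifetimes, amplitudes = rep(1 / length(lifetimes),
                                                       length(lifetimes)),
                           irf_center = 2, irf_fwhm = 0.2,
                           n_channels = 256L, channel_width = 0.056,
                           peak_counts = 10000L, background_rate = 0,
                           seed = 1L) {
  if (!length(lifetimes) || any(!is.finite(lifetimes)) || any(lifetimes <= 0))
    stop_ox("lifetimes must be strictly positive")
  if (length(amplitudes) != length(lifetimes) || any(amplitudes < 0))
    stop_ox("amplitudes must be non-negative and match lifetimes")
  if (abs(sum(amplitudes) - 1) > 1e-12)
    stop_ox("amplitudes must sum to 1 (got %.15g)", sum(amplitudes))
  assert_scalar_num(irf_center, "irf_center", 0)
  assert_scalar_num(irf_fwhm, "irf_fwhm", 0)
  assert_scalar_num(n_channels, "n_channels", 8)
  assert_scalar_num(channel_width, "channel_width", 0, strict_lower = TRUE)
  assert_scalar_num(peak_counts, "peak_counts", 1)
  assert_scalar_num(background_rate, "background_rate", 0)
  structure(list(lifetimes = as.numeric(lifetimes),
                 amplitudes = as.numeric(amplitudes),
                 irf_center = irf_center, irf_fwhm = irf_fwhm,
                 n_channels = as.integer(n_channels),
                 channel_width = channel_width,
                 peak_counts = peak_counts,
                 background_rate = background_rate,
                 seed = as.integer(seed)),
            class = "decay_sim_spec")
}

#' Construct a decay trace
#'
#' @param channel_times ascending, uniformly spaced channel centres (ns).
#' @param counts non-negative counts per channel.
#' @param irf_counts IRF trace on the same channels.
#' @param metadata optional list of acquisition descriptors.
#' @return `decay_trace` object.
#' @export
decay_trace <- function(channel_times, counts, irf_counts,
                        metadata = list()) {
  n <- length(channel_times)
  if (length(counts) != n || length(irf_counts) != n)
    stop_ox("channel_times, counts and irf_counts must have equal length")
  if (any(counts < 0) || any(irf_counts < 0))
    stop_ox("counts must be non-negative")
  dt <- diff(channel_times)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-9)
    stop_ox("channel_times must be ascending and uniform")
  structure(list(channel_times = as.numeric(channel_times),
                 counts = as.numeric(counts),
                 irf_counts = as.numeric(irf_counts),
                 metadata = metadata),
            class = "decay_trace")
}

## Gaussian IRF evaluated on channel centres; delta IRF when fwhm == 0
irf_profile <- function(times, center, fwhm) {
  if (fwhm <= 0) {
    irf <- numeric(length(times))
    irf[which.min(abs(times - center))] <- 1
    return(irf)
  }
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  irf <- stats::dnorm(times, mean = center, sd = sigma)
  irf / sum(irf)
}

## discrete reconvolution: causal convolution of a unit-sum IRF with a
## multi-exponential sampled on the channel grid
reconvolve <- function(irf, lifetimes, amplitudes, channel_width, n) {
  t_rel <- (seq_len(n) - 1) * channel_width
  dec <- drop(exp(-outer(t_rel, 1 / lifetimes)) %*% amplitudes)
  full <- stats::convolve(dec, rev(irf / sum(irf)), type = "open")
  pmax(full[seq_len(n)], 0)  # FFT round-off can go slightly negative
}

#' Generate a synthetic TCSPC decay trace
#'
#' Draws Poisson counts around the IRF-convolved multi-exponential model,
#' scaled so the expected peak equals `peak_counts`, plus a constant
#' background. The noiseless expectation and the ground truth are carried in
#' the trace metadata.
#'
#' @param spec a [decay_sim_spec()].
#' @return A [decay_trace()] whose `metadata$truth` holds the generating
#'   parameters and `metadata$expected` the noiseless mean counts.
#' @export
gen_decay <- function(spec) {
  if (!inherits(spec, "decay_sim_spec")) stop_ox("spec must be a decay_sim_spec")
  n <- spec$n_channels
  times <- (seq_len(n) - 0.5) * spec$channel_width
  irf <- irf_profile(times, spec$irf_center, spec$irf_fwhm)
  model <- reconvolve(irf, spec$lifetimes, spec$amplitudes,
                      spec$channel_width, n)
  mu <- spec$peak_counts * model / max(model) + spec$background_rate
  set.seed(spec$seed)
  counts <- stats::rpois(n, mu)
  decay_trace(times, counts, irf * spec$peak_counts / max(irf),
              metadata = list(
                truth = spec,
                expected = mu,
                channel_width_ns = spec$channel_width))
}

#' Specify a vesicle-rim FLIM geometry
#'
#' @param nx,ny image size in pixels.
#' @param center vesicle centre `(x, y)` in pixels; defaults to the image
#'   centre.
#' @param radius rim radius in pixels.
#' @param rim_width rim thickness in pixels.
#' @return `rim_geometry` object.
#' @export
rim_geometry <- function(nx = 32L, ny = 32L, center = NULL,
                         radius = 10, rim_width = 2) {
  if (is.null(center)) center <- c((nx + 1) / 2, (ny + 1) / 2)
  assert_scalar_num(radius, "radius", 0, strict_lower = TRUE)
  assert_scalar_num(rim_width, "rim_width", 0, strict_lower = TRUE)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 center = center, radius = radius, rim_width = rim_width),
            class = "rim_geometry")
}

rim_mask <- function(geom) {
  xs <- matrix(seq_len(geom$nx), geom$nx, geom$ny)
  ys <- matrix(seq_len(geom$ny), geom$nx, geom$ny, byrow = TRUE)
  r <- sqrt((xs - geom$center[1])^2 + (ys - geom$center[2])^2)
  abs(r - geom$radius) <= geom$rim_width / 2
}

#' Generate a synthetic FLIM stack of a vesicle rim
#'
#' Builds a per-pixel TCSPC image of a circular vesicle rim whose angular
#' sectors carry different fluorescence lifetimes (emulating membrane domains
#' of different microviscosity on a giant vesicle). Off-rim pixels contain
#' background counts only.
#'
#' @param geometry a [rim_geometry()].
#' @param populations list of lists with elements `lifetime` (ns), and either
#'   `region = c(theta_min, theta_max)` in radians over `[0, 2*pi)` or
#'   `fraction` (contiguous angular sectors are then derived from the
#'   fractions). Regions must partition the rim without overlap.
#' @param decay_spec a [decay_sim_spec()] providing IRF, channel layout, peak
#'   counts and background for every rim pixel (its `lifetimes` are ignored).
#' @return A `flim_stack`: list with `counts` array `[nx, ny, n_channels]`,
#'   `irf`, `channel_times`, `channel_width`, and ground truth
#'   (`region_map`, `lifetime_map`).
#' @export
gen_flim_stack <- function(geometry, populations, decay_spec) {
  if (!inherits(geometry, "rim_geometry")) stop_ox("geometry must be a rim_geometry")
  if (!inherits(decay_spec, "decay_sim_spec")) stop_ox("decay_spec must be a decay_sim_spec")
  if (!length(populations)) stop_ox("at least one population required")
  has_region <- vapply(populations, function(p) !is.null(p$region), logical(1))
  if (!all(has_region)) {
    fr <- vapply(populations, function(p) p$fraction, numeric(1))
    if (abs(sum(fr) - 1) > 1e-9) stop_ox("population fractions must sum to 1")
    edges <- 2 * pi * cumsum(c(0, fr))
    for (i in seq_along(populations))
      populations[[i]]$region <- c(edges[i], edges[i + 1])
  }
  regions <- t(vapply(populations, function(p) p$region, numeric(2)))
  o <- order(regions[, 1])
  if (any(regions[o, 1][-1] < regions[o, 2][-nrow(regions)] - 1e-12))
    stop_ox("population regions overlap")

  n <- decay_spec$n_channels
  times <- (seq_len(n) - 0.5) * decay_spec$channel_width
  irf <- irf_profile(times, decay_spec$irf_center, decay_spec$irf_fwhm)
  mask <- rim_mask(geometry)
  counts <- array(0L, dim = c(geometry$nx, geometry$ny, n))
  region_map <- matrix(NA_integer_, geometry$nx, geometry$ny)
  lifetime_map <- matrix(NA_real_, geometry$nx, geometry$ny)

  set.seed(decay_spec$seed)
  for (ix in seq_len(geometry$nx)) {
    for (iy in seq_len(geometry$ny)) {
      if (!mask[ix, iy]) {
        if (decay_spec$background_rate > 0)
          counts[ix, iy, ] <- stats::rpois(n, decay_spec$background_rate)
        next
      }
      theta <- atan2(iy - geometry$center[2], ix - geometry$center[1]) %% (2 * pi)
      k <- which(theta >= regions[, 1] & theta < regions[, 2])
      if (!length(k)) k <- which.max(regions[, 2])  # wrap edge
      k <- k[1]
      tau <- populations[[k]]$lifetime
      model <- reconvolve(irf, tau, 1, decay_spec$channel_width, n)
      mu <- decay_spec$peak_counts * model / max(model) +
        decay_spec$background_rate
      counts[ix, iy, ] <- stats::rpois(n, mu)
      region_map[ix, iy] <- k
      lifetime_map[ix, iy] <- tau
    }
  }
  structure(list(counts = counts,
                 irf = irf * decay_spec$peak_counts / max(irf),
                 channel_times = times,
                 channel_width = decay_spec$channel_width,
                 truth = list(region_map = region_map,
                              lifetime_map = lifetime_map,
                              populations = populations),
                 metadata = list(geometry = geometry,
                                 decay_spec = decay_spec)),
            class = "flim_stack")
}
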