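## Per-pixel FLIM fitting: binning, count thresholding, viscosity maps and
## lifetime-distribution heterogeneity statistics.

## sum decays over a (2b+1)^2 square neighbourhood (truncated at edges)
bin_stack <- function(counts, b) {
  if (b == 0) return(counts)
  d <- dim(counts)
  out <- array(0, d)
  for (dx in -b:b) {
    xs <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
    for (dy in -b:b) {
      ys <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
      out <- out + counts[xs, ys, , drop = FALSE]
    }
  }
  out
}

#' Fit every pixel of a FLIM stack
#'
#' Aggregates decays over a square binning neighbourhood, masks pixels whose
#' peak channel falls below `min_peak_counts`, fits the survivors by
#' reconvolution ([fit_decay()]) and converts the reported lifetime to
#' microviscosity.
#'
#' @param stack a `flim_stack` (see [gen_flim_stack()]).
#' @param binning neighbourhood half-width b; decays are summed over
#'   (2b+1) x (2b+1) pixels before fitting (0 = no binning).
#' @param min_peak_counts minimum counts in the peak channel after binning
#'   (typically 200 for mono-exponential and 500 for bi-exponential dyes).
#' @param dye_mode `"mono"` or `"bi_long"` (see
#'   [select_reported_lifetime()]).
#' @param method fit objective, passed to [fit_decay()].
#' @param calibration a `viscosity_calibration`.
#' @return A `viscosity_map`: lifetime and viscosity rasters (NA outside the
#'   validity mask), the mask, and per-pixel reduced chi-square. If no pixel
#'   passes the threshold the map is empty and `empty = TRUE`.
#' @export
fit_flim_stack <- function(stack, binning = 0L, min_peak_counts = 200,
                           dye_mode = c("mono", "bi_long"),
                           method = "poisson_mle",
                           calibration = default_calibration()) {
  if (!inherits(stack, "flim_stack")) stop_ox("stack must be a flim_stack")
  dye_mode <- match.arg(dye_mode)
  if (binning < 0) stop_ox("binning must be >= 0")
  n_comp <- if (dye_mode == "mono") 1L else 2L
  counts <- bin_stack(stack$counts, as.integer(binning))
  peak <- apply(counts, c(1, 2), max)
  mask <- peak >= min_peak_counts
  d <- dim(counts)
  tau_map <- matrix(NA_real_, d[1], d[2])
  chi2_map <- matrix(NA_real_, d[1], d[2])
  if (!any(mask)) {
    return(structure(list(lifetime = tau_map,
                          viscosity = tau_map, chi2 = chi2_map,
                          mask = mask, n_fitted = 0L, empty = TRUE,
                          binning = binning,
                          min_peak_counts = min_peak_counts,
                          calibration = calibration),
                     class = "viscosity_map"))
  }
  for (ix in seq_len(d[1])) {
    for (iy in seq_len(d[2])) {
      if (!mask[ix, iy]) next
      tr <- decay_trace(stack$channel_times, counts[ix, iy, ], stack$irf)
      fit <- tryCatch(suppressWarnings(fit_decay(tr, n_comp, method)),
                      error = function(e) NULL)
      if (is.null(fit)) { mask[ix, iy] <- FALSE; next }
      tau_map[ix, iy] <- as.numeric(
        suppressWarnings(select_reported_lifetime(fit, dye_mode)))
      chi2_map[ix, iy] <- fit$reduced_chi2
    }
  }
  visc_map <- matrix(NA_real_, d[1], d[2])
  ok <- mask & is.finite(tau_map)
  visc_map[ok] <- suppressWarnings(
    lifetime_to_viscosity(tau_map[ok], calibration))
  structure(list(lifetime = tau_map, viscosity = visc_map, chi2 = chi2_map,
                 mask = mask, n_fitted = sum(ok), empty = FALSE,
                 binning = binning, min_peak_counts = min_peak_counts,
                 calibration = calibration),
            class = "viscosity_map")
}

#' Lifetime-distribution heterogeneity of a FLIM map
#'
#' Summarizes the per-pixel lifetime (or viscosity) distribution: SD,
#' skewness, excess kurtosis, and a two-component Gaussian-mixture
#' bimodality score `delta_bic = BIC(1 component) - BIC(2 components)`
#' (positive = two populations preferred), the signature of lateral domains
#' of distinct microviscosity within a single vesicle.
#'
#' @param map a `viscosity_map`.
#' @param value `"lifetime"` or `"viscosity"`.
#' @param breaks passed to [hist()].
#' @return A `lifetime_histogram`: histogram bins/counts, moments, and the
#'   mixture comparison (delta_bic, component means/sds/proportions).
#' @export
histogram_heterogeneity <- function(map, value = c("lifetime", "viscosity"),
                                    breaks = "Sturges") {
  if (!inherits(map, "viscosity_map")) stop_ox("map must be a viscosity_map")
  value <- match.arg(value)
  v <- map[[value]][map$mask]
  v <- v[is.finite(v)]
  if (length(v) < 30L) stop_ox("need >= 30 valid pixels (got %d)", length(v))
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  mom <- sample_moments(v)
  mix <- if (mom$sd > 0) gmm_delta_bic(v) else
    list(delta_bic = -Inf, means = mom$mean, sds = 0, proportions = 1)
  structure(list(value = value, n = length(v), breaks = h$breaks,
                 counts = h$counts, mean = mom$mean, sd = mom$sd,
                 skewness = mom$skewness, ex_kurtosis = mom$ex_kurtosis,
                 delta_bic = mix$delta_bic, gmm_means = mix$means,
                 gmm_sds = mix$sds, gmm_proportions = mix$proportions),
            class = "lifetime_histogram")
}

#' Spatial autocorrelation (Moran's I) of a lifetime map
#'
#' Rook-adjacency Moran's I over the valid pixels, with a permutation null.
#' A homogeneous membrane fitted at the photon-noise limit should show
#' I ~ 0; spatial domains give I > 0.
#'
#' @param map a `viscosity_map`.
#' @param n_perm permutations for the null.
#' @param seed permutation seed.
#' @return list with `I`, `p_value`, `n`.
#' @export
map_morans_i <- function(map, n_perm = 199L, seed = 1L) {
  if (!inherits(map, "viscosity_map")) stop_ox("map must be a viscosity_map")
  ok <- map$mask & is.finite(map$lifetime)
  idx <- which(ok, arr.ind = TRUE)
  n <- nrow(idx)
  if (n < 10L) stop_ox("need >= 10 valid pixels")
  v <- map$lifetime[ok]
  key <- idx[, 1] * 1e5 + idx[, 2]
  pairs <- NULL
  for (shift in list(c(1, 0), c(0, 1))) {
    nb_key <- (idx[, 1] + shift[1]) * 1e5 + (idx[, 2] + shift[2])
    m <- match(nb_key, key)
    has <- !is.na(m)
    pairs <- rbind(pairs, cbind(which(has), m[has]))
  }
  if (is.null(pairs) || nrow(pairs) == 0) stop_ox("no adjacent valid pixels")
  w_sum <- 2 * nrow(pairs)  # symmetric weights
  moran <- function(x) {
    z <- x - mean(x)
    n * 2 * sum(z[pairs[, 1]] * z[pairs[, 2]]) / (w_sum * sum(z^2))
  }
  i_obs <- moran(v)
  set.seed(seed)
  null <- replicate(n_perm, moran(sample(v)))
  p <- (1 + sum(abs(null) >= abs(i_obs))) / (n_perm + 1)
  list(I = i_obs, p_value = p, n = n)
}
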