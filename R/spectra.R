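## Laurdan generalized polarization, three-lognormal decomposition and
## temperature-series breakpoint detection.

#' Generalized polarization of an emission spectrum
#'
#' `GP = (I_blue - I_red) / (I_blue + I_red)` with band intensities
#' integrated (trapezoid) over the stated wavelength windows. The absolute
#' GP value depends on the band convention; the defaults integrate
#' 430-450 nm (blue, ordered-phase emission) and 480-500 nm (red,
#' relaxed/hydrated emission).
#'
#' @param spectrum an [emission_spectrum()].
#' @param blue_band,red_band `c(lo, hi)` nm windows; must lie inside the
#'   spectrum and not overlap.
#' @return A `gp_result`: `gp` in [-1, 1], band definitions and integrated
#'   band intensities.
#' @export
compute_gp <- function(spectrum, blue_band = c(430, 450),
                       red_band = c(480, 500)) {
  if (!inherits(spectrum, "emission_spectrum")) stop_ox("spectrum must be an emission_spectrum")
  wl <- spectrum$wavelengths
  for (b in list(blue_band, red_band)) {
    if (length(b) != 2 || b[1] >= b[2]) stop_ox("bands must be c(lo, hi)")
    if (b[1] < min(wl) || b[2] > max(wl)) stop_ox("band outside spectrum range")
  }
  if (max(blue_band[1], red_band[1]) < min(blue_band[2], red_band[2]))
    stop_ox("blue and red bands overlap")
  band_intensity <- function(band) {
    sel <- wl >= band[1] & wl <= band[2]
    trapz(wl[sel], spectrum$intensities[sel])
  }
  i_blue <- band_intensity(blue_band)
  i_red <- band_intensity(red_band)
  total <- trapz(wl, spectrum$intensities)
  if (i_blue + i_red <= 1e-9 * max(total, .Machine$double.xmin))
    stop_ox("no signal in GP bands")
  structure(list(gp = (i_blue - i_red) / (i_blue + i_red),
                 blue_band = blue_band, red_band = red_band,
                 i_blue = i_blue, i_red = i_red,
                 convention = "integrated trapezoid bands"),
            class = "gp_result")
}

#' Decompose an emission spectrum into three lognormal bands
#'
#' Constrained nonlinear least squares (Levenberg-Marquardt, multistart with
#' jittered initial centers) of three Siano-Metzler lognormal bands,
#' representing the apolar (~425 nm), polar-aprotic (~450-470 nm) and
#' polar-protic (~480-510 nm) environments of the probe. By default the
#' three bands share one asymmetry parameter: with three strongly
#' overlapping bands a per-band asymmetry is poorly identified and trades
#' off against the centers under realistic noise. Residuals are weighted by
#' the inverse intensity (floored at 20% of the peak), matching the
#' predominantly multiplicative noise of emission spectra. Area fractions
#' are computed by trapezoid integration over the spectral grid.
#'
#' @param spectrum an [emission_spectrum()] covering ~400-560 nm.
#' @param center_windows list of 3 `c(lo, hi)` nm windows constraining the
#'   band centers.
#' @param shared_asym share one asymmetry across bands (default) or fit one
#'   per band.
#' @param n_starts number of jittered multistart fits (best residual kept).
#' @param seed jitter seed.
#' @return A `lognormal_decomposition`: per-band center/width/asymmetry/
#'   area fraction (centers ascending), residual RMS, and a degeneracy flag
#'   when a single band fits as well as three.
#' @export
decompose_lognormal3 <- function(spectrum,
                                 center_windows = list(c(415, 435),
                                                       c(450, 470),
                                                       c(480, 510)),
                                 shared_asym = TRUE,
                                 n_starts = 7L, seed = 1L) {
  if (!inherits(spectrum, "emission_spectrum")) stop_ox("spectrum must be an emission_spectrum")
  wl <- spectrum$wavelengths
  y <- spectrum$intensities
  if (all(y == 0)) stop_ox("spectrum is all zeros")
  if (min(wl) > 415 || max(wl) < 515)
    warn_ox("spectrum does not cover the usual 400-560 nm decomposition range")
  if (length(center_windows) != 3L) stop_ox("three center windows required")
  ymax <- max(y)
  wt <- 1 / pmax(y, 0.2 * ymax)
  clo <- vapply(center_windows, `[`, numeric(1), 1)
  chi <- vapply(center_windows, `[`, numeric(1), 2)
  centers0 <- (clo + chi) / 2

  if (shared_asym) {
    ## params: (center, width, amplitude) x3, shared asym
    lower <- c(rbind(clo, 15, 0), 1.05)
    upper <- c(rbind(chi, 120, 2 * ymax), 2.0)
    make_p0 <- function(c0) c(c0[1], 40, 0.8 * ymax, c0[2], 45, 0.5 * ymax,
                              c0[3], 50, 0.3 * ymax, 1.3)
    model <- function(p)
      lognormal_band(wl, p[1], p[2], p[10], p[3]) +
      lognormal_band(wl, p[4], p[5], p[10], p[6]) +
      lognormal_band(wl, p[7], p[8], p[10], p[9])
    unpack <- function(p) cbind(center = p[c(1, 4, 7)],
                                width = p[c(2, 5, 8)],
                                asym = rep(p[10], 3),
                                amplitude = p[c(3, 6, 9)])
    cidx <- c(1, 4, 7)
  } else {
    lower <- c(rbind(clo, 15, 1.05, 0))
    upper <- c(rbind(chi, 120, 2.0, 2 * ymax))
    make_p0 <- function(c0) c(c0[1], 40, 1.3, 0.8 * ymax,
                              c0[2], 45, 1.3, 0.5 * ymax,
                              c0[3], 50, 1.3, 0.3 * ymax)
    model <- function(p)
      lognormal_band(wl, p[1], p[2], p[3], p[4]) +
      lognormal_band(wl, p[5], p[6], p[7], p[8]) +
      lognormal_band(wl, p[9], p[10], p[11], p[12])
    unpack <- function(p) matrix(p, 3, 4, byrow = TRUE,
                                 dimnames = list(NULL, c("center", "width",
                                                         "asym", "amplitude")))
    cidx <- c(1, 5, 9)
  }

  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    jit <- if (s == 1) rep(0, 3) else stats::runif(3, -8, 8)
    c0 <- pmin(pmax(centers0 + jit, lower[cidx]), upper[cidx])
    fit <- tryCatch(
      minpack.lm::nls.lm(par = make_p0(c0),
                         fn = function(p) (y - model(p)) * wt,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop_ox("lognormal decomposition failed to converge")
  comps <- unpack(best$fit$par)
  o <- order(comps[, "center"])
  comps <- comps[o, , drop = FALSE]
  areas <- vapply(seq_len(3), function(i) {
    trapz(wl, lognormal_band(wl, comps[i, 1], comps[i, 2], comps[i, 3],
                             comps[i, 4]))
  }, numeric(1))
  total <- sum(areas)
  area_frac <- if (total > 0) areas / total else rep(0, 3)
  resid <- y - rowSums(vapply(seq_len(3), function(i) {
    lognormal_band(wl, comps[i, 1], comps[i, 2], comps[i, 3], comps[i, 4])
  }, numeric(length(y))))
  rms <- sqrt(mean(resid^2))

  ## degeneracy check: single lognormal as good as three?
  fit1 <- tryCatch(
    minpack.lm::nls.lm(par = c(wl[which.max(y)], 50, 1.3, ymax),
                       fn = function(p) (y - lognormal_band(wl, p[1], p[2],
                                                            p[3], p[4])) * wt,
                       lower = c(min(wl), 10, 1.01, 0),
                       upper = c(max(wl), 150, 2.5, 2 * ymax)),
    error = function(e) NULL)
  degenerate <- !is.null(fit1) && sum(fit1$fvec^2) <= best$rss * (1 + 1e-6)
  if (degenerate) warn_ox("three-band fit no better than a single band")

  structure(list(components = cbind(comps, area_fraction = area_frac),
                 residual_rms = rms, rss = best$rss,
                 total_area = trapz(wl, y),
                 degenerate = degenerate,
                 bounds = list(lower = lower, upper = upper)),
            class = "lognormal_decomposition")
}

#' Detect a change of slope in a temperature series
#'
#' Exhaustive two-segment continuous ("hinge") least squares over candidate
#' breakpoints at the data abscissae (excluding two edge points per side),
#' compared with a single straight line by an F-like variance ratio. Used to
#' locate the phase-separation signature, a gradient change near ~50 degC in
#' GP or intensity versus temperature. The confidence interval comes from a
#' seeded residual bootstrap.
#'
#' @param temperature,value numeric vectors (degC, signal). At least 6
#'   points spanning >= 20 degC.
#' @param alpha significance level for declaring a breakpoint.
#' @param n_boot residual-bootstrap replicates for the CI.
#' @param seed bootstrap seed.
#' @return A `breakpoint_result`: `breakpoint` (degC, NA when the series is
#'   adequately linear), slopes below/above, F statistic + p-value, CI.
#' @export
find_breakpoint <- function(temperature, value, alpha = 0.05,
                            n_boot = 199L, seed = 1L) {
  o <- order(temperature)
  x <- as.numeric(temperature[o]); y <- as.numeric(value[o])
  n <- length(x)
  if (n < 6L) stop_ox("need >= 6 points (got %d)", n)
  if (diff(range(x)) < 20) stop_ox("series must span >= 20 degC")
  candidates <- x[3:(n - 2)]
  if (!length(candidates)) stop_ox("insufficient interior points")

  hinge_fit <- function(xb) {
    h <- pmax(x - xb, 0)
    f <- stats::lm(y ~ x + h)
    list(rss = sum(stats::resid(f)^2), coef = stats::coef(f), xb = xb)
  }
  fits <- lapply(unique(candidates), hinge_fit)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
  lin <- stats::lm(y ~ x)
  rss1 <- sum(stats::resid(lin)^2)
  df2 <- n - 4  # intercept, slope, hinge slope, breakpoint
  fstat <- if (best$rss > 0) ((rss1 - best$rss) / 2) / (best$rss / df2) else Inf
  p_val <- stats::pf(fstat, 2, df2, lower.tail = FALSE)
  significant <- is.finite(fstat) && p_val < alpha

  slope_below <- best$coef[["x"]]
  slope_above <- best$coef[["x"]] + best$coef[["h"]]

  ci <- c(NA_real_, NA_real_)
  if (significant && n_boot > 0) {
    h <- pmax(x - best$xb, 0)
    fitted_best <- stats::fitted(stats::lm(y ~ x + h))
    res <- y - fitted_best
    set.seed(seed)
    bb <- replicate(n_boot, {
      yb <- fitted_best + sample(res, n, replace = TRUE)
      fb <- vapply(unique(candidates), function(xb) {
        hb <- pmax(x - xb, 0)
        sum(stats::resid(stats::lm(yb ~ x + hb))^2)
      }, numeric(1))
      unique(candidates)[which.min(fb)]
    })
    ci <- stats::quantile(bb, c(0.025, 0.975), names = FALSE)
  }
  structure(list(breakpoint = if (significant) best$xb else NA_real_,
                 slopes = c(below = slope_below, above = slope_above),
                 improvement = fstat, p_value = p_val,
                 significant = significant, ci = ci,
                 rss_linear = rss1, rss_hinge = best$rss, n = n),
            class = "breakpoint_result")
}
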