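## Lateral diffusion from MSD and the Saffman-Delbruck viscosity bridge.

## unwrap wrapped 2-D coordinates along frames (minimum-image steps)
unwrap_xy <- function(xy, box) {
  nf <- dim(xy)[3]
  if (nf < 2L) return(xy)
  out <- xy
  for (d in 1:2) {
    steps <- xy[, d, -1, drop = FALSE] - xy[, d, -nf, drop = FALSE]
    wrapped_steps <- min_image(steps, box[d])
    if (any(abs(wrapped_steps) >= 0.49 * box[d]))
      stop_ox("wrap-ambiguous steps (> box/2); use a finer frame interval")
    cum <- apply(wrapped_steps, 1, cumsum)
    cum <- if (is.matrix(cum)) t(cum) else matrix(cum, ncol = nf - 1L)
    out[, d, -1] <- xy[, d, 1] + cum
  }
  out
}

#' Lateral diffusion coefficient from the mean squared displacement
#'
#' Time- and ensemble-averaged 2-D MSD per species; the diffusion
#' coefficient is the slope / 4 of a variance-weighted through-origin
#' straight-line fit on an interior lag window (default 10-50% of the
#' maximum lag: shorter lags are noise- and localization-dominated, longer
#' lags poorly sampled and strongly correlated). A log-log slope far
#' from 1 flags non-diffusive motion.
#'
#' @param traj a `bilayer_trajectory` (wrapped coordinates are unwrapped
#'   internally; ambiguous wrap steps raise an error).
#' @param species optional species subset.
#' @param fit_fraction `c(lo, hi)` fraction of the lag range to fit.
#' @param max_lags at most this many lag values are evaluated.
#' @return A `diffusion_estimate` data.frame: species, D (Angstrom^2/ns),
#'   se, alpha (log-log slope), flag; the MSD curves are attached as
#'   attribute `msd`.
#' @export
msd_diffusion <- function(traj, species = NULL,
                          fit_fraction = c(0.1, 0.5), max_lags = 100L) {
  if (!inherits(traj, "bilayer_trajectory")) stop_ox("traj must be a bilayer_trajectory")
  if (traj$n_frames < 10L) stop_ox("need >= 10 frames")
  sp <- if (is.null(species)) unique(traj$molecules$species) else species
  xy_un <- unwrap_xy(traj$xy, traj$box)
  nf <- traj$n_frames
  max_lag <- max(3L, floor(nf * max(fit_fraction[2], 0.5)))
  lags <- unique(round(seq(1, max_lag, length.out = min(max_lags, max_lag))))
  rows <- list(); curves <- list()
  for (s in sp) {
    sel <- which(traj$molecules$species == s)
    if (!length(sel)) stop_ox("species '%s' not present", s)
    msd <- vapply(lags, function(L) {
      dx <- xy_un[sel, 1, (1 + L):nf, drop = FALSE] -
        xy_un[sel, 1, 1:(nf - L), drop = FALSE]
      dy <- xy_un[sel, 2, (1 + L):nf, drop = FALSE] -
        xy_un[sel, 2, 1:(nf - L), drop = FALSE]
      mean(dx^2 + dy^2)
    }, numeric(1))
    t_lag <- lags * traj$dt
    win <- lags >= fit_fraction[1] * max_lag & lags <= fit_fraction[2] * max_lag
    if (sum(win) < 3L) win <- seq_along(lags) <= max(3L, length(lags) %/% 2L)
    ## absolute sampling variance of the time-averaged MSD grows
    ## ~ lag^3 / (T - lag) for Brownian motion; a through-origin fit with
    ## inverse-variance weights is then a weighted mean of msd / (4 lag)
    w <- (nf - lags[win]) / lags[win]^3
    fit <- stats::lm(msd[win] ~ 0 + t_lag[win], weights = w)
    d_hat <- stats::coef(fit)[[1]] / 4
    se <- summary(fit)$coefficients[1, 2] / 4
    alpha <- stats::coef(stats::lm(log(msd[win]) ~ log(t_lag[win])))[[2]]
    flag <- if (abs(alpha - 1) > 0.2)
      sprintf("non-diffusive (log-log slope %.2f)", alpha) else ""
    rows[[s]] <- data.frame(species = s, D = d_hat, se = se, alpha = alpha,
                            flag = flag, stringsAsFactors = FALSE)
    curves[[s]] <- data.frame(species = s, lag_ns = t_lag, msd_A2 = msd)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "msd") <- do.call(rbind, curves)
  class(out) <- c("diffusion_estimate", "data.frame")
  out
}

.euler_gamma <- 0.57721566490153286

#' Saffman-Delbruck diffusion coefficient
#'
#' `D = kB T / (4 pi eta_m h) * (ln(L_sd / r) - gamma)` with the
#' Saffman-Delbruck length `L_sd = eta_m h / (2 eta_w)`: the lateral
#' diffusion coefficient of a cylindrical inclusion of radius `r` in a
#' membrane of bulk viscosity `eta_m` and thickness `h` bathed in water of
#' viscosity `eta_w`. Valid only for `r < L_sd`. This is the bridge between
#' rotor-derived microviscosity and lipid diffusion.
#'
#' @param eta_m membrane viscosity (cP).
#' @param h membrane thickness (nm).
#' @param probe_radius inclusion radius (nm).
#' @param eta_w water viscosity (cP).
#' @param temperature absolute temperature (K).
#' @return list with `D_um2_s`, `D_A2_ns`, `L_sd_nm`.
#' @export
saffman_delbruck <- function(eta_m, h = 3.24, probe_radius = 0.45,
                             eta_w = 1, temperature = 300) {
  assert_scalar_num(eta_m, "eta_m", 0, strict_lower = TRUE)
  assert_scalar_num(h, "h", 0, strict_lower = TRUE)
  assert_scalar_num(probe_radius, "probe_radius", 0, strict_lower = TRUE)
  kB <- 1.380649e-23
  eta_m_si <- eta_m * 1e-3; eta_w_si <- eta_w * 1e-3
  h_si <- h * 1e-9; r_si <- probe_radius * 1e-9
  L_sd <- eta_m_si * h_si / (2 * eta_w_si)
  if (r_si >= L_sd)
    stop_ox("outside SD regime: probe radius %.3g nm >= L_sd %.3g nm",
            probe_radius, L_sd * 1e9)
  D <- kB * temperature / (4 * pi * eta_m_si * h_si) *
    (log(L_sd / r_si) - .euler_gamma)
  list(D_um2_s = D * 1e12, D_A2_ns = D * 1e11, L_sd_nm = L_sd * 1e9)
}

#' Membrane viscosity from a Saffman-Delbruck diffusion coefficient
#'
#' Numerical inverse of [saffman_delbruck()] (monotone bisection on
#' log viscosity).
#'
#' @param D_um2_s lateral diffusion coefficient (um^2/s).
#' @param h,probe_radius,eta_w,temperature as in [saffman_delbruck()].
#' @return membrane viscosity (cP).
#' @export
sd_membrane_viscosity <- function(D_um2_s, h = 3.24, probe_radius = 0.45,
                                  eta_w = 1, temperature = 300) {
  assert_scalar_num(D_um2_s, "D_um2_s", 0, strict_lower = TRUE)
  f <- function(log_eta) {
    saffman_delbruck(exp(log_eta), h, probe_radius, eta_w,
                     temperature)$D_um2_s - D_um2_s
  }
  ## D(eta) peaks at L_sd = r * exp(1 + gamma); invert on the physical,
  ## strictly decreasing large-viscosity branch
  eta_peak <- 2 * eta_w * probe_radius * exp(1 + .euler_gamma) / h
  lo <- log(eta_peak); hi <- log(1e8)
  if (f(lo) < 0)
    stop_ox("D = %g um^2/s exceeds the SD maximum at these parameters",
            D_um2_s)
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root)
}
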