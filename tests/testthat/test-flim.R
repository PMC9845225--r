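test_that("reconvolution fit matches a tail log-linear oracle on noiseless data", {
  spec <- decay_sim_spec(1.0, irf_center = 1, irf_fwhm = 0,
                         background_rate = 0, peak_counts = 10000, seed = 1)
  tr <- noiseless_decay(spec)
  fit <- fit_decay(tr, 1, method = "lsq")
  ## independent oracle: log-linear regression on the tail
  peak <- which.max(tr$counts)
  idx <- (peak + 10):length(tr$counts)
  keep <- tr$counts[idx] > 1e-6
  tau_tail <- -1 / coef(lm(log(tr$counts[idx][keep]) ~
                             tr$channel_times[idx][keep]))[[2]]
  expect_equal(fit$lifetimes[1], tau_tail, tolerance = 1e-3)
})

test_that("empty or degenerate decays are rejected", {
  tr <- decay_trace(seq(0.5, 10, 0.5), rep(0, 20), c(1, rep(0, 19)))
  expect_error(fit_decay(tr), "empty decay")
  expect_error(decay_trace(c(1, 2, 4), c(1, 1, 1), c(1, 0, 0)), "uniform")
})

test_that("biexponential fit separates two components at high counts", {
  spec <- decay_sim_spec(c(3.0, 0.6), amplitudes = c(0.5, 0.5),
                         peak_counts = 5e4, n_channels = 512,
                         channel_width = 0.056, seed = 7)
  fit <- fit_decay(gen_decay(spec), 2)
  expect_equal(fit$lifetimes[1], 3.0, tolerance = 0.1)
  expect_equal(fit$lifetimes[2], 0.6, tolerance = 0.15)
  expect_equal(sum(fit$amplitudes), 1)
  expect_true(all(diff(fit$lifetimes) <= 0))
})

test_that("Poisson-MLE and weighted-LSQ agree within 1 SD at high counts", {
  spec <- decay_sim_spec(2.1, peak_counts = 1e4, seed = 11)
  tr <- gen_decay(spec)
  f1 <- fit_decay(tr, 1, "poisson_mle")
  f2 <- fit_decay(tr, 1, "lsq")
  expect_lt(abs(f1$lifetimes[1] - f2$lifetimes[1]),
            max(f1$se[1], f2$se[1]))
})

test_that("fit precision scales like 1/sqrt(peak counts)", {
  sd_at <- function(pc) {
    taus <- vapply(1:15, function(s) {
      fit_decay(gen_decay(decay_sim_spec(2.1, peak_counts = pc,
                                         seed = 100 + s)), 1)$lifetimes[1]
    }, numeric(1))
    sd(taus)
  }
  s3 <- sd_at(1e3); s4 <- sd_at(1e4)
  expect_gt(s3 / s4, sqrt(10) / 2.5)
  expect_lt(s3 / s4, sqrt(10) * 2.5)
})

test_that("reported-lifetime selection follows the dye mode", {
  fit <- structure(list(lifetimes = c(2.3, 0.6), amplitudes = c(0.5, 0.5),
                        n_components = 2L, converged = TRUE,
                        flags = character(0)), class = "lifetime_fit")
  expect_equal(select_reported_lifetime(fit, "bi_long"), 2.3)
  expect_error(select_reported_lifetime(fit, "mono"), "mono")
  mono <- structure(list(lifetimes = 1.8, amplitudes = 1,
                         n_components = 1L, converged = TRUE,
                         flags = character(0)), class = "lifetime_fit")
  expect_equal(select_reported_lifetime(mono, "mono"), 1.8)
  tie <- structure(list(lifetimes = c(2, 2), amplitudes = c(0.5, 0.5),
                        n_components = 2L, converged = TRUE,
                        flags = character(0)), class = "lifetime_fit")
  expect_true(isTRUE(attr(select_reported_lifetime(tie, "bi_long"), "tie")))
})

test_that("calibration is a strictly monotone, invertible power law", {
  cal <- calibrate_from_pairs(cbind(c(100, 400), c(1.0, 2.0)))
  expect_equal(cal$exponent, log(2) / log(4), tolerance = 1e-12)
  taus <- seq(0.5, 4, 0.1)
  etas <- suppressWarnings(lifetime_to_viscosity(taus, cal))
  expect_true(all(diff(etas) > 0))
  expect_equal(suppressWarnings(viscosity_to_lifetime(etas, cal)), taus,
               tolerance = 1e-10)
  expect_error(calibrate_from_pairs(cbind(100, 1)), "at least 2")
  expect_error(lifetime_to_viscosity(-1, cal), "positive")
  ## identity calibration
  ident <- viscosity_calibration(1, 1)
  expect_equal(lifetime_to_viscosity(2.5, ident), 2.5)
})

test_that("pixel threshold masks exactly the planted sub-threshold pixels", {
  ## 2x2 image: two pixels above and two below the count threshold
  spec_hi <- decay_sim_spec(2.0, n_channels = 64, peak_counts = 400, seed = 1)
  spec_lo <- decay_sim_spec(2.0, n_channels = 64, peak_counts = 120, seed = 2)
  mk <- function(s) gen_decay(s)$counts
  counts <- array(0, c(2, 2, 64))
  counts[1, 1, ] <- mk(spec_hi); counts[2, 2, ] <- mk(spec_hi)
  counts[1, 2, ] <- mk(spec_lo); counts[2, 1, ] <- mk(spec_lo)
  tr <- gen_decay(spec_hi)
  stk <- structure(list(counts = counts, irf = tr$irf_counts,
                        channel_times = tr$channel_times,
                        channel_width = spec_hi$channel_width),
                   class = "flim_stack")
  mp <- fit_flim_stack(stk, binning = 0, min_peak_counts = 200)
  expect_equal(mp$n_fitted, 2L)
  expect_true(all(is.na(mp$lifetime[cbind(c(1, 2), c(2, 1))])))
  ## raising the threshold never increases the fitted-pixel count
  mp_hi <- fit_flim_stack(stk, binning = 0, min_peak_counts = 500)
  expect_lte(mp_hi$n_fitted, mp$n_fitted)
})

test_that("explicit binning equals fitting the pre-summed decay", {
  dspec <- decay_sim_spec(2.0, n_channels = 64, peak_counts = 150, seed = 4)
  counts <- array(0, c(3, 3, 64))
  set.seed(9)
  for (i in 1:3) for (j in 1:3)
    counts[i, j, ] <- gen_decay(decay_sim_spec(2.0, n_channels = 64,
                                               peak_counts = 150,
                                               seed = i * 10 + j))$counts
  tr0 <- gen_decay(dspec)
  stk <- structure(list(counts = counts, irf = tr0$irf_counts,
                        channel_times = tr0$channel_times,
                        channel_width = dspec$channel_width),
                   class = "flim_stack")
  mp <- fit_flim_stack(stk, binning = 1, min_peak_counts = 200)
  summed <- apply(counts, 3, sum)
  fit <- fit_decay(decay_trace(tr0$channel_times, summed, tr0$irf_counts), 1)
  expect_equal(mp$lifetime[2, 2], fit$lifetimes[1], tolerance = 1e-8)
})

test_that("heterogeneity statistics separate one and two lifetime populations", {
  geom <- rim_geometry(nx = 28, ny = 28, radius = 9, rim_width = 2.5)
  dspec <- decay_sim_spec(2.0, n_channels = 128, peak_counts = 500, seed = 6)
  ## planted two-mode rim at 2.0 / 2.4 ns
  stk2 <- gen_flim_stack(geom, list(list(lifetime = 2.0, fraction = 0.5),
                                    list(lifetime = 2.4, fraction = 0.5)),
                         dspec)
  h2 <- histogram_heterogeneity(fit_flim_stack(stk2, min_peak_counts = 200))
  expect_gt(h2$delta_bic, 10)
  expect_equal(sort(h2$gmm_means), c(2.0, 2.4), tolerance = 0.05)
  ## homogeneous rim: one component preferred, no spatial structure
  stk1 <- gen_flim_stack(geom, list(list(lifetime = 2.0, fraction = 1)),
                         dspec)
  mp1 <- fit_flim_stack(stk1, min_peak_counts = 200)
  h1 <- histogram_heterogeneity(mp1)
  expect_lte(h1$delta_bic, 0)
  mi <- map_morans_i(mp1, seed = 2)
  expect_gt(mi$p_value, 0.01)
})

test_that("histogram of a constant map has zero spread", {
  mp <- structure(list(lifetime = matrix(2, 10, 10),
                       viscosity = matrix(100, 10, 10),
                       mask = matrix(TRUE, 10, 10)),
                  class = "viscosity_map")
  h <- histogram_heterogeneity(mp)
  expect_equal(h$sd, 0)
  small <- structure(list(lifetime = matrix(2, 2, 2),
                          viscosity = matrix(100, 2, 2),
                          mask = matrix(TRUE, 2, 2)),
                     class = "viscosity_map")
  expect_error(histogram_heterogeneity(small), ">= 30")
})
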