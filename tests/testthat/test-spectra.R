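test_that("GP hits its algebraic limits and boundary cases", {
  wl <- seq(400, 560, 0.5)
  ## equal band intensities -> GP = 0
  sym <- emission_spectrum(wl, lognormal_band(wl, 440, 8, 1, 1) +
                             lognormal_band(wl, 490, 8, 1, 1))
  expect_equal(compute_gp(sym)$gp, 0, tolerance = 1e-6)
  ## no red signal -> GP = 1
  blue_only <- emission_spectrum(wl, lognormal_band(wl, 440, 8, 1, 1))
  expect_equal(compute_gp(blue_only)$gp, 1, tolerance = 1e-6)
  ## both bands empty -> error
  empty <- emission_spectrum(wl, lognormal_band(wl, 540, 5, 1, 1))
  expect_error(compute_gp(empty), "no signal")
})

test_that("a blue/red ratio of 0.802 reproduces the POPC-like GP of -0.11", {
  ## narrow bands fully inside the integration windows; the amplitude
  ## ratio sets the band-integral ratio, so GP follows algebraically
  wl <- seq(400, 560, 0.1)
  sp <- emission_spectrum(wl, 0.802 * lognormal_band(wl, 440, 8, 1, 1) +
                            lognormal_band(wl, 490, 8, 1, 1))
  gp <- compute_gp(sp)
  expect_equal(gp$i_blue / gp$i_red, 0.802, tolerance = 1e-3)
  expect_equal(gp$gp, (0.802 - 1) / (0.802 + 1), tolerance = 1e-3)
  expect_equal(round(gp$gp, 2), -0.11)
})

test_that("GP is invariant to uniform intensity scaling", {
  sp <- gen_spectrum(spectrum_sim_spec(three_band_components(),
                                       noise_sd = 0.01, seed = 2))
  g1 <- compute_gp(sp)$gp
  sp2 <- emission_spectrum(sp$wavelengths, sp$intensities * 37.5)
  expect_equal(compute_gp(sp2)$gp, g1, tolerance = 1e-12)
})

test_that("three-band decomposition recovers planted truth", {
  truth <- three_band_components()
  centers <- vapply(truth, `[`, numeric(1), 1)
  ## noiseless: centers within 1 nm, areas within 2%
  sp0 <- gen_spectrum(spectrum_sim_spec(truth, noise_sd = 0))
  d0 <- decompose_lognormal3(sp0)
  expect_lt(max(abs(d0$components[, "center"] - centers)), 1)
  true_areas <- vapply(truth, function(p)
    oxmembrane:::trapz(sp0$wavelengths,
                       lognormal_band(sp0$wavelengths, p[1], p[2], p[3],
                                      p[4])), numeric(1))
  expect_equal(d0$components[, "area_fraction"],
               true_areas / sum(true_areas), tolerance = 0.02,
               ignore_attr = TRUE)
  ## fitted areas conserve the total spectral area within 1%
  fitted_total <- sum(vapply(1:3, function(i)
    oxmembrane:::trapz(sp0$wavelengths,
                       lognormal_band(sp0$wavelengths,
                                      d0$components[i, 1],
                                      d0$components[i, 2],
                                      d0$components[i, 3],
                                      d0$components[i, 4])), numeric(1)))
  expect_equal(fitted_total, d0$total_area, tolerance = 0.01)
  ## 1% multiplicative noise: centers within a few nm across seeds
  errs <- vapply(1:5, function(s) {
    sp <- gen_spectrum(spectrum_sim_spec(truth, noise_sd = 0.01, seed = s))
    d <- decompose_lognormal3(sp, seed = s)
    max(abs(d$components[, "center"] - centers))
  }, numeric(1))
  expect_lt(mean(errs), 2)
  expect_lt(max(errs), 3)
})

test_that("two-component spectra leave the third band empty", {
  sp <- gen_spectrum(spectrum_sim_spec(list(c(425, 40, 1.3, 1),
                                            c(495, 50, 1.3, 0.6)),
                                       noise_sd = 0))
  d <- decompose_lognormal3(sp)
  expect_lt(min(d$components[, "area_fraction"]), 0.02)
  zero <- emission_spectrum(seq(400, 560, 1), rep(0, 161))
  expect_error(decompose_lognormal3(zero), "zeros")
})

test_that("breakpoint detection finds a planted hinge and rejects a line", {
  x <- seq(30, 70, 2.5)
  y_hinge <- -0.002 * x - 0.006 * pmax(x - 50, 0)
  set.seed(4)
  bp <- find_breakpoint(x, y_hinge + rnorm(length(x), 0, 0.004))
  expect_true(bp$significant)
  expect_equal(bp$breakpoint, 50, tolerance = 3)
  expect_lt(bp$slopes["below"], 0)
  expect_lt(bp$slopes["above"], bp$slopes["below"])
  ## perfectly linear: no breakpoint claimed
  set.seed(5)
  lin <- find_breakpoint(x, 0.01 * x + rnorm(length(x), 0, 0.05))
  expect_false(lin$significant)
  expect_true(is.na(lin$breakpoint))
  ## too few points
  expect_error(find_breakpoint(c(30, 40, 50, 60), c(1, 2, 3, 4)), ">= 6")
})

test_that("breakpoint CI shrinks with sample size", {
  width_at <- function(n, seed) {
    x <- seq(30, 70, length.out = n)
    y <- -0.002 * x - 0.006 * pmax(x - 50, 0)
    set.seed(seed)
    bp <- find_breakpoint(x, y + rnorm(n, 0, 0.008), n_boot = 99,
                          seed = seed)
    diff(bp$ci)
  }
  w_small <- mean(vapply(1:3, function(s) width_at(12, s), numeric(1)))
  w_large <- mean(vapply(1:3, function(s) width_at(60, s), numeric(1)))
  expect_lt(w_large, w_small + 1e-9)
})
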