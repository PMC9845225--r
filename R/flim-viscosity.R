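## Molecular-rotor lifetime <-> microviscosity power-law calibration.

#' Construct a lifetime-viscosity calibration
#'
#' Molecular rotors obey a Forster-Hoffmann-type power law
#' `tau = coefficient * eta^exponent`, so viscosity is recovered as
#' `eta = (tau / coefficient)^(1 / exponent)`.
#'
#' @param coefficient scale (ns at 1 cP); > 0.
#' @param exponent power; > 0 (lifetime increases with viscosity).
#' @param valid_range lifetime range (ns) over which the calibration was
#'   established.
#' @param source free-text provenance.
#' @return `viscosity_calibration` object.
#' @export
viscosity_calibration <- function(coefficient, exponent,
                                  valid_range = c(0, Inf),
                                  source = "user") {
  assert_scalar_num(coefficient, "coefficient", 0, strict_lower = TRUE)
  assert_scalar_num(exponent, "exponent", 0, strict_lower = TRUE)
  structure(list(coefficient = coefficient, exponent = exponent,
                 valid_range = valid_range, source = source),
            class = "viscosity_calibration")
}

#' Fit a power-law calibration through viscosity-lifetime pairs
#'
#' Log-log least squares of `tau = coefficient * eta^exponent`; exact
#' through two points.
#'
#' @param pairs two-column matrix or data.frame: viscosity (cP), lifetime
#'   (ns). At least 2 rows with distinct viscosities.
#' @param source provenance string.
#' @return `viscosity_calibration`.
#' @export
calibrate_from_pairs <- function(pairs, source = "fitted pairs") {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 2L) stop_ox("need at least 2 calibration pairs")
  eta <- pairs[, 1]; tau <- pairs[, 2]
  if (any(eta <= 0) || any(tau <= 0)) stop_ox("pairs must be positive")
  if (length(unique(eta)) < 2L) stop_ox("viscosities must be distinct")
  fit <- stats::lm(log(tau) ~ log(eta))
  viscosity_calibration(coefficient = exp(stats::coef(fit)[[1]]),
                        exponent = stats::coef(fit)[[2]],
                        valid_range = range(tau), source = source)
}

#' Default rotor calibration anchored to the in-scope measurements
#'
#' Power law fitted exactly through the two anchor pairs 1.8 ns <-> 159 cP
#' (pure POPC) and 2.1 ns <-> 241 cP (fully peroxidized POPC-OOH). These
#' anchors tie the calibration to the reported lifetime and microviscosity
#' endpoints; they are not the constants of the original published
#' calibration, which are not reproduced here.
#'
#' @return `viscosity_calibration`.
#' @export
default_calibration <- function() {
  calibrate_from_pairs(cbind(c(159, 241), c(1.8, 2.1)),
                       source = "anchored: 1.8 ns ~ 159 cP, 2.1 ns ~ 241 cP")
}

#' Convert a rotor lifetime to microviscosity
#'
#' @param tau lifetime(s) in ns; must be positive.
#' @param cal a `viscosity_calibration`.
#' @return viscosity in cP; strictly increasing in `tau`. Values outside the
#'   calibration's valid lifetime range trigger a warning.
#' @export
lifetime_to_viscosity <- function(tau, cal = default_calibration()) {
  if (!inherits(cal, "viscosity_calibration")) stop_ox("cal must be a viscosity_calibration")
  if (any(!is.finite(tau)) || any(tau <= 0)) stop_ox("tau must be positive")
  if (any(tau < cal$valid_range[1] | tau > cal$valid_range[2]))
    warn_ox("lifetime outside calibration valid range [%g, %g] ns",
            cal$valid_range[1], cal$valid_range[2])
  (tau / cal$coefficient)^(1 / cal$exponent)
}

#' Convert microviscosity back to a rotor lifetime
#'
#' Exact inverse of [lifetime_to_viscosity()].
#'
#' @param eta viscosity in cP; positive.
#' @param cal a `viscosity_calibration`.
#' @return lifetime in ns.
#' @export
viscosity_to_lifetime <- function(eta, cal = default_calibration()) {
  if (!inherits(cal, "viscosity_calibration")) stop_ox("cal must be a viscosity_calibration")
  if (any(!is.finite(eta)) || any(eta <= 0)) stop_ox("eta must be positive")
  cal$coefficient * eta^cal$exponent
}
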