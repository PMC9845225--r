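#' @keywords internal
#' @importFrom mclust Mclust mclustBIC
"_PACKAGE"

## Internal helpers shared across modules. Units throughout the package:
## distance in Angstrom, time in ns, viscosity in cP, energies in kT.

stop_ox <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_ox <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_ox("'%s' must be a finite numeric scalar", name)
  if (strict_lower && x <= lower)
    stop_ox("'%s' must be > %g", name, lower)
  if (!strict_lower && x < lower)
    stop_ox("'%s' must be >= %g", name, lower)
  if (x > upper) stop_ox("'%s' must be <= %g", name, upper)
  invisible(x)
}

## trapezoidal integral on an (optionally irregular) grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

sample_moments <- function(x) {
  n <- length(x)
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    return(list(mean = m, sd = s, skewness = 0, ex_kurtosis = 0))
  }
  z <- (x - m) / s
  list(mean = m, sd = s,
       skewness = mean(z^3),
       ex_kurtosis = mean(z^4) - 3)
}

## FNV-1a 32-bit hash of a deparsed R object; used for config provenance
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), b) + 2^30  # keep in int range
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

## minimum-image displacement components for a periodic box
min_image <- function(d, L) d - L * round(d / L)

## standard two-component Gaussian mixture comparison.
## delta_bic = BIC(1 component) - BIC(2 components) in the smaller-is-better
## convention: positive values favour two components.
gmm_delta_bic <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 10L) stop_ox("need >= 10 values for mixture comparison")
  fit1 <- mclust::Mclust(x, G = 1, modelNames = "V", verbose = FALSE)
  fit2 <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  if (is.null(fit2)) return(list(delta_bic = -Inf, means = mean(x), fit = fit1))
  ## mclust reports BIC as 2*loglik - penalty (larger is better); convert
  delta <- as.numeric(fit2$bic - fit1$bic)
  list(delta_bic = delta,
       means = as.numeric(fit2$parameters$mean),
       sds = sqrt(as.numeric(fit2$parameters$variance$sigmasq)),
       proportions = as.numeric(fit2$parameters$pro),
       fit = fit2)
}
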