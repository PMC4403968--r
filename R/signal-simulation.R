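#' Noiseless IVIM forward signal
#'
#' Evaluates the bi-exponential IVIM model
#' `S(b) = s0 * (f * exp(-b * dStar) + (1 - f) * exp(-b * d))`
#' at every measurement of the scheme.  With `f = 0` this reduces exactly to
#' the mono-exponential ADC model `S(b) = s0 * exp(-b * d)`.
#'
#' @param params an [IVIMParams-class] object.
#' @param scheme an [AcquisitionScheme-class] object.
#' @return Numeric vector of noiseless signals, one per measurement.
#' @examples
#' sc <- dwiScheme()
#' ivimSignal(ivimParams(s0 = 1000, d = 1.099e-3, f = 0), sc)
#' @export
ivimSignal <- function(params, scheme) {
  validObject(params)
  validObject(scheme)
  b <- bValues(scheme)
  params@s0 * (params@f * exp(-b * params@dStar) +
                 (1 - params@f) * exp(-b * params@d))
}

#' Noiseless diffusion-tensor forward signal
#'
#' Evaluates the standard tensor forward model
#' `S = s0 * exp(-b * g' D g)` for every direction-encoded measurement;
#' b = 0 measurements return `s0`.
#'
#' @param params a [TensorParams-class] object.
#' @param scheme an [AcquisitionScheme-class] object whose b > 0
#'   measurements all carry unit directions.
#' @return Numeric vector of noiseless signals, one per measurement.
#' @examples
#' sc <- dtiScheme(32)
#' tensorSignal(tensorParams(1000, c(1.7e-3, 0.3e-3, 0.1e-3)), sc)
#' @export
tensorSignal <- function(params, scheme) {
  validObject(params)
  validObject(scheme)
  b <- bValues(scheme)
  g <- gradientDirections(scheme)
  weighted <- b > 0
  if (any(weighted & rowSums(is.na(g)) > 0L)) {
    stopValidation("all b > 0 measurements need gradient directions")
  }
  out <- rep(params@s0, length(b))
  if (any(weighted)) {
    gw <- g[weighted, , drop = FALSE]
    quad <- rowSums((gw %*% params@tensor) * gw)
    out[weighted] <- params@s0 * exp(-b[weighted] * quad)
  }
  out
}

#' Add Rician magnitude noise to a signal
#'
#' Magnitude MR images carry Rician noise: the noiseless signal is placed in
#' the real channel, independent zero-mean Gaussian noise of scale `sigma`
#' is added to both quadrature channels, and the magnitude
#' `sqrt((s + n1)^2 + n2^2)` is returned.  This reproduces the rectified
#' noise floor that biases FA and the IVIM perfusion fraction upward at low
#' SNR; Gaussian noise would not.
#'
#' @param signal numeric vector (or array) of noiseless magnitudes.
#' @param sigma noise scale in signal units, `>= 0`.  `sigma = 0` returns
#'   the input unchanged.
#' @param seed integer seed; required when `sigma > 0` (the function never
#'   consumes hidden global RNG state).
#' @return Noisy magnitudes with the same shape as `signal`; always
#'   non-negative.
#' @examples
#' addRicianNoise(c(100, 50, 10), sigma = 1, seed = 7)
#' @export
addRicianNoise <- function(signal, sigma, seed = NULL) {
  assertScalarNumber(sigma, "sigma")
  if (sigma < 0) stopValidation("'sigma' must be >= 0, got %g", sigma)
  if (sigma == 0) return(signal)
  if (is.null(seed)) {
    stopValidation("a 'seed' is required when sigma > 0")
  }
  withSeed(seed, {
    n <- length(signal)
    n1 <- rnorm(n, 0, sigma)
    n2 <- rnorm(n, 0, sigma)
    out <- sqrt((as.numeric(signal) + n1)^2 + n2^2)
    if (!is.null(dim(signal))) dim(out) <- dim(signal)
    out
  })
}
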