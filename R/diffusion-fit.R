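#' ADCFit: result of a log-linear mono-exponential fit
#'
#' @slot adc apparent diffusion coefficient (mm^2 s^-1), the negative slope
#'   of the ordinary least-squares line through (b, ln signal).
#' @slot intercept fitted ln-signal at b = 0.
#' @slot nPoints number of (b, signal) points used.
#' @slot valid `FALSE` when fewer than two positive-signal b-values were
#'   available.
#' @seealso [fitADC()]
#' @export
setClass("ADCFit",
  representation(adc = "numeric", intercept = "numeric",
                 nPoints = "integer", valid = "logical"))

#' IVIMFit: result of the segmented bi-exponential fit
#'
#' @slot d slow (tissue) diffusion coefficient (mm^2 s^-1), from step 1.
#' @slot f perfusion fraction in `[0, 1]`, from step 2.
#' @slot dStar pseudo-diffusion coefficient (mm^2 s^-1), from step 2.
#' @slot converged optimizer status of the Nelder-Mead step.
#' @slot sse residual sum of squares of the step-2 objective.
#' @slot valid `FALSE` for degenerate signals.
#' @seealso [fitIVIM()]
#' @export
setClass("IVIMFit",
  representation(d = "numeric", f = "numeric", dStar = "numeric",
                 converged = "logical", sse = "numeric", valid = "logical"))

#' TensorFit: result of the log-linear tensor fit
#'
#' @slot tensor estimated 3 x 3 symmetric tensor (mm^2 s^-1).
#' @slot eigenvalues eigenvalues sorted descending (raw, unclamped).
#' @slot md mean diffusivity, `mean(eigenvalues)`.
#' @slot fa fractional anisotropy in `[0, 1]`, computed after clamping
#'   negative eigenvalues to zero.
#' @slot clamped `TRUE` when any eigenvalue was negative and clamped.
#' @slot valid `FALSE` for degenerate signals.
#' @seealso [fitTensor()]
#' @export
setClass("TensorFit",
  representation(tensor = "matrix", eigenvalues = "numeric",
                 md = "numeric", fa = "numeric", clamped = "logical",
                 valid = "logical"))

#' @export
setMethod("show", "ADCFit", function(object) {
  cat(sprintf("ADCFit: adc = %g mm^2/s (n = %d%s)\n", object@adc,
              object@nPoints, if (object@valid) "" else ", INVALID"))
})

#' @export
setMethod("show", "IVIMFit", function(object) {
  cat(sprintf("IVIMFit: D = %g, f = %g, D* = %g (sse = %g%s%s)\n",
              object@d, object@f, object@dStar, object@sse,
              if (object@converged) "" else ", not converged",
              if (object@valid) "" else ", INVALID"))
})

#' @export
setMethod("show", "TensorFit", function(object) {
  cat(sprintf("TensorFit: MD = %g, FA = %g; eigenvalues (%g, %g, %g)%s\n",
              object@md, object@fa, object@eigenvalues[1],
              object@eigenvalues[2], object@eigenvalues[3],
              if (object@valid) "" else " INVALID"))
})

invalidADCFit <- function() {
  new("ADCFit", adc = NA_real_, intercept = NA_real_, nPoints = 0L,
      valid = FALSE)
}

invalidIVIMFit <- function() {
  new("IVIMFit", d = NA_real_, f = NA_real_, dStar = NA_real_,
      converged = FALSE, sse = NA_real_, valid = FALSE)
}

## Average repeated measurements per unique b-value (multiple b = 0 images
## and signal-averaged trace measurements); used for the scalar ADC/IVIM
## fits, never for tensor fitting where each direction matters.
collapseByB <- function(signals, b) {
  ub <- sort(unique(b))
  s <- vapply(ub, function(bb) mean(signals[b == bb]), numeric(1))
  list(b = ub, s = s)
}

#' Log-linear ADC fit
#'
#' Fits the mono-exponential decay by unweighted ordinary least squares on
#' `ln(signal)` versus b; the ADC is the negative slope.  The b = 0
#' intercept is fitted rather than pinned to the measured b = 0 signal.
#' Repeated measurements at the same b-value are averaged first, and
#' non-positive signals are excluded from the log fit; a voxel with fewer
#' than two usable distinct b-values yields an invalid fit (not an error),
#' so that volume-level fitting can flag rather than abort.
#'
#' With exactly two b-values the estimate equals the closed form
#' `ln(s0 / sb) / (b - b0)`.
#'
#' @param signals numeric vector of measured magnitudes.
#' @param scheme an [AcquisitionScheme-class] object matching `signals`, or
#'   a numeric vector of b-values.
#' @param bSubset optional b-values to restrict the fit to (e.g. the
#'   clinical subset `c(0, 500, 1000)` of a richer acquisition).
#' @return An [ADCFit-class] object.
#' @examples
#' sc <- dwiScheme(c(0, 500, 1000))
#' s <- ivimSignal(ivimParams(s0 = 1000, d = 1.099e-3, f = 0), sc)
#' fitADC(s, sc)
#' @export
fitADC <- function(signals, scheme, bSubset = NULL) {
  b <- if (is(scheme, "AcquisitionScheme")) bValues(scheme)
       else as.numeric(scheme)
  if (length(signals) != length(b)) {
    stopValidation("length of 'signals' (%d) does not match the scheme (%d)",
                   length(signals), length(b))
  }
  if (!is.null(bSubset)) {
    keep <- b %in% bSubset
    signals <- signals[keep]
    b <- b[keep]
  }
  cb <- collapseByB(signals, b)
  use <- cb$s > 0
  if (sum(use) < 2L || length(unique(cb$b[use])) < 2L) {
    return(invalidADCFit())
  }
  fit <- lm.fit(cbind(1, cb$b[use]), log(cb$s[use]))
  new("ADCFit", adc = -unname(fit$coefficients[2]),
      intercept = unname(fit$coefficients[1]),
      nPoints = sum(use), valid = TRUE)
}

#' Segmented (stepwise-sequential) IVIM fit
#'
#' Two-step estimation of the bi-exponential IVIM model, as used when a
#' direct four-parameter fit is too unstable for clinical data:
#'
#' 1. **D** comes from ordinary least squares on `ln(signal)` versus b
#'    restricted to `b >= bThreshold` (default 300 s mm^-2), where the fast
#'    pseudo-diffusion compartment has decayed away.
#' 2. **f and D*** minimise the untransformed-signal sum of squares
#'    `sum((S_b - s0 * (f * exp(-b * dStar) + (1 - f) * exp(-b * d)))^2)`
#'    over all b-values with D fixed, via Nelder-Mead.  `s0` is fixed at
#'    the mean measured b = 0 signal.
#'
#' Bounds (`f` in \[0, 1\], `dStar` in \[d, 1\] mm^2 s^-1) are enforced by a
#' logistic reparameterisation so the simplex stays unconstrained.
#' Initialisation: `f0 = 1 - exp(step-1 intercept) / s0` clamped to
#' \[0.01, 0.5\] (the intercept deficit is the standard segmented-IVIM f
#' estimate) and `dStar0 = 10 * d`.  Convergence uses a relative tolerance
#' of 1e-8 with at most 2000 iterations; on non-convergence the best point
#' so far is returned with `converged = FALSE`.
#'
#' Because the pseudo-diffusion tail has not fully decayed at the
#' threshold (about 0.7% of the signal at b = 300 for f = 0.1,
#' D* = 10e-3), the plain two-step estimate of D carries a bias of order
#' 1%.  The two steps are therefore iterated: each refinement pass
#' re-estimates D on the perfusion-corrected high-b signals
#' `S - s0 * f * exp(-b * dStar)` and then re-runs step 2, until the
#' parameters are stable to 1e-10 relative (at most `maxRefine` passes).
#' On noiseless data this converges to the exact generating parameters;
#' `maxRefine = 0` gives the plain two-step estimate.
#'
#' @param signals numeric vector of measured magnitudes.
#' @param scheme an [AcquisitionScheme-class] object or numeric b-values.
#' @param bThreshold split point (s mm^-2) between the perfusion regime and
#'   the pure-diffusion regime.
#' @param maxRefine maximum number of step-1/step-2 refinement passes after
#'   the initial two steps.
#' @return An [IVIMFit-class] object.
#' @examples
#' sc <- dwiScheme()
#' s <- ivimSignal(ivimParams(1000, d = 0.7e-3, dStar = 10e-3, f = 0.1), sc)
#' fitIVIM(s, sc)
#' @export
fitIVIM <- function(signals, scheme, bThreshold = 300, maxRefine = 25L) {
  b <- if (is(scheme, "AcquisitionScheme")) bValues(scheme)
       else as.numeric(scheme)
  if (length(signals) != length(b)) {
    stopValidation("length of 'signals' (%d) does not match the scheme (%d)",
                   length(signals), length(b))
  }
  cb <- collapseByB(signals, b)
  hi <- cb$b >= bThreshold
  lo <- cb$b < bThreshold
  if (sum(hi & cb$s > 0) < 2L || !any(lo)) {
    return(invalidIVIMFit())
  }
  s0 <- mean(cb$s[cb$b == 0])
  if (!is.finite(s0) || s0 <= 0) return(invalidIVIMFit())
  dStarMax <- 1

  ## step 1: D from the high-b log-linear fit (own intercept);
  ## `perfusion` is the current estimate of the fast compartment, zero on
  ## the first pass.
  step1 <- function(perfusion) {
    sCorr <- cb$s - perfusion
    use <- hi & sCorr > 0
    if (sum(use) < 2L) return(NULL)
    fit <- lm.fit(cbind(1, cb$b[use]), log(sCorr[use]))
    list(d = -unname(fit$coefficients[2]),
         intercept = unname(fit$coefficients[1]))
  }

  ## step 2: f and D* on all b with D fixed, logistic-transformed bounds
  step2 <- function(d, f0, dStar0) {
    dLow <- max(d, 0)
    f0 <- min(max(f0, 1e-8), 1 - 1e-8)
    dStar0 <- min(max(dStar0, dLow + 1e-9), dStarMax - 1e-9)
    fromTheta <- function(theta) {
      c(f = plogis(theta[1]),
        dStar = dLow + (dStarMax - dLow) * plogis(theta[2]))
    }
    objective <- function(theta) {
      p <- fromTheta(theta)
      pred <- s0 * (p[1] * exp(-cb$b * p[2]) + (1 - p[1]) * exp(-cb$b * d))
      sum((cb$s - pred)^2)
    }
    theta0 <- c(qlogis(f0), qlogis((dStar0 - dLow) / (dStarMax - dLow)))
    opt <- optim(theta0, objective, method = "Nelder-Mead",
                 control = list(reltol = 1e-8, maxit = 2000))
    p <- fromTheta(opt$par)
    list(f = unname(p[1]), dStar = unname(p[2]),
         converged = opt$convergence == 0L, sse = opt$value)
  }

  s1 <- step1(0)
  if (is.null(s1)) return(invalidIVIMFit())
  d <- s1$d
  f0 <- min(max(1 - exp(s1$intercept) / s0, 0.01), 0.5)
  s2 <- step2(d, f0, 10 * max(d, 1e-6))
  for (it in seq_len(maxRefine)) {
    prev <- c(d, s2$f, s2$dStar)
    perfusion <- s0 * s2$f * exp(-cb$b * s2$dStar)
    s1 <- step1(perfusion)
    if (is.null(s1)) break
    d <- s1$d
    s2 <- step2(d, max(s2$f, 1e-8), s2$dStar)
    if (all(abs(c(d, s2$f, s2$dStar) - prev) <=
              1e-10 * (abs(prev) + 1e-12))) break
  }
  new("IVIMFit", d = d, f = s2$f, dStar = s2$dStar,
      converged = s2$converged, sse = s2$sse, valid = TRUE)
}

#' Log-linear diffusion-tensor fit
#'
#' Solves the linearised tensor model `ln(S/S0) = -b g' D g` by unweighted
#' least squares over all measurements (each gradient direction kept, the
#' ln-S0 intercept fitted alongside the six tensor elements).  Eigenvalues
#' are reported sorted descending; negative eigenvalues are clamped to zero
#' before FA (and the clamping recorded) but returned unclamped in the
#' `eigenvalues` slot.
#'
#' @param signals numeric vector of measured magnitudes.
#' @param scheme an [AcquisitionScheme-class] object with at least six
#'   non-collinear directions at b > 0 and at least one b = 0 measurement.
#' @return A [TensorFit-class] object.
#' @examples
#' sc <- dtiScheme(32)
#' s <- tensorSignal(tensorParams(1000, c(1.7e-3, 0.3e-3, 0.1e-3)), sc)
#' fitTensor(s, sc)
#' @export
fitTensor <- function(signals, scheme) {
  if (!is(scheme, "AcquisitionScheme")) {
    stopValidation("'scheme' must be an AcquisitionScheme")
  }
  b <- bValues(scheme)
  g <- gradientDirections(scheme)
  if (length(signals) != length(b)) {
    stopValidation("length of 'signals' (%d) does not match the scheme (%d)",
                   length(signals), length(b))
  }
  if (any(b > 0 & rowSums(is.na(g)) > 0L)) {
    stopValidation("tensor fitting needs gradient directions at every b > 0")
  }
  use <- signals > 0
  if (sum(use) < 7L) {
    return(new("TensorFit", tensor = matrix(NA_real_, 3, 3),
               eigenvalues = rep(NA_real_, 3), md = NA_real_,
               fa = NA_real_, clamped = FALSE, valid = FALSE))
  }
  g0 <- g
  g0[is.na(g0)] <- 0
  X <- cbind(1,
             -b * g0[, 1]^2, -b * g0[, 2]^2, -b * g0[, 3]^2,
             -2 * b * g0[, 1] * g0[, 2],
             -2 * b * g0[, 1] * g0[, 3],
             -2 * b * g0[, 2] * g0[, 3])[use, , drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < 7L) {
    stopValidation(paste0(
      "rank-deficient tensor design (rank %d < 7): the scheme needs >= 6 ",
      "non-collinear gradient directions at b > 0 plus a b = 0 measurement"),
      qrX$rank)
  }
  beta <- qr.coef(qrX, log(signals[use]))
  D <- matrix(c(beta[2], beta[5], beta[6],
                beta[5], beta[3], beta[7],
                beta[6], beta[7], beta[4]), 3, 3)
  ev <- sort(eigen(D, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  clamped <- any(ev < 0)
  mf <- mdFA(pmax(ev, 0))
  new("TensorFit", tensor = D, eigenvalues = ev,
      md = mean(ev), fa = mf[["fa"]], clamped = clamped, valid = TRUE)
}

#' Mean diffusivity and fractional anisotropy from eigenvalues
#'
#' `md = mean(lambda)`;
#' `fa = sqrt(3/2) * sqrt(sum((lambda - md)^2)) / sqrt(sum(lambda^2))`.
#' FA is 0 for isotropic diffusion, 1 in the single-nonzero-eigenvalue
#' (stick) limit, and defined as 0 for all-zero eigenvalues.
#'
#' @param eigenvalues numeric length-3 vector of non-negative eigenvalues.
#' @return Named numeric vector with elements `md` and `fa`.
#' @examples
#' mdFA(c(1.7e-3, 0.3e-3, 0.1e-3))
#' @export
mdFA <- function(eigenvalues) {
  if (length(eigenvalues) != 3L || any(!is.finite(eigenvalues))) {
    stopValidation("'eigenvalues' must be three finite numbers")
  }
  if (any(eigenvalues < 0)) {
    stopValidation("'eigenvalues' must be >= 0 (clamp before calling)")
  }
  md <- mean(eigenvalues)
  ss <- sum(eigenvalues^2)
  fa <- if (ss == 0) 0 else {
    sqrt(1.5) * sqrt(sum((eigenvalues - md)^2)) / sqrt(ss)
  }
  c(md = md, fa = min(max(fa, 0), 1))
}
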