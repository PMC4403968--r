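#' AcquisitionScheme: b-values and gradient directions of a DWI protocol
#'
#' An acquisition scheme lists, per measurement, the diffusion weighting
#' (b-value, s mm^-2) and, for direction-encoded measurements, the unit
#' gradient direction.  Trace-weighted DWI protocols carry no directions;
#' tensor protocols need at least six non-collinear directions at b > 0.
#'
#' @slot bValues numeric vector of b-values (s mm^-2), one per measurement.
#' @slot directions numeric matrix with one row per measurement and three
#'   columns; rows of `NA` mark trace-weighted or b = 0 measurements.
#'
#' @seealso [acquisitionScheme()], [dwiScheme()], [dtiScheme()]
#' @export
setClass("AcquisitionScheme",
  representation(bValues = "numeric", directions = "matrix"),
  validity = function(object) {
    b <- object@bValues
    g <- object@directions
    if (length(b) == 0L) return("scheme has no measurements")
    if (any(!is.finite(b)) || any(b < 0)) {
      return("all b-values must be finite and >= 0")
    }
    if (!any(b == 0)) return("at least one b = 0 measurement is required")
    if (nrow(g) != length(b) || ncol(g) != 3L) {
      return("'directions' must have one row per measurement and 3 columns")
    }
    hasDir <- rowSums(is.na(g)) == 0L
    if (any(hasDir)) {
      nrm <- sqrt(rowSums(g[hasDir, , drop = FALSE]^2))
      if (any(abs(nrm - 1) > 1e-9)) {
        return("gradient directions must have unit norm (tolerance 1e-9)")
      }
    }
    TRUE
  }
)

#' IVIMParams: ground-truth bi-exponential voxel parameters
#'
#' Parameters of the intra-voxel incoherent motion (IVIM) signal model
#' `S(b) = s0 * (f * exp(-b * dStar) + (1 - f) * exp(-b * d))`, in which a
#' perfusion fraction `f` of the signal decays with the fast pseudo-diffusion
#' coefficient `dStar` and the remainder with the tissue diffusion
#' coefficient `d`.
#'
#' @slot s0 unattenuated signal (> 0, arbitrary units).
#' @slot d tissue diffusion coefficient (mm^2 s^-1).
#' @slot dStar pseudo-diffusion coefficient (mm^2 s^-1), `>= d`.
#' @slot f perfusion fraction in `[0, 1]`.
#'
#' @seealso [ivimParams()], [ivimSignal()]
#' @export
setClass("IVIMParams",
  representation(s0 = "numeric", d = "numeric", dStar = "numeric",
                 f = "numeric"),
  validity = function(object) {
    if (length(object@s0) != 1L || !is.finite(object@s0) || object@s0 <= 0) {
      return("'s0' must be a single positive number")
    }
    if (object@f < 0 || object@f > 1) return("'f' must lie in [0, 1]")
    if (object@d < 0) return("'d' must be >= 0")
    if (object@d > object@dStar) return("'d' must not exceed 'dStar'")
    TRUE
  }
)

#' TensorParams: ground-truth diffusion-tensor voxel parameters
#'
#' @slot s0 unattenuated signal (> 0).
#' @slot tensor 3 x 3 symmetric positive-semidefinite diffusivity matrix
#'   (mm^2 s^-1).
#'
#' @seealso [tensorParams()], [tensorSignal()]
#' @export
setClass("TensorParams",
  representation(s0 = "numeric", tensor = "matrix"),
  validity = function(object) {
    if (length(object@s0) != 1L || !is.finite(object@s0) || object@s0 <= 0) {
      return("'s0' must be a single positive number")
    }
    D <- object@tensor
    if (!is.numeric(D) || any(dim(D) != c(3L, 3L))) {
      return("'tensor' must be a numeric 3 x 3 matrix")
    }
    if (max(abs(D - t(D))) > 1e-12) {
      return("'tensor' must be symmetric (tolerance 1e-12)")
    }
    ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < -1e-12 * max(abs(ev), 1e-30))) {
      return("'tensor' must be positive semidefinite")
    }
    TRUE
  }
)

#' PhantomSpec: geometry and diffusivities of the ice-water phantom
#'
#' Describes a cylindrical-tube diffusion phantom: five tubes of distilled
#' water at the ice-water reference diffusivity (1.099e-3 mm^2 s^-1 at 0
#' degrees C) plus one sucrose tube, arranged in a ring inside the field of
#' view.
#'
#' @slot nWaterTubes number of water tubes.
#' @slot waterD water diffusivity (mm^2 s^-1).
#' @slot sucroseD sucrose-tube diffusivity (mm^2 s^-1).
#' @slot tubeRadiusVox tube radius in voxels (in plane).
#' @slot imageShape integer length-3 spatial image dimensions.
#' @slot voxelSizeMM voxel dimensions in mm.
#' @slot s0 unattenuated in-tube signal.
#'
#' @seealso [phantomSpec()], [simulatePhantom()]
#' @export
setClass("PhantomSpec",
  representation(nWaterTubes = "integer", waterD = "numeric",
                 sucroseD = "numeric", tubeRadiusVox = "numeric",
                 imageShape = "integer", voxelSizeMM = "numeric",
                 s0 = "numeric"),
  validity = function(object) {
    if (object@nWaterTubes < 1L) return("'nWaterTubes' must be >= 1")
    if (object@waterD <= 0) return("'waterD' must be > 0")
    if (object@sucroseD < 0) return("'sucroseD' must be >= 0")
    if (object@tubeRadiusVox <= 0) return("'tubeRadiusVox' must be > 0")
    if (length(object@imageShape) != 3L || any(object@imageShape < 1L)) {
      return("'imageShape' must be three positive integers")
    }
    if (length(object@voxelSizeMM) != 3L || any(object@voxelSizeMM <= 0)) {
      return("'voxelSizeMM' must be three positive numbers")
    }
    if (object@s0 <= 0) return("'s0' must be > 0")
    TRUE
  }
)

#' ScannerProfile: one scanner in a multi-centre design
#'
#' Carries the scanner's field strength, its per-metric additive fixed
#' effect (the systematic offset the scanner imposes on each diffusion
#' metric, in metric units) and its Rician noise scale for image-level
#' simulation.
#'
#' @slot scannerId scanner label (e.g. `"A"`).
#' @slot fieldStrength 1.5 or 3 (tesla).
#' @slot metricOffsets named numeric vector of additive fixed effects.
#' @slot noiseSigma Rician noise scale (signal units), `>= 0`.
#'
#' @seealso [scannerProfile()], [studyDesign()]
#' @export
setClass("ScannerProfile",
  representation(scannerId = "character", fieldStrength = "numeric",
                 metricOffsets = "numeric", noiseSigma = "numeric"),
  validity = function(object) {
    if (length(object@scannerId) != 1L || !nzchar(object@scannerId)) {
      return("'scannerId' must be a non-empty string")
    }
    if (!object@fieldStrength %in% c(1.5, 3)) {
      return("'fieldStrength' must be 1.5 or 3")
    }
    if (length(object@metricOffsets) &&
        is.null(names(object@metricOffsets))) {
      return("'metricOffsets' must be named by metric")
    }
    if (object@noiseSigma < 0) return("'noiseSigma' must be >= 0")
    TRUE
  }
)

#' StudyDesign: scanner/volunteer/session layout and effect sizes
#'
#' Defines a multi-centre volunteer study: which volunteers visit which
#' scanner, how many sessions each (scanner, volunteer) pair contributes,
#' and, per metric and region, the true grand mean, the volunteer
#' random-effect SD and the session-level residual SD used by
#' [simulateStudy()].
#'
#' @slot scanners list of [ScannerProfile-class] objects.
#' @slot volunteers named list mapping scanner id to volunteer ids.
#' @slot repeats data.frame with columns `scanner`, `volunteer`, `sessions`
#'   giving session counts above 1 (pairs absent from the table have one
#'   session).
#' @slot truth data.frame with columns `metric`, `region`, `grandMean`,
#'   `volunteerSD`, `residualSD`.
#'
#' @seealso [studyDesign()], [replicaStudyDesign()], [simulateStudy()]
#' @export
setClass("StudyDesign",
  representation(scanners = "list", volunteers = "list",
                 repeats = "data.frame", truth = "data.frame"),
  validity = function(object) {
    if (length(object@scanners) == 0L) return("design has no scanners")
    if (!all(vapply(object@scanners, is, logical(1), "ScannerProfile"))) {
      return("'scanners' must all be ScannerProfile objects")
    }
    ids <- vapply(object@scanners, function(s) s@scannerId, character(1))
    if (anyDuplicated(ids)) return("scanner ids must be unique")
    if (!setequal(names(object@volunteers), ids)) {
      return("'volunteers' must be named by the scanner ids")
    }
    if (any(lengths(object@volunteers) < 1L)) {
      return("every scanner needs at least one volunteer")
    }
    need <- c("scanner", "volunteer", "sessions")
    if (!all(need %in% names(object@repeats))) {
      return("'repeats' needs columns scanner, volunteer, sessions")
    }
    if (nrow(object@repeats)) {
      ok <- mapply(function(s, v) s %in% ids &&
                     v %in% object@volunteers[[s]],
                   object@repeats$scanner, object@repeats$volunteer)
      if (!all(ok)) return("'repeats' refers to unknown scanner/volunteer")
      if (any(object@repeats$sessions < 1)) {
        return("session counts must be >= 1")
      }
    }
    needT <- c("metric", "region", "grandMean", "volunteerSD", "residualSD")
    if (!all(needT %in% names(object@truth)) || nrow(object@truth) == 0L) {
      return("'truth' needs rows with metric, region, grandMean, volunteerSD, residualSD")
    }
    if (any(object@truth$volunteerSD < 0) || any(object@truth$residualSD < 0)) {
      return("all effect SDs must be >= 0")
    }
    TRUE
  }
)

#' VarianceComponents: mixed-model decomposition for one metric and region
#'
#' Holds the grand mean and the three standard deviations the mixed model
#' separates: the SD of the scanner fixed effects (inter-scanner), the SD of
#' the volunteer random effect (inter-volunteer) and the residual SD
#' (intra-scanner).
#'
#' @slot mu grand mean (unweighted mean of the estimated scanner means).
#' @slot sigmaInter sample SD of the estimated scanner means.
#' @slot sigmaVolunteer volunteer random-effect SD.
#' @slot sigmaIntra residual SD.
#' @slot volunteerEstimable `FALSE` when the random-effect variance hit the
#'   zero boundary (reported as "NE").
#' @slot converged `FALSE` when the REML fit did not converge cleanly.
#' @slot metric,region,subgroup labels.
#' @slot nObs,nScanners,nVolunteers data dimensions used in the fit.
#'
#' @seealso [fitVarianceComponents()], [reproResult()]
#' @export
setClass("VarianceComponents",
  representation(mu = "numeric", sigmaInter = "numeric",
                 sigmaVolunteer = "numeric", sigmaIntra = "numeric",
                 volunteerEstimable = "logical", converged = "logical",
                 metric = "character", region = "character",
                 subgroup = "character", nObs = "integer",
                 nScanners = "integer", nVolunteers = "integer"),
  validity = function(object) {
    if (!is.finite(object@mu)) return("'mu' must be finite")
    sds <- c(object@sigmaInter, object@sigmaVolunteer, object@sigmaIntra)
    if (any(is.na(sds)) || any(sds < 0)) return("all SDs must be >= 0")
    TRUE
  }
)

#' ReproResult: reproducibility metrics for one metric, region and subgroup
#'
#' Derived from a [VarianceComponents-class] object: coefficients of
#' variation (percent, `100 * sigma / mu`) for the inter-scanner,
#' inter-volunteer and intra-scanner components, and the intraclass
#' correlation pair splitting `sigmaInter^2 + sigmaIntra^2` between
#' between-scanner and within-scanner sources.
#'
#' @slot metric,region,subgroup labels.
#' @slot mu,sigmaInter,sigmaVolunteer,sigmaIntra model estimates.
#' @slot cvInter,cvVolunteer,cvIntra CVs in percent.
#' @slot iccInter,iccIntra intraclass correlation proportions (sum to 1).
#' @slot volunteerEstimable flag propagated from the variance components.
#'
#' @seealso [reproResult()], [summarizeReport()]
#' @export
setClass("ReproResult",
  representation(metric = "character", region = "character",
                 subgroup = "character", mu = "numeric",
                 sigmaInter = "numeric", sigmaVolunteer = "numeric",
                 sigmaIntra = "numeric", cvInter = "numeric",
                 cvVolunteer = "numeric", cvIntra = "numeric",
                 iccInter = "numeric", iccIntra = "numeric",
                 volunteerEstimable = "logical"),
  validity = function(object) {
    iccs <- c(object@iccInter, object@iccIntra)
    if (all(is.finite(iccs)) && abs(sum(iccs) - 1) > 1e-12) {
      return("iccInter + iccIntra must equal 1")
    }
    cvs <- c(object@cvInter, object@cvVolunteer, object@cvIntra)
    if (any(is.finite(cvs) & cvs < 0)) return("CVs must be >= 0")
    TRUE
  }
)
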