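#' Construct an acquisition scheme
#'
#' @param bValues numeric vector of b-values (s mm^-2); at least one must
#'   be 0.
#' @param directions optional matrix of gradient directions with one row
#'   per measurement (rows for b = 0 measurements are ignored and stored as
#'   `NA`).  Omit for trace-weighted DWI.
#'
#' @return An [AcquisitionScheme-class] object.
#' @examples
#' acquisitionScheme(c(0, 50, 100, 300, 500, 600, 1000))
#' @export
acquisitionScheme <- function(bValues, directions = NULL) {
  bValues <- as.numeric(bValues)
  if (is.null(directions)) {
    directions <- matrix(NA_real_, nrow = length(bValues), ncol = 3L)
  } else {
    directions <- as.matrix(directions)
    if (nrow(directions) == 3L && ncol(directions) != 3L) {
      directions <- t(directions)
    }
    dimnames(directions) <- NULL
    directions[bValues == 0, ] <- NA_real_
  }
  new("AcquisitionScheme", bValues = bValues, directions = directions)
}

#' @rdname acquisitionScheme
#' @export
dwiScheme <- function(bValues = c(0, 50, 100, 300, 500, 600, 1000)) {
  acquisitionScheme(bValues)
}

#' Direction-encoded scheme for tensor estimation
#'
#' Directions are placed on a deterministic Fibonacci hemisphere, giving a
#' well-conditioned design matrix for any `nDirections >= 6`.
#'
#' @param nDirections number of diffusion-weighted directions.
#' @param b b-value of the weighted measurements (s mm^-2).
#' @param nB0 number of b = 0 measurements.
#' @rdname acquisitionScheme
#' @export
dtiScheme <- function(nDirections = 32, b = 1000, nB0 = 1) {
  if (nDirections < 6) {
    stopValidation("tensor estimation needs >= 6 directions, got %d",
                   nDirections)
  }
  i <- seq_len(nDirections) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- i / nDirections          # hemisphere: z in (0, 1)
  r <- sqrt(pmax(1 - z^2, 0))
  g <- cbind(r * cos(phi), r * sin(phi), z)
  g <- g / sqrt(rowSums(g^2))
  acquisitionScheme(c(rep(0, nB0), rep(b, nDirections)),
                    rbind(matrix(NA_real_, nB0, 3), g))
}

#' Construct IVIM voxel parameters
#'
#' @param s0 unattenuated signal (> 0).
#' @param d tissue diffusion coefficient (mm^2 s^-1).
#' @param dStar pseudo-diffusion coefficient (mm^2 s^-1); must be `>= d`.
#' @param f perfusion fraction in `[0, 1]`.
#' @return An [IVIMParams-class] object.
#' @examples
#' ivimParams(s0 = 1000, d = 0.7e-3, dStar = 10e-3, f = 0.1)
#' @export
ivimParams <- function(s0 = 1000, d = 1.099e-3, dStar = 10e-3, f = 0) {
  new("IVIMParams", s0 = as.numeric(s0), d = as.numeric(d),
      dStar = as.numeric(dStar), f = as.numeric(f))
}

#' Construct diffusion-tensor voxel parameters
#'
#' @param s0 unattenuated signal (> 0).
#' @param tensor 3 x 3 symmetric positive-semidefinite matrix, or a length-3
#'   vector of eigenvalues placed on the diagonal.
#' @return A [TensorParams-class] object.
#' @examples
#' tensorParams(1000, c(1.7e-3, 0.3e-3, 0.1e-3))
#' @export
tensorParams <- function(s0 = 1000, tensor = diag(1e-3, 3)) {
  if (is.numeric(tensor) && is.null(dim(tensor)) && length(tensor) == 3L) {
    tensor <- diag(tensor)
  }
  new("TensorParams", s0 = as.numeric(s0), tensor = tensor)
}

#' Construct an ice-water phantom specification
#'
#' @param nWaterTubes number of water tubes (default 5).
#' @param waterD water diffusivity; defaults to the ice-water reference
#'   value 1.099e-3 mm^2 s^-1 at 0 degrees C.
#' @param sucroseD sucrose-tube diffusivity (mm^2 s^-1).
#' @param tubeRadiusVox in-plane tube radius in voxels.
#' @param imageShape spatial image dimensions.
#' @param voxelSizeMM voxel size in mm.
#' @param s0 unattenuated in-tube signal.
#' @return A [PhantomSpec-class] object.
#' @export
phantomSpec <- function(nWaterTubes = 5L, waterD = 1.099e-3,
                        sucroseD = 0.5e-3, tubeRadiusVox = 4,
                        imageShape = c(48L, 48L, 4L),
                        voxelSizeMM = c(1.8, 1.8, 5), s0 = 1000) {
  new("PhantomSpec", nWaterTubes = as.integer(nWaterTubes),
      waterD = waterD, sucroseD = sucroseD, tubeRadiusVox = tubeRadiusVox,
      imageShape = as.integer(imageShape), voxelSizeMM = voxelSizeMM,
      s0 = s0)
}

#' Construct a scanner profile
#'
#' @param scannerId scanner label.
#' @param fieldStrength 1.5 or 3 (tesla).
#' @param metricOffsets named numeric vector of per-metric additive fixed
#'   effects (metric units).
#' @param noiseSigma Rician noise scale used by the image-level simulator.
#' @return A [ScannerProfile-class] object.
#' @export
scannerProfile <- function(scannerId, fieldStrength = 1.5,
                           metricOffsets = numeric(0), noiseSigma = 0) {
  new("ScannerProfile", scannerId = as.character(scannerId),
      fieldStrength = fieldStrength, metricOffsets = metricOffsets,
      noiseSigma = noiseSigma)
}

#' Construct a study design
#'
#' @param scanners list of [ScannerProfile-class] objects.
#' @param volunteers named list mapping scanner id to the volunteer ids
#'   scanned there.
#' @param repeats data.frame with columns `scanner`, `volunteer`,
#'   `sessions`; pairs not listed contribute one session.
#' @param truth data.frame with columns `metric`, `region`, `grandMean`,
#'   `volunteerSD`, `residualSD`.
#' @return A [StudyDesign-class] object.
#' @seealso [replicaStudyDesign()] for the eight-scanner default layout.
#' @export
studyDesign <- function(scanners, volunteers, repeats = NULL, truth) {
  if (is.null(repeats)) {
    repeats <- data.frame(scanner = character(0), volunteer = character(0),
                          sessions = integer(0))
  }
  new("StudyDesign", scanners = scanners, volunteers = volunteers,
      repeats = repeats, truth = truth)
}

#' @rdname fitVarianceComponents
#' @param mu,sigmaInter,sigmaVolunteer,sigmaIntra component estimates.
#' @param volunteerEstimable,converged status flags.
#' @param metric,region,subgroup labels.
#' @param nObs,nScanners,nVolunteers data dimensions.
#' @export
varianceComponents <- function(mu, sigmaInter, sigmaVolunteer, sigmaIntra,
                               volunteerEstimable = TRUE, converged = TRUE,
                               metric = "", region = "", subgroup = "",
                               nObs = 0L, nScanners = 0L, nVolunteers = 0L) {
  new("VarianceComponents", mu = mu, sigmaInter = sigmaInter,
      sigmaVolunteer = sigmaVolunteer, sigmaIntra = sigmaIntra,
      volunteerEstimable = volunteerEstimable, converged = converged,
      metric = metric, region = region, subgroup = subgroup,
      nObs = as.integer(nObs), nScanners = as.integer(nScanners),
      nVolunteers = as.integer(nVolunteers))
}
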