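## Tube centres arranged on a ring in the axial plane, replicated across
## slices.  Returns a (nTubes x 2) matrix of centre coordinates (voxels).
tubeCentres <- function(spec) {
  nTubes <- spec@nWaterTubes + 1L
  cx <- (spec@imageShape[1] + 1) / 2
  cy <- (spec@imageShape[2] + 1) / 2
  ringR <- min(cx, cy) - spec@tubeRadiusVox - 2
  ang <- 2 * pi * (seq_len(nTubes) - 1) / nTubes
  centres <- cbind(cx + ringR * cos(ang), cy + ringR * sin(ang))
  ## tubes must be disjoint and inside the image
  minSep <- if (nTubes > 1) 2 * ringR * sin(pi / nTubes) else Inf
  if (ringR < spec@tubeRadiusVox + 1 || minSep <= 2 * spec@tubeRadiusVox) {
    stopValidation(paste0(
      "phantom geometry cannot fit %d non-overlapping tubes of radius %g ",
      "in a %d x %d image"), nTubes, spec@tubeRadiusVox,
      spec@imageShape[1], spec@imageShape[2])
  }
  centres
}

#' Simulate an ice-water phantom acquisition
#'
#' Builds a 4-D diffusion-weighted volume (x, y, z, measurement) of a
#' tube phantom: `nWaterTubes` tubes of distilled water at the ice-water
#' diffusivity, one sucrose tube, and signal-free background.  In-tube
#' signals follow the mono-exponential decay (the IVIM model with f = 0);
#' optional Rician noise is added over the whole volume, so the background
#' acquires the Rayleigh noise floor of real magnitude images.
#'
#' @param spec a [PhantomSpec-class] object.
#' @param scheme an [AcquisitionScheme-class] object.
#' @param sigma Rician noise scale (0 for a noiseless phantom).
#' @param seed integer seed, required when `sigma > 0`.
#' @return A list with elements `image` (4-D array), `labels` (3-D integer
#'   array: 0 background, 1..nWaterTubes water tubes, nWaterTubes + 1
#'   sucrose), `waterLabels`, `sucroseLabel` and `spec`.
#' @examples
#' ph <- simulatePhantom(phantomSpec(), dwiScheme())
#' table(ph$labels)
#' @export
simulatePhantom <- function(spec, scheme, sigma = 0, seed = NULL) {
  validObject(spec)
  validObject(scheme)
  centres <- tubeCentres(spec)
  shape <- spec@imageShape
  labels <- array(0L, dim = shape)
  xy <- cbind(rep(seq_len(shape[1]), shape[2]),
              rep(seq_len(shape[2]), each = shape[1]))
  plane <- integer(shape[1] * shape[2])
  for (k in seq_len(nrow(centres))) {
    inTube <- (xy[, 1] - centres[k, 1])^2 + (xy[, 2] - centres[k, 2])^2 <=
      spec@tubeRadiusVox^2
    plane[inTube] <- k
  }
  for (z in seq_len(shape[3])) labels[, , z] <- plane

  sucroseLabel <- spec@nWaterTubes + 1L
  waterSig <- ivimSignal(ivimParams(s0 = spec@s0, d = spec@waterD,
                                    dStar = spec@waterD, f = 0), scheme)
  sucroseSig <- ivimSignal(ivimParams(s0 = spec@s0, d = spec@sucroseD,
                                      dStar = max(spec@sucroseD, 1e-12),
                                      f = 0), scheme)
  nMeas <- nMeasurements(scheme)
  image <- array(0, dim = c(shape, nMeas))
  water <- labels >= 1L & labels < sucroseLabel
  sucrose <- labels == sucroseLabel
  for (m in seq_len(nMeas)) {
    vol <- array(0, dim = shape)
    vol[water] <- waterSig[m]
    vol[sucrose] <- sucroseSig[m]
    image[, , , m] <- vol
  }
  if (sigma > 0) {
    image <- addRicianNoise(image, sigma, seed = seed)
  }
  list(image = image, labels = labels,
       waterLabels = seq_len(spec@nWaterTubes),
       sucroseLabel = sucroseLabel, spec = spec)
}

#' Binary mask of the water tubes of a simulated phantom
#'
#' @param phantom result of [simulatePhantom()].
#' @param erode number of one-voxel erosion passes applied to the tube mask
#'   (avoids boundary partial-volume voxels, mirroring manual ROI placement
#'   away from tube edges).
#' @return Logical 3-D array.
#' @export
waterMask <- function(phantom, erode = 0L) {
  mask <- phantom$labels %in% phantom$waterLabels
  dim(mask) <- dim(phantom$labels)
  if (erode > 0L) mask <- erodeMask(mask, iterations = erode)
  mask
}
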