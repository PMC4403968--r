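#' Voxelwise model fitting over a 4-D volume
#'
#' Applies [fitADC()], [fitIVIM()] or [fitTensor()] to every voxel inside
#' the mask of a 4-D (x, y, z, measurement) volume.  Voxels outside the
#' mask, and voxels whose fit is flagged invalid, are set to the sentinel
#' `NA` in every output map.  A fit log with voxel counts accompanies the
#' maps so silent failures cannot hide.
#'
#' @param volume 4-D numeric array; the 4th axis must match the scheme.
#' @param scheme an [AcquisitionScheme-class] object.
#' @param model one of `"adc"`, `"ivim"`, `"dti"`.
#' @param mask optional logical 3-D array selecting voxels to fit; `NULL`
#'   fits everything.
#' @param ... passed to the voxel-level fitter (e.g. `bThreshold`,
#'   `bSubset`).
#' @return A list with `maps` (named list of 3-D arrays: `adc` for ADC;
#'   `d`, `f`, `dStar` for IVIM; `md`, `fa` for DTI), `log` (counts:
#'   `nFitted`, `nInvalid`, `nNonConverged`, `nMasked`) and `model`.
#' @examples
#' ph <- simulatePhantom(phantomSpec(imageShape = c(16, 16, 1),
#'                                   tubeRadiusVox = 2), dwiScheme())
#' fit <- fitVolume(ph$image, dwiScheme(), "adc", waterMask(ph))
#' fit$log
#' @export
fitVolume <- function(volume, scheme, model = c("adc", "ivim", "dti"),
                      mask = NULL, ...) {
  model <- match.arg(model)
  dims <- dim(volume)
  if (length(dims) != 4L) stopValidation("'volume' must be 4-D")
  if (dims[4] != nMeasurements(scheme)) {
    stopValidation("volume has %d measurements but the scheme has %d",
                   dims[4], nMeasurements(scheme))
  }
  spatial <- dims[1:3]
  if (is.null(mask)) {
    mask <- array(TRUE, dim = spatial)
  } else if (!identical(as.integer(dim(mask)), as.integer(spatial))) {
    stopValidation("mask shape (%s) does not match the volume (%s)",
                   paste(dim(mask), collapse = "x"),
                   paste(spatial, collapse = "x"))
  }
  mapNames <- switch(model, adc = "adc", ivim = c("d", "f", "dStar"),
                     dti = c("md", "fa"))
  maps <- lapply(mapNames, function(nm) array(mapSentinel(), dim = spatial))
  names(maps) <- mapNames

  flat <- matrix(volume, nrow = prod(spatial), ncol = dims[4])
  idx <- which(as.vector(mask))
  nInvalid <- 0L
  nNonConverged <- 0L
  for (v in idx) {
    sig <- flat[v, ]
    res <- switch(model,
      adc = {
        fit <- fitADC(sig, scheme, ...)
        if (!fit@valid) NULL else c(adc = fit@adc)
      },
      ivim = {
        fit <- fitIVIM(sig, scheme, ...)
        if (!fit@valid) NULL else {
          if (!fit@converged) nNonConverged <- nNonConverged + 1L
          c(d = fit@d, f = fit@f, dStar = fit@dStar)
        }
      },
      dti = {
        fit <- fitTensor(sig, scheme)
        if (!fit@valid) NULL else c(md = fit@md, fa = fit@fa)
      })
    if (is.null(res)) {
      nInvalid <- nInvalid + 1L
    } else {
      for (nm in mapNames) maps[[nm]][v] <- res[[nm]]
    }
  }
  list(maps = maps,
       log = list(nFitted = length(idx) - nInvalid, nInvalid = nInvalid,
                  nNonConverged = nNonConverged,
                  nMasked = as.integer(prod(spatial) - length(idx))),
       model = model)
}
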