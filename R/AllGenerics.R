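#' @rdname AcquisitionScheme-class
#' @param object an object.
#' @export
setGeneric("bValues", function(object) standardGeneric("bValues"))

#' @rdname AcquisitionScheme-class
#' @export
setGeneric("gradientDirections",
           function(object) standardGeneric("gradientDirections"))

#' @rdname AcquisitionScheme-class
#' @export
setGeneric("nB0", function(object) standardGeneric("nB0"))

#' @rdname AcquisitionScheme-class
#' @export
setGeneric("nMeasurements",
           function(object) standardGeneric("nMeasurements"))

#' @rdname StudyDesign-class
#' @export
setGeneric("sessionCount", function(object) standardGeneric("sessionCount"))

#' @export
setMethod("bValues", "AcquisitionScheme", function(object) object@bValues)

#' @export
setMethod("gradientDirections", "AcquisitionScheme",
          function(object) object@directions)

#' @export
setMethod("nB0", "AcquisitionScheme",
          function(object) sum(object@bValues == 0))

#' @export
setMethod("nMeasurements", "AcquisitionScheme",
          function(object) length(object@bValues))

#' @export
setMethod("sessionCount", "StudyDesign", function(object) {
  base <- sum(lengths(object@volunteers))
  extra <- if (nrow(object@repeats)) sum(object@repeats$sessions - 1L) else 0L
  as.integer(base + extra)
})

#' @export
setMethod("show", "AcquisitionScheme", function(object) {
  b <- object@bValues
  cat("AcquisitionScheme with", length(b), "measurements\n")
  cat("  b-values (s/mm^2):", paste(sort(unique(b)), collapse = ", "), "\n")
  nd <- sum(rowSums(is.na(object@directions)) == 0L)
  cat("  ", nd, " direction-encoded, ", nB0(object), " b=0\n", sep = "")
})

#' @export
setMethod("show", "IVIMParams", function(object) {
  cat(sprintf(
    "IVIMParams: s0 = %g, D = %g, D* = %g mm^2/s, f = %g\n",
    object@s0, object@d, object@dStar, object@f))
})

#' @export
setMethod("show", "TensorParams", function(object) {
  ev <- sort(eigen(object@tensor, symmetric = TRUE,
                   only.values = TRUE)$values, decreasing = TRUE)
  cat(sprintf("TensorParams: s0 = %g, eigenvalues = (%g, %g, %g) mm^2/s\n",
              object@s0, ev[1], ev[2], ev[3]))
})

#' @export
setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %d water tubes (D = %g) + 1 sucrose tube (D = %g)\n",
    object@nWaterTubes, object@waterD, object@sucroseD))
  cat("  image", paste(object@imageShape, collapse = " x "),
      "voxels of", paste(object@voxelSizeMM, collapse = " x "), "mm\n")
})

#' @export
setMethod("show", "ScannerProfile", function(object) {
  cat(sprintf("ScannerProfile %s (%.1fT), noise sigma = %g\n",
              object@scannerId, object@fieldStrength, object@noiseSigma))
})

#' @export
setMethod("show", "StudyDesign", function(object) {
  ids <- vapply(object@scanners, function(s) s@scannerId, character(1))
  cat("StudyDesign:", length(ids), "scanners,",
      length(unique(unlist(object@volunteers))), "volunteers,",
      sessionCount(object), "sessions\n")
  cat("  metrics:", paste(unique(object@truth$metric), collapse = ", "), "\n")
  cat("  regions:", paste(unique(object@truth$region), collapse = ", "), "\n")
})

#' @export
setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf("VarianceComponents [%s / %s%s]\n", object@metric,
              object@region,
              if (nzchar(object@subgroup)) paste0(" / ", object@subgroup)
              else ""))
  cat(sprintf("  mu = %.4g; sigma inter = %.4g, volunteer = %s, intra = %.4g\n",
              object@mu, object@sigmaInter,
              if (object@volunteerEstimable)
                sprintf("%.4g", object@sigmaVolunteer) else "NE",
              object@sigmaIntra))
  cat(sprintf("  n = %d obs / %d scanners / %d volunteers%s\n", object@nObs,
              object@nScanners, object@nVolunteers,
              if (object@converged) "" else " (fit did not converge)"))
})

#' @export
setMethod("show", "ReproResult", function(object) {
  cat(sprintf("ReproResult [%s / %s%s]\n", object@metric, object@region,
              if (nzchar(object@subgroup)) paste0(" / ", object@subgroup)
              else ""))
  cat(sprintf("  mean %.4g; CV inter %.1f%%, volunteer %s, intra %.1f%%\n",
              object@mu, object@cvInter,
              if (object@volunteerEstimable)
                sprintf("%.1f%%", object@cvVolunteer) else "NE",
              object@cvIntra))
  cat(sprintf("  ICC inter/intra = %.2f / %.2f\n",
              object@iccInter, object@iccIntra))
})
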