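#' Read and write FSL-dialect acquisition tables
#'
#' `.bval` files hold one space-separated row of b-values; `.bvec` files
#' hold three rows (x, y, z) with one column per measurement.  Zero columns
#' in the `.bvec` (the FSL convention for b = 0 measurements) become `NA`
#' direction rows in the scheme.
#'
#' @param bvalPath,bvecPath file paths; `bvecPath = NULL` reads a
#'   trace-weighted scheme with no directions.
#' @return [readScheme()] returns an [AcquisitionScheme-class];
#'   [writeScheme()] invisibly returns the paths written.
#' @export
readScheme <- function(bvalPath, bvecPath = NULL) {
  b <- scan(bvalPath, what = numeric(), quiet = TRUE)
  if (is.null(bvecPath)) {
    return(acquisitionScheme(b))
  }
  v <- as.matrix(read.table(bvecPath))
  if (nrow(v) != 3L || ncol(v) != length(b)) {
    stopValidation("bvec must be 3 rows x %d columns, got %d x %d",
                   length(b), nrow(v), ncol(v))
  }
  g <- t(v)
  zero <- rowSums(g^2) == 0
  g[zero, ] <- NA_real_
  nz <- !zero
  g[nz, ] <- g[nz, , drop = FALSE] / sqrt(rowSums(g[nz, , drop = FALSE]^2))
  acquisitionScheme(b, g)
}

#' @rdname readScheme
#' @param scheme an [AcquisitionScheme-class] object.
#' @param prefix output path prefix; writes `<prefix>.bval` and, when the
#'   scheme has directions, `<prefix>.bvec`.
#' @export
writeScheme <- function(scheme, prefix) {
  validObject(scheme)
  bvalPath <- paste0(prefix, ".bval")
  writeLines(paste(sprintf("%.10g", bValues(scheme)), collapse = " "),
             bvalPath)
  paths <- bvalPath
  g <- gradientDirections(scheme)
  if (any(rowSums(is.na(g)) == 0L)) {
    g[is.na(g)] <- 0
    bvecPath <- paste0(prefix, ".bvec")
    writeLines(apply(t(g), 1, function(row) {
      paste(sprintf("%.15g", row), collapse = " ")
    }), bvecPath)
    paths <- c(paths, bvecPath)
  }
  invisible(paths)
}

#' NIfTI-1 volume input/output
#'
#' Thin wrappers over \pkg{RNifti} that record the voxel size and a units
#' note in the header.
#'
#' @param image 3-D or 4-D numeric array.
#' @param path output `.nii` / `.nii.gz` path.
#' @param voxelSizeMM voxel dimensions in mm.
#' @param description free-text header description (e.g. the map units).
#' @return [writeVolume()] invisibly returns `path`; [readVolume()]
#'   returns a plain numeric array with attribute `"pixdim"`.
#' @export
writeVolume <- function(image, path, voxelSizeMM = c(1, 1, 1),
                        description = "") {
  img <- RNifti::asNifti(image)
  img <- RNifti::`pixdim<-`(img, voxelSizeMM)
  hdr <- RNifti::niftiHeader(img)
  hdr$descrip <- substr(description, 1, 79)
  img <- RNifti::asNifti(image, reference = hdr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "pixdim") <- RNifti::pixdim(img)
  out
}

measurementTableColumns <- function() {
  c("scanner", "volunteer", "session", "region", "metric", "value")
}

#' Read and write the canonical measurement table
#'
#' The interchange CSV between the imaging and statistics stages, with
#' header `scanner,volunteer,session,region,metric,value`.
#'
#' @param path CSV file path.
#' @return [readMeasurementTable()] returns the validated data.frame.
#' @export
readMeasurementTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- measurementTableColumns()
  if (!identical(names(df)[seq_along(need)], need)) {
    stopValidation("measurement table must have header %s",
                   paste(need, collapse = ","))
  }
  if (anyDuplicated(df[, c("scanner", "volunteer", "session", "region",
                           "metric")])) {
    stopValidation("duplicate (scanner, volunteer, session, region, metric) keys")
  }
  if (any(!is.finite(df$value))) {
    stopValidation("measurement values must be finite")
  }
  df
}

#' @rdname readMeasurementTable
#' @param table measurement data.frame.
#' @export
writeMeasurementTable <- function(table, path) {
  need <- measurementTableColumns()
  if (!all(need %in% names(table))) {
    stopValidation("table must have columns %s", paste(need, collapse = ","))
  }
  write.csv(table[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundled reference summary tables
#'
#' `volunteerSummary()` returns the per-region grey/white-matter and
#' sub-region summary (model mean, the three component SDs, CVs and ICC
#' pair, per metric) published by the eight-scanner multi-centre volunteer
#' study whose design this package replicates; `phantomScannerMeans()`
#' returns that study's per-scanner ice-water phantom means and SDs.  Both
#' are printed summary values, used as worked-example inputs for the
#' reproducibility arithmetic — the underlying scans are not public.
#'
#' @return data.frame.
#' @export
volunteerSummary <- function() {
  read.csv(system.file("extdata", "volunteer_summary.csv",
                       package = "dwirepro"), stringsAsFactors = FALSE)
}

#' @rdname volunteerSummary
#' @export
phantomScannerMeans <- function() {
  read.csv(system.file("extdata", "phantom_scanner_means.csv",
                       package = "dwirepro"), stringsAsFactors = FALSE)
}
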