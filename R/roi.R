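#' Threshold a tissue-probability map
#'
#' A voxel enters the mask iff its probability is strictly greater than the
#' threshold (strict `>`: a uniform map exactly at the threshold yields an
#' empty mask).
#'
#' @param map 3-D numeric array with values in `[0, 1]`.
#' @param threshold probability threshold in `(0, 1]`; default 0.95.
#' @return Logical array of the same shape.
#' @export
thresholdProbabilityMap <- function(map, threshold = 0.95) {
  if (any(map < 0 | map > 1, na.rm = TRUE)) {
    stopValidation("probability map values must lie in [0, 1]")
  }
  assertScalarNumber(threshold, "threshold")
  if (threshold <= 0 || threshold > 1) {
    stopValidation("'threshold' must lie in (0, 1]")
  }
  out <- map > threshold
  out[is.na(out)] <- FALSE
  out
}

## Logical shift of a 3-D array along one axis, padding with FALSE.
shiftMask <- function(mask, axis, by) {
  out <- array(FALSE, dim = dim(mask))
  n <- dim(mask)[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- if (by > 0) (1 + by):n else 1:(n + by)
  ix <- list(seq_len(dim(mask)[1]), seq_len(dim(mask)[2]),
             seq_len(dim(mask)[3]))
  src.ix <- ix; src.ix[[axis]] <- src
  dst.ix <- ix; dst.ix[[axis]] <- dst
  out[dst.ix[[1]], dst.ix[[2]], dst.ix[[3]]] <-
    mask[src.ix[[1]], src.ix[[2]], src.ix[[3]]]
  out
}

#' Morphological erosion of a binary 3-D mask
#'
#' One-voxel erosion with a face-adjacent (6-connected) structuring element
#' by default: a voxel survives iff itself and all its face neighbours are
#' in the mask.  Voxels beyond the array border count as background, so the
#' outermost layer always erodes.  `connectivity = 26` uses the full
#' 3 x 3 x 3 neighbourhood instead.  Erosion is anti-extensive (the result
#' is a subset of the input).
#'
#' @param mask logical 3-D array.
#' @param iterations number of erosion passes.
#' @param connectivity 6 (faces) or 26 (faces, edges and corners).
#' @return Logical array of the same shape.
#' @examples
#' cube <- array(TRUE, dim = c(3, 3, 3))
#' which(erodeMask(cube))   # only the centre voxel survives
#' @export
erodeMask <- function(mask, iterations = 1L, connectivity = c(6, 26)) {
  connectivity <- match.arg(as.character(connectivity[1]), c("6", "26"))
  if (length(dim(mask)) != 3L) stopValidation("'mask' must be 3-D")
  mask <- array(as.logical(mask), dim = dim(mask))
  offsets <- if (connectivity == "6") {
    list(c(1, 1), c(1, -1), c(2, 1), c(2, -1), c(3, 1), c(3, -1))
  } else {
    grid <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    grid <- grid[rowSums(grid != 0) > 0, ]
    split(as.matrix(grid), seq_len(nrow(grid)))
  }
  for (it in seq_len(iterations)) {
    out <- mask
    if (connectivity == "6") {
      for (off in offsets) {
        out <- out & shiftMask(mask, off[1], off[2])
      }
    } else {
      for (off in offsets) {
        shifted <- mask
        for (ax in 1:3) {
          if (off[ax] != 0) shifted <- shiftMask(shifted, ax, off[ax])
        }
        out <- out & shifted
      }
    }
    mask <- out
  }
  mask
}

#' Mean parameter value over a region of interest
#'
#' Arithmetic mean over in-mask voxels, skipping sentinel (`NA`) voxels
#' left by invalid fits.  An empty or all-sentinel region returns a
#' missing-value result with a zero count rather than an error, mirroring
#' how failed segmentations are dropped from study tables.
#'
#' @param map 3-D numeric parameter map.
#' @param mask logical array of the same shape.
#' @return List with `mean` and `n` (voxels contributing).
#' @export
roiMean <- function(map, mask) {
  if (!identical(dim(map), dim(mask))) {
    stopValidation("map and mask shapes differ")
  }
  vals <- map[mask & !is.na(map)]
  if (length(vals) == 0L) return(list(mean = NA_real_, n = 0L))
  list(mean = mean(vals), n = length(vals))
}

#' Assemble the long-format ROI measurement table
#'
#' Produces one row per (session, region, metric) by averaging each
#' session's parameter maps over each region mask.  Regions whose mask is
#' empty (or covered only by invalid voxels) in a session yield no row; the
#' omissions are reported in the attached log and as a warning.
#'
#' @param maps named list (by session id) of named lists (by metric) of
#'   3-D parameter maps.
#' @param masks named list (by session id) of named lists (by region) of
#'   logical masks.
#' @param metadata data.frame with columns `id`, `scanner`, `volunteer`,
#'   `session`, one row per session id appearing in `maps`.
#' @return data.frame with columns `scanner`, `volunteer`, `session`,
#'   `region`, `metric`, `value` and attribute `"log"` listing skipped
#'   region/session pairs.
#' @export
buildMeasurementTable <- function(maps, masks, metadata) {
  need <- c("id", "scanner", "volunteer", "session")
  if (!all(need %in% names(metadata))) {
    stopValidation("'metadata' needs columns id, scanner, volunteer, session")
  }
  if (anyDuplicated(metadata[, c("scanner", "volunteer", "session")])) {
    stopValidation("duplicate (scanner, volunteer, session) keys in metadata")
  }
  if (!all(names(maps) %in% metadata$id)) {
    stopValidation("every session in 'maps' needs a metadata row")
  }
  rows <- list()
  skipped <- character(0)
  for (id in names(maps)) {
    meta <- metadata[metadata$id == id, ]
    sessionMasks <- masks[[id]]
    for (region in names(sessionMasks)) {
      for (metric in names(maps[[id]])) {
        rm <- roiMean(maps[[id]][[metric]], sessionMasks[[region]])
        if (rm$n == 0L) {
          skipped <- c(skipped, paste(id, region, metric, sep = "/"))
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          scanner = meta$scanner, volunteer = meta$volunteer,
          session = meta$session, region = region, metric = metric,
          value = rm$mean, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(scanner = character(0), volunteer = character(0),
               session = character(0), region = character(0),
               metric = character(0), value = numeric(0))
  }
  rownames(out) <- NULL
  if (length(skipped)) {
    warning(sprintf("%d empty region/metric cells skipped: %s",
                    length(skipped), paste(skipped, collapse = ", ")),
            call. = FALSE)
  }
  attr(out, "log") <- list(skipped = skipped, nRows = nrow(out))
  out
}
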