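## Default effect sizes for the replica design, in reporting units
## (diffusivities in 1e-3 mm^2/s; f and FA dimensionless).  Grand means and
## the volunteer/residual SDs are the grey- and white-matter values of the
## eight-scanner multi-centre volunteer study this package models; the
## scanner fixed-effect SD per metric is the GM/WM average of that study's
## inter-scanner SDs.
replicaTruth <- function() {
  data.frame(
    metric = rep(c("ADC", "D", "f", "MD", "FA"), each = 2),
    region = rep(c("GM", "WM"), times = 5),
    grandMean   = c(0.8327, 0.7010, 0.7495, 0.6506, 0.1005, 0.0799,
                    0.8490, 0.6971, 0.1726, 0.4187),
    volunteerSD = c(0.0246, 0.0156, 0.0186, 0.0115, 0.0026, 0.0020,
                    0.0080, 0.0180, 0.0097, 0.0157),
    residualSD  = c(0.0242, 0.0072, 0.0159, 0.0108, 0.0111, 0.0047,
                    0.0202, 0.0094, 0.0128, 0.0088),
    stringsAsFactors = FALSE
  )
}

replicaOffsetSD <- function() {
  c(ADC = 0.02065, D = 0.0228, f = 0.0219, MD = 0.01615, FA = 0.0065)
}

#' Eight-scanner replica study design
#'
#' Builds the default multi-centre layout: eight scanners (A, B, D, G at
#' 1.5 T; C, E, F, H at 3 T) sharing nine volunteers, with 4-8 volunteers
#' per scanner and repeat sessions (two volunteers rescanned on A, B, F, G
#' and H; one on C, D and E) for a total of 65 imaging sessions.  Per-metric
#' scanner fixed effects are drawn once from centred normals whose SDs match
#' the study-scale inter-scanner SDs; volunteer and residual SDs come from
#' [replicaTruth()].  Scanner G receives a larger image-noise sigma,
#' emulating the low-SNR high-resolution acquisition that inflated its
#' perfusion-fraction estimates.
#'
#' @param seed integer seed used (only) to draw the scanner fixed effects.
#' @param truth optional replacement for the default effect-size table.
#' @param offsetSD optional named per-metric SD for the scanner fixed
#'   effects.
#' @return A [StudyDesign-class] object with 65 sessions.
#' @examples
#' d <- replicaStudyDesign(seed = 1)
#' sessionCount(d)
#' @export
replicaStudyDesign <- function(seed = 1, truth = replicaTruth(),
                               offsetSD = replicaOffsetSD()) {
  ids <- LETTERS[1:8]
  fields <- c(A = 1.5, B = 1.5, C = 3, D = 1.5, E = 3, F = 3, G = 1.5,
              H = 3)
  counts <- c(A = 8L, B = 7L, C = 6L, D = 6L, E = 6L, F = 7L, G = 6L,
              H = 6L)
  nRepeats <- c(A = 2L, B = 2L, C = 1L, D = 1L, E = 1L, F = 2L, G = 2L,
                H = 2L)
  volunteerPool <- paste0("V", 1:9)
  metrics <- unique(truth$metric)

  offsets <- withSeed(deriveSeed(seed, "scanner-offsets"), {
    vapply(ids, function(id) {
      rnorm(length(metrics), 0, offsetSD[metrics])
    }, numeric(length(metrics)))
  })
  rownames(offsets) <- metrics

  scanners <- lapply(ids, function(id) {
    scannerProfile(id, fieldStrength = fields[[id]],
                   metricOffsets = offsets[, id],
                   noiseSigma = if (id == "G") 40 else 20)
  })

  volunteers <- lapply(seq_along(ids), function(i) {
    idx <- ((i - 1 + seq_len(counts[i]) - 1) %% length(volunteerPool)) + 1
    volunteerPool[sort(idx)]
  })
  names(volunteers) <- ids

  repeats <- do.call(rbind, lapply(ids, function(id) {
    data.frame(scanner = id,
               volunteer = volunteers[[id]][seq_len(nRepeats[[id]])],
               sessions = 2L, stringsAsFactors = FALSE)
  }))

  studyDesign(scanners, volunteers, repeats, truth)
}

## One row per imaging session of the design.
enumerateSessions <- function(design) {
  rep <- design@repeats
  out <- do.call(rbind, lapply(design@scanners, function(sc) {
    id <- sc@scannerId
    do.call(rbind, lapply(design@volunteers[[id]], function(v) {
      hit <- rep$scanner == id & rep$volunteer == v
      n <- if (any(hit)) rep$sessions[hit][1] else 1L
      data.frame(scanner = id, volunteer = v,
                 session = paste0("S", seq_len(n)),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a multi-centre ROI measurement table
#'
#' For every metric/region of the design, each session value is drawn as
#' `value = grandMean + scannerOffset + volunteerEffect + residual`, with
#' volunteer effects `~ N(0, volunteerSD^2)` shared across that volunteer's
#' sessions and residuals `~ N(0, residualSD^2)` independent per session.
#' Scanner offsets are the fixed effects stored in the design's scanner
#' profiles (0 for metrics without an entry).
#'
#' @param design a [StudyDesign-class] object.
#' @param seed integer seed; all draws derive deterministically from it.
#' @return A list with `table` (long-format data.frame with columns
#'   `scanner`, `volunteer`, `session`, `region`, `metric`, `value`) and
#'   `truth` (the generating components: per-metric scanner offsets,
#'   per-metric/region volunteer effects and the design effect sizes).
#' @examples
#' sim <- simulateStudy(replicaStudyDesign(1), seed = 42)
#' nrow(sim$table)
#' @export
simulateStudy <- function(design, seed) {
  validObject(design)
  if (missing(seed)) stopValidation("'seed' is required")
  sessions <- enumerateSessions(design)
  volunteerIds <- sort(unique(unlist(design@volunteers)))
  scannerIds <- vapply(design@scanners, function(s) s@scannerId,
                       character(1))
  offsets <- vapply(design@scanners, function(s) s@metricOffsets[
    match(unique(design@truth$metric), names(s@metricOffsets))],
    numeric(length(unique(design@truth$metric))))
  if (is.null(dim(offsets))) offsets <- matrix(offsets, nrow = 1)
  rownames(offsets) <- unique(design@truth$metric)
  colnames(offsets) <- scannerIds
  offsets[is.na(offsets)] <- 0

  volunteerEffects <- list()
  rows <- vector("list", nrow(design@truth))
  for (i in seq_len(nrow(design@truth))) {
    tr <- design@truth[i, ]
    vEff <- withSeed(deriveSeed(seed, "volunteer", tr$metric, tr$region), {
      setNames(rnorm(length(volunteerIds), 0, tr$volunteerSD), volunteerIds)
    })
    eps <- withSeed(deriveSeed(seed, "residual", tr$metric, tr$region), {
      rnorm(nrow(sessions), 0, tr$residualSD)
    })
    volunteerEffects[[paste(tr$metric, tr$region, sep = ".")]] <- vEff
    rows[[i]] <- data.frame(
      scanner = sessions$scanner, volunteer = sessions$volunteer,
      session = sessions$session, region = tr$region, metric = tr$metric,
      value = tr$grandMean + offsets[tr$metric, sessions$scanner] +
        vEff[sessions$volunteer] + eps,
      stringsAsFactors = FALSE)
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(table = table,
       truth = list(effects = design@truth, offsets = offsets,
                    volunteerEffects = volunteerEffects, seed = seed))
}
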