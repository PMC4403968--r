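#' RunConfig: one end-to-end pipeline run
#'
#' @slot mode `"phantom"`, `"volunteer-study"` or `"table-only"`.
#' @slot params mode-specific options (generator specs, input paths, model
#'   list); see [runPipeline()].
#' @slot seed master seed; mandatory for the generator modes.
#' @slot outDir output directory (`NA` to skip writing files).
#' @seealso [runConfig()], [runPipeline()]
#' @export
setClass("RunConfig",
  representation(mode = "character", params = "list", seed = "integer",
                 outDir = "character"),
  validity = function(object) {
    if (!object@mode %in% c("phantom", "volunteer-study", "table-only")) {
      return("mode must be phantom, volunteer-study or table-only")
    }
    if (object@mode != "table-only" && is.na(object@seed)) {
      return("generator modes require a seed")
    }
    TRUE
  }
)

#' @rdname RunConfig-class
#' @param mode,params,seed,outDir see the class slots.
#' @export
runConfig <- function(mode, params = list(), seed = NA_integer_,
                      outDir = NA_character_) {
  new("RunConfig", mode = mode, params = params,
      seed = as.integer(seed), outDir = outDir)
}

#' Read a run configuration from YAML or JSON
#'
#' The file mirrors the [RunConfig-class] fields: `mode`, `seed`, `outDir`
#' and a `params` block.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A [RunConfig-class] object.
#' @export
readRunConfig <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  runConfig(mode = cfg$mode,
            params = if (is.null(cfg$params)) list() else cfg$params,
            seed = if (is.null(cfg$seed)) NA_integer_ else cfg$seed,
            outDir = if (is.null(cfg$outDir)) NA_character_ else cfg$outDir)
}

writeManifest <- function(manifest, outDir, name = "manifest.json") {
  if (is.na(outDir)) return(invisible(NULL))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  path <- file.path(outDir, name)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

## Reporting units: diffusivities are reported in 1e-3 mm^2/s, matching the
## units of the scanner metric offsets; f and FA are dimensionless.
reportScale <- function(metric) {
  if (metric %in% c("ADC", "D", "MD")) 1e3 else 1
}

#' Phantom reproducibility pipeline
#'
#' Runs the ice-water phantom workflow end to end: simulate one phantom
#' acquisition per scanner (each scanner's ADC fixed effect shifts the
#' ground-truth water diffusivity and its `noiseSigma` sets the Rician
#' noise), fit the requested models voxelwise, average each metric over the
#' eroded water-tube mask, and summarise the per-scanner means with the
#' group CV plus leave-one-scanner-out recomputations.  In table mode a
#' ready-made per-scanner means table (columns `scanner`, `metric`,
#' `mean`) is summarised directly.
#'
#' `params` fields (simulate mode): `models` (subset of `"adc"`, `"ivim"`,
#' `"dti"`; default `c("adc", "ivim")`), `scanners` (list of
#' [ScannerProfile-class]; default the replica set), `phantom` (a
#' [PhantomSpec-class]), `bValues`, `noiseless` (logical), `erode`
#' (erosion passes on the water mask, default 1).  Table mode: `table` (a
#' data.frame or CSV path).
#'
#' @param config a [RunConfig-class] object.
#' @return List with `perScanner`, `overall` (mean/SD/CV per metric),
#'   `leaveOneOut` (CV per excluded scanner and metric) and `manifest`.
#'   Diffusivities are reported in 1e-3 mm^2/s.
#' @export
runPhantomPipeline <- function(config) {
  validObject(config)
  p <- config@params
  manifest <- list(package = "dwirepro",
                   version = as.character(packageVersion("dwirepro")),
                   mode = config@mode, seed = config@seed,
                   stages = list(), warnings = character(0))
  writeManifest(manifest, config@outDir)

  if (!is.null(p$table)) {
    perScanner <- if (is.character(p$table)) {
      read.csv(p$table, stringsAsFactors = FALSE)
    } else as.data.frame(p$table)
    if (!all(c("scanner", "metric", "mean") %in% names(perScanner))) {
      stopValidation("phantom table needs columns scanner, metric, mean")
    }
  } else {
    if (is.na(config@seed)) stopValidation("simulation requires a seed")
    models <- if (is.null(p$models)) c("adc", "ivim") else p$models
    scanners <- if (is.null(p$scanners)) {
      replicaStudyDesign(config@seed)@scanners
    } else p$scanners
    spec <- if (is.null(p$phantom)) phantomSpec() else p$phantom
    scheme <- if (is.null(p$bValues)) dwiScheme() else dwiScheme(p$bValues)
    dirScheme <- if ("dti" %in% models) {
      if (is.null(p$dtiDirections)) dtiScheme(32) else
        dtiScheme(p$dtiDirections)
    } else NULL
    erode <- if (is.null(p$erode)) 1L else p$erode
    noiseless <- isTRUE(p$noiseless)
    rows <- list()
    for (sc in scanners) {
      off <- sc@metricOffsets
      dTrue <- spec@waterD +
        (if ("ADC" %in% names(off)) off[["ADC"]] else 0) / reportScale("ADC")
      specI <- spec
      specI@waterD <- dTrue
      sigma <- if (noiseless) 0 else sc@noiseSigma
      seedI <- deriveSeed(config@seed, "phantom", sc@scannerId)
      ph <- simulatePhantom(specI, scheme, sigma = sigma, seed = seedI)
      mask <- waterMask(ph, erode = erode)
      for (model in models) {
        mScheme <- if (model == "dti") dirScheme else scheme
        img <- if (model == "dti") {
          simulatePhantom(specI, dirScheme, sigma = sigma,
                          seed = deriveSeed(seedI, "dti"))$image
        } else ph$image
        fit <- fitVolume(img, mScheme, model, mask)
        metricOf <- switch(model, adc = c(adc = "ADC"),
                           ivim = c(d = "D", f = "f"),
                           dti = c(md = "MD", fa = "FA"))
        for (mp in names(metricOf)) {
          metric <- metricOf[[mp]]
          rm <- roiMean(fit$maps[[mp]], mask)
          rows[[length(rows) + 1L]] <- data.frame(
            scanner = sc@scannerId, metric = metric,
            mean = rm$mean * reportScale(metric), n = rm$n,
            stringsAsFactors = FALSE)
        }
      }
    }
    perScanner <- do.call(rbind, rows)
    manifest$stages$simulate <- list(nScanners = length(scanners),
                                     models = models)
  }

  metrics <- unique(perScanner$metric)
  overall <- do.call(rbind, lapply(metrics, function(m) {
    g <- groupCV(perScanner$mean[perScanner$metric == m])
    data.frame(metric = m, mean = g$mean, sd = g$sd, cv = g$cv,
               stringsAsFactors = FALSE)
  }))
  leaveOneOut <- do.call(rbind, lapply(metrics, function(m) {
    sub <- perScanner[perScanner$metric == m, ]
    do.call(rbind, lapply(sub$scanner, function(ex) {
      g <- groupCV(sub$mean[sub$scanner != ex])
      data.frame(metric = m, excluded = ex, mean = g$mean, sd = g$sd,
                 cv = g$cv, stringsAsFactors = FALSE)
    }))
  }))
  manifest$stages$summarize <- list(nMetrics = length(metrics),
                                    nScanners = length(unique(perScanner$scanner)))
  if (!is.na(config@outDir)) {
    write.csv(perScanner, file.path(config@outDir, "phantom_per_scanner.csv"),
              row.names = FALSE)
    write.csv(overall, file.path(config@outDir, "phantom_overall.csv"),
              row.names = FALSE)
    write.csv(leaveOneOut, file.path(config@outDir, "phantom_loo.csv"),
              row.names = FALSE)
  }
  writeManifest(manifest, config@outDir)
  list(perScanner = perScanner, overall = overall,
       leaveOneOut = leaveOneOut, manifest = manifest)
}

#' Volunteer-study reproducibility pipeline
#'
#' Generates (or loads) the multi-centre ROI measurement table, fits the
#' scanner-fixed / volunteer-random mixed model per metric and region —
#' combined and separately per field strength — and tabulates CVs and
#' ICCs.  When simulating, a ground-truth recovery summary comparing the
#' estimated components with the generating ones is included.
#'
#' `params` fields: `design` (a [StudyDesign-class]; default
#' [replicaStudyDesign()]), or `table` (data.frame or CSV path) with
#' `fieldStrengths` (named scanner -> tesla map) for table mode;
#' `bySubgroup` (logical, default `TRUE`) to add per-field-strength rows.
#'
#' @param config a [RunConfig-class] object.
#' @return List with `table`, `report` (data.frame from
#'   [summarizeReport()]), `recovery` (or `NULL` in table mode) and
#'   `manifest`.
#' @export
runVolunteerPipeline <- function(config) {
  validObject(config)
  p <- config@params
  manifest <- list(package = "dwirepro",
                   version = as.character(packageVersion("dwirepro")),
                   mode = config@mode, seed = config@seed,
                   stages = list(), warnings = character(0))
  writeManifest(manifest, config@outDir)

  truthInfo <- NULL
  if (!is.null(p$table)) {
    table <- if (is.character(p$table)) readMeasurementTable(p$table)
             else as.data.frame(p$table)
    fields <- p$fieldStrengths
    design <- NULL
  } else {
    if (is.na(config@seed)) stopValidation("simulation requires a seed")
    design <- if (is.null(p$design)) replicaStudyDesign(config@seed)
              else p$design
    sim <- simulateStudy(design, seed = deriveSeed(config@seed, "study"))
    table <- sim$table
    truthInfo <- sim$truth
    fields <- design@scanners
    manifest$stages$simulate <- list(nSessions = sessionCount(design),
                                     nRows = nrow(table))
  }
  bySubgroup <- if (is.null(p$bySubgroup)) TRUE else isTRUE(p$bySubgroup)
  cells <- unique(table[, c("metric", "region")])
  results <- list()
  for (i in seq_len(nrow(cells))) {
    m <- cells$metric[i]
    r <- cells$region[i]
    if (bySubgroup && !is.null(fields)) {
      results <- c(results, unname(subgroupAnalysis(table, fields, m, r)))
    } else {
      results <- c(results,
                   list(reproResult(fitVarianceComponents(table, m, r,
                                                          subgroup = "all"))))
    }
  }
  report <- summarizeReport(results)
  manifest$stages$model <- list(nCells = nrow(cells),
                                nResults = nrow(report))

  recovery <- NULL
  if (!is.null(truthInfo)) {
    all <- report[report$subgroup == "all", ]
    tr <- truthInfo$effects
    key <- paste(all$metric, all$region)
    tkey <- paste(tr$metric, tr$region)
    offSD <- apply(truthInfo$offsets, 1, sd)
    recovery <- data.frame(
      metric = all$metric, region = all$region,
      trueMean = tr$grandMean[match(key, tkey)],
      estMean = all$mean,
      trueSigmaInter = offSD[all$metric],
      estSigmaInter = all$sd_inter,
      trueSigmaVolunteer = tr$volunteerSD[match(key, tkey)],
      estSigmaVolunteer = all$sd_volunteer,
      trueSigmaIntra = tr$residualSD[match(key, tkey)],
      estSigmaIntra = all$sd_intra,
      stringsAsFactors = FALSE)
    rownames(recovery) <- NULL
  }
  if (!is.na(config@outDir)) {
    writeMeasurementTable(table, file.path(config@outDir,
                                           "measurement_table.csv"))
    write.csv(report, file.path(config@outDir, "repro_report.csv"),
              row.names = FALSE)
    if (!is.null(recovery)) {
      write.csv(recovery, file.path(config@outDir, "recovery.csv"),
                row.names = FALSE)
    }
  }
  writeManifest(manifest, config@outDir)
  list(table = table, report = report, recovery = recovery,
       manifest = manifest)
}

#' Dispatch an end-to-end run
#'
#' `mode = "phantom"` runs [runPhantomPipeline()];
#' `mode = "volunteer-study"` runs [runVolunteerPipeline()];
#' `mode = "table-only"` routes the supplied table to the phantom pipeline
#' when `params$what == "phantom"` and to the volunteer pipeline otherwise.
#'
#' @param config a [RunConfig-class] object or a path to a YAML/JSON
#'   configuration file.
#' @return The corresponding pipeline result list.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  validObject(config)
  switch(config@mode,
    "phantom" = runPhantomPipeline(config),
    "volunteer-study" = runVolunteerPipeline(config),
    "table-only" = {
      if (identical(config@params$what, "phantom")) {
        runPhantomPipeline(config)
      } else {
        runVolunteerPipeline(config)
      }
    })
}
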