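#' Group coefficient of variation
#'
#' Mean, sample standard deviation (n - 1 denominator) and
#' `CV = 100 * sd / mean` of a set of group means — e.g. the per-scanner
#' mean ADC of an ice-water phantom.  The CV is scale invariant.
#'
#' @param values numeric vector of group means (length >= 2).
#' @return List with `mean`, `sd` and `cv` (percent).  A zero mean yields
#'   `cv = NA` with a warning (undefined CV).
#' @examples
#' groupCV(c(1.1103, 1.1116, 1.1064, 1.0971, 1.1106, 1.1525, 1.1092,
#'           1.1223))
#' @export
groupCV <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || any(!is.finite(values))) {
    stopValidation("'values' must be >= 2 finite numbers")
  }
  m <- mean(values)
  s <- sd(values)
  cv <- if (m == 0) {
    warning("CV undefined for zero mean", call. = FALSE)
    NA_real_
  } else 100 * s / m
  list(mean = m, sd = s, cv = cv)
}

#' Coefficient of variation from model components
#'
#' `cv = 100 * sigma / mu`, the reproducibility of a metric implied by one
#' variance component at the model grand mean.  Report tables round to one
#' decimal; the returned value is unrounded.
#'
#' @param mu model grand mean (non-zero).
#' @param sigma component standard deviation (`>= 0`).
#' @return CV in percent (`NA` with a warning when `mu = 0`).
#' @examples
#' cvFromComponents(0.8327, 0.0203)   # ~2.4%
#' @export
cvFromComponents <- function(mu, sigma) {
  assertScalarNumber(mu, "mu")
  if (is.na(sigma)) return(NA_real_)
  if (sigma < 0) stopValidation("'sigma' must be >= 0")
  if (mu == 0) {
    warning("CV undefined for zero mean", call. = FALSE)
    return(NA_real_)
  }
  100 * sigma / mu
}

#' Intraclass correlation pair from inter- and intra-scanner SDs
#'
#' Splits the combined inter + intra variance into the proportion due to
#' between-scanner differences and the proportion due to within-scanner
#' (session) noise:
#' `iccInter = sigmaInter^2 / (sigmaInter^2 + sigmaIntra^2)` and
#' `iccIntra = 1 - iccInter`.
#'
#' @param sigmaInter inter-scanner SD (`>= 0`).
#' @param sigmaIntra intra-scanner SD (`>= 0`); not both zero.
#' @return Named numeric vector `c(iccInter, iccIntra)`; sums to 1.
#' @examples
#' iccPair(0.0203, 0.0242)   # grey-matter ADC: ~0.41 / 0.59
#' @export
iccPair <- function(sigmaInter, sigmaIntra) {
  assertScalarNumber(sigmaInter, "sigmaInter")
  assertScalarNumber(sigmaIntra, "sigmaIntra")
  if (sigmaInter < 0 || sigmaIntra < 0) {
    stopValidation("SDs must be >= 0")
  }
  tot <- sigmaInter^2 + sigmaIntra^2
  if (tot == 0) {
    warning("ICC undefined when both SDs are zero", call. = FALSE)
    return(c(iccInter = NA_real_, iccIntra = NA_real_))
  }
  icc <- sigmaInter^2 / tot
  c(iccInter = icc, iccIntra = 1 - icc)
}

## Deterministic (zero-residual) limit of the mixed model: exact scanner
## means, volunteer effects from the two-way fixed-effects fit.
degenerateComponents <- function(df, metric, region, subgroup) {
  scannerMeans <- tapply(df$value, df$scanner, mean)
  nVol <- length(unique(df$volunteer))
  volSD <- 0
  if (nVol > 1L) {
    fit <- lm(value ~ 0 + scanner + volunteer, data = df)
    vcoef <- coef(fit)[grepl("^volunteer", names(coef(fit)))]
    vcoef <- c(0, unname(vcoef))         # reference level
    volSD <- if (any(is.na(vcoef))) 0 else sd(vcoef - mean(vcoef))
    if (!is.finite(volSD) || volSD < 1e-8 * max(sd(df$value), 1e-300)) {
      volSD <- 0
    }
  }
  varianceComponents(
    mu = mean(scannerMeans), sigmaInter = sd(scannerMeans),
    sigmaVolunteer = volSD, sigmaIntra = 0,
    volunteerEstimable = volSD > 0, converged = TRUE,
    metric = metric, region = region, subgroup = subgroup,
    nObs = nrow(df), nScanners = length(scannerMeans), nVolunteers = nVol)
}

#' REML variance components for one metric and region
#'
#' Fits the mixed model `value ~ scanner (fixed) + (1 | volunteer) +
#' residual` by restricted maximum likelihood (via \pkg{lme4}), then
#' summarises it the way multi-centre reproducibility studies report it:
#'
#' * `mu` — unweighted mean of the estimated scanner means (scanners are
#'   treated symmetrically regardless of volunteer counts);
#' * `sigmaInter` — sample SD (n - 1) of the estimated scanner means;
#' * `sigmaVolunteer` — volunteer random-effect SD;
#' * `sigmaIntra` — residual SD.
#'
#' When the random-effect variance collapses to the zero boundary
#' (estimate below `1e-8 * sigmaIntra`) the component is flagged not
#' estimable (`volunteerEstimable = FALSE`, rendered "NE" in reports).
#' Repeat sessions are additional observations within the (scanner,
#' volunteer) cell; no session-level random term is used.  Data whose full
#' two-way fit leaves (numerically) zero residual bypass REML and use the
#' exact deterministic limit.
#'
#' @param table long-format measurement data.frame with columns `scanner`,
#'   `volunteer`, `session`, `region`, `metric`, `value`.
#' @param metric,region which slice of the table to fit.
#' @param subgroup label recorded on the result (e.g. `"1.5T"`).
#' @return A [VarianceComponents-class] object.
#' @examples
#' sim <- simulateStudy(replicaStudyDesign(1), seed = 7)
#' fitVarianceComponents(sim$table, "ADC", "GM")
#' @export
fitVarianceComponents <- function(table, metric, region, subgroup = "") {
  df <- table[table$metric == metric & table$region == region, , drop = FALSE]
  if (nrow(df) == 0L) {
    stopValidation("no rows for metric '%s' in region '%s'", metric, region)
  }
  if (any(!is.finite(df$value))) {
    stopValidation("non-finite values for metric '%s' in region '%s'",
                   metric, region)
  }
  nScanners <- length(unique(df$scanner))
  nVol <- length(unique(df$volunteer))
  if (nScanners < 2L) {
    stopValidation("variance components need >= 2 scanners, got %d",
                   nScanners)
  }
  df$scanner <- factor(df$scanner)
  df$volunteer <- factor(df$volunteer)

  ## numerically zero residual after scanner + volunteer: exact limit
  resid2 <- sum(lm(value ~ 0 + scanner + volunteer, data = df)$residuals^2)
  scale2 <- max(var(df$value), .Machine$double.eps)
  if (resid2 <= 1e-20 * scale2 * nrow(df)) {
    return(degenerateComponents(df, metric, region, subgroup))
  }

  converged <- TRUE
  fit <- withCallingHandlers(
    lme4::lmer(value ~ 0 + scanner + (1 | volunteer), data = df,
               REML = TRUE),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage")
  )
  scannerMeans <- lme4::fixef(fit)
  sigmaIntra <- stats::sigma(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigmaVol <- vc$sdcor[vc$grp == "volunteer"][1]
  estimable <- is.finite(sigmaVol) && sigmaVol >= 1e-8 * sigmaIntra
  varianceComponents(
    mu = mean(scannerMeans), sigmaInter = sd(scannerMeans),
    sigmaVolunteer = if (is.finite(sigmaVol)) sigmaVol else 0,
    sigmaIntra = sigmaIntra,
    volunteerEstimable = estimable, converged = converged,
    metric = metric, region = region, subgroup = subgroup,
    nObs = nrow(df), nScanners = nScanners, nVolunteers = nVol)
}

#' Reproducibility metrics from variance components
#'
#' Converts a [VarianceComponents-class] fit into the reported quantities:
#' inter-scanner, inter-volunteer and intra-scanner CV
#' (`100 * sigma / mu`, with the mean fixed at the model estimate) and the
#' intraclass correlation pair of [iccPair()].  A non-estimable volunteer
#' component propagates as `cvVolunteer = NA`.
#'
#' @param vc a [VarianceComponents-class] object.
#' @return A [ReproResult-class] object.
#' @export
reproResult <- function(vc) {
  stopifnot(is(vc, "VarianceComponents"))
  icc <- iccPair(vc@sigmaInter, vc@sigmaIntra)
  new("ReproResult", metric = vc@metric, region = vc@region,
      subgroup = vc@subgroup, mu = vc@mu, sigmaInter = vc@sigmaInter,
      sigmaVolunteer = if (vc@volunteerEstimable) vc@sigmaVolunteer
                       else NA_real_,
      sigmaIntra = vc@sigmaIntra,
      cvInter = cvFromComponents(vc@mu, vc@sigmaInter),
      cvVolunteer = if (vc@volunteerEstimable)
        cvFromComponents(vc@mu, vc@sigmaVolunteer) else NA_real_,
      cvIntra = cvFromComponents(vc@mu, vc@sigmaIntra),
      iccInter = unname(icc["iccInter"]), iccIntra = unname(icc["iccIntra"]),
      volunteerEstimable = vc@volunteerEstimable)
}

#' Field-strength subgroup analysis
#'
#' Runs the variance-component pipeline separately within each field
#' strength and on all scanners combined, for one metric and region.
#' Subgroups with fewer than two scanners cannot support the model and are
#' returned as flagged rows (all-`NA` estimates); the remaining subgroups
#' are still computed.
#'
#' @param table long-format measurement data.frame.
#' @param fieldStrengths named numeric vector mapping scanner id to 1.5 or
#'   3, or a list of [ScannerProfile-class] objects.
#' @param metric,region which slice to analyse.
#' @return A list of [ReproResult-class] objects named `"1.5T"`, `"3T"`,
#'   `"all"`; flagged subgroups are `NA`-filled.
#' @export
subgroupAnalysis <- function(table, fieldStrengths, metric, region) {
  if (is.list(fieldStrengths)) {
    fieldStrengths <- setNames(
      vapply(fieldStrengths, function(s) s@fieldStrength, numeric(1)),
      vapply(fieldStrengths, function(s) s@scannerId, character(1)))
  }
  groups <- list(
    "1.5T" = names(fieldStrengths)[fieldStrengths == 1.5],
    "3T" = names(fieldStrengths)[fieldStrengths == 3],
    "all" = names(fieldStrengths))
  lapply(setNames(names(groups), names(groups)), function(g) {
    sub <- table[table$scanner %in% groups[[g]], , drop = FALSE]
    nScanners <- length(unique(sub$scanner[
      sub$metric == metric & sub$region == region]))
    if (nScanners < 2L) {
      return(new("ReproResult", metric = metric, region = region,
                 subgroup = g, mu = NA_real_, sigmaInter = NA_real_,
                 sigmaVolunteer = NA_real_, sigmaIntra = NA_real_,
                 cvInter = NA_real_, cvVolunteer = NA_real_,
                 cvIntra = NA_real_, iccInter = NA_real_,
                 iccIntra = NA_real_, volunteerEstimable = FALSE))
    }
    reproResult(fitVarianceComponents(sub, metric, region, subgroup = g))
  })
}

#' Tabulate reproducibility results
#'
#' Collects [ReproResult-class] objects into one report data.frame shaped
#' like the summary tables of multi-centre reproducibility studies: mean,
#' the three component SDs, the three CVs, the ICC pair, and a
#' minimum-detectable-change column equal to `2 * cvInter` (a change must
#' exceed two inter-scanner standard deviations to be attributable to
#' something other than scanner variability).
#'
#' @param results list of [ReproResult-class] objects (empty list allowed).
#' @return data.frame with one row per result; numeric columns unrounded.
#' @seealso [formatReport()] for the rounded, "NE"-rendered version.
#' @export
summarizeReport <- function(results) {
  if (is(results, "ReproResult")) results <- list(results)
  cols <- c("metric", "region", "subgroup", "mean", "sd_inter",
            "sd_volunteer", "sd_intra", "cv_inter", "cv_volunteer",
            "cv_intra", "icc_inter", "icc_intra", "mdc")
  if (length(results) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), 3), cols[1:3]))
    for (nm in cols[-(1:3)]) out[[nm]] <- numeric(0)
    return(out)
  }
  out <- do.call(rbind, lapply(results, function(r) {
    data.frame(metric = r@metric, region = r@region, subgroup = r@subgroup,
               mean = r@mu, sd_inter = r@sigmaInter,
               sd_volunteer = r@sigmaVolunteer, sd_intra = r@sigmaIntra,
               cv_inter = r@cvInter, cv_volunteer = r@cvVolunteer,
               cv_intra = r@cvIntra, icc_inter = r@iccInter,
               icc_intra = r@iccIntra, mdc = 2 * r@cvInter,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Render a report with study-table rounding
#'
#' CVs and the minimum detectable change are rounded to one decimal, ICCs
#' to two; non-estimable volunteer components print as `"NE"`.  Internal
#' values are never rounded — this affects only the rendered table.
#'
#' @param report data.frame from [summarizeReport()].
#' @return data.frame of character/numeric columns ready for printing.
#' @export
formatReport <- function(report) {
  fmtCV <- function(x) ifelse(is.na(x), "NE", sprintf("%.1f", x))
  fmtICC <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))
  data.frame(
    metric = report$metric, region = report$region,
    subgroup = report$subgroup,
    mean = sprintf("%.4f", report$mean),
    cv_inter = fmtCV(report$cv_inter),
    cv_volunteer = fmtCV(report$cv_volunteer),
    cv_intra = fmtCV(report$cv_intra),
    icc_inter = fmtICC(report$icc_inter),
    icc_intra = fmtICC(report$icc_intra),
    mdc = fmtCV(report$mdc),
    stringsAsFactors = FALSE)
}
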