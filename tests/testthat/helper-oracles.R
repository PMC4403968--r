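## Independent oracles used across the suite.  These deliberately avoid the
## package's own code paths.

## Brute-force binary erosion by explicit neighbour loops.
naiveErode <- function(mask, connectivity = 6) {
  d <- dim(mask)
  out <- array(FALSE, dim = d)
  offs <- if (connectivity == 6) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
          c(0, 0, 1), c(0, 0, -1))
  } else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(g != 0) > 0, ]
  }
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!mask[x, y, z]) next
    keep <- TRUE
    for (k in seq_len(nrow(offs))) {
      nx <- x + offs[k, 1]; ny <- y + offs[k, 2]; nz <- z + offs[k, 3]
      if (nx < 1 || ny < 1 || nz < 1 || nx > d[1] || ny > d[2] ||
          nz > d[3] || !mask[nx, ny, nz]) {
        keep <- FALSE
        break
      }
    }
    out[x, y, z] <- keep
  }
  out
}

## Closed-form ANOVA method-of-moments components for a balanced crossed
## design: every volunteer on every scanner, r sessions per pair.
momComponents <- function(df) {
  s <- length(unique(df$scanner))
  v <- length(unique(df$volunteer))
  r <- nrow(df) / (s * v)
  stopifnot(r == round(r))
  gm <- mean(df$value)
  scannerMeans <- tapply(df$value, df$scanner, mean)
  volMeans <- tapply(df$value, df$volunteer, mean)
  pred <- scannerMeans[df$scanner] + volMeans[df$volunteer] - gm
  sse <- sum((df$value - pred)^2)
  mse <- sse / (nrow(df) - s - v + 1)
  msVol <- r * s * sum((volMeans - gm)^2) / (v - 1)
  sigmaVol2 <- max((msVol - mse) / (r * s), 0)
  list(mu = mean(scannerMeans), sigmaInter = sd(scannerMeans),
       sigmaVolunteer = sqrt(sigmaVol2), sigmaIntra = sqrt(mse))
}

## Balanced crossed study design: `s` scanners sharing the same `v`
## volunteers, `r` sessions per (scanner, volunteer) pair, one metric.
balancedDesign <- function(s = 8, v = 6, r = 2, offsets, volunteerSD,
                           residualSD, grandMean = 1) {
  ids <- LETTERS[seq_len(s)]
  vols <- paste0("V", seq_len(v))
  scanners <- lapply(seq_len(s), function(i) {
    scannerProfile(ids[i], fieldStrength = if (i %% 2) 1.5 else 3,
                   metricOffsets = c(M = offsets[i]))
  })
  volunteers <- setNames(rep(list(vols), s), ids)
  repeats <- if (r > 1) {
    expand.grid(scanner = ids, volunteer = vols,
                stringsAsFactors = FALSE)
  } else NULL
  if (!is.null(repeats)) repeats$sessions <- as.integer(r)
  truth <- data.frame(metric = "M", region = "R", grandMean = grandMean,
                      volunteerSD = volunteerSD, residualSD = residualSD)
  studyDesign(scanners, volunteers, repeats, truth)
}

## Mean of the Rice distribution by numerical integration (sigma = 1).
riceMeanOracle <- function(nu) {
  integrand <- function(x) {
    x^2 * exp(-(x - nu)^2 / 2) * besselI(x * nu, 0, expon.scaled = TRUE)
  }
  integrate(integrand, max(0, nu - 12), nu + 12, rel.tol = 1e-10)$value
}

## Alternative FA formulation (pairwise eigenvalue differences), used as an
## independent check on the variance-based formula.
faPairwise <- function(l) {
  sqrt(0.5 * ((l[1] - l[2])^2 + (l[2] - l[3])^2 + (l[3] - l[1])^2) /
         sum(l^2))
}

## Random rotation matrix from a fixed-seed QR decomposition.
randomRotation <- function(seed) {
  set.seed(seed)
  qrd <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qrd)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
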