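test_that("the replica design matches the published study layout", {
  d <- replicaStudyDesign(seed = 1)
  expect_equal(sessionCount(d), 65)
  counts <- lengths(d@volunteers)
  expect_true(all(counts >= 4 & counts <= 8))
  expect_equal(length(d@scanners), 8)
  fields <- vapply(d@scanners, function(s) s@fieldStrength, numeric(1))
  expect_equal(sum(fields == 1.5), 4)
  expect_equal(sum(fields == 3), 4)
  expect_lte(length(unique(unlist(d@volunteers))), 9)
})

test_that("simulated tables have one row per session, metric and region", {
  sim <- simulateStudy(replicaStudyDesign(1), seed = 42)
  tab <- sim$table
  cells <- table(tab$metric, tab$region)
  expect_true(all(cells == 65))
  expect_equal(nrow(tab), 65 * 10)
  expect_false(anyDuplicated(tab[, c("scanner", "volunteer", "session",
                                     "region", "metric")]) > 0)
})

test_that("zero variances and offsets collapse every value to the grand mean", {
  des <- balancedDesign(s = 3, v = 2, r = 1, offsets = rep(0, 3),
                        volunteerSD = 0, residualSD = 0, grandMean = 0.75)
  sim <- simulateStudy(des, seed = 9)
  expect_true(all(sim$table$value == 0.75))
})

test_that("study generation is seed-deterministic and seed-sensitive", {
  d <- replicaStudyDesign(1)
  expect_identical(simulateStudy(d, seed = 3)$table,
                   simulateStudy(d, seed = 3)$table)
  expect_false(identical(simulateStudy(d, seed = 3)$table$value,
                         simulateStudy(d, seed = 4)$table$value))
})

test_that("generator moments converge to the design effect sizes", {
  ## empirical SDs of the realized components across replicates, checked
  ## against the design values within 3 Monte-Carlo SEs
  des <- balancedDesign(s = 4, v = 5, r = 2, offsets = rep(0, 4),
                        volunteerSD = 0.015, residualSD = 0.01)
  nRep <- 50
  volDraws <- numeric(0)
  resDraws <- numeric(0)
  for (k in seq_len(nRep)) {
    sim <- simulateStudy(des, seed = 1000 + k)
    volDraws <- c(volDraws, sim$truth$volunteerEffects[["M.R"]])
    resid <- sim$table$value - 1 -
      sim$truth$volunteerEffects[["M.R"]][sim$table$volunteer]
    resDraws <- c(resDraws, resid)
  }
  seSD <- function(sigma, n) sigma / sqrt(2 * (n - 1))
  expect_lt(abs(sd(volDraws) - 0.015), 3 * seSD(0.015, length(volDraws)))
  expect_lt(abs(sd(resDraws) - 0.010), 3 * seSD(0.010, length(resDraws)))
})

test_that("degenerate designs are rejected", {
  expect_error(studyDesign(list(), list(), NULL, data.frame()), "scanners")
})
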