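phantomADC <- c(1.1103, 1.1116, 1.1064, 1.0971, 1.1106, 1.1525, 1.1092,
                1.1223)

test_that("group CV reproduces the phantom summary arithmetic", {
  g <- groupCV(phantomADC)
  expect_equal(round(g$mean, 4), 1.1150)
  expect_equal(round(g$sd, 4), 0.0167)
  expect_equal(round(g$cv, 1), 1.5)

  noF <- groupCV(phantomADC[-6])          # drop the outlying scanner
  expect_equal(round(noF$cv, 1), 0.7)

  expect_equal(groupCV(c(3, 3, 3))$cv, 0)
  expect_error(groupCV(1), ">= 2")
  expect_warning(g0 <- groupCV(c(-1, 1)), "zero mean")
  expect_true(is.na(g0$cv))
})

test_that("group CV is scale-invariant", {
  for (c in c(1e-3, 2, 1e4)) {
    expect_equal(groupCV(c * phantomADC)$cv, groupCV(phantomADC)$cv,
                 tolerance = 1e-12)
  }
})

test_that("component CVs match the published worked examples", {
  expect_equal(round(cvFromComponents(0.8327, 0.0203), 1), 2.4)
  expect_equal(round(cvFromComponents(0.1726, 0.0128), 1), 7.4)
  expect_equal(cvFromComponents(0.5, 0), 0)
  expect_warning(cv0 <- cvFromComponents(0, 0.1), "zero mean")
  expect_true(is.na(cv0))
})

test_that("ICC pairs split the variance and sum to one", {
  gm <- iccPair(0.0203, 0.0242)
  expect_equal(round(unname(gm), 2), c(0.41, 0.59))
  wm <- iccPair(0.0210, 0.0072)
  ## Eq. arithmetic on the printed SDs gives 0.8948 (prints as 0.90 in the
  ## source, which rounded from unrounded SDs)
  expect_equal(round(unname(wm), 2), c(0.89, 0.11))
  expect_equal(unname(iccPair(0.3, 0.3)), c(0.5, 0.5))

  set.seed(8)
  for (i in 1:50) {
    p <- iccPair(runif(1, 0, 2), runif(1, 1e-6, 2))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0 & p <= 1))
  }
  expect_warning(nd <- iccPair(0, 0), "undefined")
  expect_true(all(is.na(nd)))
})

test_that("the deterministic limit returns exact scanner components", {
  offs <- c(A = 0.05, B = -0.02, C = 0.01, D = -0.04)
  tab <- expand.grid(scanner = names(offs), volunteer = paste0("V", 1:3),
                     stringsAsFactors = FALSE)
  tab$session <- "S1"; tab$region <- "R"; tab$metric <- "M"
  tab$value <- 0.8 + offs[tab$scanner]
  vc <- fitVarianceComponents(tab, "M", "R")
  expect_equal(vc@sigmaIntra, 0)
  expect_equal(vc@sigmaInter, sd(offs), tolerance = 1e-12)
  expect_equal(vc@mu, 0.8 + mean(offs), tolerance = 1e-12)
  expect_false(vc@volunteerEstimable)
})

test_that("REML components agree with the balanced-ANOVA oracle", {
  set.seed(51)
  for (rep in 1:3) {
    offsets <- rnorm(6, 0, 0.02)
    des <- balancedDesign(s = 6, v = 5, r = 2, offsets = offsets,
                          volunteerSD = 0.015, residualSD = 0.01)
    sim <- simulateStudy(des, seed = 500 + rep)
    vc <- fitVarianceComponents(sim$table, "M", "R")
    mom <- momComponents(sim$table)
    expect_equal(vc@mu, mom$mu, tolerance = 1e-6)
    expect_equal(vc@sigmaInter, mom$sigmaInter, tolerance = 1e-6)
    expect_equal(vc@sigmaVolunteer, mom$sigmaVolunteer, tolerance = 1e-6)
    expect_equal(vc@sigmaIntra, mom$sigmaIntra, tolerance = 1e-6)
  }
})

test_that("a zero volunteer effect hits the boundary and is flagged NE", {
  ## with a true zero random-effect variance the REML estimate collapses to
  ## the boundary in about half of replicates (asymptotic probability 1/2);
  ## with a solidly positive variance it almost never does
  countNE <- function(volunteerSD, seeds) {
    sum(vapply(seeds, function(sd0) {
      des <- balancedDesign(s = 5, v = 4, r = 2,
                            offsets = c(0.02, -0.01, 0.03, -0.02, 0.01),
                            volunteerSD = volunteerSD, residualSD = 0.01)
      sim <- simulateStudy(des, seed = sd0)
      !fitVarianceComponents(sim$table, "M", "R")@volunteerEstimable
    }, logical(1)))
  }
  nRep <- 40
  neNull <- countNE(0, 900 + seq_len(nRep))
  expect_gt(neNull / nRep, 0.3)
  expect_lt(neNull / nRep, 0.75)
  neAlt <- countNE(0.02, 900 + seq_len(nRep))
  expect_lt(neAlt / nRep, 0.1)
})

test_that("too few scanners is a validation error", {
  tab <- data.frame(scanner = "A", volunteer = paste0("V", 1:4),
                    session = "S1", region = "R", metric = "M",
                    value = rnorm(4))
  expect_error(fitVarianceComponents(tab, "M", "R"), ">= 2 scanners")
})

test_that("field-strength subgroups are symmetric under identical effects", {
  ## same effect sizes at both field strengths: subgroup CVs should agree
  ## on average within Monte-Carlo error
  nRep <- 25
  diffs <- numeric(nRep)
  for (rep in seq_len(nRep)) {
    set.seed(3000 + rep)
    des <- balancedDesign(s = 8, v = 5, r = 2,
                          offsets = rnorm(8, 0, 0.02),
                          volunteerSD = 0.01, residualSD = 0.01)
    sim <- simulateStudy(des, seed = 3000 + rep)
    sub <- subgroupAnalysis(sim$table, des@scanners, "M", "R")
    diffs[rep] <- sub[["1.5T"]]@cvInter - sub[["3T"]]@cvInter
  }
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(nRep))
})

test_that("a single-scanner subgroup is flagged while others are computed", {
  des <- balancedDesign(s = 3, v = 4, r = 2,
                        offsets = c(0.01, -0.01, 0.02),
                        volunteerSD = 0.01, residualSD = 0.01)
  ## scanners A, C are 1.5T and B is 3T under the alternating assignment
  sim <- simulateStudy(des, seed = 77)
  sub <- subgroupAnalysis(sim$table, des@scanners, "M", "R")
  expect_true(is.na(sub[["3T"]]@cvInter))
  expect_false(is.na(sub[["1.5T"]]@cvInter))
  expect_false(is.na(sub[["all"]]@cvInter))
})

test_that("combined CV dominates subgroup CVs when only the subgroup means differ", {
  ## two field strengths with different grand means but no scanner effect
  ## inside either subgroup
  tab <- expand.grid(scanner = c("A", "C", "B", "D"),
                     volunteer = paste0("V", 1:4),
                     stringsAsFactors = FALSE)
  tab$session <- "S1"; tab$region <- "R"; tab$metric <- "M"
  tab$value <- ifelse(tab$scanner %in% c("A", "C"), 0.7, 0.9)
  fields <- c(A = 1.5, C = 1.5, B = 3, D = 3)
  ## all-zero within-subgroup variance makes the subgroup ICCs undefined
  sub <- suppressWarnings(subgroupAnalysis(tab, fields, "M", "R"))
  expect_equal(sub[["1.5T"]]@cvInter, 0)
  expect_equal(sub[["3T"]]@cvInter, 0)
  expect_gt(sub[["all"]]@cvInter,
            max(sub[["1.5T"]]@cvInter, sub[["3T"]]@cvInter))
})

test_that("reports carry the two-CV minimum detectable change and NE cells", {
  expect_equal(nrow(summarizeReport(list())), 0)

  vc <- varianceComponents(mu = 1, sigmaInter = 0.015, sigmaVolunteer = 0.01,
                           sigmaIntra = 0.01, metric = "ADC", region = "GM")
  rep1 <- summarizeReport(list(reproResult(vc)))
  expect_equal(rep1$mdc, 2 * rep1$cv_inter)
  expect_equal(rep1$cv_inter, 1.5)

  ne <- varianceComponents(mu = 1, sigmaInter = 0.03, sigmaVolunteer = 0,
                           sigmaIntra = 0.01, volunteerEstimable = FALSE,
                           metric = "ADC", region = "BS")
  fm <- formatReport(summarizeReport(list(reproResult(ne))))
  expect_equal(fm$cv_volunteer, "NE")
  expect_equal(fm$cv_inter, "3.0")
  expect_equal(fm$mdc, "6.0")
})
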