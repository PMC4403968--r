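test_that("probability thresholding uses strict > semantics", {
  zero <- array(0, dim = c(4, 4, 2))
  expect_equal(sum(thresholdProbabilityMap(zero)), 0)
  uniform <- array(0.95, dim = c(4, 4, 2))
  expect_equal(sum(thresholdProbabilityMap(uniform, 0.95)), 0)

  set.seed(14)
  p <- array(runif(4 * 4 * 2), dim = c(4, 4, 2))
  k <- sum(p > 0.95)
  expect_equal(sum(thresholdProbabilityMap(p, 0.95)), k)
  expect_error(thresholdProbabilityMap(array(1.4, c(2, 2, 1))), "\\[0, 1\\]")
  expect_error(thresholdProbabilityMap(zero, 0), "\\(0, 1\\]")
})

test_that("erosion matches the brute-force oracle on random masks", {
  for (seed in 1:3) {
    set.seed(seed)
    m <- array(runif(7 * 6 * 5) > 0.35, dim = c(7, 6, 5))
    expect_identical(erodeMask(m, 1, 6), naiveErode(m, 6))
    expect_identical(erodeMask(m, 1, 26), naiveErode(m, 26))
    expect_identical(erodeMask(m, 2, 6), naiveErode(naiveErode(m, 6), 6))
  }
})

test_that("erosion shrinks cubes to their centres and is anti-extensive", {
  single <- array(FALSE, dim = c(5, 5, 5)); single[3, 3, 3] <- TRUE
  expect_equal(sum(erodeMask(single)), 0)

  cube3 <- array(FALSE, dim = c(5, 5, 5))
  cube3[2:4, 2:4, 2:4] <- TRUE
  e3 <- erodeMask(cube3)
  expect_equal(which(e3), which(single))

  cube5 <- array(FALSE, dim = c(9, 9, 9))
  cube5[3:7, 3:7, 3:7] <- TRUE
  e5 <- erodeMask(cube5, iterations = 2)
  expect_equal(sum(e5), 1)
  expect_true(e5[5, 5, 5])

  set.seed(4)
  m <- array(runif(6^3) > 0.3, dim = c(6, 6, 6))
  expect_true(all(m[erodeMask(m)]))
})

test_that("erosion commutes with translation", {
  m <- array(FALSE, dim = c(10, 10, 6))
  m[2:5, 3:6, 2:4] <- TRUE
  shifted <- array(FALSE, dim = dim(m))
  shifted[4:7, 4:7, 3:5] <- TRUE        # +2, +1, +1 translation
  e <- erodeMask(m)
  eShift <- erodeMask(shifted)
  expect_equal(which(eShift, arr.ind = TRUE),
               sweep(which(e, arr.ind = TRUE), 2, c(2, 1, 1), "+"),
               ignore_attr = TRUE)
})

test_that("roiMean averages in-mask voxels and tolerates sentinels", {
  map <- array(7, dim = c(3, 3, 1))
  full <- array(TRUE, dim = c(3, 3, 1))
  expect_equal(roiMean(map, full), list(mean = 7, n = 9L))

  map2 <- array(c(1, 2, 3), dim = c(3, 1, 1))
  expect_equal(roiMean(map2, array(TRUE, c(3, 1, 1)))$mean, 2)

  withNA <- map
  withNA[1, 1, 1] <- NA                 # invalid-fit sentinel
  expect_equal(roiMean(withNA, full), list(mean = 7, n = 8L))

  empty <- array(FALSE, dim = c(3, 3, 1))
  expect_equal(roiMean(map, empty), list(mean = NA_real_, n = 0L))
  expect_error(roiMean(map, array(TRUE, c(2, 2, 1))), "shapes")
})

test_that("measurement tables count sessions x regions x metrics", {
  mk <- function(v) array(v, dim = c(2, 2, 1))
  mask <- array(TRUE, dim = c(2, 2, 1))
  maps <- list(s1 = list(ADC = mk(1), FA = mk(2)),
               s2 = list(ADC = mk(3), FA = mk(4)))
  masks <- list(s1 = list(GM = mask, WM = mask, BS = mask),
                s2 = list(GM = mask, WM = mask, BS = mask))
  meta <- data.frame(id = c("s1", "s2"), scanner = c("A", "B"),
                     volunteer = c("V1", "V1"), session = c("S1", "S1"))
  tab <- buildMeasurementTable(maps, masks, meta)
  expect_equal(nrow(tab), 12)           # 2 sessions x 3 regions x 2 metrics

  ## a region lost in one session drops its rows with a logged warning
  masks$s2$BS <- array(FALSE, dim = c(2, 2, 1))
  expect_warning(tab2 <- buildMeasurementTable(maps, masks, meta),
                 "skipped")
  expect_equal(nrow(tab2), 10)
  expect_length(attr(tab2, "log")$skipped, 2)

  metaDup <- meta
  metaDup$scanner <- "A"; metaDup$volunteer <- "V1"; metaDup$session <- "S1"
  expect_error(buildMeasurementTable(maps, masks, metaDup), "duplicate")
})

test_that("eroded ROI means beat uneroded means under boundary contamination", {
  ## a solid region at value 1 whose one-voxel rim is contaminated upward,
  ## emulating partial-volume voxels at tissue boundaries
  map <- array(0, dim = c(12, 12, 5))
  region <- array(FALSE, dim = dim(map))
  region[3:10, 3:10, 2:4] <- TRUE
  inner <- erodeMask(region)
  rim <- region & !inner
  map[inner] <- 1
  map[rim] <- 1.6
  errFull <- abs(roiMean(map, region)$mean - 1)
  errEroded <- abs(roiMean(map, erodeMask(region))$mean - 1)
  expect_lt(errEroded, errFull)
  expect_equal(roiMean(map, erodeMask(region))$mean, 1)
})
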