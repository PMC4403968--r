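## Full regression of the reproducibility arithmetic against the bundled
## published summary tables.  Printed CVs were computed by the source from
## unrounded model SDs, so recomputation from the 4-decimal printed SDs can
## legitimately differ by one unit in the last printed digit.  Two cells
## disagree grossly and are consistent with a dropped digit in the printed
## SD (the printed CV and mean imply inter-scanner SDs of ~0.0803 and
## ~0.0398 respectively); they are asserted as known discrepancies rather
## than silently skipped.

cvTypos <- data.frame(
  metric = c("ADC", "D"), region = c("basal_ganglia", "thalamus"),
  component = "cv_inter", stringsAsFactors = FALSE)

## Cells whose printed ICC_inter is not the Eq.-arithmetic of the printed
## SDs even allowing one unit of rounding (several ADC sub-region rows
## appear shifted/mismatched in the source table).
iccDiscrepant <- data.frame(
  metric = c("ADC", "ADC", "ADC", "ADC", "ADC", "ADC", "ADC", "D"),
  region = c("cerebellar_cortex", "brain_stem", "cerebral_wm",
             "basal_ganglia", "thalamus", "choroid_plexus", "optic_chiasm",
             "thalamus"),
  stringsAsFactors = FALSE)

test_that("every printed CV cell is reproduced to its printed precision", {
  tab <- volunteerSummary()
  comps <- c(cv_inter = "sd_inter", cv_volunteer = "sd_volunteer",
             cv_intra = "sd_intra")
  nChecked <- 0
  for (i in seq_len(nrow(tab))) {
    for (cvCol in names(comps)) {
      printed <- tab[[cvCol]][i]
      sdv <- tab[[comps[[cvCol]]]][i]
      if (is.na(printed) || is.na(sdv)) next
      got <- cvFromComponents(tab$mean[i], sdv)
      isTypo <- any(cvTypos$metric == tab$metric[i] &
                      cvTypos$region == tab$region[i] &
                      cvTypos$component == cvCol)
      if (isTypo) {
        expect_gt(abs(got - printed), 1)
      } else {
        expect_lt(abs(round(got, 1) - printed), 0.1 + 1e-9)
        nChecked <- nChecked + 1
      }
    }
  }
  expect_equal(nChecked, 144)
})

test_that("printed ICCs are reproduced outside the known-discrepant cells", {
  tab <- volunteerSummary()
  for (i in seq_len(nrow(tab))) {
    icc <- iccPair(tab$sd_inter[i], tab$sd_intra[i])
    known <- any(iccDiscrepant$metric == tab$metric[i] &
                   iccDiscrepant$region == tab$region[i])
    if (known) {
      expect_gt(abs(icc[["iccInter"]] - tab$icc_inter[i]), 0.011)
    } else {
      expect_lt(abs(icc[["iccInter"]] - tab$icc_inter[i]), 0.011)
      ## the FA cerebellar-WM printed pair (0.47/0.33) does not sum to 1;
      ## its intra cell is a misprint of the 0.53 complement
      if (!(tab$metric[i] == "FA" && tab$region[i] == "cerebellar_wm")) {
        expect_lt(abs(icc[["iccIntra"]] - tab$icc_intra[i]), 0.011)
      }
    }
  }
})

test_that("the phantom summary rows recompute from the per-scanner means", {
  ph <- phantomScannerMeans()
  expected <- data.frame(
    metric = c("ADC", "D", "f", "MD", "FA"),
    mean = c(1.1150, 1.1289, 0.0193, 1.1157, 0.0371),
    sd = c(0.0167, 0.0345, 0.0168, 0.0334, 0.0103),
    cv = c(1.5, 3.1, 87.1, 3.0, 27.8))
  for (i in seq_len(nrow(expected))) {
    g <- groupCV(ph$mean[ph$metric == expected$metric[i]])
    expect_equal(round(g$mean, 4), expected$mean[i])
    expect_equal(round(g$sd, 4), expected$sd[i])
    expect_equal(round(g$cv, 1), expected$cv[i])
  }
})
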