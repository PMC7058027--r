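test_that("dF/F0 uses the first 100 s as baseline", {
  # constant trace -> identically zero
  rec <- makeRecording(rep(100, 300), rate = 2)
  expect_equal(computeDff(rec), rep(0, 300))
  # F0 = 100, sample at 250 -> 1.5
  f <- rep(100, 300); f[250] <- 250
  expect_equal(computeDff(makeRecording(f, rate = 2))[250], 1.5)
  # recordings shorter than the window are rejected by the class itself
  expect_error(makeRecording(rep(100, 99), rate = 1), "100 s")
  # non-positive baseline
  expect_error(computeDff(makeRecording(rep(0, 300), rate = 2)),
               "baseline")
})

test_that("triangle pulse yields the closed-form peak geometry", {
  dff <- triangleDff(height = 2, halfS = 4, rate = 2, totalS = 300,
                     startS = 140)
  peaks <- detectTransients(dff, rate = 2)
  expect_equal(nrow(peaks), 1)
  expect_equal(peaks$amplitude, 2)
  expect_equal(peaks$prominence, 2)
  expect_equal(peaks$width, 4)
  expect_equal(peaks$time, 144)
  # triangle area via the cell summary: auc 8, frequency 1/300
  s <- summarizeCell(dff, peaks, duration = 300, rate = 2)
  expect_equal(s$auc, 8)
  expect_equal(s$frequency, 1 / 300)
  expect_equal(s$n_peaks, 1)
})

test_that("flat or sub-threshold series yield no peaks", {
  expect_equal(nrow(detectTransients(rep(0, 100), 2)), 0)
  expect_equal(nrow(detectTransients(triangleDff(1.1, 4, 2), 2)), 0)
  expect_equal(nrow(detectTransients(c(0, 2), 2)), 0)  # too short
  expect_error(detectTransients(rep(0, 10), rate = 0), "positive")
})

test_that("the separation rule keeps the taller of two close peaks", {
  rate <- 10
  t <- (0:199) / rate
  tri <- function(center, height, halfS)
    pmax(0, height * (1 - abs(t - center) / halfS))
  # candidate peaks 0.5 s apart (both pass prominence and width floors)
  dff <- pmax(tri(10, 2.0, 0.4), tri(10.5, 1.5, 0.4))
  peaks <- detectTransients(dff, rate, minWidthS = 0.1)
  expect_equal(nrow(peaks), 1)
  expect_equal(peaks$amplitude, 2.0)
  # with a relaxed separation floor both peaks survive
  both <- detectTransients(dff, rate, minWidthS = 0.1, minSepS = 0.4)
  expect_equal(nrow(both), 2)
})

test_that("every emitted peak re-validates the four thresholds and
           detection is threshold-monotone and shift-equivariant", {
  cfg <- smallTraceConfig()
  sim <- simulateCalciumTraces(cfg, seed = 21)
  recs <- sim$recordings
  nPeaks <- function(dff, ...) nrow(detectTransients(dff, 2, ...))
  checked <- 0
  for (rec in recs[seq(1, length(recs), by = 5)]) {
    dff <- computeDff(rec)
    peaks <- detectTransients(dff, rec@samplingRate)
    if (nrow(peaks)) {
      expect_true(all(peaks$amplitude > 1.15))
      expect_true(all(peaks$prominence >= 0.1))
      expect_true(all(peaks$width >= 2))
      if (nrow(peaks) > 1)
        expect_true(all(diff(sort(peaks$time)) >= 1))
      checked <- checked + 1
    }
    # raising any threshold never increases the peak count
    n0 <- nrow(peaks)
    expect_lte(nPeaks(dff, heightThr = 1.5), n0)
    expect_lte(nPeaks(dff, minWidthS = 3), n0)
    expect_lte(nPeaks(dff, minSepS = 5), n0)
    expect_lte(nPeaks(dff, minProm = 0.5), n0)
  }
  expect_gt(checked, 0)

  # time shift moves peak times, leaves other parameters unchanged
  dff <- triangleDff(2, 4, 2, totalS = 200, startS = 50)
  shifted <- c(numeric(40), dff)[seq_along(dff)]
  p0 <- detectTransients(dff, 2)
  p1 <- detectTransients(shifted, 2)
  expect_equal(p1$time, p0$time + 20)
  expect_equal(p1$amplitude, p0$amplitude)
  expect_equal(p1$width, p0$width)
})

test_that("planted event parameters are recovered within 10%", {
  cfg <- smallTraceConfig(nPerRegion = c(L1 = 40))
  tp <- cfg@traceParams
  tp$noiseSd <- 0.05
  tp$nonResponderFraction <- 0
  cfg@traceParams <- tp
  sim <- simulateCalciumTraces(cfg, seed = 31)
  params <- transientParameters(sim$recordings)
  phe <- params[params$condition == "PHE" & params$n_peaks > 0, ]
  planted <- tp$regimes$L1$PHE$ampMean
  expect_lt(abs(mean(phe$amplitude) - planted) / planted, 0.1)
})

test_that("inactive cells are summarized as inactive", {
  s <- summarizeCell(rep(0, 100), detectTransients(rep(0, 100), 2),
                     duration = 50, rate = 2)
  expect_false(s$active)
  expect_equal(s$frequency, 0)
  expect_true(is.na(s$amplitude))
})

test_that("responder filtering keeps PHE responders and reports
           condition activity", {
  params <- data.frame(
    cell_id = rep(c("a", "b", "c"), each = 3),
    condition = rep(c("BASE", "TTX", "PHE"), 3),
    n_peaks = c(2, 0, 3,   1, 1, 0,   0, 0, 1))
  fr <- filterResponders(params)
  expect_setequal(fr$retained, c("a", "c"))   # b has no PHE response
  expect_setequal(fr$activeIn$BASE, "a")
  expect_true(all(fr$activeIn$BASE %in% fr$retained))
  expect_equal(unname(fr$activeFraction["BASE"]), 0.5)
  # missing PHE recording -> excluded with warning
  expect_warning(fr2 <- filterResponders(params[params$cell_id != "b" |
                                          params$condition != "PHE", ]),
                 "PHE")
  expect_setequal(fr2$retained, c("a", "c"))
})

test_that("planted non-responder fraction is recovered by the filter", {
  cfg <- smallTraceConfig(nPerRegion = c(CA1 = 100))
  sim <- simulateCalciumTraces(cfg, seed = 41)
  params <- transientParameters(sim$recordings)
  fr <- filterResponders(params)
  expect_equal(length(fr$retained), sum(sim$truth$responder))
  # 3-SE binomial band around the planted 80%
  se <- sqrt(0.2 * 0.8 / 100)
  expect_lt(abs(length(fr$retained) / 100 - 0.8), 3 * se)
})

test_that("physiology clustering recovers two planted regimes and is
           duplication-invariant", {
  cfg <- smallTraceConfig(nPerRegion = c(L1 = 25, CA1 = 25))
  sim <- simulateCalciumTraces(cfg, seed = 51)
  params <- transientParameters(sim$recordings)
  fr <- filterResponders(params)
  phe <- params[params$condition == "PHE" &
                  params$cell_id %in% fr$retained, ]
  cl <- clusterPhysiology(phe, kMax = 6)
  expect_equal(nClusters(cl), 2)
  lab <- clusterLabels(cl)
  region <- phe$region[match(names(lab), phe$cell_id)]
  tab <- table(lab, region)
  expect_gt(sum(apply(tab, 1, max)) / sum(tab), 0.9)

  # duplicating every cell keeps k and the label structure
  dup <- phe
  dup$cell_id <- paste0(dup$cell_id, "_dup")
  both <- rbind(phe, dup)
  cl2 <- clusterPhysiology(both, kMax = 6)
  expect_equal(nClusters(cl2), 2)
  lab2 <- clusterLabels(cl2)
  expect_equal(unname(lab2[names(lab)]), unname(lab2[paste0(names(lab),
                                                            "_dup")]))

  # constant columns are dropped with a warning, not an error
  const <- phe
  const$width <- 3
  expect_warning(clusterPhysiology(const, kMax = 6), "constant")
})

test_that("group comparisons gate normality, test KW and Dunn with BH", {
  set.seed(61)
  params <- data.frame(
    cell_id = sprintf("c%02d", 1:30),
    region = rep(c("L1", "L3-5", "CA1"), each = 10),
    condition = "PHE",
    amplitude = c(rnorm(10, 1.5, 0.1), rnorm(10, 3.5, 0.1),
                  rnorm(10, 6, 0.1)),
    prominence = rnorm(30, 2, 0.1), width = rnorm(30, 3, 0.1),
    peak_time = rnorm(30, 200, 5), frequency = rnorm(30, 0.05, 0.01),
    auc = rnorm(30, 100, 10))
  res <- compareGroups(params, "region",
                       parameters = c("amplitude", "width"))
  expect_equal(nrow(res$kruskal), 2)
  expect_equal(sum(res$dunn$parameter == "amplitude"), 3)
  amp <- res$dunn[res$dunn$parameter == "amplitude", ]
  expect_true(all(amp$p.adjusted >= amp$p.value - 1e-15))
  expect_true(all(amp$p.adjusted[order(amp$p.value)] ==
                    cummax(amp$p.adjusted[order(amp$p.value)])))
  expect_equal(nrow(res$normality), 6)
  # permuted identical groups: KW p near 1-ish (not significant)
  same <- params
  same$amplitude <- rep(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10), 3)
  res2 <- compareGroups(same, "region", parameters = "amplitude")
  expect_gt(res2$kruskal$p, 0.95)
  expect_true(all(res2$dunn$p.adjusted > 0.05))
  # a group with < 2 observations is skipped with a warning
  few <- params[c(1, 11, 12, 21, 22), ]
  expect_warning(res3 <- compareGroups(few, "region",
                                       parameters = "amplitude"),
                 "skipped")
  expect_null(res3$kruskal)
})
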