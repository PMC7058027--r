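makeSce <- function(counts, ...) {
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), ...)
}

test_that("QC floor keeps cells at or above the threshold and partitions", {
  m <- matrix(0L, nrow = 2, ncol = 3,
              dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  m[1, ] <- c(53L, 54L, 55L)
  sce <- makeSce(m)
  qc <- qcFilterCells(sce, minTotal = 54)
  expect_equal(qc$discarded, "a")
  expect_equal(colnames(qc$kept), c("b", "c"))
  expect_setequal(c(colnames(qc$kept), qc$discarded), colnames(sce))

  allZero <- makeSce(matrix(0L, 2, 3,
                            dimnames = list(c("g1", "g2"),
                                            c("a", "b", "c"))))
  expect_equal(length(qcFilterCells(allZero)$discarded), 3)
  expect_error(qcFilterCells(sce, minTotal = -1), "non-negative")
})

test_that("ln-normalization matches direct evaluation and its invariances", {
  m <- matrix(c(10L, 990L, 20L, 1980L), nrow = 2,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  norm <- lnNormalize(makeSce(m), scaleFactor = 1e4)
  ln <- SummarizedExperiment::assay(norm, "logcounts")
  # count 10 of total 1000 at scale 10000 -> ln(101)
  expect_equal(ln["g1", "a"], log(101), tolerance = 1e-12)
  # doubling all counts in a cell leaves its values unchanged
  expect_equal(ln[, "a"], ln[, "b"], tolerance = 1e-12)
  # zeros preserved
  m2 <- m; m2[1, 1] <- 0L
  ln2 <- SummarizedExperiment::assay(lnNormalize(makeSce(m2)), "logcounts")
  expect_identical(unname(ln2[1, 1]), 0)
  # zero-total cells are rejected with advice
  m3 <- m; m3[, 1] <- 0L
  expect_error(lnNormalize(makeSce(m3)), "qcFilterCells")
})

test_that("HVG selection applies strict thresholds and is monotone", {
  # three genes engineered around the (0.5, 0.5) astrocyte-pass cut:
  # a clear pass, the published near-miss (ln-mean 0.28, dispersion 0.41)
  # and a constant gene
  n <- 400
  ln <- rbind(
    pass = c(rep(3, n / 4), rep(0, 3 * n / 4)),
    near = c(rep(0.69, 162), rep(0, n - 162)),
    const = rep(2, n))
  stats <- data.frame(lnMean = rowMeans(ln),
                      disp = apply(ln, 1, var) / rowMeans(ln))
  expect_lt(abs(stats["near", "lnMean"] - 0.28), 0.01)
  expect_lt(abs(stats["near", "disp"] - 0.41), 0.02)

  sce <- makeSce(matrix(1L, nrow(ln), n,
                        dimnames = list(rownames(ln), NULL)))
  SummarizedExperiment::assay(sce, "logcounts") <- ln
  hvg <- selectHvg(sce, meanThr = 0.5, dispThr = 0.5)
  expect_true(hvg["pass", "selected"])
  expect_false(hvg["near", "selected"])   # fails both strict thresholds
  expect_false(hvg["const", "selected"])  # dispersion 0
  expect_equal(unname(hvg["const", "dispersion"]), 0)

  # threshold monotonicity: raising either threshold never adds genes
  h1 <- selectHvg(sce, 0.2, 0.2)
  h2 <- selectHvg(sce, 0.5, 0.2)
  h3 <- selectHvg(sce, 0.2, 0.5)
  expect_true(all(rownames(sce)[h2$selected] %in%
                    rownames(sce)[h1$selected]))
  expect_true(all(rownames(sce)[h3$selected] %in%
                    rownames(sce)[h1$selected]))
})

test_that("HVG selection recovers the planted count on generator output", {
  cfg <- smallConfig()
  sce <- simulateCounts(cfg, seed = 11)
  astro <- sce[, sce$trueType == "astrocyte"]
  hvg <- selectHvg(lnNormalize(astro), 0.5, 0.5)
  expect_equal(sum(hvg$selected), cfg@plantedHvgCount)
  expect_setequal(rownames(astro)[hvg$selected],
                  S4Vectors::metadata(sce)$plantedHvg)
})

test_that("clustering recovers planted blobs and flags no substructure", {
  set.seed(20)
  n <- 30
  ln <- cbind(matrix(rnorm(20 * n, 0, 0.1), 20),
              matrix(rnorm(20 * n, 4, 0.1), 20))
  ln[ln < 0] <- 0
  rownames(ln) <- paste0("g", 1:20)
  colnames(ln) <- paste0("c", seq_len(2 * n))
  sce <- makeSce(matrix(1L, 20, 2 * n, dimnames = dimnames(ln)))
  SummarizedExperiment::assay(sce, "logcounts") <- ln
  cl <- clusterCells(sce, paste0("g", 1:20), kMax = 6, nPcs = 5)
  expect_equal(nClusters(cl), 2)
  truth <- rep(1:2, each = n)
  tab <- table(clusterLabels(cl), truth)
  expect_equal(sum(apply(tab, 1, max)) / (2 * n), 1)

  # single blob: low silhouette flagged as no substructure
  one <- matrix(rnorm(20 * 100, 2, 0.5), 20,
                dimnames = list(paste0("g", 1:20), paste0("c", 1:100)))
  sce1 <- makeSce(matrix(1L, 20, 100, dimnames = dimnames(one)))
  SummarizedExperiment::assay(sce1, "logcounts") <- one
  cl1 <- clusterCells(sce1, paste0("g", 1:20), kMax = 5, nPcs = 5)
  expect_true(cl1@noSubstructure)

  expect_error(clusterCells(sce, character(0)), "2 selected")
})

test_that("higher-order typing scores panels and handles ties", {
  panels <- list(astrocyte = c("Slc1a3", "Aqp4"), neuron = c("Snap25"))
  ln <- rbind(Slc1a3 = c(3, 3, 0, 0), Aqp4 = c(2, 2, 0, 0),
              Snap25 = c(0, 0, 3, 3))
  colnames(ln) <- paste0("c", 1:4)
  sce <- makeSce(matrix(1L, 3, 4, dimnames = dimnames(ln)))
  SummarizedExperiment::assay(sce, "logcounts") <- ln
  cl <- new("ClusterResult", labels = setNames(c(1L, 1L, 2L, 2L),
                                               colnames(ln)),
            k = 2L, silhouetteByK = c(`2` = 0.9),
            noSubstructure = FALSE)
  ty <- assignHigherOrderTypes(sce, cl, panels)
  expect_equal(unname(ty[c("1", "2")]), c("astrocyte", "neuron"))
  expect_equal(colnames(extractTypedCells(sce, cl, ty, "astrocyte")),
               c("c1", "c2"))

  # all-zero cluster ties every panel -> warning, lexicographic winner
  ln0 <- ln; ln0[, 3:4] <- 0
  sce0 <- makeSce(matrix(1L, 3, 4, dimnames = dimnames(ln)))
  SummarizedExperiment::assay(sce0, "logcounts") <- ln0
  expect_warning(ty0 <- assignHigherOrderTypes(sce0, cl, panels), "tie")
  expect_equal(unname(ty0["2"]), "astrocyte")

  expect_error(assignHigherOrderTypes(sce, cl, list(x = "NoSuchGene")),
               "NoSuchGene")
})

test_that("marker calling implements the three criteria and the
           rank-sum p matches an exhaustive permutation oracle", {
  set.seed(30)
  nA <- 10; nB <- 10
  # distinct values, planted shift, no ties
  x <- sort(runif(nA, 1.5, 3)); y <- sort(runif(nB, 0, 1.4))
  marker <- c(x, y)
  offGene <- seq(0.1, 2, length.out = nA + nB)  # identical distribution
  ln <- rbind(planted = marker, flat = offGene)
  colnames(ln) <- paste0("c", seq_len(nA + nB))
  sce <- makeSce(matrix(1L, 2, nA + nB, dimnames = dimnames(ln)))
  SummarizedExperiment::assay(sce, "logcounts") <- ln
  cl <- new("ClusterResult",
            labels = setNames(rep(1:2, c(nA, nB)), colnames(ln)),
            k = 2L, silhouetteByK = c(`2` = 0.5), noSubstructure = FALSE)
  mk <- findClusterMarkers(sce, cl, cluster = 1)
  expect_true("planted" %in% mk$gene)
  expect_true(mk$passes[mk$gene == "planted"])

  # exhaustive permutation oracle for the rank-sum p value
  r <- rank(marker)
  obs <- sum(r[seq_len(nA)])
  combos <- utils::combn(nA + nB, nA)
  sums <- colSums(matrix(r[combos], nrow = nA))
  pLo <- mean(sums <= obs); pHi <- mean(sums >= obs)
  pOracle <- min(1, 2 * min(pLo, pHi))
  expect_equal(mk$p_value[mk$gene == "planted"], pOracle,
               tolerance = 1e-6)

  # gene expressed only in the cluster passes all three criteria
  ln2 <- rbind(exclusive = c(rep(2, nA), rep(0, nB)))
  colnames(ln2) <- colnames(ln)
  sce2 <- makeSce(matrix(1L, 1, nA + nB, dimnames = dimnames(ln2)))
  SummarizedExperiment::assay(sce2, "logcounts") <- ln2
  mk2 <- findClusterMarkers(sce2, cl, cluster = 1)
  expect_true(all(mk2$passes[mk2$gene == "exclusive"]))

  # lowering fold or pct thresholds never removes a passing marker
  mkLoose <- findClusterMarkers(sce, cl, cluster = 1, foldThr = 1,
                                pctThr = 0)
  expect_true(all(mk$gene[mk$passes] %in% mkLoose$gene[mkLoose$passes]))

  expect_error(findClusterMarkers(sce, cl, cluster = 9), "unknown")
})

test_that("subtype proportions sum to one and split by region", {
  labels <- c("AST1", "AST1", "AST2", "AST3")
  region <- c("CX", "HP", "CX", "CX")
  pr <- subtypeProportions(labels, region)
  expect_equal(sum(pr$fraction), 1, tolerance = 1e-12)
  expect_equal(pr$count[pr$subtype == "AST1"], 2)
  expect_equal(pr$count_HP[pr$subtype == "AST1"], 1)
  single <- subtypeProportions(rep("AST2", 5))
  expect_equal(single$fraction, 1)
})
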