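# Shared fixtures. Small configs keep the unit tests fast; the
# full-default simulations used by the acceptance-scale tests are built
# lazily and cached for the session.

smallConfig <- function(...) {
  astroSimConfig(nCells = 160, contaminantCounts = c(neuron = 10,
                                                     microglia = 8),
                 nLowQuality = 3, plantedHvgCount = 40, nGenes = 400, ...)
}

smallTraceConfig <- function(nPerRegion = c(L1 = 15, "L3-5" = 15,
                                            CA1 = 15), ...) {
  cfg <- smallConfig(...)
  tp <- cfg@traceParams
  tp$nCellsPerRegion <- nPerRegion
  cfg@traceParams <- tp
  cfg
}

# a CalciumRecording wrapping a raw fluorescence vector
makeRecording <- function(f, rate = 2, cellId = "c1", region = "L1",
                          condition = "PHE") {
  new("CalciumRecording", cellId = cellId, region = region,
      condition = condition, samplingRate = rate, fluorescence = f,
      duration = length(f) / rate)
}

# symmetric triangle dF/F0 pulse: rises 0 -> height over halfS seconds,
# falls back over halfS, embedded in a zero trace of total `totalS` s
triangleDff <- function(height = 2, halfS = 4, rate = 2, totalS = NULL,
                        startS = 0) {
  up <- seq(0, height, length.out = halfS * rate + 1)
  tri <- c(up, rev(up)[-1])
  if (is.null(totalS)) return(tri)
  n <- totalS * rate
  out <- numeric(n)
  i0 <- startS * rate + 1
  out[i0:(i0 + length(tri) - 1)] <- tri
  out
}

.fixtureCache <- new.env(parent = emptyenv())

fullFixture <- function() {
  if (!is.null(.fixtureCache$full)) return(.fixtureCache$full)
  cfg <- astroSimConfig()
  sce <- simulateCounts(cfg, seed = 101)
  qc <- qcFilterCells(sce)
  norm <- lnNormalize(qc$kept)
  hvgAll <- selectHvg(norm, meanThr = 0.3, dispThr = 0.1)
  clAll <- clusterCells(norm, hvgAll)
  types <- assignHigherOrderTypes(norm, clAll)
  astro <- lnNormalize(extractTypedCells(norm, clAll, types))
  .fixtureCache$full <- list(cfg = cfg, sce = sce, qc = qc, norm = norm,
                             hvgAll = hvgAll, clAll = clAll,
                             types = types, astro = astro)
  .fixtureCache$full
}
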