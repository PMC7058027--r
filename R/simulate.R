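# Synthetic-data generators with planted ground truth. The defaults encode
# the study conditions: 2031 single-cell libraries of which 16 fall below
# the 54-transcript QC floor and 204 are contaminating higher-order cell
# types, leaving 1811 astrocytes in five subtypes at the published
# frequency profile (AST1 36.5% ... AST5 1.4%); 886 genes planted above
# both astrocyte-pass HVG thresholds; ISH sections with cortical layers and
# hippocampal strata; and three-condition calcium recordings with
# region-specific transient regimes and a non-responder fraction.

# Subtype combinations over which planted highly-variable genes are "high".
# Every combination covers between 25% and 74% of astrocytes under the
# default frequency profile, which keeps the expected ln-mean and
# dispersion of a planted gene at least 20% above the (0.5, 0.5)
# astrocyte-pass selection thresholds, while subtype-private markers of the
# rare subtypes (AST4, AST5) fall well below the ln-mean threshold.
.sigPatterns <- list(
  1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L), c(2L, 4L), c(3L, 4L),
  c(1L, 4L), c(3L, 5L), c(2L, 5L), c(1L, 5L), c(2L, 3L, 4L),
  c(1L, 4L, 5L), c(2L, 3L, 5L), c(1L, 2L, 4L), c(3L, 4L, 5L),
  c(1L, 3L, 4L)
)

#' Default atlas-style ISH layout
#'
#' A schematic coronal layout: five cortical layers stacked above six
#' hippocampal strata, as non-overlapping rectangles (micrometres, origin
#' top-left, y down), with per-region nucleus counts and per-region
#' subtype frequencies qualitatively following the published maps (AST4
#' concentrated in the subgranular zone, AST1 dominant subpially and in
#' stratum lacunosum-moleculare, AST2 restricted to mid-cortical layers).
#'
#' @return list with elements \code{regions} (polygon vertex table),
#'   \code{nNuclei} (named integer) and \code{regionFreqs} (region x
#'   subtype frequency matrix, rows summing to 1).
#' @export
ishLayoutDefault <- function() {
  rect <- function(region, x0, x1, y0, y1)
    data.frame(region = region, vertex_index = 1:4,
               x_um = c(x0, x0, x1, x1), y_um = c(y0, y1, y1, y0))
  bands <- list(
    c("L1", 0, 150), c("L2/3", 155, 400), c("L4", 405, 550),
    c("L5", 555, 750), c("L6", 755, 950),
    c("SO", 1000, 1100), c("SP", 1105, 1165), c("SR", 1170, 1400),
    c("SLM", 1405, 1550), c("SG", 1555, 1625), c("DG", 1630, 1800))
  regions <- do.call(rbind, lapply(bands, function(b)
    rect(b[1], 0, 2000, as.numeric(b[2]), as.numeric(b[3]))))
  nNuclei <- c(L1 = 60, "L2/3" = 110, L4 = 70, L5 = 90, L6 = 90,
               SO = 45, SP = 25, SR = 100, SLM = 60, SG = 40, DG = 70)
  freqs <- rbind(
    L1     = c(0.60, 0.05, 0.25, 0.00, 0.10),
    "L2/3" = c(0.10, 0.40, 0.35, 0.00, 0.15),
    L4     = c(0.05, 0.30, 0.55, 0.00, 0.10),
    L5     = c(0.05, 0.40, 0.40, 0.00, 0.15),
    L6     = c(0.05, 0.15, 0.75, 0.00, 0.05),
    SO     = c(0.45, 0.02, 0.50, 0.00, 0.03),
    SP     = c(0.40, 0.02, 0.55, 0.00, 0.03),
    SR     = c(0.45, 0.02, 0.50, 0.00, 0.03),
    SLM    = c(0.60, 0.02, 0.25, 0.00, 0.13),
    SG     = c(0.10, 0.00, 0.10, 0.75, 0.05),
    DG     = c(0.30, 0.00, 0.45, 0.05, 0.20))
  colnames(freqs) <- paste0("AST", 1:5)
  list(regions = regions, nNuclei = nNuclei, regionFreqs = freqs)
}

#' Single-region ISH layout with a shared subtype profile
#'
#' A convenience layout with one square region populated at the given
#' subtype frequencies; used to emulate a population draw at the global
#' subtype proportions (for instance to round-trip the published subtype
#' percentages through the puncta-counting and rule classifier).
#'
#' @param nNuclei number of nuclei to place.
#' @param freqs named subtype frequency vector (default: the global
#'   profile of \code{\link{astroSimConfig}}).
#' @param sideUm side length of the square region in micrometres; the
#'   default keeps nuclear density low enough that cell disks rarely touch.
#' @param region region name.
#' @return layout list as in \code{\link{ishLayoutDefault}}.
#' @export
ishLayoutUniform <- function(nNuclei = 1811,
                             freqs = c(AST1 = 0.365, AST2 = 0.25,
                                       AST3 = 0.30, AST4 = 0.071,
                                       AST5 = 0.014),
                             sideUm = 4000, region = "CX") {
  regions <- data.frame(region = region, vertex_index = 1:4,
                        x_um = c(0, 0, sideUm, sideUm),
                        y_um = c(0, sideUm, sideUm, 0))
  fr <- matrix(freqs, nrow = 1, dimnames = list(region, names(freqs)))
  list(regions = regions, nNuclei = setNames(as.integer(nNuclei), region),
       regionFreqs = fr)
}

.defaultTraceParams <- function() {
  regime <- function(rate, amp, tau, delay = 0)
    list(rate = rate, ampMean = amp, ampSd = 0.15, tauS = tau,
         delayS = delay)
  # cell-level random effects (fractional SDs): cell-to-cell
  # heterogeneity of mean amplitude, decay constant and event rate
  # within a regime, giving continuous unimodal parameter spreads
  list(
    samplingRateHz = 2, durationS = 300, f0 = 100, noiseSd = 0.02,
    riseS = 0, nonResponderFraction = 0.2, quietBaseline = TRUE,
    cellAmpSd = 0.08, cellTauSd = 0.08, cellRateSd = 0.08,
    nCellsPerRegion = c(L1 = 200, "L3-5" = 200, CA1 = 214),
    regimes = list(
      L1 = list(BASE = regime(0.010, 1.8, 5), TTX = regime(0.004, 1.6, 5),
                PHE = regime(0.035, 1.5, 3.5, 0)),
      "L3-5" = list(BASE = regime(0.008, 1.7, 6),
                    TTX = regime(0.003, 1.6, 6),
                    PHE = regime(0.055, 3.5, 6.0, 30)),
      CA1 = list(BASE = regime(0.012, 1.9, 7), TTX = regime(0.005, 1.7, 7),
                 PHE = regime(0.085, 6.0, 4.5, 60))
    )
  )
}

#' Construct a synthetic-data generator configuration
#'
#' Builds an \code{\linkS4class{AstroSimConfig}} whose defaults encode the
#' study conditions; see the class documentation for slot meanings. The
#' defaults give 2031 libraries = 1811 astrocytes + 204 contaminants + 16
#' planted low-quality cells, subtype frequencies AST1 0.365, AST2 0.25,
#' AST3 0.30, AST4 0.071, AST5 0.014 (the AST1/AST5 extremes are the
#' published values; the middle three are unpublished fills), and 886
#' planted highly-variable genes.
#'
#' @param nCells total libraries.
#' @param subtypeFreqs named astrocyte subtype frequencies summing to 1.
#' @param contaminantCounts named integer vector of planted contaminant
#'   cells per higher-order type.
#' @param nLowQuality number of libraries thinned below the QC floor.
#' @param fingerprint subtype x gene "high"/"low" matrix; must cover every
#'   gene referenced by the rule table.
#' @param nbParams negative-binomial (mu, size) per expression-level class.
#' @param plantedHvgCount number of genes planted above both HVG
#'   thresholds (>= 3: the fingerprint markers Gfap, Agt and Unc13c are
#'   always part of the planted set).
#' @param nGenes total genes (>= plantedHvgCount + 100).
#' @param ishLayout ISH layout list (see \code{\link{ishLayoutDefault}}).
#' @param punctaParams Poisson means for "+"/"-" marker states, background
#'   puncta rate per square micrometre, and intensity distributions.
#' @param traceParams calcium-trace regime parameters.
#' @return a validated \code{AstroSimConfig}.
#' @export
#' @examples
#' cfg <- astroSimConfig(nCells = 120, contaminantCounts = c(neuron = 10),
#'                       nLowQuality = 2, plantedHvgCount = 40,
#'                       nGenes = 400)
#' cfg
astroSimConfig <- function(
    nCells = 2031,
    subtypeFreqs = c(AST1 = 0.365, AST2 = 0.25, AST3 = 0.30,
                     AST4 = 0.071, AST5 = 0.014),
    contaminantCounts = c(oligodendrocyte = 60, OPC = 30, microglia = 50,
                          endothelial = 30, neuron = 34),
    nLowQuality = 16,
    fingerprint = defaultFingerprint(),
    nbParams = list(hi = list(mu = 80, size = 4),
                    lo = list(mu = 0.05, size = 2),
                    housekeeping = list(mu = 20, size = 20)),
    plantedHvgCount = 886,
    nGenes = 3000,
    ishLayout = ishLayoutDefault(),
    punctaParams = list(lambdaPlus = 12, lambdaMinus = 0.3,
                        backgroundPerUm2 = 1e-4, areaScale = 1.3,
                        intensityTrue = c(mean = 150, sd = 20),
                        intensityBackground = c(mean = 60, sd = 15)),
    traceParams = .defaultTraceParams()) {
  if (plantedHvgCount < 3)
    stop("plantedHvgCount must be >= 3 (the planted set always contains ",
         "the variable fingerprint markers Gfap, Agt and Unc13c)")
  if (nGenes < plantedHvgCount + 100)
    stop("nGenes must be at least plantedHvgCount + 100")
  ruleGenes <- unique(unlist(lapply(subtypeRules()@rules, function(r)
    c(names(r$requires), unlist(lapply(r$split, names))))))
  missing <- setdiff(ruleGenes, colnames(fingerprint))
  if (length(missing))
    stop("fingerprint does not cover rule-table gene(s): ",
         paste(missing, collapse = ", "))
  new("AstroSimConfig",
      nCells = as.integer(nCells),
      subtypeFreqs = subtypeFreqs,
      contaminantCounts = setNames(as.integer(contaminantCounts),
                                   names(contaminantCounts)),
      nLowQuality = as.integer(nLowQuality),
      fingerprint = fingerprint,
      nbParams = nbParams,
      plantedHvgCount = as.integer(plantedHvgCount),
      nGenes = as.integer(nGenes),
      ishLayout = ishLayout,
      punctaParams = punctaParams,
      traceParams = traceParams)
}

# Gene model: per-gene expression-level class for every simulated cell
# type. Returns gene names, per-type NB mean and size matrices, and the
# planted-HVG gene set.
.geneModel <- function(config) {
  subtypes <- names(config@subtypeFreqs)
  contamTypes <- names(config@contaminantCounts)
  types <- c(subtypes, contamTypes)
  nb <- config@nbParams
  fp <- config@fingerprint

  panels <- higherOrderPanels()
  markerGenes <- colnames(fp)
  nSig <- config@plantedHvgCount - 3L
  sigGenes <- sprintf("sig%04d", seq_len(nSig))
  panExtra <- setdiff(panels$astrocyte, markerGenes)
  contamGenes <- unlist(panels[setdiff(names(panels), "astrocyte")],
                        use.names = FALSE)
  nFixed <- length(markerGenes) + length(sigGenes) + length(panExtra) +
    length(contamGenes)
  nHk <- max(50L, as.integer(round(0.27 * config@nGenes)))
  nBg <- config@nGenes - nFixed - nHk
  if (nBg < 0) stop("nGenes too small for the requested gene model")
  hkGenes <- sprintf("hk%04d", seq_len(nHk))
  bgGenes <- if (nBg) sprintf("bg%04d", seq_len(nBg)) else character(0)
  genes <- c(markerGenes, sigGenes, panExtra, contamGenes, hkGenes, bgGenes)

  mu <- matrix(nb$lo$mu, nrow = length(genes), ncol = length(types),
               dimnames = list(genes, types))
  size <- matrix(nb$lo$size, nrow = length(genes), ncol = length(types),
                 dimnames = list(genes, types))
  setLevel <- function(g, t, level) {
    mu[g, t] <<- nb[[level]]$mu
    size[g, t] <<- nb[[level]]$size
  }
  # fingerprint markers follow the subtype table; Slc1a3 doubles as a
  # pan-astrocyte gene and stays off in contaminants
  for (g in markerGenes)
    for (s in subtypes)
      if (fp[s, g] == "high") setLevel(g, s, "hi")
  # planted signature genes cycle through the pattern pool
  pat <- .sigPatterns[((seq_len(nSig) - 1L) %% length(.sigPatterns)) + 1L]
  for (i in seq_len(nSig)) {
    sel <- pat[[i]][pat[[i]] <= length(subtypes)]
    if (length(sel)) setLevel(sigGenes[i], subtypes[sel], "hi")
  }
  # remaining pan-astrocyte panel genes: high in every subtype
  for (g in panExtra) setLevel(g, subtypes, "hi")
  # contaminant panel genes: high only in their own type
  for (ct in setdiff(names(panels), "astrocyte"))
    if (ct %in% contamTypes) setLevel(panels[[ct]], ct, "hi")
  # housekeeping: moderate stable expression in every cell type
  mu[hkGenes, ] <- nb$housekeeping$mu
  size[hkGenes, ] <- nb$housekeeping$size

  planted <- c("Gfap", "Agt", "Unc13c", sigGenes)
  list(genes = genes, mu = mu, size = size, plantedHvg = planted,
       types = types, subtypes = subtypes, contamTypes = contamTypes)
}

# Largest-remainder rounding of fractions to integer counts summing to n.
.apportion <- function(n, freqs) {
  raw <- n * freqs
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(freqs))
}

#' Simulate a single-cell count matrix with planted ground truth
#'
#' Draws a genes x cells negative-binomial count matrix. Cell composition
#' is planted exactly: \code{nCells - sum(contaminantCounts) - nLowQuality}
#' astrocytes whose subtype labels are drawn at \code{subtypeFreqs},
#' \code{contaminantCounts} cells per contaminating higher-order type, and
#' \code{nLowQuality} libraries thinned to a total below the QC floor.
#' Exactly \code{plantedHvgCount} genes are constructed to exceed both
#' astrocyte-pass HVG selection thresholds in expectation with at least a
#' 20% margin, every other gene failing at least one threshold by a
#' comparable margin, so downstream selection recovers the planted count.
#'
#' @param config an \code{\link{astroSimConfig}}.
#' @param seed integer seed; the output is deterministic given
#'   (config, seed). The caller's RNG state is preserved.
#' @return a \code{SingleCellExperiment} with assay \code{"counts"},
#'   colData columns \code{region}, \code{batch}, \code{trueType}
#'   (higher-order type or \code{"lowQuality"}) and \code{trueSubtype}
#'   (AST1-5 for astrocytes, \code{NA} otherwise), and metadata entries
#'   \code{plantedHvg} (gene names) and \code{simConfig}.
#' @export
#' @examples
#' cfg <- astroSimConfig(nCells = 150, contaminantCounts = c(neuron = 10),
#'                       nLowQuality = 2, plantedHvgCount = 40,
#'                       nGenes = 400)
#' sce <- simulateCounts(cfg, seed = 1)
#' table(sce$trueType)
simulateCounts <- function(config, seed = NULL) {
  stopifnot(is(config, "AstroSimConfig"))
  .withSeed(seed, {
    gm <- .geneModel(config)
    nContam <- sum(config@contaminantCounts)
    nAstro <- config@nCells - nContam - config@nLowQuality
    if (nAstro < 1) stop("nCells leaves no astrocytes after planting")

    subLabels <- sample(gm$subtypes, nAstro + config@nLowQuality,
                        replace = TRUE, prob = config@subtypeFreqs)
    typeLabels <- c(subLabels[seq_len(nAstro)],
                    rep(gm$contamTypes, config@contaminantCounts),
                    subLabels[nAstro + seq_len(config@nLowQuality)])
    higher <- c(rep("astrocyte", nAstro),
                rep(gm$contamTypes, config@contaminantCounts),
                rep("lowQuality", config@nLowQuality))
    ord <- sample(length(typeLabels))
    typeLabels <- typeLabels[ord]
    higher <- higher[ord]

    idx <- match(typeLabels, gm$types)
    n <- length(gm$genes) * length(typeLabels)
    counts <- matrix(
      rnbinom(n, mu = as.vector(gm$mu[, idx]),
              size = as.vector(gm$size[, idx])),
      nrow = length(gm$genes),
      dimnames = list(gm$genes,
                      sprintf("cell%04d", seq_along(typeLabels))))
    storage.mode(counts) <- "integer"


    # thin planted low-quality libraries below the 54-transcript floor
    lowIdx <- which(higher == "lowQuality")
    for (j in lowIdx) {
      target <- sample(10:40, 1)
      tot <- sum(counts[, j])
      counts[, j] <- if (tot > 0)
        as.integer(rmultinom(1, min(target, tot), counts[, j]))
      else counts[, j]
    }

    subtype <- ifelse(higher == "astrocyte", typeLabels, NA_character_)
    pHip <- c(AST1 = 0.5, AST2 = 0.1, AST3 = 0.5, AST4 = 0.9,
              AST5 = 0.5)[typeLabels]
    pHip[is.na(pHip)] <- 0.5
    region <- ifelse(runif(length(typeLabels)) < pHip, "HP", "CX")
    batch <- sample(c("b1", "b2"), length(typeLabels), replace = TRUE)

    SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = counts),
      colData = S4Vectors::DataFrame(
        region = region, batch = batch,
        trueType = ifelse(higher == "lowQuality", "lowQuality",
                          ifelse(higher == "astrocyte", "astrocyte",
                                 typeLabels)),
        trueSubtype = subtype,
        row.names = colnames(counts)),
      metadata = list(plantedHvg = gm$plantedHvg, simConfig = config))
  })
}

#' Simulate a multiplexed ISH section
#'
#' Places nuclei uniformly within each region polygon of the layout,
#' assigns each nucleus a true subtype from the region's frequency profile,
#' and draws per-channel puncta: Poisson counts with mean
#' \code{lambdaPlus} for fingerprint-"high" markers and \code{lambdaMinus}
#' otherwise, positions uniform within the cell disk (nuclear area scaled
#' by \code{areaScale}), intensities from the true-signal distribution;
#' plus uniform background puncta at \code{backgroundPerUm2} over the
#' section bounding box with lower intensities.
#'
#' @param config an \code{\link{astroSimConfig}}; the layout is taken from
#'   \code{config@ishLayout} unless overridden.
#' @param seed integer seed (deterministic output; caller RNG preserved).
#' @param layout optional layout list overriding the config's.
#' @param sectionId,animalId identifiers stored in the section.
#' @return list with \code{section} (an \code{\linkS4class{IshSection}})
#'   and \code{truth} (data.frame cell_id, region, subtype).
#' @export
simulateIshSection <- function(config, seed = NULL,
                               layout = config@ishLayout,
                               sectionId = "S1", animalId = "A1") {
  stopifnot(is(config, "AstroSimConfig"))
  if (!nrow(layout$regions)) stop("ish layout has no regions")
  if (.regionsOverlap(layout$regions))
    stop("ish layout region polygons overlap")
  .withSeed(seed, {
    fp <- config@fingerprint
    pp <- config@punctaParams
    channels <- colnames(fp)
    nucList <- list(); truthList <- list()
    for (r in names(layout$nNuclei)) {
      nr <- layout$nNuclei[[r]]
      if (nr == 0) next
      sub <- layout$regions[layout$regions$region == r, ]
      sub <- sub[order(sub$vertex_index), ]
      pos <- .runifPolygon(nr, sub$x_um, sub$y_um)
      st <- sample(colnames(layout$regionFreqs), nr, replace = TRUE,
                   prob = layout$regionFreqs[r, ])
      nucList[[r]] <- data.frame(x_um = pos$x, y_um = pos$y,
                                 area_um2 = rlnorm(nr, log(50), 0.15))
      truthList[[r]] <- data.frame(region = r, subtype = st)
    }
    nuclei <- do.call(rbind, nucList)
    truth <- do.call(rbind, truthList)
    if (is.null(nuclei)) {
      nuclei <- data.frame(cell_id = integer(0), x_um = numeric(0),
                           y_um = numeric(0), area_um2 = numeric(0))
      truth <- data.frame(cell_id = integer(0), region = character(0),
                          subtype = character(0))
    } else {
      nuclei <- data.frame(cell_id = seq_len(nrow(nuclei)), nuclei,
                           row.names = NULL)
      truth <- data.frame(cell_id = nuclei$cell_id, truth,
                          row.names = NULL)
    }

    radius <- sqrt(pp$areaScale * nuclei$area_um2 / pi)
    punctaList <- list()
    for (g in channels) {
      lam <- ifelse(fp[truth$subtype, g] == "high",
                    pp$lambdaPlus, pp$lambdaMinus)
      counts <- if (nrow(nuclei)) rpois(nrow(nuclei), lam) else integer(0)
      tot <- sum(counts)
      if (tot > 0) {
        ci <- rep(seq_len(nrow(nuclei)), counts)
        rr <- radius[ci] * sqrt(runif(tot))
        th <- runif(tot, 0, 2 * pi)
        punctaList[[paste0(g, ".t")]] <- data.frame(
          gene = g, x_um = nuclei$x_um[ci] + rr * cos(th),
          y_um = nuclei$y_um[ci] + rr * sin(th),
          intensity = pmax(0, rnorm(tot, pp$intensityTrue["mean"],
                                    pp$intensityTrue["sd"])))
      }
      # uniform background over the section bounding box
      bbox <- layout$regions
      w <- diff(range(bbox$x_um)); h <- diff(range(bbox$y_um))
      nbg <- rpois(1, pp$backgroundPerUm2 * w * h)
      if (nbg > 0)
        punctaList[[paste0(g, ".b")]] <- data.frame(
          gene = g,
          x_um = runif(nbg, min(bbox$x_um), max(bbox$x_um)),
          y_um = runif(nbg, min(bbox$y_um), max(bbox$y_um)),
          intensity = pmax(0, rnorm(nbg, pp$intensityBackground["mean"],
                                    pp$intensityBackground["sd"])))
    }
    puncta <- if (length(punctaList)) do.call(rbind, punctaList) else
      data.frame(gene = character(0), x_um = numeric(0),
                 y_um = numeric(0), intensity = numeric(0))
    rownames(puncta) <- NULL

    section <- new("IshSection", sectionId = sectionId,
                   animalId = animalId, regions = layout$regions,
                   nuclei = nuclei, puncta = puncta)
    list(section = section, truth = truth)
  })
}

# One transient train: onset times, amplitudes; returns the dF/F0-scale
# signal s(t) with instant (or linear riseS) rise and exponential decay.
.eventSignal <- function(t, onsets, amps, tauS, riseS) {
  s <- numeric(length(t))
  for (i in seq_along(onsets)) {
    dt <- t - onsets[i]
    if (riseS > 0) {
      up <- dt >= 0 & dt < riseS
      s[up] <- s[up] + amps[i] * dt[up] / riseS
      dec <- dt >= riseS
      s[dec] <- s[dec] + amps[i] * exp(-(dt[dec] - riseS) / tauS)
    } else {
      dec <- dt >= 0
      s[dec] <- s[dec] + amps[i] * exp(-dt[dec] / tauS)
    }
  }
  s
}

#' Simulate three-condition calcium recordings
#'
#' For each cell (region counts from \code{traceParams$nCellsPerRegion})
#' and each condition BASE, TTX, PHE, draws transient onsets at the
#' region-and-condition event rate, amplitudes from a normal distribution,
#' and builds the trace \code{F0 * (1 + sum(events)) + noise} with
#' instant-rise/exponential-decay events. A planted fraction of cells
#' (\code{nonResponderFraction}) has zero PHE events. With
#' \code{quietBaseline = TRUE} (default) onsets are restricted to times
#' after the 100 s baseline window, so F0 estimation is unbiased.
#'
#' @param config an \code{\link{astroSimConfig}}.
#' @param seed integer seed (deterministic output; caller RNG preserved).
#' @return list with \code{recordings} (list of
#'   \code{\linkS4class{CalciumRecording}}) and \code{truth} (data.frame
#'   cell_id, region, responder, nEvents per condition).
#' @export
simulateCalciumTraces <- function(config, seed = NULL) {
  stopifnot(is(config, "AstroSimConfig"))
  tp <- config@traceParams
  if (tp$durationS < 100)
    stop("trace duration must be >= 100 s: the baseline window is the ",
         "first 100 s of each recording")
  .withSeed(seed, {
    rate <- tp$samplingRateHz
    nSamp <- round(tp$durationS * rate)
    t <- (seq_len(nSamp) - 1) / rate
    t0 <- if (isTRUE(tp$quietBaseline)) 100 else 0
    recordings <- list(); truthRows <- list(); cellN <- 0L
    for (r in names(tp$nCellsPerRegion)) {
      for (i in seq_len(tp$nCellsPerRegion[[r]])) {
        cellN <- cellN + 1L
        id <- sprintf("cell%04d", cellN)
        nonResp <- runif(1) < tp$nonResponderFraction
        nEv <- c(BASE = NA, TTX = NA, PHE = NA)
        ampRe <- 1 + rnorm(1, 0, tp$cellAmpSd %||% 0)
        tauRe <- 1 + rnorm(1, 0, tp$cellTauSd %||% 0)
        rateRe <- 1 + rnorm(1, 0, tp$cellRateSd %||% 0)
        for (cond in c("BASE", "TTX", "PHE")) {
          rg <- tp$regimes[[r]][[cond]]
          winStart <- t0 + (rg$delayS %||% 0)
          nEvents <- if (cond == "PHE" && nonResp) 0L else
            rpois(1, max(rg$rate * rateRe, 0) * (tp$durationS - winStart))
          # random onsets with a refractory gap: uniform times subject to
          # a minimal inter-event spacing of ~2.5 decay constants, so
          # events do not pile on each other's decaying shoulder
          W <- tp$durationS - winStart
          tauCell <- rg$tauS * max(tauRe, 0.2)
          gap <- min(2.5 * tauCell, 0.8 * W / max(nEvents, 1L))
          span <- W - (nEvents - 1) * gap
          onsets <- winStart + sort(runif(nEvents, 0, max(span, 0))) +
            (seq_len(nEvents) - 1) * gap
          amps <- pmax(0.2, rnorm(nEvents, rg$ampMean * max(ampRe, 0.2),
                                  rg$ampSd))
          s <- .eventSignal(t, onsets, amps,
                            rg$tauS * max(tauRe, 0.2), tp$riseS)
          f <- tp$f0 * (1 + s) +
            rnorm(nSamp, 0, tp$noiseSd * tp$f0)
          recordings[[length(recordings) + 1L]] <- new(
            "CalciumRecording", cellId = id, region = r,
            condition = cond, samplingRate = rate, fluorescence = f,
            duration = tp$durationS)
          nEv[cond] <- nEvents
        }
        truthRows[[cellN]] <- data.frame(
          cell_id = id, region = r, responder = !nonResp,
          nBase = nEv["BASE"], nTtx = nEv["TTX"], nPhe = nEv["PHE"],
          row.names = NULL)
      }
    }
    list(recordings = recordings, truth = do.call(rbind, truthRows))
  })
}
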