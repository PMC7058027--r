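#' @import methods
#' @importFrom stats var sd setNames p.adjust pnorm pchisq kruskal.test
#'   shapiro.test wilcox.test prcomp dist hclust cutree rnbinom rpois rnorm
#'   runif rmultinom rlnorm rexp quantile aggregate median
#' @importFrom utils head read.csv write.csv read.delim write.table
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' Clustering result with silhouette-based model selection
#'
#' Holds the cluster labels chosen by maximising the mean silhouette width
#' over a scanned range of cluster numbers, together with the full
#' silhouette profile so the selection can be inspected.
#'
#' @slot labels integer vector of cluster assignments, one per observation
#'   (named when the observations are named).
#' @slot k integer, the selected number of clusters.
#' @slot silhouetteByK named numeric vector, mean silhouette width for each
#'   scanned k (names are the k values).
#' @slot noSubstructure logical; \code{TRUE} when the best mean silhouette
#'   fell below the no-substructure floor (see \code{\link{clusterCells}}).
#'
#' @seealso \code{\link{silhouetteSelectK}}, \code{\link{clusterCells}},
#'   \code{\link{clusterPhysiology}}
#' @export
setClass("ClusterResult",
  slots = c(
    labels = "integer",
    k = "integer",
    silhouetteByK = "numeric",
    noSubstructure = "logical"
  )
)

setValidity("ClusterResult", function(object) {
  msg <- NULL
  if (length(object@k) != 1L) msg <- c(msg, "'k' must be length 1")
  if (length(object@labels) &&
      length(unique(object@labels)) != object@k)
    msg <- c(msg, "'k' must equal the number of distinct labels")
  if (length(object@silhouetteByK)) {
    best <- as.integer(names(object@silhouetteByK))[
      which.max(object@silhouetteByK)]
    if (length(object@labels) && best != object@k)
      msg <- c(msg, "'k' must be the argmax of silhouetteByK")
  }
  if (is.null(msg)) TRUE else msg
})

#' Multiplexed ISH section
#'
#' A quantified in situ hybridization section: named region polygons
#' (micrometre coordinates, origin top-left, y increasing downward), nuclei
#' (DAPI centroids and areas) and per-channel puncta with intensities.
#'
#' @slot sectionId,animalId single character identifiers.
#' @slot regions data.frame with columns \code{region}, \code{vertex_index},
#'   \code{x_um}, \code{y_um}; one closed simple polygon per region name,
#'   vertices ordered counter-clockwise, regions mutually non-overlapping.
#' @slot nuclei data.frame with columns \code{cell_id}, \code{x_um},
#'   \code{y_um}, \code{area_um2}; areas strictly positive.
#' @slot puncta data.frame with columns \code{gene}, \code{x_um},
#'   \code{y_um}, \code{intensity}; intensities non-negative.
#'
#' @seealso \code{\link{readIshSection}}, \code{\link{simulateIshSection}},
#'   \code{\link{classifyCells}}
#' @export
setClass("IshSection",
  slots = c(
    sectionId = "character",
    animalId = "character",
    regions = "data.frame",
    nuclei = "data.frame",
    puncta = "data.frame"
  )
)

setValidity("IshSection", function(object) {
  msg <- NULL
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      sprintf("%s is missing column(s): %s", what,
              paste(miss, collapse = ", "))
    else NULL
  }
  msg <- c(msg,
    need(object@regions, c("region", "vertex_index", "x_um", "y_um"),
         "regions"),
    need(object@nuclei, c("cell_id", "x_um", "y_um", "area_um2"), "nuclei"),
    need(object@puncta, c("gene", "x_um", "y_um", "intensity"), "puncta"))
  if (is.null(msg)) {
    if (nrow(object@nuclei) && any(object@nuclei$area_um2 <= 0))
      msg <- c(msg, "nuclear areas must be strictly positive")
    if (nrow(object@puncta) && any(object@puncta$intensity < 0))
      msg <- c(msg, "puncta intensities must be non-negative")
    if (nrow(object@nuclei) && anyDuplicated(object@nuclei$cell_id))
      msg <- c(msg, "nucleus cell_ids must be unique")
    if (nrow(object@regions) && .regionsOverlap(object@regions))
      msg <- c(msg, "region polygons must not overlap")
  }
  if (is.null(msg)) TRUE else msg
})

#' Marker requirement table for rule-based subtype classification
#'
#' An ordered set of subtype rules, each a set of per-gene requirements
#' ("+" the marker must be called present at high level, "-" it must be
#' called absent/low). Rules are evaluated in table order and the first
#' fully satisfied rule wins. One rule clause may be declared a split-panel
#' alternative (used for subtypes mapped with two complementary probe
#' panels): its requirements are grouped by panel and a cell satisfies the
#' clause when the requirements of the staining panel in use hold.
#'
#' @slot rules named list (in evaluation order); each element is a list with
#'   \code{requires} (named character vector of "+"/"-" per gene) and
#'   optionally \code{split} (named list panel -> named requirement vector).
#'
#' @seealso \code{\link{subtypeRules}}, \code{\link{classifySubtype}}
#' @export
setClass("SubtypeRuleTable", slots = c(rules = "list"))

setValidity("SubtypeRuleTable", function(object) {
  msg <- NULL
  if (is.null(names(object@rules)) || any(names(object@rules) == ""))
    msg <- c(msg, "rules must be a named list")
  for (nm in names(object@rules)) {
    r <- object@rules[[nm]]
    if (!is.list(r) || is.null(r$requires))
      msg <- c(msg, sprintf("rule '%s' lacks a 'requires' vector", nm))
    else if (!all(r$requires %in% c("+", "-")))
      msg <- c(msg, sprintf("rule '%s': requirements must be '+' or '-'", nm))
    if (!is.null(r$split)) {
      for (p in names(r$split))
        if (!all(r$split[[p]] %in% c("+", "-")))
          msg <- c(msg, sprintf("rule '%s' split panel '%s': bad calls",
                                nm, p))
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Single calcium imaging recording
#'
#' One cell's fluorescence time series under one pharmacological condition.
#' Conditions follow the BASE (spontaneous activity), TTX (neuronal firing
#' blocked) and PHE (phenylephrine on top of TTX) ladder; regions are
#' cortical layer 1 (L1), cortical layers 3-5 (L3-5) and hippocampal CA1.
#'
#' @slot cellId,region,condition single character values.
#' @slot samplingRate sampling frequency in Hz (the study acquired at
#'   1.8-4 Hz; any positive rate is accepted).
#' @slot fluorescence numeric vector of raw fluorescence, arbitrary units.
#' @slot duration recording duration in seconds; must be at least 100 s so
#'   the baseline window exists.
#'
#' @seealso \code{\link{computeDff}}, \code{\link{detectTransients}},
#'   \code{\link{readTraces}}
#' @export
setClass("CalciumRecording",
  slots = c(
    cellId = "character",
    region = "character",
    condition = "character",
    samplingRate = "numeric",
    fluorescence = "numeric",
    duration = "numeric"
  )
)

setValidity("CalciumRecording", function(object) {
  msg <- NULL
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be > 0")
  if (object@duration < 100)
    msg <- c(msg, "duration must be >= 100 s (baseline window undefined)")
  if (length(object@fluorescence) !=
      round(object@duration * object@samplingRate))
    msg <- c(msg, "series length must equal round(duration * samplingRate)")
  if (is.null(msg)) TRUE else msg
})

#' Configuration of the synthetic-data generator
#'
#' Bundles every tunable of the three generators (expression, ISH sections,
#' calcium traces). Construct with \code{\link{astroSimConfig}}, which
#' supplies defaults encoding the study conditions (subtype frequency
#' profile, marker fingerprint, planted highly-variable-gene structure,
#' three-condition trace regimes).
#'
#' @slot nCells total number of expression libraries to simulate.
#' @slot subtypeFreqs named numeric, astrocyte subtype frequencies (sum 1).
#' @slot contaminantCounts named integer, planted cells per contaminating
#'   higher-order type.
#' @slot nLowQuality number of planted low-quality libraries (total counts
#'   below the QC floor).
#' @slot fingerprint character matrix subtype x gene with entries "high" or
#'   "low" giving each subtype's marker expression class.
#' @slot nbParams list of negative-binomial mean/size pairs per expression
#'   level class (\code{hi}, \code{lo}, \code{housekeeping}).
#' @slot plantedHvgCount number of genes planted above both HVG thresholds.
#' @slot nGenes total number of genes in the simulated matrix.
#' @slot ishLayout list describing region polygons, per-region nucleus
#'   counts and per-region subtype frequencies.
#' @slot punctaParams list: Poisson means for "+" and "-" marker states,
#'   background puncta rate per square micrometre, and intensity
#'   distributions of true and background puncta.
#' @slot traceParams list of per-region, per-condition event rates,
#'   amplitude distributions, decay constants, rise time, noise SD,
#'   non-responder fraction, sampling rate and duration.
#'
#' @seealso \code{\link{astroSimConfig}}, \code{\link{simulateCounts}},
#'   \code{\link{simulateIshSection}}, \code{\link{simulateCalciumTraces}}
#' @export
setClass("AstroSimConfig",
  slots = c(
    nCells = "integer",
    subtypeFreqs = "numeric",
    contaminantCounts = "integer",
    nLowQuality = "integer",
    fingerprint = "matrix",
    nbParams = "list",
    plantedHvgCount = "integer",
    nGenes = "integer",
    ishLayout = "list",
    punctaParams = "list",
    traceParams = "list"
  )
)

setValidity("AstroSimConfig", function(object) {
  msg <- NULL
  if (abs(sum(object@subtypeFreqs) - 1) > 1e-9)
    msg <- c(msg, "subtypeFreqs must sum to 1 (within 1e-9)")
  if (any(object@subtypeFreqs < 0))
    msg <- c(msg, "subtypeFreqs must be non-negative")
  if (object@nCells < 1L) msg <- c(msg, "nCells must be >= 1")
  nb <- object@nbParams
  for (lev in c("hi", "lo", "housekeeping")) {
    if (is.null(nb[[lev]]))
      msg <- c(msg, sprintf("nbParams must contain level '%s'", lev))
    else if (nb[[lev]]$mu < 0 || nb[[lev]]$size <= 0)
      msg <- c(msg, sprintf("nbParams$%s: mu must be >= 0, size > 0", lev))
  }
  tp <- object@traceParams
  if (!is.null(tp$durationS) && tp$durationS < 100)
    msg <- c(msg, "trace duration must be >= 100 s (baseline window)")
  if (!is.null(tp$samplingRateHz) && tp$samplingRateHz <= 0)
    msg <- c(msg, "sampling rate must be strictly positive")
  if (!is.null(tp$nonResponderFraction) &&
      (tp$nonResponderFraction < 0 || tp$nonResponderFraction > 1))
    msg <- c(msg, "nonResponderFraction must lie in [0, 1]")
  fp <- object@fingerprint
  if (!all(fp %in% c("high", "low")))
    msg <- c(msg, "fingerprint entries must be 'high' or 'low'")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: %d observations in k = %d clusters\n",
              length(object@labels), object@k))
  sil <- object@silhouetteByK
  cat(sprintf("  mean silhouette at k = %d: %.3f%s\n", object@k,
              max(sil), if (object@noSubstructure)
                " (below no-substructure floor)" else ""))
  cat("  scanned k:", paste(names(sil), collapse = " "), "\n")
})

setMethod("show", "IshSection", function(object) {
  cat(sprintf(
    "IshSection '%s' (animal '%s'): %d regions, %d nuclei, %d puncta in %d channel(s)\n",
    object@sectionId, object@animalId,
    length(unique(object@regions$region)), nrow(object@nuclei),
    nrow(object@puncta), length(unique(object@puncta$gene))))
})

setMethod("show", "SubtypeRuleTable", function(object) {
  cat("SubtypeRuleTable (evaluated in order):\n")
  for (nm in names(object@rules)) {
    r <- object@rules[[nm]]
    req <- paste(names(r$requires), r$requires, sep = "", collapse = ", ")
    cat(sprintf("  %s: %s", nm, req))
    if (!is.null(r$split)) {
      alt <- vapply(names(r$split), function(p)
        sprintf("panel %s: %s", p,
                paste(names(r$split[[p]]), r$split[[p]], sep = "",
                      collapse = ", ")), "")
      cat(" and (", paste(alt, collapse = " | "), ")")
    }
    cat("\n")
  }
})

setMethod("show", "CalciumRecording", function(object) {
  cat(sprintf(
    "CalciumRecording cell '%s' [%s, %s]: %.0f s at %.2f Hz (%d samples)\n",
    object@cellId, object@region, object@condition, object@duration,
    object@samplingRate, length(object@fluorescence)))
})

setMethod("show", "AstroSimConfig", function(object) {
  cat(sprintf(
    "AstroSimConfig: %d cells (%d astrocytes in %d subtypes, %d contaminants, %d low-quality), %d genes (%d planted HVGs)\n",
    object@nCells,
    object@nCells - sum(object@contaminantCounts) - object@nLowQuality,
    length(object@subtypeFreqs), sum(object@contaminantCounts),
    object@nLowQuality, object@nGenes, object@plantedHvgCount))
})

#' @rdname ClusterResult-class
#' @param object,x a \code{ClusterResult}.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname ClusterResult-class
#' @export
setMethod("clusterLabels", "ClusterResult", function(x) x@labels)

#' @rdname ClusterResult-class
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname ClusterResult-class
#' @export
setMethod("nClusters", "ClusterResult", function(x) x@k)

#' @rdname ClusterResult-class
#' @export
setGeneric("silhouetteByK", function(x) standardGeneric("silhouetteByK"))

#' @rdname ClusterResult-class
#' @export
setMethod("silhouetteByK", "ClusterResult", function(x) x@silhouetteByK)

#' Accessors for IshSection components
#'
#' @param x an \code{IshSection}.
#' @return the corresponding coordinate table.
#' @name IshSection-accessors
NULL

#' @rdname IshSection-accessors
#' @export
setGeneric("ishRegions", function(x) standardGeneric("ishRegions"))
#' @rdname IshSection-accessors
#' @export
setMethod("ishRegions", "IshSection", function(x) x@regions)
#' @rdname IshSection-accessors
#' @export
setGeneric("ishNuclei", function(x) standardGeneric("ishNuclei"))
#' @rdname IshSection-accessors
#' @export
setMethod("ishNuclei", "IshSection", function(x) x@nuclei)
#' @rdname IshSection-accessors
#' @export
setGeneric("ishPuncta", function(x) standardGeneric("ishPuncta"))
#' @rdname IshSection-accessors
#' @export
setMethod("ishPuncta", "IshSection", function(x) x@puncta)
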