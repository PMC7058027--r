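# ISH quantification: disk-shaped cell boundaries around DAPI nuclei,
# threshold-gated puncta counting with nearest-centroid assignment,
# "+"/"-" marker calls, ordered rule classification, regional
# distributions and fluorescence-threshold robustness sweeps.

#' Build cell boundary disks around nuclei
#'
#' Each cell boundary is a disk centred on the nucleus centroid with area
#' \code{areaScale} times the nuclear (DAPI) area, i.e. radius
#' \code{sqrt(areaScale * area / pi)}. The published average boundary is
#' about 1.3 times the DAPI signal.
#'
#' @param nuclei data.frame with cell_id, x_um, y_um, area_um2 (> 0).
#' @param areaScale positive area scaling factor.
#' @return data.frame with cell_id, x_um, y_um, radius_um.
#' @export
#' @examples
#' buildCellPolygons(data.frame(cell_id = 1, x_um = 0, y_um = 0,
#'                              area_um2 = 100))$radius_um  # ~6.433
buildCellPolygons <- function(nuclei, areaScale = 1.3) {
  if (areaScale <= 0) stop("areaScale must be strictly positive")
  if (!nrow(nuclei))
    return(data.frame(cell_id = integer(0), x_um = numeric(0),
                      y_um = numeric(0), radius_um = numeric(0)))
  if (any(nuclei$area_um2 <= 0)) stop("nuclear areas must be positive")
  data.frame(cell_id = nuclei$cell_id, x_um = nuclei$x_um,
             y_um = nuclei$y_um,
             radius_um = sqrt(areaScale * nuclei$area_um2 / pi))
}

#' Count thresholded puncta per cell for one channel
#'
#' Counts puncta of one gene whose intensity exceeds \code{intensityThr}
#' and whose position falls inside a cell disk. A punctum inside several
#' overlapping disks is assigned to the nearest centroid; exact ties go to
#' the lowest cell id.
#'
#' @param section an \code{\linkS4class{IshSection}}.
#' @param polygons result of \code{\link{buildCellPolygons}}.
#' @param gene channel to count; must exist in the section.
#' @param intensityThr background intensity threshold (strict).
#' @return named integer vector cell_id -> punctum count.
#' @export
countPuncta <- function(section, polygons, gene, intensityThr) {
  channels <- unique(ishPuncta(section)$gene)
  counts <- setNames(integer(nrow(polygons)),
                     as.character(polygons$cell_id))
  if (!gene %in% channels) {
    if (!length(channels)) return(counts)   # puncta-free section
    stop("no channel '", gene, "'; available: ",
         paste(sort(channels), collapse = ", "))
  }
  pts <- ishPuncta(section)
  pts <- pts[pts$gene == gene & pts$intensity > intensityThr, ]
  if (!nrow(pts) || !nrow(polygons)) return(counts)
  ord <- order(polygons$cell_id)
  px <- polygons$x_um[ord]; py <- polygons$y_um[ord]
  pr2 <- polygons$radius_um[ord]^2
  ids <- as.character(polygons$cell_id[ord])
  # chunked distance computation; cells are in ascending id order so
  # max.col's "first" tie rule realizes the lowest-id tie-break
  chunk <- 2000L
  winner <- rep(NA_character_, nrow(pts))
  for (start in seq(1L, nrow(pts), by = chunk)) {
    j <- start:min(start + chunk - 1L, nrow(pts))
    d2 <- outer(pts$x_um[j], px, "-")^2 + outer(pts$y_um[j], py, "-")^2
    d2[!sweep(d2, 2, pr2, "<=")] <- Inf
    best <- max.col(-d2, ties.method = "first")
    hit <- is.finite(d2[cbind(seq_along(j), best)])
    winner[j][hit] <- ids[best[hit]]
  }
  tb <- table(winner)
  counts[names(tb)] <- as.integer(tb)
  counts
}

#' Call markers "+"/"-"/indeterminate from puncta counts
#'
#' A marker is called \code{"+"} when its count reaches \code{thetaHi}
#' (boundary inclusive), \code{"-"} when at or below \code{thetaLo}, and
#' \code{"indeterminate"} in between. Defaults (5, 2) are configurable per
#' marker; the robustness sweep covers the sensitivity to this choice.
#'
#' @param counts matrix or data.frame cells x genes of puncta counts, or a
#'   named vector for a single cell.
#' @param thetaHi,thetaLo per-gene thresholds: named vectors or single
#'   values recycled over genes; \code{thetaLo < thetaHi} required.
#' @return character matrix (cells x genes) of calls, or a named vector
#'   for single-cell input.
#' @export
callMarkers <- function(counts, thetaHi = 5, thetaLo = 2) {
  vec <- is.null(dim(counts))
  m <- if (vec) matrix(counts, nrow = 1,
                       dimnames = list(NULL, names(counts))) else
    as.matrix(counts)
  genes <- colnames(m)
  hi <- if (length(thetaHi) == 1) setNames(rep(thetaHi, length(genes)),
                                           genes) else thetaHi[genes]
  lo <- if (length(thetaLo) == 1) setNames(rep(thetaLo, length(genes)),
                                           genes) else thetaLo[genes]
  if (any(is.na(hi)) || any(is.na(lo)))
    stop("thresholds must cover every gene")
  if (any(lo >= hi))
    stop("thetaLo must be strictly below thetaHi for every gene")
  calls <- matrix("indeterminate", nrow(m), ncol(m),
                  dimnames = dimnames(m))
  calls[sweep(m, 2, hi, ">=")] <- "+"
  calls[sweep(m, 2, lo, "<=")] <- "-"
  if (vec) calls[1, ] else calls
}

#' Classify one astrocyte's subtype from its marker calls
#'
#' Evaluates the rule table in order; the first rule whose requirements
#' are all met wins. An indeterminate call fails any requirement on that
#' gene. A rule requirement on a gene absent from the staining panel fails
#' the rule, except for the split clause (AST3), where only the clause of
#' the panel in use is evaluated; with the \code{"full"} panel either
#' split alternative may satisfy the clause. Cells matching no rule are
#' \code{"unclassified"}.
#'
#' @param calls named character vector of "+"/"-"/"indeterminate" calls
#'   for one cell; must include a \code{"+"} for Slc1a3 (astrocyte
#'   definition) - non-astrocytes are an error.
#' @param rules a \code{\linkS4class{SubtypeRuleTable}}.
#' @param panel \code{"A"}, \code{"B"} or \code{"full"}.
#' @return subtype name or \code{"unclassified"}.
#' @export
#' @examples
#' classifySubtype(c(Frzb = "+", Ascl1 = "+", Slc1a3 = "+",
#'                   Gfap = "-", Agt = "-", Unc13c = "-", Ogt = "+",
#'                   Fam107a = "-"), subtypeRules(), panel = "full")
classifySubtype <- function(calls, rules = subtypeRules(),
                            panel = c("full", "A", "B")) {
  panel <- match.arg(panel)
  if (is.na(calls["Slc1a3"]) || calls[["Slc1a3"]] != "+")
    stop("classifySubtype expects an astrocyte (Slc1a3 call '+')")
  panelGenes <- markerPanels()[[panel]]
  satisfied <- function(req, genes = names(req)) {
    all(genes %in% panelGenes & genes %in% names(calls) &
          calls[genes] == req)
  }
  for (nm in names(rules@rules)) {
    r <- rules@rules[[nm]]
    if (!satisfied(r$requires)) next
    if (is.null(r$split)) return(nm)
    alts <- if (panel == "full") r$split else r$split[panel]
    ok <- any(vapply(alts, function(a) !is.null(a) && satisfied(a),
                     logical(1)))
    if (ok) return(nm)
  }
  "unclassified"
}

#' Quantify and classify every cell of a section
#'
#' Runs the full per-section pipeline: cell disks, per-channel threshold
#' counting, marker calls, astrocyte gating on the Slc1a3 call, and rule
#' classification with the chosen staining panel.
#'
#' @param section an \code{\linkS4class{IshSection}}.
#' @param intensityThr background intensity threshold.
#' @param areaScale disk area scale (see \code{\link{buildCellPolygons}}).
#' @param thetaHi,thetaLo marker call thresholds
#'   (see \code{\link{callMarkers}}).
#' @param rules rule table.
#' @param panel staining panel: only channels of the panel (plus any rule
#'   genes available) are used; \code{"full"} uses every channel.
#' @return data.frame (one row per nucleus): cell_id, region (or
#'   "outside"), one count and one call column per gene, is_astrocyte,
#'   subtype ("unclassified" for astrocytes matching no rule, NA for
#'   non-astrocytes).
#' @export
classifyCells <- function(section, intensityThr = 100, areaScale = 1.3,
                          thetaHi = 5, thetaLo = 2,
                          rules = subtypeRules(),
                          panel = c("full", "A", "B")) {
  panel <- match.arg(panel)
  polygons <- buildCellPolygons(ishNuclei(section), areaScale)
  channels <- intersect(markerPanels()$full,
                        unique(ishPuncta(section)$gene))
  if (panel != "full") channels <- intersect(channels,
                                             markerPanels()[[panel]])
  if (!"Slc1a3" %in% channels)
    stop("section has no Slc1a3 channel: astrocytes cannot be gated")
  counts <- vapply(channels, function(g)
    countPuncta(section, polygons, g, intensityThr),
    integer(nrow(polygons)))
  if (!nrow(polygons))
    counts <- matrix(integer(0), 0, length(channels),
                     dimnames = list(NULL, channels))
  calls <- callMarkers(counts, thetaHi, thetaLo)
  region <- .regionOfPoints(ishRegions(section), polygons$x_um,
                            polygons$y_um)
  isAstro <- calls[, "Slc1a3"] == "+"
  subtype <- rep(NA_character_, nrow(polygons))
  for (i in which(isAstro))
    subtype[i] <- classifySubtype(calls[i, ], rules, panel)
  out <- data.frame(cell_id = polygons$cell_id, region = region,
                    row.names = NULL)
  for (g in channels) out[[paste0("count_", g)]] <- counts[, g]
  for (g in channels) out[[paste0("call_", g)]] <- calls[, g]
  out$is_astrocyte <- isAstro
  out$subtype <- subtype
  out
}

#' Regional subtype distribution across sections
#'
#' Per region and subtype: mean cell count per section, SEM across
#' sections (SD/sqrt(n); 0 with a flag when only one section is given)
#' and the astrocyte-normalized fraction (subtype count over all Slc1a3+
#' cells of that region, pooled over sections). Cells outside every
#' region polygon are excluded.
#'
#' @param cellsBySection named list of \code{\link{classifyCells}}
#'   outputs, one per section.
#' @return data.frame with region, subtype, mean_count, sem, fraction,
#'   n_sections.
#' @export
regionDistribution <- function(cellsBySection) {
  if (!length(cellsBySection)) stop("need at least one section")
  nSec <- length(cellsBySection)
  if (nSec == 1)
    message("single section: SEM reported as 0 by convention (n = 1)")
  all <- do.call(rbind, lapply(seq_along(cellsBySection), function(i) {
    df <- cellsBySection[[i]]
    df$section <- i
    df
  }))
  all <- all[all$region != "outside" & all$is_astrocyte, ]
  regions <- sort(unique(all$region))
  subtypes <- sort(unique(all$subtype))
  rows <- list()
  for (r in regions) {
    inRegion <- all[all$region == r, ]
    totalAstro <- nrow(inRegion)
    for (s in subtypes) {
      perSection <- vapply(seq_len(nSec), function(i)
        sum(inRegion$section == i & inRegion$subtype == s), numeric(1))
      sem <- if (nSec > 1) sd(perSection) / sqrt(nSec) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        region = r, subtype = s, mean_count = mean(perSection),
        sem = sem,
        fraction = if (totalAstro > 0)
          sum(perSection) / totalAstro else NA_real_,
        n_sections = nSec)
    }
  }
  do.call(rbind, rows)
}

#' Robustness of the subtype map to the fluorescence threshold
#'
#' Re-runs count -> call -> classify over a grid of intensity thresholds
#' and reports, per region and subtype, the range of astrocyte-normalized
#' fractions over the grid, plus the overall fraction of cells whose
#' subtype label is constant across the grid.
#'
#' @param section an \code{\linkS4class{IshSection}}.
#' @param thrGrid non-empty numeric vector of intensity thresholds.
#' @param ... further arguments passed to \code{\link{classifyCells}}.
#' @return list with \code{fractions} (data.frame region, subtype,
#'   fraction_min, fraction_max) and \code{stability} (fraction of cells
#'   with a constant label, counting the astrocyte gate as part of the
#'   label).
#' @export
thresholdSweep <- function(section, thrGrid, ...) {
  if (!length(thrGrid)) stop("threshold grid must be non-empty")
  runs <- lapply(thrGrid, function(thr)
    classifyCells(section, intensityThr = thr, ...))
  labels <- vapply(runs, function(df)
    ifelse(df$is_astrocyte, df$subtype, "non-astrocyte"),
    character(nrow(runs[[1]])))
  if (nrow(runs[[1]]) == 0) {
    stability <- 1
  } else {
    labels <- matrix(labels, nrow = nrow(runs[[1]]))
    stability <- mean(apply(labels, 1, function(z)
      length(unique(z)) == 1))
  }
  fracs <- lapply(runs, function(df) {
    rd <- regionDistribution(list(df))
    rd[, c("region", "subtype", "fraction")]
  })
  merged <- do.call(rbind, fracs)
  if (nrow(merged)) {
    agg <- aggregate(fraction ~ region + subtype, data = merged,
                     FUN = function(z) c(min = min(z), max = max(z)))
    fractions <- data.frame(region = agg$region, subtype = agg$subtype,
                            fraction_min = agg$fraction[, "min"],
                            fraction_max = agg$fraction[, "max"])
  } else {
    fractions <- data.frame(region = character(0), subtype = character(0),
                            fraction_min = numeric(0),
                            fraction_max = numeric(0))
  }
  list(fractions = fractions, stability = stability)
}
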