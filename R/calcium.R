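# Calcium transient analysis: dF/F0 against a 100 s baseline, peak
# detection under four thresholds (height 1.15 dF/F0, width >= 2 s at half
# prominence, separation >= 1 s, prominence >= 0.1), per-cell
# parameterization, PHE-responder filtering, physiology clustering and
# nonparametric group comparisons.

#' Fractional fluorescence change against the initial baseline
#'
#' F0 is the mean fluorescence over the first \code{baselineWindow}
#' seconds (samples with t < baselineWindow); the output is
#' (F - F0) / F0.
#'
#' @param rec a \code{\linkS4class{CalciumRecording}}.
#' @param baselineWindow baseline duration in seconds (default 100).
#' @return numeric dF/F0 series of the same length as the recording.
#' @export
computeDff <- function(rec, baselineWindow = 100) {
  if (rec@duration < baselineWindow)
    stop("recording shorter than the baseline window (",
         baselineWindow, " s)")
  t <- (seq_along(rec@fluorescence) - 1) / rec@samplingRate
  f0 <- mean(rec@fluorescence[t < baselineWindow])
  if (!is.finite(f0) || f0 <= 0)
    stop("non-positive baseline F0: trace unusable")
  (rec@fluorescence - f0) / f0
}

# Topographic prominence of the peak at index p: extend to each side until
# a strictly higher sample (or the series end), take the minimum over each
# side, and subtract the higher of the two minima from the peak height.
.prominence <- function(x, p) {
  h <- x[p]
  leftMin <- h; i <- p - 1
  while (i >= 1 && x[i] <= h) {
    if (x[i] < leftMin) leftMin <- x[i]
    i <- i - 1
  }
  rightMin <- h; i <- p + 1
  while (i <= length(x) && x[i] <= h) {
    if (x[i] < rightMin) rightMin <- x[i]
    i <- i + 1
  }
  h - max(leftMin, rightMin)
}

# Width of the peak at reference height h = amplitude - prominence / 2,
# with linear interpolation of the crossings; clipped at the series ends.
.widthAtHalfProm <- function(x, p, prom, rate) {
  ref <- x[p] - prom / 2
  i <- p
  while (i > 1 && x[i - 1] >= ref) i <- i - 1
  tL <- if (i == 1 && x[1] >= ref) 1 else
    (i - 1) + (x[i - 1] - ref) / (x[i - 1] - x[i])
  i <- p
  n <- length(x)
  while (i < n && x[i + 1] >= ref) i <- i + 1
  tR <- if (i == n && x[n] >= ref) n else
    i + (x[i] - ref) / (x[i] - x[i + 1])
  (tR - tL) / rate
}

#' Detect calcium transients in a dF/F0 series
#'
#' Candidates are strict local maxima (series endpoints excluded, where
#' prominence is undefined) with dF/F0 above \code{heightThr}. Prominence
#' follows the standard topographic definition; width is measured at the
#' half-prominence height with linearly interpolated crossings. Candidates
#' failing the prominence or width floors are removed; among survivors
#' closer than \code{minSepS}, the taller peak wins (greedy by descending
#' amplitude). Output is sorted by time.
#'
#' @param dff numeric dF/F0 series (length >= 3 for any peak to exist).
#' @param rate sampling rate in Hz (> 0).
#' @param heightThr minimal dF/F0 at the maximum (strict).
#' @param minWidthS minimal width at half prominence, seconds.
#' @param minSepS minimal separation between peak times, seconds.
#' @param minProm minimal prominence, dF/F0.
#' @return data.frame with time (s), amplitude, prominence, width (s).
#' @export
detectTransients <- function(dff, rate, heightThr = 1.15, minWidthS = 2,
                             minSepS = 1, minProm = 0.1) {
  if (rate <= 0) stop("sampling rate must be strictly positive")
  empty <- data.frame(time = numeric(0), amplitude = numeric(0),
                      prominence = numeric(0), width = numeric(0))
  n <- length(dff)
  if (n < 3) return(empty)
  inner <- 2:(n - 1)
  isPeak <- dff[inner] > dff[inner - 1] & dff[inner] > dff[inner + 1] &
    dff[inner] > heightThr
  cand <- inner[isPeak]
  if (!length(cand)) return(empty)
  prom <- vapply(cand, function(p) .prominence(dff, p), numeric(1))
  keep <- prom >= minProm
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(empty)
  width <- vapply(seq_along(cand), function(i)
    .widthAtHalfProm(dff, cand[i], prom[i], rate), numeric(1))
  keep <- width >= minWidthS
  cand <- cand[keep]; prom <- prom[keep]; width <- width[keep]
  if (!length(cand)) return(empty)
  # greedy separation rule: taller peaks claim their neighbourhood
  ord <- order(dff[cand], decreasing = TRUE)
  times <- (cand - 1) / rate
  accepted <- logical(length(cand))
  for (i in ord) {
    if (any(accepted & abs(times - times[i]) < minSepS)) next
    accepted[i] <- TRUE
  }
  out <- data.frame(time = times[accepted],
                    amplitude = dff[cand[accepted]],
                    prominence = prom[accepted],
                    width = width[accepted])
  out[order(out$time), , drop = FALSE]
}

#' Per-cell, per-condition transient summary
#'
#' Means over the detected peaks (undefined for inactive cells), peak
#' frequency (count / duration) and the trapezoidal area under the whole
#' dF/F0 window (negative excursions included, no clipping).
#'
#' @param dff dF/F0 series of the condition window.
#' @param peaks result of \code{\link{detectTransients}}.
#' @param duration window duration, seconds (> 0).
#' @param rate sampling rate in Hz.
#' @param cellId,condition,region identifiers copied into the record.
#' @return one-row data.frame: cell_id, region, condition, n_peaks,
#'   amplitude, prominence, width, peak_time, frequency, auc, active.
#' @export
summarizeCell <- function(dff, peaks, duration, rate, cellId = NA,
                          condition = NA, region = NA) {
  if (duration <= 0) stop("duration must be positive")
  auc <- sum((dff[-1] + dff[-length(dff)]) / 2) / rate
  active <- nrow(peaks) > 0
  data.frame(
    cell_id = cellId, region = region, condition = condition,
    n_peaks = nrow(peaks),
    amplitude = if (active) mean(peaks$amplitude) else NA_real_,
    prominence = if (active) mean(peaks$prominence) else NA_real_,
    width = if (active) mean(peaks$width) else NA_real_,
    peak_time = if (active) mean(peaks$time) else NA_real_,
    frequency = nrow(peaks) / duration,
    auc = auc, active = active, row.names = NULL)
}

#' Transient parameters for a set of recordings
#'
#' Convenience wrapper running \code{\link{computeDff}},
#' \code{\link{detectTransients}} and \code{\link{summarizeCell}} over a
#' list of recordings.
#'
#' @param recordings list of \code{\linkS4class{CalciumRecording}}.
#' @param ... detection thresholds passed to
#'   \code{\link{detectTransients}}.
#' @param baselineWindow baseline window in seconds.
#' @return data.frame with one row per recording.
#' @export
transientParameters <- function(recordings, baselineWindow = 100, ...) {
  do.call(rbind, lapply(recordings, function(rec) {
    dff <- computeDff(rec, baselineWindow)
    peaks <- detectTransients(dff, rec@samplingRate, ...)
    summarizeCell(dff, peaks, rec@duration, rec@samplingRate,
                  cellId = rec@cellId, condition = rec@condition,
                  region = rec@region)
  }))
}

#' Filter cells by PHE response
#'
#' Cells with at least one PHE transient are retained for all analyses;
#' within the BASE and TTX analyses the retained set is further restricted
#' to cells active in that condition. Cells without a PHE recording are
#' excluded with a warning. Also reports the fraction of PHE responders
#' active under BASE and TTX.
#'
#' @param params result of \code{\link{transientParameters}} covering all
#'   three conditions.
#' @return list with \code{retained} (PHE-responder cell ids),
#'   \code{activeIn} (list condition -> retained cells active in it) and
#'   \code{activeFraction} (named numeric, BASE and TTX).
#' @export
filterResponders <- function(params) {
  cells <- unique(params$cell_id)
  hasPhe <- cells %in% params$cell_id[params$condition == "PHE"]
  if (any(!hasPhe)) {
    warning(sum(!hasPhe), " cell(s) lack a PHE recording; excluded")
    cells <- cells[hasPhe]
  }
  phe <- params[params$condition == "PHE" & params$cell_id %in% cells, ]
  retained <- phe$cell_id[phe$n_peaks >= 1]
  activeIn <- lapply(c(BASE = "BASE", TTX = "TTX", PHE = "PHE"),
                     function(cond) {
    sub <- params[params$condition == cond & params$cell_id %in% retained, ]
    sub$cell_id[sub$n_peaks >= 1]
  })
  activeFraction <- c(
    BASE = length(activeIn$BASE) / max(length(retained), 1),
    TTX = length(activeIn$TTX) / max(length(retained), 1))
  list(retained = retained, activeIn = activeIn,
       activeFraction = activeFraction)
}

#' Cluster cells on their PHE transient parameters
#'
#' z-scales each parameter (amplitude, prominence, width, peak time,
#' frequency, AUC) across cells, drops constant columns with a warning,
#' and selects the cluster number by maximal mean silhouette width under
#' Ward agglomeration over \code{2:kMax}.
#'
#' @param params \code{\link{transientParameters}} rows for one condition
#'   (typically PHE responders only), complete in all parameters.
#' @param kMax largest cluster number scanned (needs kMax + 1 cells).
#' @param includePeakTime keep the mean peak time as a feature (it is one
#'   of the measured parameters; set FALSE to exclude it).
#' @return a \code{\linkS4class{ClusterResult}} with labels named by cell.
#' @export
clusterPhysiology <- function(params, kMax = 8, includePeakTime = TRUE) {
  feats <- c("amplitude", "prominence", "width",
             if (includePeakTime) "peak_time", "frequency", "auc")
  x <- as.matrix(params[, feats])
  rownames(x) <- params$cell_id
  if (anyNA(x))
    stop("parameter vectors must be complete: cluster only active cells")
  if (nrow(x) < kMax + 1)
    stop("clustering over 2:", kMax, " needs at least ", kMax + 1, " cells")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warning("dropping constant parameter column(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  silhouetteSelectK(scale(x), kRange = 2:kMax)
}

#' Per-cluster region composition
#'
#' @param clusters a \code{\linkS4class{ClusterResult}} from
#'   \code{\link{clusterPhysiology}}.
#' @param params the parameter table the clustering was run on (must
#'   contain cell_id and region).
#' @return data.frame cluster x region counts and fractions.
#' @export
clusterRegionComposition <- function(clusters, params) {
  labels <- clusterLabels(clusters)
  region <- params$region[match(names(labels), params$cell_id)]
  tab <- table(cluster = labels, region = region)
  out <- as.data.frame(tab)
  out$fraction <- out$Freq / rep(rowSums(tab), times = ncol(tab))
  names(out)[names(out) == "Freq"] <- "count"
  out
}

#' Nonparametric group comparisons of transient parameters
#'
#' For each parameter: Shapiro-Wilk p per group (recorded as a gate, not
#' branched on - the analysis always proceeds nonparametrically),
#' Kruskal-Wallis H and p across groups, and Dunn's pairwise post-hoc
#' with Benjamini-Hochberg adjustment across the pairwise family of that
#' parameter. Raw (unscaled) parameters are used. Groups with fewer than
#' 2 observations cause that parameter's comparison to be skipped with a
#' warning.
#'
#' @param params \code{\link{transientParameters}} rows for one condition.
#' @param grouping column to group by: \code{"region"} or a vector of
#'   cluster labels aligned with \code{params}.
#' @param parameters parameter columns to compare.
#' @return list with \code{normality}, \code{kruskal} and \code{dunn}
#'   data.frames.
#' @export
compareGroups <- function(params,
                          grouping = "region",
                          parameters = c("amplitude", "prominence",
                                         "width", "peak_time",
                                         "frequency", "auc")) {
  g <- if (length(grouping) == 1 && is.character(grouping))
    params[[grouping]] else grouping
  g <- factor(g)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  normRows <- list(); kwRows <- list(); dunnRows <- list()
  for (par in parameters) {
    groups <- split(params[[par]], g)
    groups <- lapply(groups, function(z) z[is.finite(z)])
    if (any(lengths(groups) < 2)) {
      warning("parameter '", par,
              "': a group has < 2 observations; comparison skipped")
      next
    }
    for (nm in names(groups)) {
      swp <- tryCatch(shapiroWilk(groups[[nm]])$p.value,
                      warning = function(w) 0)
      normRows[[length(normRows) + 1L]] <- data.frame(
        parameter = par, group = nm, shapiro_p = swp)
    }
    kw <- kruskalWallis(groups)
    kwRows[[length(kwRows) + 1L]] <- data.frame(
      parameter = par, H = kw$statistic, df = kw$df, p = kw$p.value)
    dn <- dunnPosthoc(groups)
    dn <- cbind(parameter = par, dn)
    dunnRows[[length(dunnRows) + 1L]] <- dn
  }
  list(normality = do.call(rbind, normRows),
       kruskal = do.call(rbind, kwRows),
       dunn = do.call(rbind, dunnRows))
}
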