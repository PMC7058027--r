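# Single-cell pipeline: QC floor, ln-normalization, HVG selection with
# explicit mean/dispersion thresholds, silhouette-selected Ward clustering,
# higher-order typing by marker panels, and marker-gene calling.

#' Filter cells by a minimal total-transcript floor
#'
#' Keeps cells whose total counts reach \code{minTotal} (the published
#' floor is 54 transcripts; a cell with exactly the floor is kept). Cell
#' order is preserved and kept plus discarded cells partition the input.
#'
#' @param sce a \code{SingleCellExperiment} with a \code{"counts"} assay.
#' @param minTotal minimal acceptable total transcript count (>= 0).
#' @return list with \code{kept} (the filtered object) and
#'   \code{discarded} (character vector of discarded cell names).
#' @export
#' @examples
#' cfg <- astroSimConfig(nCells = 120, contaminantCounts = c(neuron = 8),
#'                       nLowQuality = 3, plantedHvgCount = 40,
#'                       nGenes = 400)
#' sce <- simulateCounts(cfg, seed = 1)
#' qc <- qcFilterCells(sce)
#' length(qc$discarded)  # the 3 planted low-quality libraries
qcFilterCells <- function(sce, minTotal = 54) {
  if (minTotal < 0) stop("minTotal must be non-negative")
  if (nrow(sce) == 0) stop("count matrix has no genes")
  totals <- Matrix::colSums(SummarizedExperiment::assay(sce, "counts"))
  keep <- totals >= minTotal
  list(kept = sce[, keep], discarded = colnames(sce)[!keep])
}

#' Library-size ln-normalization
#'
#' Computes \code{ln(1 + scaleFactor * count / total)} per gene and cell
#' and stores it as the \code{"logcounts"} assay (natural log). Values are
#' zero exactly where counts are zero, monotone in the count at fixed
#' library size, and invariant to rescaling a cell's counts.
#'
#' @param sce a \code{SingleCellExperiment} with a \code{"counts"} assay;
#'   every cell must have a positive total (run
#'   \code{\link{qcFilterCells}} first).
#' @param scaleFactor positive scale constant (default 10000).
#' @return the object with a \code{"logcounts"} assay added.
#' @export
lnNormalize <- function(sce, scaleFactor = 1e4) {
  if (scaleFactor <= 0) stop("scaleFactor must be positive")
  counts <- SummarizedExperiment::assay(sce, "counts")
  totals <- Matrix::colSums(counts)
  if (any(totals == 0))
    stop("some cells have zero total counts; run qcFilterCells() first")
  ln <- log1p(sweep(as.matrix(counts), 2, scaleFactor / totals, "*"))
  SummarizedExperiment::assay(sce, "logcounts") <- ln
  S4Vectors::metadata(sce)$scaleFactor <- scaleFactor
  sce
}

#' Select highly variable genes by ln-mean and dispersion thresholds
#'
#' For each gene computes the mean of its ln-normalized values and its
#' dispersion (variance/mean of the ln values; 0 for constant or silent
#' genes) and selects genes strictly exceeding both thresholds. The
#' published thresholds are (0.3, 0.1) for the all-cell pass and
#' (0.5, 0.5) for the astrocyte pass.
#'
#' @param sce a \code{SingleCellExperiment} with \code{"logcounts"} (see
#'   \code{\link{lnNormalize}}) and at least 2 cells.
#' @param meanThr,dispThr strict selection thresholds.
#' @return \code{DataFrame} (rows = genes) with \code{lnMean},
#'   \code{dispersion} and \code{selected}.
#' @export
selectHvg <- function(sce, meanThr = 0.5, dispThr = 0.5) {
  if (ncol(sce) < 2) stop("HVG selection needs at least 2 cells")
  ln <- SummarizedExperiment::assay(sce, "logcounts")
  lnMean <- rowMeans(ln)
  lnVar <- apply(ln, 1, var)
  dispersion <- ifelse(lnMean > 0, lnVar / lnMean, 0)
  S4Vectors::DataFrame(
    lnMean = lnMean, dispersion = dispersion,
    selected = lnMean > meanThr & dispersion > dispThr,
    row.names = rownames(sce))
}

#' Cluster cells on the HVG submatrix
#'
#' Pipeline: per-gene z-scaling of the ln-normalized HVG submatrix, PCA to
#' \code{nPcs} components, Ward (ward.D2) agglomeration on Euclidean
#' distances, and selection of the cluster number by maximal mean
#' silhouette width over \code{2:kMax}. Deterministic.
#'
#' @param sce a \code{SingleCellExperiment} with \code{"logcounts"}.
#' @param hvg result of \code{\link{selectHvg}} (needs >= 2 selected
#'   genes), or a character vector of gene names.
#' @param kMax largest cluster number scanned; needs \code{kMax + 1} cells.
#' @param nPcs number of principal components retained (capped at the
#'   matrix rank).
#' @param noStructureFloor mean-silhouette floor below which the result is
#'   flagged as having no substructure (single-fingerprint inputs).
#' @return a \code{\linkS4class{ClusterResult}} with labels named by cell.
#' @export
clusterCells <- function(sce, hvg, kMax = 10, nPcs = 20,
                         noStructureFloor = 0.15) {
  genes <- if (is.character(hvg)) hvg else rownames(hvg)[hvg$selected]
  if (length(genes) < 2)
    stop("clustering needs at least 2 selected highly variable genes")
  if (ncol(sce) < kMax + 1)
    stop("clustering over 2:", kMax, " needs at least ", kMax + 1, " cells")
  ln <- SummarizedExperiment::assay(sce, "logcounts")[genes, , drop = FALSE]
  z <- t(scale(t(ln)))                       # per-gene z-scale
  z <- z[apply(is.finite(z), 1, all), , drop = FALSE]
  pcs <- prcomp(t(z), center = FALSE, scale. = FALSE)
  nPcs <- min(nPcs, ncol(pcs$x))
  silhouetteSelectK(pcs$x[, seq_len(nPcs), drop = FALSE],
                    kRange = 2:kMax, noStructureFloor = noStructureFloor)
}

#' Assign clusters to higher-order cell types by marker panels
#'
#' Each cluster is assigned the cell type whose marker panel has the
#' highest mean ln-expression across the cluster's cells. Ties are broken
#' toward the lexicographically smallest type with a warning.
#'
#' @param sce a \code{SingleCellExperiment} with \code{"logcounts"}.
#' @param clusters a \code{\linkS4class{ClusterResult}} for the same cells.
#' @param panels named list celltype -> marker gene vector (default
#'   \code{\link{higherOrderPanels}}); panel genes must be present in the
#'   matrix.
#' @return named character vector cluster id -> cell type.
#' @seealso \code{\link{extractTypedCells}}
#' @export
assignHigherOrderTypes <- function(sce, clusters,
                                   panels = higherOrderPanels()) {
  if (!length(panels)) stop("panels must be non-empty")
  missing <- setdiff(unlist(panels), rownames(sce))
  if (length(missing))
    stop("panel gene(s) absent from the matrix: ",
         paste(missing, collapse = ", "))
  ln <- SummarizedExperiment::assay(sce, "logcounts")
  labels <- clusterLabels(clusters)
  out <- character(0)
  for (cl in sort(unique(labels))) {
    cells <- which(labels == cl)
    score <- vapply(panels, function(g)
      mean(ln[g, cells, drop = FALSE]), numeric(1))
    best <- which(score == max(score))
    if (length(best) > 1) {
      nm <- sort(names(score)[best])[1]
      warning("cluster ", cl, ": tie between panels ",
              paste(sort(names(score)[best]), collapse = ", "),
              "; assigning '", nm, "'")
    } else nm <- names(score)[best]
    out[as.character(cl)] <- nm
  }
  out
}

#' Extract all cells belonging to clusters of one assigned type
#'
#' @param sce the clustered object.
#' @param clusters the \code{\linkS4class{ClusterResult}} used for typing.
#' @param assignment result of \code{\link{assignHigherOrderTypes}}.
#' @param type the cell type to extract (default \code{"astrocyte"}).
#' @return the subset \code{SingleCellExperiment}.
#' @export
extractTypedCells <- function(sce, clusters, assignment,
                              type = "astrocyte") {
  keepClusters <- names(assignment)[assignment == type]
  keep <- as.character(clusterLabels(clusters)) %in% keepClusters
  sce[, keep]
}

#' Marker genes of one cluster
#'
#' For every gene, tests the cluster against all remaining cells with a
#' two-sided Wilcoxon rank-sum test on ln-normalized values, and records
#' the linear fold change of de-logged means (epsilon-regularized) and the
#' fraction of cluster cells expressing the gene. A record passes when
#' p < \code{pThr}, fold change >= \code{foldThr} and percent expressing
#' > \code{pctThr} (published criteria: 0.01, 1.28, 0.25). Only
#' upregulated genes (cluster mean above rest mean) are returned, sorted
#' by p then fold change descending.
#'
#' @param sce a \code{SingleCellExperiment} with \code{"logcounts"}.
#' @param clusters a \code{\linkS4class{ClusterResult}}.
#' @param cluster the cluster id of interest.
#' @param pThr,foldThr,pctThr the three marker criteria.
#' @param eps regularizer added to both de-logged means.
#' @return data.frame with gene, cluster, p_value, fold_change,
#'   pct_expressing, passes.
#' @export
findClusterMarkers <- function(sce, clusters, cluster, pThr = 0.01,
                               foldThr = 1.28, pctThr = 0.25,
                               eps = 1e-9) {
  labels <- clusterLabels(clusters)
  if (!cluster %in% labels)
    stop("unknown cluster id '", cluster, "'; available: ",
         paste(sort(unique(labels)), collapse = ", "))
  inCl <- labels == cluster
  if (all(inCl)) stop("cluster complement is empty")
  ln <- SummarizedExperiment::assay(sce, "logcounts")
  res <- lapply(rownames(ln), function(g) {
    x <- ln[g, inCl]; y <- ln[g, !inCl]
    mx <- mean(expm1(x)); my <- mean(expm1(y))
    if (mx <= my) return(NULL)          # only upregulated genes
    p <- suppressWarnings(wilcox.test(x, y)$p.value)
    data.frame(gene = g, cluster = cluster, p_value = p,
               fold_change = (mx + eps) / (my + eps),
               pct_expressing = mean(x > 0))
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(gene = character(0), cluster = character(0),
                      p_value = numeric(0), fold_change = numeric(0),
                      pct_expressing = numeric(0), passes = logical(0)))
  out$passes <- out$p_value < pThr & out$fold_change >= foldThr &
    out$pct_expressing > pctThr
  out[order(out$p_value, -out$fold_change), , drop = FALSE]
}

#' Subtype composition table
#'
#' Tabulates counts and fractions per label, optionally split by region
#' (e.g. cortex CX vs hippocampus HP). Fractions sum to 1.
#'
#' @param labels character/factor vector of subtype (or cluster) labels.
#' @param region optional region vector of the same length.
#' @return data.frame with subtype, count, fraction and, when regions are
#'   given, one count column per region.
#' @export
subtypeProportions <- function(labels, region = NULL) {
  tab <- table(labels)
  out <- data.frame(subtype = names(tab), count = as.integer(tab),
                    fraction = as.numeric(tab) / sum(tab),
                    row.names = NULL)
  if (!is.null(region)) {
    stopifnot(length(region) == length(labels))
    split <- table(labels, region)
    for (r in colnames(split))
      out[[paste0("count_", r)]] <- as.integer(split[out$subtype, r])
  }
  out
}
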