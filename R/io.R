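# Plain-text interchange: MTX + TSV for count matrices, CSV tables for
# ISH sections, long-format CSV for calcium traces.

#' Write a count matrix as MTX plus TSV sidecars
#'
#' Writes \code{matrix.mtx} (MatrixMarket sparse), \code{genes.tsv} (one
#' gene id per line) and \code{cells.tsv} (cell id plus the colData
#' columns, tab-separated with header).
#'
#' @param sce a \code{SingleCellExperiment} with a \code{"counts"} assay.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeCountsMTX <- function(sce, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts <- SummarizedExperiment::assay(sce, "counts")
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(counts,
    sparse = TRUE), "CsparseMatrix"), "generalMatrix"),
    file.path(dir, "matrix.mtx"))
  writeLines(rownames(sce), file.path(dir, "genes.tsv"))
  meta <- as.data.frame(SummarizedExperiment::colData(sce))
  meta <- cbind(cell = colnames(sce), meta)
  write.table(meta, file.path(dir, "cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a count matrix written by \code{\link{writeCountsMTX}}
#'
#' @param dir directory containing matrix.mtx, genes.tsv, cells.tsv.
#' @return a \code{SingleCellExperiment} with integer counts and the cell
#'   metadata restored as colData.
#' @export
readCountsMTX <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  storage.mode(m) <- "integer"
  genes <- readLines(file.path(dir, "genes.tsv"))
  meta <- read.delim(file.path(dir, "cells.tsv"),
                     stringsAsFactors = FALSE)
  dimnames(m) <- list(genes, meta$cell)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(meta[, setdiff(names(meta), "cell"),
                                        drop = FALSE],
                                   row.names = meta$cell))
}

#' Write an ISH section as CSV tables
#'
#' Writes \code{regions.csv} (region, vertex_index, x_um, y_um),
#' \code{nuclei.csv} (cell_id, x_um, y_um, area_um2) and
#' \code{puncta.csv} (gene, x_um, y_um, intensity). Coordinates are
#' micrometres, origin top-left, y increasing downward.
#'
#' @param section an \code{\linkS4class{IshSection}}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeIshSection <- function(section, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(ishRegions(section), file.path(dir, "regions.csv"),
            row.names = FALSE)
  write.csv(ishNuclei(section), file.path(dir, "nuclei.csv"),
            row.names = FALSE)
  write.csv(ishPuncta(section), file.path(dir, "puncta.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read an ISH section from CSV tables
#'
#' @param dir directory with regions.csv, nuclei.csv, puncta.csv.
#' @param sectionId,animalId identifiers to attach.
#' @return an \code{\linkS4class{IshSection}}.
#' @export
readIshSection <- function(dir, sectionId = basename(dir),
                           animalId = "unknown") {
  new("IshSection", sectionId = sectionId, animalId = animalId,
      regions = read.csv(file.path(dir, "regions.csv")),
      nuclei = read.csv(file.path(dir, "nuclei.csv")),
      puncta = read.csv(file.path(dir, "puncta.csv")))
}

#' Write calcium recordings as a long-format CSV
#'
#' Columns: cell_id, region, condition, t_s, F.
#'
#' @param recordings list of \code{\linkS4class{CalciumRecording}}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeTraces <- function(recordings, file) {
  rows <- lapply(recordings, function(rec) {
    t <- (seq_along(rec@fluorescence) - 1) / rec@samplingRate
    data.frame(cell_id = rec@cellId, region = rec@region,
               condition = rec@condition, t_s = t,
               F = rec@fluorescence)
  })
  write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}

#' Read calcium recordings from a long-format CSV
#'
#' The sampling rate is recovered from the median time step of each
#' trace; the duration from the sample count over the rate.
#'
#' @param file CSV with columns cell_id, region, condition, t_s, F.
#' @return list of \code{\linkS4class{CalciumRecording}}.
#' @export
readTraces <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  keys <- unique(df[, c("cell_id", "region", "condition")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$cell_id == keys$cell_id[i] &
                df$condition == keys$condition[i], ]
    sub <- sub[order(sub$t_s), ]
    rate <- 1 / median(diff(sub$t_s))
    new("CalciumRecording", cellId = as.character(keys$cell_id[i]),
        region = as.character(keys$region[i]),
        condition = as.character(keys$condition[i]),
        samplingRate = rate, fluorescence = sub$F,
        duration = length(sub$F) / rate)
  })
}
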