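#' Astrocyte subtype marker fingerprint
#'
#' The default subtype-by-marker expression-class table used by the
#' synthetic generator and documented alongside the classification rules.
#' Entries are \code{"high"} (the marker is highly expressed in that
#' subtype) or \code{"low"} (absent/low). The rows are the five astrocyte
#' subtypes AST1-AST5; the columns are the eight in situ marker genes:
#' the pan-astrocytic marker Slc1a3 (GLAST, high in every subtype) plus
#' Gfap, Agt, Unc13c, Frzb, Ascl1, Ogt and Fam107a. The calls relevant to
#' classification follow the published mapping (AST1: Gfap/Agt high;
#' AST2: Unc13c high, Agt low; AST3: Agt high, Gfap and Unc13c low;
#' AST4: Frzb/Ascl1 high; AST5: Fam107a high, Ogt low); the remaining
#' cells are synthetic fills chosen to keep the table consistent with the
#' rule table under its stated precedence.
#'
#' @return character matrix (5 subtypes x 8 genes) of "high"/"low" calls.
#' @seealso \code{\link{subtypeRules}}
#' @export
#' @examples
#' defaultFingerprint()["AST4", c("Frzb", "Ascl1", "Slc1a3")]
defaultFingerprint <- function() {
  genes <- c("Slc1a3", "Gfap", "Agt", "Unc13c", "Frzb", "Ascl1", "Ogt",
             "Fam107a")
  fp <- matrix("low", nrow = 5, ncol = length(genes),
               dimnames = list(paste0("AST", 1:5), genes))
  fp[, "Slc1a3"] <- "high"
  fp["AST1", c("Gfap", "Agt", "Ogt")] <- "high"
  fp["AST2", c("Unc13c", "Ogt")] <- "high"
  fp["AST3", c("Agt", "Ogt")] <- "high"
  fp["AST4", c("Frzb", "Ascl1", "Ogt")] <- "high"
  fp["AST5", "Fam107a"] <- "high"
  fp
}

#' Subtype classification rule table
#'
#' The ordered marker-colocalization rules mapping per-gene "+"/"-" calls
#' to astrocyte subtypes. Rules are evaluated in order, specific
#' progenitor-type rules before the broader mature-astrocyte rules:
#' AST4 (Frzb+, Ascl1+, Slc1a3+), AST5 (Ogt-, Fam107a+, Slc1a3+),
#' AST1 (Gfap+, Agt+, Slc1a3+), AST2 (Agt-, Unc13c+, Slc1a3+), and
#' AST3 (Agt+, Slc1a3+ with a split clause: Gfap- when stained with
#' panel A, Unc13c- with panel B). The split clause reflects the
#' three-channel limit of the original stainings, which forced AST3 to be
#' mapped with two complementary probe panels.
#'
#' @return a \code{\link{SubtypeRuleTable}}.
#' @seealso \code{\link{classifySubtype}}, \code{\link{markerPanels}}
#' @export
#' @examples
#' subtypeRules()
subtypeRules <- function() {
  new("SubtypeRuleTable", rules = list(
    AST4 = list(requires = c(Frzb = "+", Ascl1 = "+", Slc1a3 = "+")),
    AST5 = list(requires = c(Ogt = "-", Fam107a = "+", Slc1a3 = "+")),
    AST1 = list(requires = c(Gfap = "+", Agt = "+", Slc1a3 = "+")),
    AST2 = list(requires = c(Agt = "-", Unc13c = "+", Slc1a3 = "+")),
    AST3 = list(requires = c(Agt = "+", Slc1a3 = "+"),
                split = list(A = c(Gfap = "-"), B = c(Unc13c = "-")))
  ))
}

#' Probe panels for the split-staining design
#'
#' The two three-channel probe panels used for the split mapping of AST3
#' (panel A: Gfap/Agt/Slc1a3; panel B: Unc13c/Agt/Slc1a3), plus the
#' \code{"full"} panel covering every fingerprint marker, which is
#' available for synthetic sections.
#'
#' @return named list of character vectors of gene names.
#' @export
markerPanels <- function() {
  list(
    A = c("Gfap", "Agt", "Slc1a3"),
    B = c("Unc13c", "Agt", "Slc1a3"),
    full = colnames(defaultFingerprint())
  )
}

#' Marker panels for higher-order cell typing
#'
#' Canonical marker genes used to assign clusters of the full single-cell
#' mixture to higher-order CNS cell types before astrocyte extraction.
#'
#' @return named list celltype -> character vector of marker genes.
#' @seealso \code{\link{assignHigherOrderTypes}}
#' @export
higherOrderPanels <- function() {
  list(
    astrocyte = c("Slc1a3", "Aqp4", "Gja1"),
    oligodendrocyte = c("Plp1", "Mbp", "Mog"),
    OPC = c("Pdgfra", "Cspg4"),
    microglia = c("C1qa", "Cx3cr1", "Csf1r"),
    endothelial = c("Cldn5", "Flt1"),
    neuron = c("Snap25", "Rbfox3", "Syt1")
  )
}
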