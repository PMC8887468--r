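#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowRanges
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqnames seqlengths seqlevels
#' @importFrom stats median quantile var sd rnbinom rpois rbinom runif rlnorm
#'   pchisq pnorm pt chisq.test wilcox.test t.test p.adjust setNames lowess
#'   cor dist hclust complete.cases aggregate rnorm approx
#' @importFrom utils head tail packageVersion
NULL

.VALUE_KINDS <- c("rpkm", "log2_norm", "group_mean")

#' Configuration of the synthetic oocyte-epigenome simulation
#'
#' Holds every parameter of the seeded multi-omic simulation: genome
#' geometry, annotation density, planted effect counts and sizes,
#' sequencing depths, and the negative-binomial overdispersion used for
#' count sampling. The defaults are the study conditions of the package:
#' a 4 x 5 Mb toy genome with 400 genes, 3 replicates per group, 3-fold
#' planted H3K4me3 effects, 40-percentage-point methylation drops at
#' planted hypoDMRs (94% of planted DMRs hypomethylated), and 2.5-fold
#' planted expression changes.
#'
#' @slot nChroms number of chromosomes.
#' @slot chromLength chromosome length in bp.
#' @slot nGenes total number of genes (placed on a uniform slot grid).
#' @slot cpgIslandDensity CpG islands per Mb.
#' @slot nPlantedGainWindows,nPlantedLossWindows planted differential
#'   H3K4me3 5 kb windows (gain / loss in the knockout).
#' @slot nPlantedHypoDmrs,nPlantedHyperDmrs planted 100-CpG differentially
#'   methylated windows (hypo / hyper in the knockout).
#' @slot nPlantedDegDown,nPlantedDegUp planted down/upregulated genes.
#' @slot chipDepth ChIP reads per sample.
#' @slot methDepth mean bisulfite reads per CpG (Poisson).
#' @slot rnaDepth total RNA counts per sample.
#' @slot effectChip fold-change of planted H3K4me3 effects (1 = null).
#' @slot effectMeth percentage-point methylation drop at planted DMRs.
#' @slot effectRna fold-change of planted expression effects (1 = null).
#' @slot nbDispersion negative-binomial dispersion of count sampling.
#' @slot nRepsPerGroup replicates per group.
#' @slot seed integer seed; fully determines all outputs.
#' @export
setClass("SimConfig",
  representation(
    nChroms = "numeric", chromLength = "numeric", nGenes = "numeric",
    cpgIslandDensity = "numeric",
    nPlantedGainWindows = "numeric", nPlantedLossWindows = "numeric",
    nPlantedHypoDmrs = "numeric", nPlantedHyperDmrs = "numeric",
    nPlantedDegDown = "numeric", nPlantedDegUp = "numeric",
    chipDepth = "numeric", methDepth = "numeric", rnaDepth = "numeric",
    effectChip = "numeric", effectMeth = "numeric", effectRna = "numeric",
    nbDispersion = "numeric", nRepsPerGroup = "numeric", seed = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  pos <- c(
    nChroms = object@nChroms, chromLength = object@chromLength,
    nGenes = object@nGenes, chipDepth = object@chipDepth,
    methDepth = object@methDepth, rnaDepth = object@rnaDepth,
    nRepsPerGroup = object@nRepsPerGroup
  )
  if (any(pos <= 0)) {
    msg <- c(msg, paste("must be > 0:", paste(names(pos)[pos <= 0], collapse = ", ")))
  }
  if (object@effectChip < 1) msg <- c(msg, "effectChip must be >= 1 (1 = null simulation)")
  if (object@effectRna < 1) msg <- c(msg, "effectRna must be >= 1 (1 = null simulation)")
  if (object@effectMeth < 0 || object@effectMeth > 100) {
    msg <- c(msg, "effectMeth must be in [0, 100] percentage points")
  }
  if (object@nbDispersion < 0) msg <- c(msg, "nbDispersion must be >= 0")
  if (object@nRepsPerGroup < 2) msg <- c(msg, "nRepsPerGroup must be >= 2")
  if (object@seed != round(object@seed)) msg <- c(msg, "seed must be an integer")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' @param nChroms,chromLength,nGenes,cpgIslandDensity genome geometry.
#' @param nPlantedGainWindows,nPlantedLossWindows,nPlantedHypoDmrs,nPlantedHyperDmrs,nPlantedDegDown,nPlantedDegUp
#'   planted effect counts.
#' @param chipDepth,methDepth,rnaDepth sequencing depths.
#' @param effectChip,effectMeth,effectRna planted effect sizes.
#' @param nbDispersion negative-binomial dispersion.
#' @param nRepsPerGroup replicates per group.
#' @param seed integer seed.
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(seed = 7)
#' cfg
#' @export
simConfig <- function(nChroms = 4, chromLength = 5e6, nGenes = 400,
                      cpgIslandDensity = 40,
                      nPlantedGainWindows = 60, nPlantedLossWindows = 60,
                      nPlantedHypoDmrs = 47, nPlantedHyperDmrs = 3,
                      nPlantedDegDown = 40, nPlantedDegUp = 40,
                      chipDepth = 5e5, methDepth = 10, rnaDepth = 2e6,
                      effectChip = 3, effectMeth = 40, effectRna = 2.5,
                      nbDispersion = 0.05, nRepsPerGroup = 3, seed = 1) {
  new("SimConfig",
    nChroms = nChroms, chromLength = chromLength, nGenes = nGenes,
    cpgIslandDensity = cpgIslandDensity,
    nPlantedGainWindows = nPlantedGainWindows,
    nPlantedLossWindows = nPlantedLossWindows,
    nPlantedHypoDmrs = nPlantedHypoDmrs,
    nPlantedHyperDmrs = nPlantedHyperDmrs,
    nPlantedDegDown = nPlantedDegDown, nPlantedDegUp = nPlantedDegUp,
    chipDepth = chipDepth, methDepth = methDepth, rnaDepth = rnaDepth,
    effectChip = effectChip, effectMeth = effectMeth, effectRna = effectRna,
    nbDispersion = nbDispersion, nRepsPerGroup = nRepsPerGroup,
    seed = seed
  )
}

#' @describeIn simConfig a null configuration: same geometry, all planted
#'   effects at their neutral value (no true differences).
#' @param ... passed to \code{simConfig}.
#' @export
nullSimConfig <- function(...) {
  simConfig(effectChip = 1, effectMeth = 0, effectRna = 1, ...)
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d x %.1f Mb genome, %d genes, %d islands/Mb\n",
    object@nChroms, object@chromLength / 1e6, object@nGenes,
    object@cpgIslandDensity
  ))
  cat(sprintf(
    "  planted: %d gain / %d loss windows, %d hypo / %d hyper DMRs, %d down / %d up DEGs\n",
    object@nPlantedGainWindows, object@nPlantedLossWindows,
    object@nPlantedHypoDmrs, object@nPlantedHyperDmrs,
    object@nPlantedDegDown, object@nPlantedDegUp
  ))
  cat(sprintf(
    "  effects: chip x%.2g, meth -%g pts, rna x%.2g; n = %d vs %d; seed %d\n",
    object@effectChip, object@effectMeth, object@effectRna,
    object@nRepsPerGroup, object@nRepsPerGroup, as.integer(object@seed)
  ))
})

#' Windows-by-samples quantitation matrix
#'
#' A \linkS4class{RangedSummarizedExperiment} whose rows are genomic
#' windows and whose single assay \code{"values"} holds per-(window,
#' sample) quantitation, with value-kind provenance: \code{"rpkm"} (reads
#' per kb per million mapped reads), \code{"log2_norm"}
#' (enrichment-normalized log2 RPKM) or \code{"group_mean"} (per-group
#' averages of normalized values). Library sizes travel in
#' \code{colData()$librarySize}.
#'
#' @seealso \code{\link{quantifyRpkm}}, \code{\link{enrichmentNormalize}},
#'   \code{\link{averageReplicates}}
#' @export
setClass("QuantMatrix", contains = "RangedSummarizedExperiment")

setValidity("QuantMatrix", function(object) {
  msg <- character()
  if (!"values" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'values' is required")
  }
  kind <- S4Vectors::metadata(object)$valueKind
  if (is.null(kind) || !kind %in% .VALUE_KINDS) {
    msg <- c(msg, sprintf("metadata()$valueKind must be one of %s",
                          paste(.VALUE_KINDS, collapse = ", ")))
  } else if (kind == "rpkm") {
    v <- SummarizedExperiment::assay(object, "values")
    if (any(v < 0, na.rm = TRUE)) msg <- c(msg, "rpkm values must be >= 0")
    if (!"librarySize" %in% colnames(SummarizedExperiment::colData(object))) {
      msg <- c(msg, "colData()$librarySize is required for rpkm matrices")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a QuantMatrix
#'
#' @param values numeric matrix, windows x samples.
#' @param windows \code{GRanges} of the windows (rowRanges); names become
#'   window ids.
#' @param valueKind one of \code{"rpkm"}, \code{"log2_norm"},
#'   \code{"group_mean"}.
#' @param librarySizes optional named numeric, reads per sample.
#' @return A \linkS4class{QuantMatrix}.
#' @export
QuantMatrix <- function(values, windows, valueKind,
                        librarySizes = NULL) {
  if (is.null(colnames(values))) {
    stop("values must have sample names as colnames")
  }
  cd <- S4Vectors::DataFrame(row.names = colnames(values))
  if (!is.null(librarySizes)) {
    cd$librarySize <- unname(librarySizes[colnames(values)])
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = values), rowRanges = windows, colData = cd
  )
  S4Vectors::metadata(se)$valueKind <- valueKind
  new("QuantMatrix", se)
}

#' @describeIn QuantMatrix the value-kind provenance tag.
#' @param x a \code{QuantMatrix}.
#' @export
valueKind <- function(x) S4Vectors::metadata(x)$valueKind

#' @describeIn QuantMatrix per-sample library sizes (mapped reads).
#' @export
librarySizes <- function(x) {
  setNames(SummarizedExperiment::colData(x)$librarySize, colnames(x))
}

#' @describeIn QuantMatrix the quantitation matrix itself.
#' @export
quantValues <- function(x) SummarizedExperiment::assay(x, "values")

setMethod("show", "QuantMatrix", function(object) {
  cat(sprintf(
    "QuantMatrix: %d windows x %d samples [%s]\n",
    nrow(object), ncol(object), valueKind(object)
  ))
  cat("  samples:", paste(colnames(object), collapse = ", "), "\n")
})
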