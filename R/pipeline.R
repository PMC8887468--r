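#' Run the full synthetic-study pipeline
#'
#' Simulates the multi-omic dataset under \code{config}, then runs the
#' complete analysis: 5 kb window RPKM quantitation, artifact filtering by
#' input RPKM, enrichment normalization, moderated-t differential window
#' calling; 100-CpG window construction with the informative-coverage
#' filter and logistic-regression DMR calling; size-factor normalization
#' and negative-binomial DEG calling; promoter classification;
#' dinucleotide composition of gain/loss/random window sets; cross-layer
#' overlap enrichment; promoter H3K4me3 profiles over DEG sets; the
#' methylation-timing comparison; and recovery statistics against the
#' planted truth.
#'
#' The artifact threshold defaults to 10.8x the genome's flat-coverage
#' RPKM (1e6 / genome length in kb), which reproduces the conventional
#' "input RPKM > 4" exclusion at mammalian genome scale while staying
#' meaningful on toy genomes.
#'
#' @param config a \linkS4class{SimConfig}; its seed drives everything.
#' @param alpha adjusted-p threshold used by all three callers.
#' @param artifactRpkm input-RPKM exclusion threshold; \code{NULL} for the
#'   genome-scaled default.
#' @param outDir optional directory; when given, result tables are written
#'   as TSV/BED and a manifest is assembled via \code{\link{runReport}}.
#' @return list of class \code{"StudyRun"} with the simulation, all
#'   intermediate objects, result tables and a \code{recovery} list of
#'   sensitivity/FDR/direction statistics per caller.
#' @export
runStudyPipeline <- function(config = simConfig(), alpha = 0.05,
                             artifactRpkm = NULL, outDir = NULL) {
  sim <- simulateOocyteEpigenome(config)
  n <- config@nRepsPerGroup
  groups <- factor(rep(c("wt", "ko"), each = n), levels = c("wt", "ko"))

  ## --- ChIP layer ---
  windows <- sim$chip$windows
  chipSamples <- names(sim$chip$reads)[!startsWith(names(sim$chip$reads), "input")]
  inputSamples <- setdiff(names(sim$chip$reads), chipSamples)
  qmAll <- quantifyRpkm(sim$chip$reads, windows)
  qmChip <- qmAll[, chipSamples]
  qmInput <- qmAll[, inputSamples]
  if (is.null(artifactRpkm)) {
    genomeKb <- sum(sim$chromSizes) / 1000
    artifactRpkm <- 10.8 * 1e6 / genomeKb
  }
  valid <- filterArtifactWindows(windows, qmInput, artifactRpkm)
  qc <- qcSignalToNoise(qmChip, qmInput)
  qmValid <- qmChip[names(valid), ]
  qmNorm <- enrichmentNormalize(qmValid)
  diffCalls <- callDifferentialWindows(qmNorm, groups, alpha)
  gains <- diffCallRanges(diffCalls, "gain")
  losses <- diffCallRanges(diffCalls, "loss")
  nRand <- max(length(gains) + length(losses), 100L)
  randomWindows <- sampleRandomWindows(valid, min(nRand, length(valid)),
                                       subSeed(config@seed, 11L))

  ## --- methylation layer ---
  cpgWindows <- makeCpgWindows(sim$cpgs, sim$meth$calls, 100, 10)
  wm <- windowMethylation(sim$meth$calls, cpgWindows)
  dmrCalls <- dmrLogisticTest(wm$meth, wm$unmeth, groups, alpha, 20)
  hypoWindows <- cpgWindows[dmrCalls$id[dmrCalls$direction == "hypo"]]

  ## --- expression layer ---
  counts <- sim$rna$counts
  degCalls <- nbDegTest(counts, groups, alpha, 2)
  genes <- sim$annotations$genes
  fpkmMat <- fpkm(counts, setNames(genes$exonLength, genes$gene_id)[rownames(counts)])
  fpkmWt <- rowMeans(fpkmMat[, groups == "wt", drop = FALSE])

  ## --- integration ---
  promClasses <- classifyPromoters(genes, fpkmWt, sim$annotations$h3k27ac,
                                   sim$annotations$h3k27me3,
                                   sim$annotations$methDomains)
  promEnrich <- promoterOverlapEnrichment(gains, losses, promClasses, genes,
                                          randomWindows)
  dmrOverlap <- dmrH3k4me3Overlap(gains, losses, dmrCalls, cpgWindows)
  degSets <- list(
    down = degCalls$id[degCalls$direction == "down"],
    up = degCalls$id[degCalls$direction == "up"],
    notDeg = degCalls$id[degCalls$direction == "none" & !degCalls$skipped]
  )
  promProfile <- promoterH3k4me3Profile(degSets, qmNorm, groups, genes)
  oogEnrich <- if (length(degSets$down) > 0) {
    geneSetFoldEnrichment(degSets$down, sim$truth$oogenesisUp,
                          rownames(counts))
  } else NULL

  background <- genomeBackgroundDimers(sim$genome)
  comp <- list(
    gain = if (length(gains)) dimerComposition(gains, sim$genome, background) else NULL,
    loss = if (length(losses)) dimerComposition(losses, sim$genome, background) else NULL,
    random = dimerComposition(randomWindows, sim$genome, background)
  )
  cgTest <- if (length(gains) >= 2) {
    cpgContentTest(gains, randomWindows, sim$genome, background)
  } else NULL

  domainBlocks <- cpgWindows[IRanges::overlapsAny(
    cpgWindows, GenomicRanges::reduce(sim$annotations$methDomains), type = "within"
  )]
  timing <- if (length(hypoWindows) > 0 && length(domainBlocks) > 0) {
    randomDomainBlocks <- sampleRandomWindows(
      domainBlocks, min(200L, length(domainBlocks)), subSeed(config@seed, 12L)
    )
    methylationTimingComparison(hypoWindows, randomDomainBlocks, sim$meth$earlier)
  } else NULL

  recovery <- list(
    windows = recoveryStats(diffCalls$id, diffCalls$direction,
                            sim$truth$windowTruth$id, sim$truth$windowTruth$label),
    dmrs = recoveryStats(dmrCalls$id, dmrCalls$direction,
                         sim$truth$dmrTruth$id, sim$truth$dmrTruth$label),
    degs = recoveryStats(degCalls$id, degCalls$direction,
                         sim$truth$geneTruth$gene_id, sim$truth$geneTruth$label)
  )

  out <- list(
    sim = sim, config = config, groups = groups,
    windows = windows, valid = valid, qc = qc,
    qmChip = qmChip, qmInput = qmInput, qmNorm = qmNorm,
    diffCalls = diffCalls, gains = gains, losses = losses,
    randomWindows = randomWindows,
    cpgWindows = cpgWindows, windowMeth = wm, dmrCalls = dmrCalls,
    degCalls = degCalls, fpkmWt = fpkmWt,
    promClasses = promClasses, promEnrich = promEnrich,
    dmrOverlap = dmrOverlap, promProfile = promProfile,
    oogEnrich = oogEnrich, composition = comp, cgTest = cgTest,
    timing = timing, recovery = recovery
  )
  class(out) <- c("StudyRun", "list")
  if (!is.null(outDir)) writeStudyRun(out, outDir)
  out
}

# Sensitivity / observed FDR / direction concordance of calls vs planted
# truth; direction labels pair up as gain/hyper/up vs loss/hypo/down.
recoveryStats <- function(callIds, callDir, truthIds, truthLabel) {
  truth <- setNames(truthLabel, truthIds)[callIds]
  truth[is.na(truth)] <- "null"
  called <- callDir != "none"
  positive <- truth != "null"
  tp <- sum(called & positive)
  fp <- sum(called & !positive)
  dirMatch <- if (tp > 0) {
    callMapped <- callDir[called & positive]
    truthPos <- truth[called & positive]
    mean((callMapped %in% c("gain", "hyper", "up") & truthPos %in% c("gain", "hyper", "up")) |
         (callMapped %in% c("loss", "hypo", "down") & truthPos %in% c("loss", "hypo", "down")))
  } else NA_real_
  list(
    nTested = length(callIds), nTruePositiveUniverse = sum(positive),
    nCalled = sum(called), tp = tp, fp = fp,
    sensitivity = if (sum(positive) > 0) tp / sum(positive) else NA_real_,
    fdr = if (sum(called) > 0) fp / sum(called) else 0,
    directionConcordance = dirMatch,
    fractionCalled = mean(called)
  )
}

#' Write pipeline result tables
#'
#' @param run a \code{StudyRun}.
#' @param dir output directory.
#' @return the manifest from \code{\link{runReport}}, invisibly.
#' @export
writeStudyRun <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) {
    data.table::fwrite(data.table::as.data.table(df), file.path(dir, f),
                       sep = "\t")
  }
  wr(run$diffCalls, "diff_windows.tsv")
  dmr <- run$dmrCalls
  cw <- run$cpgWindows[match(dmr$id, names(run$cpgWindows))]
  dmr$chrom <- as.character(GenomeInfoDb::seqnames(cw))
  dmr$start <- GenomicRanges::start(cw)
  dmr$end <- GenomicRanges::end(cw)
  wr(dmr, "dmr_calls.tsv")
  wr(run$degCalls, "deg_calls.tsv")
  wr(run$promClasses, "promoter_classes.tsv")
  wr(run$promEnrich, "overlap_enrichment.tsv")
  profiles <- data.table::data.table(dimer = .DIMERS)
  for (nm in names(run$composition)) {
    if (!is.null(run$composition[[nm]])) {
      profiles[[nm]] <- run$composition[[nm]]$profile[.DIMERS]
    }
  }
  data.table::fwrite(profiles, file.path(dir, "dimer_profiles.tsv"), sep = "\t")
  if (length(run$gains)) writeBed(run$gains, file.path(dir, "gain_windows.bed"))
  if (length(run$losses)) writeBed(run$losses, file.path(dir, "loss_windows.bed"))
  cfg <- run$config
  cfgList <- setNames(
    lapply(slotNames(cfg), function(s) slot(cfg, s)), slotNames(cfg)
  )
  jsonlite::write_json(
    c(cfgList, list(alpha = 0.05, windowSize = 5000, nCpgWindow = 100,
                    minInformative = 10, minDiffPercent = 20,
                    promoterHalf = 500)),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(runReport(dir))
}
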