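# Deterministic layout of the toy genome: genes sit on a uniform slot
# grid (one gene per slot); a fixed 60% of slots carry a CpG-island
# promoter; slot patterns assign expression classes so that CpG-poor
# active promoters (loss candidates) and CpG-rich inactive promoters
# (gain candidates) are both plentiful.
slotLayout <- function(config) {
  slotsPerChrom <- floor(config@nGenes / config@nChroms)
  stopifnot2(slotsPerChrom >= 1, "nGenes must be >= nChroms")
  slotSize <- floor(config@chromLength / slotsPerChrom)
  stopifnot2(slotSize >= 45000,
             "chromLength too small for the requested genes: need >= 45 kb per gene slot")
  chroms <- sprintf("chr%d", seq_len(config@nChroms))
  grid <- expand.grid(slot = seq_len(slotsPerChrom), chrom = chroms,
                      stringsAsFactors = FALSE)
  grid$slotStart <- (grid$slot - 1L) * slotSize + 1L
  # TSS centered in its 5 kb analysis tile so the promoter island
  # falls entirely within one window
  grid$tss <- grid$slotStart + 12499L
  grid$island <- (grid$slot %% 5L) < 3L
  islPat <- c("active", "inactive", "active", "weak", "active", "inactive")
  nonPat <- c("active", "active", "active", "inactive")
  grid$class <- ifelse(grid$island,
                       islPat[(grid$slot %% 6L) + 1L],
                       nonPat[(grid$slot %% 4L) + 1L])
  grid$gene_id <- sprintf("g%04d", seq_len(nrow(grid)))
  list(grid = grid, slotSize = slotSize,
       chromSizes = setNames(rep(config@chromLength, config@nChroms), chroms))
}

#' Generate the toy genome sequence and CpG position list
#'
#' Emits a background sequence of low CpG density (CG dimers are
#' selectively depleted after i.i.d. base sampling, mimicking the
#' CpG-depleted bulk of a mammalian genome) punctuated by CpG-rich
#' islands: one at each island-promoter slot plus intergenic islands up to
#' the configured density. The CpG list is exactly the CG dimer positions
#' of the emitted sequence. Deterministic per seed.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list with \code{genome} (\code{DNAStringSet}), \code{cpgs}
#'   (\code{GRanges} of CG dimers, width 2), \code{islands}
#'   (\code{GRanges}), \code{chromSizes}.
#' @export
generateGenome <- function(config) {
  layout <- slotLayout(config)
  grid <- layout$grid
  chromSizes <- layout$chromSizes
  nIslPerChrom <- round(config@cpgIslandDensity * config@chromLength / 1e6)
  withSeed(subSeed(config@seed, 1L), {
    chromSeqs <- list()
    islandList <- list()
    patchList <- list()
    for (ch in names(chromSizes)) {
      len <- chromSizes[[ch]]
      s <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                  prob = c(0.29, 0.21, 0.21, 0.29))
      g <- grid[grid$chrom == ch, ]
      promIsl <- head(g$tss[g$island], nIslPerChrom)
      isl <- IRanges::IRanges(start = promIsl - 500L, width = 1001L)
      nInter <- nIslPerChrom - length(promIsl)
      if (nInter > 0) {
        off1 <- floor(layout$slotSize * 0.8)
        off2 <- floor(layout$slotSize * 0.9)
        cand <- c(g$slotStart + off1, g$slotStart + off2)
        if (nInter > length(cand)) {
          stop("chromLength too small to place the requested islands", call. = FALSE)
        }
        isl <- c(isl, IRanges::IRanges(start = sort(cand)[seq_len(nInter)],
                                       width = 801L))
      }
      isl <- IRanges::restrict(isl, start = 1L, end = len)
      # CpG-rich "orphan" patch inside every gene body (at slot + 20 kb):
      # unannotated CpG-dense sequence that ends up inside methylated
      # domains, the substrate for planted hypoDMRs and H3K4me3 gains.
      # An island density of 0 disables all CpG-rich segments (flat genome).
      patches <- if (nIslPerChrom > 0) {
        IRanges::restrict(
          IRanges::IRanges(start = g$slotStart + 20000L, width = 1000L),
          start = 1L, end = len
        )
      } else IRanges::IRanges()
      rich <- c(isl, patches)
      for (k in seq_along(rich)) {
        i0 <- IRanges::start(rich)[k]; i1 <- IRanges::end(rich)[k]
        s[i0:i1] <- sample(c("A", "C", "G", "T"), i1 - i0 + 1L, replace = TRUE,
                           prob = c(0.225, 0.275, 0.275, 0.225))
      }
      # deplete CG dimers outside CpG-rich segments (keep ~40% of them)
      cg <- which(s[-len] == "C" & s[-1L] == "G")
      inIsl <- IRanges::overlapsAny(IRanges::IRanges(cg, width = 2L), rich)
      cg <- cg[!inIsl]
      drop <- cg[runif(length(cg)) < 0.6]
      if (length(drop)) {
        s[drop + 1L] <- sample(c("A", "T"), length(drop), replace = TRUE)
      }
      chromSeqs[[ch]] <- paste(s, collapse = "")
      islandList[[ch]] <- GenomicRanges::GRanges(rep(ch, length(isl)), isl)
      patchList[[ch]] <- GenomicRanges::GRanges(rep(ch, length(patches)), patches)
    }
  })
  genome <- Biostrings::DNAStringSet(unlist(chromSeqs))
  names(genome) <- names(chromSizes)
  cpgHits <- Biostrings::vmatchPattern("CG", genome)
  cpgs <- GenomicRanges::GRanges(
    rep(names(genome), lengths(cpgHits)),
    IRanges::IRanges(start = unlist(lapply(cpgHits, IRanges::start)), width = 2L)
  )
  GenomeInfoDb::seqlengths(cpgs) <- chromSizes
  islands <- do.call(c, unname(islandList))
  patches <- do.call(c, unname(patchList))
  list(genome = genome, cpgs = cpgs, islands = islands,
       cpgRichPatches = patches, chromSizes = chromSizes)
}

#' Generate gene models, chromatin features and the planted-effect plan
#'
#' Places one gene per slot (transcribed left to right), assigns expression
#' classes and FPKM values, and derives the feature annotation the
#' analysis consumes: H3K27ac at active promoters, H3K27me3 at inactive
#' CpG-island promoters, and a DNA methylated domain over each transcribed
#' (active) gene body, a configured fraction of which are flagged
#' "late-methylating". Also draws the full planted-effect plan: loss
#' windows at active CpG-poor promoters; gain windows at inactive CpG-rich
#' promoters and (co-planted with hypoDMRs) inside late-methylating
#' domains; hyper DMRs in unmethylated territory; down-DEGs preferentially
#' from the oogenesis-upregulated set and from loss-window genes; up-DEGs
#' with no H3K4me3 change.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param genomeData result of \code{\link{generateGenome}}.
#' @return list: \code{genes} (GRanges with gene_id/tss/exonLength/class/
#'   islandPromoter/fpkm), \code{h3k27ac}, \code{h3k27me3},
#'   \code{methDomains} (with \code{late} flag), \code{promoterTruth},
#'   \code{oogenesisUp}, \code{cpgBlocks}, and \code{plan} (planted ids).
#' @export
generateAnnotations <- function(config, genomeData) {
  layout <- slotLayout(config)
  grid <- layout$grid
  withSeed(subSeed(config@seed, 2L), {
    geneLen <- sample(15000:25000, nrow(grid), replace = TRUE)
    genes <- GenomicRanges::GRanges(
      grid$chrom, IRanges::IRanges(grid$tss, grid$tss + geneLen - 1L),
      strand = "+"
    )
    GenomeInfoDb::seqlengths(genes) <- layout$chromSizes
    S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
      gene_id = grid$gene_id, tss = grid$tss,
      exonLength = geneLen, class = grid$class
    )
    names(genes) <- grid$gene_id
    S4Vectors::mcols(genes)$islandPromoter <- IRanges::overlapsAny(
      promoterRanges(genes), genomeData$islands
    )

    # FPKM: actives lognormal, rescaled so the genome-wide sum of
    # FPKM x length(kb) equals 1e6 (the FPKM self-consistency identity),
    # making measured FPKM from simulated counts match these values.
    fpkm <- numeric(nrow(grid))
    act <- grid$class == "active"
    wk <- grid$class == "weak"
    inact <- grid$class == "inactive"
    fpkm[act] <- rlnorm(sum(act), meanlog = 2, sdlog = 0.8)
    fpkm[wk] <- runif(sum(wk), 0.15, 0.9)
    fpkm[inact] <- runif(sum(inact), 0.001, 0.05)
    lenKb <- geneLen / 1000
    budget <- 1e6 - sum(fpkm[!act] * lenKb[!act])
    fpkm[act] <- fpkm[act] * budget / sum(fpkm[act] * lenKb[act])
    S4Vectors::mcols(genes)$fpkm <- fpkm

    prom <- promoterRanges(genes)
    h3k27ac <- unname(prom[act])
    me3Pool <- which(inact & grid$island)
    me3Idx <- sort(sample(me3Pool, round(0.7 * length(me3Pool))))
    h3k27me3 <- unname(prom[me3Idx])
    methDomains <- GenomicRanges::GRanges(
      grid$chrom[act],
      IRanges::IRanges(grid$tss[act] + 1000L, GenomicRanges::end(genes)[act])
    )
    S4Vectors::mcols(methDomains)$gene_id <- grid$gene_id[act]
    S4Vectors::mcols(methDomains)$late <- FALSE
    lateIdx <- sample(length(methDomains), round(0.35 * length(methDomains)))
    S4Vectors::mcols(methDomains)$late[lateIdx] <- TRUE

    blocks <- cpgBlocks(genomeData$cpgs, 100)

    # planted loss windows: active CpG-poor promoters
    islandProm <- S4Vectors::mcols(genes)$islandPromoter
    lossPool <- grid$gene_id[act & !islandProm]
    stopifnot2(length(lossPool) >= config@nPlantedLossWindows,
               "not enough active CpG-poor promoters for the requested loss windows")
    lossGenes <- sort(sample(lossPool, config@nPlantedLossWindows))

    # planted gain windows, half at inactive CpG-island promoters ...
    gainPromPool <- grid$gene_id[inact & islandProm]
    nGainProm <- min(ceiling(config@nPlantedGainWindows / 2), length(gainPromPool))
    nGainDomain <- config@nPlantedGainWindows - nGainProm
    gainPromGenes <- sort(sample(gainPromPool, nGainProm))

    # ... half inside late-methylating domains, co-planted with hypoDMRs.
    late <- methDomains[S4Vectors::mcols(methDomains)$late]
    patches <- genomeData$cpgRichPatches
    patchHit <- GenomicRanges::findOverlaps(blocks, patches, select = "first")
    onPatch <- !is.na(patchHit)
    within <- GenomicRanges::findOverlaps(blocks[onPatch], late, type = "within")
    candIdx <- which(onPatch)[S4Vectors::queryHits(within)]
    candDomain <- S4Vectors::subjectHits(within)
    domTss <- grid$tss[match(S4Vectors::mcols(late)$gene_id[candDomain], grid$gene_id)]
    # the gain tile is the 5 kb window holding the CpG-rich patch the
    # hypoDMR block sits on (patches are tile-aligned by construction)
    patchStart <- GenomicRanges::start(patches)[patchHit[candIdx]]
    tileStart <- floor((patchStart - 1) / 5000) * 5000 + 1
    ok <- tileStart > domTss
    candIdx <- candIdx[ok]; candDomain <- candDomain[ok]; tileStart <- tileStart[ok]
    keep <- !duplicated(candDomain) & !duplicated(tileStart)
    candIdx <- candIdx[keep]; tileStart <- tileStart[keep]
    candChrom <- as.character(GenomeInfoDb::seqnames(blocks))[candIdx]
    nHypo <- config@nPlantedHypoDmrs
    stopifnot2(length(candIdx) >= max(nGainDomain, nHypo),
               "not enough CpG blocks inside late-methylating domains for the requested plantings")
    pick <- sample(length(candIdx), nHypo)
    hypoBlocks <- names(blocks)[candIdx[pick]]
    gainSel <- pick[seq_len(nGainDomain)]
    gainDomainTiles <- GenomicRanges::GRanges(
      candChrom[gainSel],
      IRanges::IRanges(tileStart[gainSel],
                       pmin(tileStart[gainSel] + 4999, config@chromLength))
    )

    # hyper DMRs: blocks in unmethylated (non-domain) territory
    outside <- which(!IRanges::overlapsAny(blocks, methDomains))
    stopifnot2(length(outside) >= config@nPlantedHyperDmrs,
               "not enough unmethylated CpG blocks for the requested hyper DMRs")
    hyperBlocks <- names(blocks)[sort(sample(outside, config@nPlantedHyperDmrs))]

    # oogenesis-upregulated set: half the active genes (capped at 120),
    # seeded with two thirds of the loss-window genes so that downs drawn
    # from it overlap promoters losing H3K4me3.
    activeIds <- grid$gene_id[act]
    nOog <- min(120L, round(0.5 * length(activeIds)))
    fromLoss <- sample(lossGenes, min(round(2 / 3 * length(lossGenes)), nOog))
    oogenesisUp <- sort(c(
      fromLoss,
      sample(setdiff(activeIds, lossGenes), nOog - length(fromLoss))
    ))
    # take up to n ids walking a priority list of candidate pools
    pickFrom <- function(pools, n) {
      out <- character()
      for (p in pools) {
        p <- setdiff(p, out)
        take <- min(n - length(out), length(p))
        if (take > 0) out <- c(out, sample(p, take))
        if (length(out) >= n) break
      }
      stopifnot2(length(out) >= n, "not enough genes to plant the requested DEGs")
      out
    }
    nDown <- config@nPlantedDegDown
    dLoss <- sample(intersect(lossGenes, oogenesisUp),
                    min(round(nDown * 0.625), length(fromLoss), nDown))
    degDown <- sort(c(dLoss, pickFrom(list(
      setdiff(oogenesisUp, lossGenes),
      setdiff(activeIds, c(oogenesisUp, lossGenes, gainPromGenes))
    ), nDown - length(dLoss))))
    degUp <- sort(pickFrom(list(
      setdiff(activeIds, c(lossGenes, oogenesisUp, degDown)),
      setdiff(activeIds, c(lossGenes, degDown))
    ), config@nPlantedDegUp))
  })
  promoterTruth <- data.frame(gene_id = grid$gene_id, class = grid$class,
                              stringsAsFactors = FALSE)
  list(
    genes = genes, h3k27ac = h3k27ac, h3k27me3 = h3k27me3,
    methDomains = methDomains, islands = genomeData$islands,
    promoterTruth = promoterTruth, oogenesisUp = oogenesisUp,
    cpgBlocks = blocks,
    plan = list(
      lossGenes = lossGenes, gainPromGenes = gainPromGenes,
      gainDomainTiles = gainDomainTiles,
      hypoBlocks = hypoBlocks, hyperBlocks = hyperBlocks,
      degDown = degDown, degUp = degUp
    )
  )
}

# Planted gain/loss 5 kb tiles as window names of `windows`.
plannedChipTiles <- function(windows, annotations) {
  genes <- annotations$genes
  plan <- annotations$plan
  tileOfTss <- function(ids) {
    g <- genes[match(ids, genes$gene_id)]
    tss <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(g),
                                  IRanges::IRanges(g$tss, width = 1L))
    idx <- GenomicRanges::findOverlaps(tss, windows, select = "first")
    names(windows)[idx]
  }
  loss <- tileOfTss(plan$lossGenes)
  gainProm <- tileOfTss(plan$gainPromGenes)
  mid <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(plan$gainDomainTiles),
    IRanges::IRanges(floor((GenomicRanges::start(plan$gainDomainTiles) +
                            GenomicRanges::end(plan$gainDomainTiles)) / 2), width = 1L)
  )
  gainDom <- names(windows)[GenomicRanges::findOverlaps(mid, windows, select = "first")]
  list(gain = unique(c(gainProm, gainDom)), loss = unique(loss))
}

#' Simulate ChIP and input read intervals
#'
#' Per-window expected intensity = background + a broad-domain term
#' (proportional to the window's CpG count on unmethylated sequence; the
#' monotone CpG-density relationship is a modeling assumption) + a
#' promoter term (log-scaled FPKM of any TSS in the window). Knockout
#' samples multiply planted loss windows by 1/effectChip and gain windows
#' by effectChip; read counts are negative-binomial with the configured
#' dispersion and reads are 75 bp single-end intervals placed uniformly in
#' their window. Input samples draw from a flat intensity with a few
#' spiked artifact windows (to exercise the input-RPKM exclusion rule).
#'
#' @param config a \linkS4class{SimConfig}.
#' @param annotations from \code{\link{generateAnnotations}}.
#' @param genomeData from \code{\link{generateGenome}}.
#' @return list: \code{reads} (named list of GRanges: wt*/ko* replicates
#'   and input_wt/input_ko), \code{windows} (the 5 kb tiling),
#'   \code{windowTruth} (data.frame id/label), \code{lambda} (WT expected
#'   intensities), \code{artifactWindows}.
#' @export
simulateChipReads <- function(config, annotations, genomeData) {
  windows <- makeRunningWindows(genomeData$chromSizes, 5000)
  nCpgW <- GenomicRanges::countOverlaps(windows, genomeData$cpgs)
  cov <- GenomicRanges::intersect(windows, GenomicRanges::reduce(annotations$methDomains),
                                  ignore.strand = TRUE)
  ovM <- GenomicRanges::findOverlaps(windows, cov)
  methBp <- rep(0, length(windows))
  if (length(ovM)) {
    pw <- GenomicRanges::width(GenomicRanges::pintersect(
      windows[S4Vectors::queryHits(ovM)], cov[S4Vectors::subjectHits(ovM)]
    ))
    agg <- tapply(pw, S4Vectors::queryHits(ovM), sum)
    methBp[as.integer(names(agg))] <- agg
  }
  unmethFrac <- 1 - methBp / GenomicRanges::width(windows)
  genes <- annotations$genes
  tss <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes),
                                IRanges::IRanges(genes$tss, width = 1L))
  ovT <- GenomicRanges::findOverlaps(tss, windows)
  activity <- rep(0, length(windows))
  if (length(ovT)) {
    aa <- tapply(log2(1 + genes$fpkm[S4Vectors::queryHits(ovT)]),
                 S4Vectors::subjectHits(ovT), sum)
    activity[as.integer(names(aa))] <- aa
  }
  lambda <- 1 + 0.025 * nCpgW * unmethFrac + activity
  tiles <- plannedChipTiles(windows, annotations)
  mult <- rep(1, length(windows))
  names(mult) <- names(windows)
  mult[tiles$gain] <- config@effectChip
  mult[tiles$loss] <- 1 / config@effectChip

  n <- config@nRepsPerGroup
  sampleNames <- c(paste0("wt", seq_len(n)), paste0("ko", seq_len(n)))
  readLen <- 75L
  drawReads <- function(mu) {
    counts <- if (config@nbDispersion > 0) {
      rnbinom(length(mu), size = 1 / config@nbDispersion, mu = mu)
    } else {
      rpois(length(mu), mu)
    }
    i <- rep(seq_along(mu), counts)
    maxStart <- pmax(GenomicRanges::width(windows)[i] - readLen, 1L)
    starts <- GenomicRanges::start(windows)[i] +
      floor(runif(length(i)) * maxStart)
    GenomicRanges::GRanges(as.character(GenomeInfoDb::seqnames(windows))[i],
                           IRanges::IRanges(starts, width = readLen))
  }
  withSeed(subSeed(config@seed, 3L), {
    planted <- names(mult)[mult != 1]
    if (config@effectChip == 1) {
      planted <- c(tiles$gain, tiles$loss)
    }
    artifactPool <- setdiff(names(windows), planted)
    artifactWindows <- sort(sample(artifactPool, min(6L, length(artifactPool))))
    flat <- GenomicRanges::width(windows) / 5000
    flat[match(artifactWindows, names(windows))] <-
      flat[match(artifactWindows, names(windows))] * 25
    reads <- list()
    for (s in sampleNames) {
      isKo <- startsWith(s, "ko")
      lam <- if (isKo) lambda * mult else lambda
      mu <- lam / sum(lam) * config@chipDepth
      if (max(mu) < 1) {
        warning("chipDepth too low: no window reaches expected count >= 1")
      }
      reads[[s]] <- drawReads(mu)
    }
    for (s in c("input_wt", "input_ko")) {
      reads[[s]] <- drawReads(flat / sum(flat) * config@chipDepth)
    }
  })
  label <- rep("null", length(windows))
  names(label) <- names(windows)
  if (config@effectChip > 1) {
    label[tiles$gain] <- "gain"
    label[tiles$loss] <- "loss"
  }
  windowTruth <- data.frame(
    id = names(windows),
    chrom = as.character(GenomeInfoDb::seqnames(windows)),
    start = GenomicRanges::start(windows), end = GenomicRanges::end(windows),
    label = unname(label), stringsAsFactors = FALSE
  )
  list(reads = reads, windows = windows, windowTruth = windowTruth,
       lambda = lambda, artifactWindows = artifactWindows)
}

#' Simulate bisulfite methylomes
#'
#' Per-CpG sequencing depth is Poisson(\code{methDepth}); methylated-domain
#' CpGs have true methylation 87\%, the rest 4\%. Planted hypoDMR blocks
#' reduce knockout methylation by \code{effectMeth} percentage points;
#' planted hyper blocks raise it. Methylated read counts are binomial.
#' An earlier-timepoint methylome is also emitted in which
#' late-methylating domains are still unmethylated.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param annotations from \code{\link{generateAnnotations}}.
#' @param genomeData from \code{\link{generateGenome}}.
#' @return list: \code{calls} (named list of CpG call sets, wt*/ko*),
#'   \code{earlier} (single earlier-timepoint call set), \code{dmrTruth}
#'   (data.frame over all CpG blocks).
#' @export
simulateMethylomes <- function(config, annotations, genomeData) {
  cpgs <- genomeData$cpgs
  pos <- GenomicRanges::start(cpgs)
  chrom <- as.character(GenomeInfoDb::seqnames(cpgs))
  domains <- annotations$methDomains
  inDomain <- IRanges::overlapsAny(cpgs, domains)
  inLate <- IRanges::overlapsAny(cpgs, domains[S4Vectors::mcols(domains)$late])
  pHigh <- 0.87; pLow <- 0.04
  pWt <- ifelse(inDomain, pHigh, pLow)
  blocks <- annotations$cpgBlocks
  inHypo <- IRanges::overlapsAny(cpgs, blocks[annotations$plan$hypoBlocks])
  inHyper <- IRanges::overlapsAny(cpgs, blocks[annotations$plan$hyperBlocks])
  eff <- config@effectMeth / 100
  pKo <- pWt
  pKo[inHypo] <- pmax(pWt[inHypo] - eff, 0.01)
  pKo[inHyper] <- pmin(pWt[inHyper] + eff, 0.99)
  pEarly <- ifelse(inDomain & !inLate, pHigh, pLow)

  drawSample <- function(p) {
    depth <- rpois(length(p), config@methDepth)
    keep <- depth > 0
    meth <- rbinom(sum(keep), depth[keep], p[keep])
    out <- data.table::data.table(
      chrom = chrom[keep], pos = pos[keep],
      meth = meth, unmeth = depth[keep] - meth
    )
    data.table::setattr(out, "class", c("CpGCallSet", class(out)))
    out
  }
  n <- config@nRepsPerGroup
  withSeed(subSeed(config@seed, 4L), {
    calls <- list()
    for (i in seq_len(n)) calls[[paste0("wt", i)]] <- drawSample(pWt)
    for (i in seq_len(n)) calls[[paste0("ko", i)]] <- drawSample(pKo)
    earlier <- drawSample(pEarly)
  })
  label <- rep("null", length(blocks))
  names(label) <- names(blocks)
  if (eff > 0) {
    label[annotations$plan$hypoBlocks] <- "hypo"
    label[annotations$plan$hyperBlocks] <- "hyper"
  }
  dmrTruth <- data.frame(
    id = names(blocks),
    chrom = as.character(GenomeInfoDb::seqnames(blocks)),
    start = GenomicRanges::start(blocks), end = GenomicRanges::end(blocks),
    label = unname(label), stringsAsFactors = FALSE
  )
  list(calls = calls, earlier = earlier, dmrTruth = dmrTruth)
}

#' Simulate the gene-level count matrix
#'
#' Expected counts are proportional to FPKM x gene length, scaled per
#' sample to \code{rnaDepth}; knockout samples multiply planted down-DEGs
#' by 1/effectRna and up-DEGs by effectRna; counts are negative-binomial.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param annotations from \code{\link{generateAnnotations}}.
#' @return list: \code{counts} (genes x samples), \code{geneTruth}.
#' @export
simulateRnaCounts <- function(config, annotations) {
  genes <- annotations$genes
  base <- genes$fpkm * genes$exonLength / 1000
  mult <- rep(1, length(genes))
  names(mult) <- genes$gene_id
  mult[annotations$plan$degDown] <- 1 / config@effectRna
  mult[annotations$plan$degUp] <- config@effectRna
  n <- config@nRepsPerGroup
  muWt <- base / sum(base) * config@rnaDepth
  koBase <- base * mult
  muKo <- koBase / sum(koBase) * config@rnaDepth
  withSeed(subSeed(config@seed, 5L), {
    draw <- function(mu) {
      if (config@nbDispersion > 0) {
        rnbinom(length(mu), size = 1 / config@nbDispersion, mu = mu)
      } else rpois(length(mu), mu)
    }
    counts <- cbind(
      vapply(seq_len(n), function(i) draw(muWt), numeric(length(base))),
      vapply(seq_len(n), function(i) draw(muKo), numeric(length(base)))
    )
  })
  colnames(counts) <- c(paste0("wt", seq_len(n)), paste0("ko", seq_len(n)))
  rownames(counts) <- genes$gene_id
  label <- rep("null", length(genes))
  names(label) <- genes$gene_id
  if (config@effectRna > 1) {
    label[annotations$plan$degDown] <- "down"
    label[annotations$plan$degUp] <- "up"
  }
  geneTruth <- data.frame(gene_id = genes$gene_id, label = unname(label),
                          stringsAsFactors = FALSE)
  list(counts = counts, geneTruth = geneTruth)
}

#' Simulate the full synthetic oocyte epigenome
#'
#' Runs the four generator stages (genome, annotations, ChIP reads,
#' methylomes, RNA counts) under the configured seed and assembles the
#' multi-omic dataset plus ground-truth tables.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list of class \code{"OocyteSim"} with elements \code{genome},
#'   \code{cpgs}, \code{islands}, \code{chromSizes}, \code{annotations},
#'   \code{chip}, \code{meth}, \code{rna}, \code{truth} (windowTruth,
#'   dmrTruth, geneTruth, promoterTruth, oogenesisUp), \code{config}.
#' @examples
#' \donttest{
#' sim <- simulateOocyteEpigenome(simConfig(nChroms = 1, chromLength = 1e6,
#'                                          nGenes = 20, seed = 1))
#' }
#' @export
simulateOocyteEpigenome <- function(config) {
  validObject(config)
  genomeData <- generateGenome(config)
  ann <- generateAnnotations(config, genomeData)
  chip <- simulateChipReads(config, ann, genomeData)
  meth <- simulateMethylomes(config, ann, genomeData)
  rna <- simulateRnaCounts(config, ann)
  structure(
    list(
      genome = genomeData$genome, cpgs = genomeData$cpgs,
      islands = genomeData$islands, chromSizes = genomeData$chromSizes,
      annotations = ann, chip = chip, meth = meth, rna = rna,
      truth = list(windowTruth = chip$windowTruth, dmrTruth = meth$dmrTruth,
                   geneTruth = rna$geneTruth,
                   promoterTruth = ann$promoterTruth,
                   oogenesisUp = ann$oogenesisUp),
      config = config
    ),
    class = "OocyteSim"
  )
}

#' @export
print.OocyteSim <- function(x, ...) {
  cat(sprintf("OocyteSim: %d chromosome(s), %d CpGs, %d genes\n",
              length(x$genome), length(x$cpgs), length(x$annotations$genes)))
  cat(sprintf("  ChIP samples: %s\n", paste(names(x$chip$reads), collapse = ", ")))
  cat(sprintf("  methylome samples: %s (+ earlier timepoint)\n",
              paste(names(x$meth$calls), collapse = ", ")))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits the standard-format files: genome.fa, cpgs.bed, genes.gtf and
#' genes.bed, feature BEDs, per-sample ChIP read BEDs, Bismark coverage
#' files, rna_counts.tsv and truth/*.tsv.
#'
#' @param sim an \code{OocyteSim}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  writeBed(sim$cpgs, file.path(dir, "cpgs.bed"))
  writeBed(sim$islands, file.path(dir, "islands.bed"))
  genes <- sim$annotations$genes
  gtf <- c(
    GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes),
                           IRanges::IRanges(GenomicRanges::start(genes),
                                            GenomicRanges::end(genes)),
                           strand = GenomicRanges::strand(genes),
                           type = "transcript", gene_id = genes$gene_id,
                           transcript_id = paste0(genes$gene_id, ".1")),
    GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes),
                           IRanges::IRanges(GenomicRanges::start(genes),
                                            GenomicRanges::end(genes)),
                           strand = GenomicRanges::strand(genes),
                           type = "exon", gene_id = genes$gene_id,
                           transcript_id = paste0(genes$gene_id, ".1"))
  )
  rtracklayer::export(gtf, file.path(dir, "genes.gtf"), format = "gtf")
  writeBed(genes, file.path(dir, "genes.bed"), names = genes$gene_id)
  writeBed(sim$annotations$h3k27ac, file.path(dir, "h3k27ac.bed"))
  writeBed(sim$annotations$h3k27me3, file.path(dir, "h3k27me3.bed"))
  md <- sim$annotations$methDomains
  writeBed(md, file.path(dir, "meth_domains.bed"),
           names = ifelse(S4Vectors::mcols(md)$late, "late", "early"))
  for (s in names(sim$chip$reads)) {
    writeBed(sim$chip$reads[[s]], file.path(dir, paste0("chip_", s, ".bed")))
  }
  for (s in names(sim$meth$calls)) {
    writeBismarkCov(sim$meth$calls[[s]], file.path(dir, paste0("meth_", s, ".cov")))
  }
  writeBismarkCov(sim$meth$earlier, file.path(dir, "meth_earlier.cov"))
  data.table::fwrite(
    data.table::data.table(gene_id = rownames(sim$rna$counts), sim$rna$counts),
    file.path(dir, "rna_counts.tsv"), sep = "\t"
  )
  truthDir <- file.path(dir, "truth")
  dir.create(truthDir, showWarnings = FALSE)
  for (nm in c("windowTruth", "dmrTruth", "geneTruth", "promoterTruth")) {
    data.table::fwrite(sim$truth[[nm]], file.path(truthDir, paste0(nm, ".tsv")),
                       sep = "\t")
  }
  writeLines(sim$truth$oogenesisUp, file.path(truthDir, "oogenesisUp.txt"))
  invisible(dir)
}
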