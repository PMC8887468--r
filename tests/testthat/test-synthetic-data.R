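test_that("the generator is deterministic and emits a self-consistent CpG list", {
  cfg <- smallSimConfig(seed = 5)
  g1 <- generateGenome(cfg)
  g2 <- generateGenome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(GenomicRanges::start(g1$cpgs), GenomicRanges::start(g2$cpgs))

  # CpG list = direct string scan of the emitted FASTA for "CG"
  seqchar <- as.character(g1$genome[[1]])
  scan <- gregexpr("CG", seqchar, fixed = TRUE)[[1]]
  scan <- scan[scan > 0]
  # gregexpr reports non-overlapping matches; CG cannot overlap itself
  expect_equal(GenomicRanges::start(g1$cpgs), as.integer(scan))

  # same seed: identical downstream reads and counts
  s1 <- simulateOocyteEpigenome(cfg)
  s2 <- simulateOocyteEpigenome(cfg)
  expect_identical(
    GenomicRanges::start(s1$chip$reads$wt1), GenomicRanges::start(s2$chip$reads$wt1)
  )
  expect_identical(s1$rna$counts, s2$rna$counts)
  expect_identical(as.data.frame(s1$meth$calls$ko2), as.data.frame(s2$meth$calls$ko2))
})

test_that("island-free configuration reduces to the flat background rate", {
  cfg <- simConfig(
    nChroms = 1, chromLength = 1e6, nGenes = 20, cpgIslandDensity = 0,
    nPlantedGainWindows = 1, nPlantedLossWindows = 1, nPlantedHypoDmrs = 1,
    nPlantedHyperDmrs = 0, nPlantedDegDown = 1, nPlantedDegUp = 1, seed = 3
  )
  g <- generateGenome(cfg)
  expect_equal(length(g$islands), 0L)
  # CG dimer rate ~ iid C*G times the 40% retention of the depletion step
  rate <- length(g$cpgs) / cfg@chromLength
  expect_lt(abs(rate - 0.21 * 0.21 * 0.4), 0.002)
})

test_that("planted truth respects exclusivity and co-location structure", {
  sim <- cachedSmallSim()
  truth <- sim$truth
  wt <- truth$windowTruth
  expect_true(all(table(wt$label[wt$label != "null"]) > 0))
  # gain/loss and hypo/hyper and up/down labels are disjoint by id
  expect_false(any(duplicated(wt$id)))
  expect_false(any(duplicated(truth$dmrTruth$id)))

  # planted gain windows avoid WT methylated domains except where a
  # hypoDMR is co-planted
  gains <- wt[wt$label == "gain", ]
  gainGr <- GenomicRanges::GRanges(gains$chrom, IRanges::IRanges(gains$start, gains$end))
  domains <- GenomicRanges::reduce(sim$annotations$methDomains)
  hypo <- truth$dmrTruth[truth$dmrTruth$label == "hypo", ]
  hypoGr <- GenomicRanges::GRanges(hypo$chrom, IRanges::IRanges(hypo$start, hypo$end))
  inDomain <- overlapsFeatures(gainGr, domains)$hit
  withHypo <- overlapsFeatures(gainGr, hypoGr)$hit
  expect_true(all(!inDomain | withHypo))

  # promoter truth is recovered by the classifier from truth inputs
  ann <- sim$annotations
  pc <- classifyPromoters(ann$genes, setNames(ann$genes$fpkm, ann$genes$gene_id),
                          ann$h3k27ac, ann$h3k27me3, ann$methDomains)
  expect_equal(pc$class, truth$promoterTruth$class)

  # down-DEG truth is enriched in the oogenesis-upregulated set
  down <- truth$geneTruth$gene_id[truth$geneTruth$label == "down"]
  fold <- (mean(down %in% truth$oogenesisUp)) /
    (length(truth$oogenesisUp) / nrow(truth$geneTruth))
  expect_gt(fold, 1)
})

test_that("sequencing depths follow their sampling laws", {
  sim <- cachedSmallSim()
  cfg <- sim$config
  # ChIP: total reads per sample ~ chipDepth within 3 SD of the NB law
  disp <- cfg@nbDispersion
  for (s in c("wt1", "ko1")) {
    n <- length(sim$chip$reads[[s]])
    sdTot <- sqrt(cfg@chipDepth + disp * cfg@chipDepth^2 / length(sim$chip$windows))
    expect_lt(abs(n - cfg@chipDepth), 3 * sdTot + 3 * sqrt(cfg@chipDepth))
  }
  # RNA: library sizes ~ rnaDepth
  libs <- colSums(sim$rna$counts)
  sdLib <- sqrt(sum(sim$rna$counts[, 1] + disp * as.numeric(sim$rna$counts[, 1])^2))
  expect_true(all(abs(libs - cfg@rnaDepth) < 4 * sdLib))

  # methylation: mean percent inside non-DMR methylated domains in [80, 95]
  domains <- sim$annotations$methDomains
  hypoIds <- sim$annotations$plan$hypoBlocks
  blocks <- sim$annotations$cpgBlocks
  nonDmrDomainCpgs <- GenomicRanges::setdiff(
    GenomicRanges::reduce(domains),
    GenomicRanges::reduce(blocks[hypoIds])
  )
  calls <- sim$meth$calls$ko1
  pos <- GenomicRanges::GRanges(calls$chrom, IRanges::IRanges(calls$pos, width = 1))
  inside <- overlapsFeatures(pos, nonDmrDomainCpgs)$hit
  pct <- 100 * sum(calls$meth[inside]) / sum(calls$meth[inside] + calls$unmeth[inside])
  expect_gt(pct, 80)
  expect_lt(pct, 95)
})

test_that("neutral effect sizes produce label-free truth tables", {
  cfg <- smallSimConfig(seed = 9, effectChip = 1, effectMeth = 0, effectRna = 1)
  sim <- simulateOocyteEpigenome(cfg)
  expect_true(all(sim$truth$windowTruth$label == "null"))
  expect_true(all(sim$truth$dmrTruth$label == "null"))
  expect_true(all(sim$truth$geneTruth$label == "null"))
})

test_that("the default configuration plants the reported DMR direction skew", {
  cfg <- simConfig()
  frac <- cfg@nPlantedHypoDmrs / (cfg@nPlantedHypoDmrs + cfg@nPlantedHyperDmrs)
  expect_equal(frac, 0.94)
  expect_error(simConfig(effectChip = 0.5), "effectChip")
  expect_error(simConfig(chromLength = -1), "> 0")
  expect_error(simConfig(effectMeth = 150), "effectMeth")
})

test_that("simulations serialize to standard formats and read back", {
  sim <- cachedSmallSim()
  dir <- withr::local_tempdir()
  writeSimulation(sim, dir)
  # FASTA round trip
  fa <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_identical(as.character(fa[[1]]), as.character(sim$genome[[1]]))
  # Bismark coverage round trip
  back <- readBismarkCov(file.path(dir, "meth_wt1.cov"))
  expect_equal(as.data.frame(back), as.data.frame(sim$meth$calls$wt1))
  # BED round trip of CpG positions (0-based half-open on disk)
  cpgs <- readBed(file.path(dir, "cpgs.bed"))
  expect_equal(GenomicRanges::start(cpgs), GenomicRanges::start(sim$cpgs))
  # GTF read-back reproduces the gene models (single-exon genes)
  gm <- readGeneModels(file.path(dir, "genes.gtf"))
  g0 <- sim$annotations$genes
  expect_equal(sort(gm$gene_id), sort(g0$gene_id))
  idx <- match(g0$gene_id, gm$gene_id)
  expect_equal(gm$tss[idx], g0$tss)
  expect_equal(gm$exonLength[idx], g0$exonLength)
  # count matrix round trip
  cnt <- readCountMatrix(file.path(dir, "rna_counts.tsv"))
  storage.mode(cnt) <- "double"
  expect_equal(cnt, sim$rna$counts)
})
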