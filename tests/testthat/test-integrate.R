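mkGenes <- function(tss, chrom = "chr1") {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(tss, tss + 5000))
  g$gene_id <- paste0("g", seq_along(tss))
  g$tss <- tss
  names(g) <- g$gene_id
  g
}

test_that("promoter classification follows the rules with active precedence", {
  genes <- mkGenes(c(10000, 30000, 50000, 70000, 90000))
  emptyGr <- GenomicRanges::GRanges()
  k27me3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(49800, 50200))
  domains <- GenomicRanges::GRanges("chr1", IRanges::IRanges(60000, 80000))
  fpkmV <- c(g1 = 5, g2 = 0.5, g3 = 0.05, g4 = 8, g5 = 0.03)
  pc <- classifyPromoters(genes, fpkmV, emptyGr, k27me3, domains)
  expect_equal(pc$class, c("active", "weak", "inactive", "active", "inactive"))
  # g4: FPKM > 1 while fully inside a methylated domain; active wins
  expect_match(pc$evidence[4], "FPKM>1")
  expect_match(pc$evidence[4], "methylated_domain")
  # H3K27ac alone makes a silent promoter active
  k27ac <- GenomicRanges::GRanges("chr1", IRanges::IRanges(89800, 90100))
  pc2 <- classifyPromoters(genes, fpkmV, k27ac, emptyGr, emptyGr)
  expect_equal(pc2$class[5], "active")
  # permuting gene order permutes but does not change classes
  o <- c(3, 1, 5, 2, 4)
  pc3 <- classifyPromoters(genes[o], fpkmV, emptyGr, k27me3, domains)
  expect_equal(pc3$class, pc$class[o])
  # edge overlap is not containment under the default rule
  edgeDom <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9800, 10000))
  pcEdge <- classifyPromoters(genes[1], c(g1 = 0.5), emptyGr, emptyGr, edgeDom)
  expect_equal(pcEdge$class, "weak")
  pcOv <- classifyPromoters(genes[1], c(g1 = 0.5), emptyGr, emptyGr, edgeDom,
                            domainRule = "overlap")
  expect_equal(pcOv$class, "inactive")
  # missing FPKM: unclassified with a warning
  expect_warning(pcNA <- classifyPromoters(genes[1], c(gX = 1), emptyGr,
                                           emptyGr, emptyGr))
  expect_equal(pcNA$class, "unclassified")
})

test_that("overlap enrichment reproduces hand chi-square values and Bonferroni rule", {
  expect_equal(bruteChisq(rbind(c(10, 90), c(30, 70))), 12.5)
  ct <- suppressWarnings(chisq.test(rbind(c(10, 90), c(30, 70)), correct = FALSE))
  expect_equal(unname(ct$statistic), 12.5)

  run <- cachedRun()
  pe <- run$promEnrich
  expect_equal(attr(pe, "bonferroni"), 0.05 / 6, tolerance = 1e-12)
  # every reported chi-square equals the hand formula on its table
  for (i in seq_len(nrow(pe))) {
    tab <- rbind(c(pe$observed[i], pe$n[i] - pe$observed[i]),
                 c(pe$randomObserved[i], pe$nRandom[i] - pe$randomObserved[i]))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(pe$statistic[i], bruteChisq(tab), tolerance = 1e-9)
  }
  # query = the random set itself: folds 1, nothing significant
  pcAll <- run$promClasses
  selfEnrich <- promoterOverlapEnrichment(run$randomWindows, run$randomWindows,
                                          pcAll, run$sim$annotations$genes,
                                          run$randomWindows)
  expect_true(all(abs(selfEnrich$fold[selfEnrich$randomObserved > 0] - 1) < 1e-12))
  expect_false(any(selfEnrich$significant))
})

test_that("differential windows partition across promoter classes as planted", {
  run <- cachedRun()
  pe <- run$promEnrich
  lossActive <- pe[pe$query == "loss" & pe$class == "active", ]
  gainInactive <- pe[pe$query == "gain" & pe$class == "inactive", ]
  expect_gt(lossActive$fold, 1)
  expect_lt(lossActive$p, attr(pe, "bonferroni"))
  expect_gt(gainInactive$fold, 1)
  expect_lt(gainInactive$p, attr(pe, "bonferroni"))
})

test_that("DMR overlap statistics separate gains from losses", {
  run <- cachedRun()
  ov <- run$dmrOverlap
  expect_gt(ov$counts["gain", "hypo"], ov$counts["loss", "hypo"])
  expect_lt(ov$tests$hypo$p, 0.05)
  # overlapping CpG windows are more hypomethylated under gains
  expect_lt(ov$methDiff$meanGain, ov$methDiff$meanLoss)
  expect_lt(ov$methDiff$p, 0.001)
  # disjoint coordinates give all-zero overlaps
  far <- GenomicRanges::GRanges("chr9", IRanges::IRanges(1, 10))
  ov0 <- suppressWarnings(dmrH3k4me3Overlap(far, far, run$dmrCalls, run$cpgWindows))
  expect_true(all(ov0$counts == 0))
  expect_true(ov0$tests$hypo$skipped)
})

test_that("promoter H3K4me3 profiles detect loss at down-DEG promoters only", {
  run <- cachedRun()
  pp <- run$promProfile
  down <- pp[pp$set == "down", ]
  up <- pp[pp$set == "up", ]
  expect_lt(down$meanDelta, 0)
  expect_lt(down$p, 0.01)
  expect_gt(up$p, 0.05)

  # identical groups: all deltas zero, p = 1
  qm <- run$qmNorm
  v <- quantValues(qm)[, 1:3]
  vv <- cbind(v, v)
  colnames(vv) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  qmSame <- QuantMatrix(vv, SummarizedExperiment::rowRanges(qm), "log2_norm")
  ppSame <- promoterH3k4me3Profile(
    list(s = run$sim$annotations$genes$gene_id[1:30]), qmSame,
    factor(rep(c("a", "b"), each = 3), levels = c("a", "b")),
    run$sim$annotations$genes
  )
  expect_equal(ppSame$meanDelta, 0)
  expect_equal(ppSame$p, 1)
})

test_that("timecourse relative enrichment separates early from late acquirers", {
  # 4-timepoint synthetic series: early promoters saturate at t1, late rise
  set.seed(23)
  w <- makeRunningWindows(c(chr1 = 5e5), 5000)
  genes <- mkGenes(seq(2500, 499000, by = 5000)[1:90])
  early <- genes$gene_id[1:40]; late <- genes$gene_id[41:80]
  base <- matrix(0.2, length(w), 4,
                 dimnames = list(names(w), c("t0", "t1", "t2", "t3")))
  gi <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(genes$tss, width = 1)), w,
    select = "first"
  )
  base[gi[1:40], c("t1", "t2", "t3")] <- 2           # early: jump then plateau
  base[gi[41:80], "t1"] <- 0.8                        # late: keep rising
  base[gi[41:80], "t2"] <- 1.4
  base[gi[41:80], "t3"] <- 2
  base <- base + matrix(rnorm(length(base), 0, 0.01), nrow(base))
  qm <- QuantMatrix(base, w, "group_mean")
  tc <- enrichmentTimecourse(qm, list(early = early, late = late), genes, "t0")
  s <- tc$summary
  earlyInc <- s$meanIncrease[s$set == "early"]
  lateInc <- s$meanIncrease[s$set == "late"]
  expect_lt(abs(earlyInc[3] - earlyInc[1]), 0.05)   # plateau
  expect_gt(lateInc[3] - lateInc[1], 0.5)           # still rising
  expect_lt(tc$pairwise[["t1"]], 0.001)
  expect_true(all(is.finite(tc$anova)))
  # brute-force mean recomputation for one cell
  relLate <- base[gi[41:80], "t2"] - base[gi[41:80], "t0"]
  expect_equal(s$meanIncrease[s$set == "late" & s$condition == "t2"],
               mean(relLate), tolerance = 1e-12)
  # identical conditions: all increases zero
  qm0 <- QuantMatrix(base[, c(1, 1, 1)] + 0, w, "group_mean")
  expect_error(enrichmentTimecourse(qm0, list(early = early), genes, "t9"),
               "baseline")
})

test_that("run manifests record headline counts and detect mutated inputs", {
  dir <- withr::local_tempdir()
  run <- suppressWarnings(runStudyPipeline(smallSimConfig(), outDir = dir))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  deg <- data.table::fread(file.path(dir, "deg_calls.tsv"))
  expect_equal(man$headline$nDegDown, sum(deg$direction == "down"))
  expect_equal(man$headline$nGain + man$headline$nLoss,
               sum(run$diffCalls$direction != "none"))
  sums1 <- man$checksums
  # mutate one table: its checksum must change
  cat("x\n", file = file.path(dir, "deg_calls.tsv"), append = TRUE)
  man2 <- runReport(dir)
  expect_false(identical(sums1$deg_calls.tsv, man2$checksums$deg_calls.tsv))
  expect_identical(sums1$diff_windows.tsv, man2$checksums$diff_windows.tsv)
})
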