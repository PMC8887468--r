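# 2x2 chi-square without continuity correction; returns stat and p.
chisq2x2 <- function(tab) {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(statistic = 0, p = 1))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p = ct$p.value)
}

#' Promoter chromatin-state classification
#'
#' Classifies each gene's promoter (TSS +/- 500 bp) as active, weak or
#' inactive from expression and chromatin marks, with rule precedence
#' active > inactive > weak (the active and inactive definitions can both
#' fire for one gene; precedence resolves the clash and every fired rule is
#' kept as evidence):
#' \itemize{
#'   \item active: promoter overlaps H3K27ac, or FPKM > 1;
#'   \item inactive: FPKM < 0.1, or the promoter lies within a DNA
#'     methylated domain, or overlaps H3K27me3;
#'   \item weak: 0.1 <= FPKM <= 1;
#'   \item unclassified otherwise (including genes with no FPKM entry,
#'     with a warning).
#' }
#'
#' @param genes gene \code{GRanges} with mcols \code{gene_id}, \code{tss}.
#' @param fpkmValues named numeric of gene FPKMs.
#' @param h3k27ac,h3k27me3,methDomains feature \code{GRanges}.
#' @param promoterHalf promoter half-width in bp (default 500).
#' @param domainRule \code{"contained"} (default: promoter fully inside a
#'   methylated domain) or \code{"overlap"}.
#' @return data.frame of class \code{"PromoterClasses"}: \code{gene_id},
#'   \code{class}, \code{evidence} (all fired rules, comma-separated).
#' @export
classifyPromoters <- function(genes, fpkmValues, h3k27ac, h3k27me3,
                              methDomains, promoterHalf = 500,
                              domainRule = c("contained", "overlap")) {
  domainRule <- match.arg(domainRule)
  prom <- promoterRanges(genes, promoterHalf)
  f <- fpkmValues[genes$gene_id]
  if (anyNA(f)) {
    warning(sum(is.na(f)), " gene(s) without an FPKM entry left unclassified")
  }
  ovAc <- overlapsFeatures(prom, h3k27ac)$hit
  ovMe3 <- overlapsFeatures(prom, h3k27me3)$hit
  inDomain <- if (domainRule == "contained") {
    GenomicRanges::countOverlaps(prom, methDomains, type = "within") > 0
  } else {
    overlapsFeatures(prom, methDomains)$hit
  }
  active <- ovAc | (!is.na(f) & f > 1)
  inactive <- (!is.na(f) & f < 0.1) | inDomain | ovMe3
  weak <- !is.na(f) & f >= 0.1 & f <= 1
  class <- rep("unclassified", length(genes))
  class[weak] <- "weak"
  class[inactive] <- "inactive"
  class[active] <- "active"
  class[is.na(f) & !ovAc & !inactive] <- "unclassified"
  ev <- mapply(function(ac, hi, lo, dom, me3, wk) {
    paste(c(
      if (ac) "H3K27ac", if (hi) "FPKM>1",
      if (lo) "FPKM<0.1", if (dom) "methylated_domain", if (me3) "H3K27me3",
      if (wk) "FPKM_0.1_1"
    ), collapse = ",")
  }, ovAc, !is.na(f) & f > 1, !is.na(f) & f < 0.1, inDomain, ovMe3, weak)
  out <- data.frame(gene_id = genes$gene_id, class = class,
                    evidence = unname(ev), stringsAsFactors = FALSE)
  class(out) <- c("PromoterClasses", "data.frame")
  out
}

#' Overlap enrichment of differential windows at promoter classes
#'
#' For each query set (gain, loss) and promoter class (active, weak,
#' inactive), counts query windows overlapping promoters of that class and
#' compares against a random window set by a 2x2 chi-square. Significance
#' is Bonferroni-adjusted over the pairwise tests actually run (6 for two
#' query sets x three classes, i.e. a 0.05/6 = 0.00833 threshold).
#'
#' @param gainWindows,lossWindows,randomWindows window \code{GRanges}.
#' @param promoterClasses from \code{\link{classifyPromoters}}.
#' @param genes gene \code{GRanges} (for promoter coordinates).
#' @param promoterHalf promoter half-width (default 500).
#' @return data.frame of class \code{"OverlapEnrichment"}: query, class,
#'   observed/random counts and rates, \code{fold}, \code{statistic},
#'   \code{p}, \code{significant}; attribute \code{bonferroni} holds the
#'   adjusted threshold.
#' @export
promoterOverlapEnrichment <- function(gainWindows, lossWindows,
                                      promoterClasses, genes,
                                      randomWindows, promoterHalf = 500) {
  prom <- promoterRanges(genes, promoterHalf)
  queries <- list(gain = gainWindows, loss = lossWindows)
  classes <- c("active", "weak", "inactive")
  rows <- list()
  for (qn in names(queries)) {
    q <- queries[[qn]]
    if (length(q) == 0L) next
    for (cl in classes) {
      p <- prom[promoterClasses$class == cl]
      nQ <- sum(overlapsFeatures(q, p)$hit)
      nR <- sum(overlapsFeatures(randomWindows, p)$hit)
      tab <- rbind(query = c(nQ, length(q) - nQ),
                   random = c(nR, length(randomWindows) - nR))
      cs <- chisq2x2(tab)
      randRate <- nR / length(randomWindows)
      rows[[length(rows) + 1L]] <- data.frame(
        query = qn, class = cl, observed = nQ, n = length(q),
        randomObserved = nR, nRandom = length(randomWindows),
        fold = if (randRate > 0) (nQ / length(q)) / randRate else NA_real_,
        statistic = cs$statistic, p = cs$p, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  bonf <- 0.05 / nrow(out)
  out$significant <- out$p < bonf
  attr(out, "bonferroni") <- bonf
  class(out) <- c("OverlapEnrichment", "data.frame")
  out
}

#' Overlap of differential H3K4me3 windows with DMRs
#'
#' Counts gain and loss windows overlapping hypo- and hypermethylated
#' 100-CpG windows, tests gain vs loss overlap rates per DMR class by
#' chi-square, and compares the mean methylation difference of
#' DMR-universe CpG windows overlapping gains vs losses by a two-tailed
#' t-test.
#'
#' @param gainWindows,lossWindows window \code{GRanges}.
#' @param dmrCalls \code{DmrCalls} data.frame from
#'   \code{\link{dmrLogisticTest}}.
#' @param cpgWindows CpG-window \code{GRanges} matching \code{dmrCalls$id}.
#' @return list with \code{counts} (per set x DMR class), \code{tests}
#'   (chi-square per class), and \code{methDiff} (per-set mean difference,
#'   t statistic, p).
#' @export
dmrH3k4me3Overlap <- function(gainWindows, lossWindows, dmrCalls, cpgWindows) {
  cw <- cpgWindows[match(dmrCalls$id, names(cpgWindows))]
  sets <- list(gain = gainWindows, loss = lossWindows)
  classes <- c("hypo", "hyper")
  counts <- matrix(0L, nrow = 2, ncol = 3,
                   dimnames = list(names(sets), c(classes, "none")))
  for (sn in names(sets)) {
    s <- sets[[sn]]
    if (length(s) == 0L) next
    for (cl in c(classes, "none")) {
      d <- cw[dmrCalls$direction == cl]
      counts[sn, cl] <- sum(overlapsFeatures(s, d)$hit)
    }
  }
  tests <- lapply(classes, function(cl) {
    tab <- rbind(
      gain = c(counts["gain", cl], length(gainWindows) - counts["gain", cl]),
      loss = c(counts["loss", cl], length(lossWindows) - counts["loss", cl])
    )
    if (sum(tab[, 1]) == 0) return(list(statistic = NA_real_, p = NA_real_, skipped = TRUE))
    c(chisq2x2(tab), skipped = FALSE)
  })
  names(tests) <- classes
  perSetDiff <- lapply(sets, function(s) {
    if (length(s) == 0L) return(numeric())
    hit <- overlapsFeatures(cw, s)$hit
    dmrCalls$diff[hit & !is.na(dmrCalls$diff)]
  })
  methDiff <- list(
    meanGain = if (length(perSetDiff$gain)) mean(perSetDiff$gain) else NA_real_,
    meanLoss = if (length(perSetDiff$loss)) mean(perSetDiff$loss) else NA_real_,
    statistic = NA_real_, p = NA_real_
  )
  if (length(perSetDiff$gain) >= 2 && length(perSetDiff$loss) >= 2) {
    tt <- t.test(perSetDiff$gain, perSetDiff$loss)
    methDiff$statistic <- unname(tt$statistic)
    methDiff$p <- tt$p.value
  }
  list(counts = counts, tests = tests, methDiff = methDiff,
       diffValues = perSetDiff)
}

# The valid 5 kb window containing each gene's TSS; NA where the TSS
# window was artifact-filtered out of the quantitated universe.
tssWindowIndex <- function(genes, windows) {
  tss <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes),
                                IRanges::IRanges(genes$tss, width = 1L))
  ov <- GenomicRanges::findOverlaps(tss, windows, select = "first")
  ov
}

#' Promoter H3K4me3 profile over DEG sets
#'
#' For each gene set (e.g. down-DEGs, up-DEGs, non-DEGs), takes the valid
#' 5 kb window containing the TSS, computes per-promoter group means of
#' normalized enrichment, and tests control vs knockout by a paired
#' two-tailed t-test. Promoters whose TSS window was artifact-filtered are
#' dropped with a count.
#'
#' @param degSets named list of character vectors of gene ids.
#' @param qm \linkS4class{QuantMatrix} of kind \code{"log2_norm"}.
#' @param groups two-level factor over samples (reference first).
#' @param genes gene \code{GRanges}.
#' @return data.frame: set, n promoters used, nDropped, means per group,
#'   \code{meanDelta} (knockout minus control), \code{statistic}, \code{p};
#'   attribute \code{perPromoter} carries the per-gene deltas.
#' @export
promoterH3k4me3Profile <- function(degSets, qm, groups, genes) {
  stopifnot2(valueKind(qm) %in% c("log2_norm", "group_mean"),
             "qm must hold normalized values")
  groups <- as.factor(groups)
  w <- SummarizedExperiment::rowRanges(qm)
  v <- quantValues(qm)
  mA <- rowMeans(v[, groups == levels(groups)[1], drop = FALSE])
  mB <- rowMeans(v[, groups == levels(groups)[2], drop = FALSE])
  idx <- tssWindowIndex(genes, w)
  names(idx) <- genes$gene_id
  perPromoter <- list()
  rows <- lapply(names(degSets), function(sn) {
    ids <- degSets[[sn]]
    if (length(ids) == 0L) {
      return(data.frame(set = sn, n = 0L, nDropped = 0L,
                        meanControl = NA_real_, meanKnockout = NA_real_,
                        meanDelta = NA_real_, statistic = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    wi <- idx[ids]
    dropped <- sum(is.na(wi))
    wi <- wi[!is.na(wi)]
    da <- mB[wi] - mA[wi]
    perPromoter[[sn]] <<- setNames(da, names(wi))
    tt <- if (length(da) >= 2 && sd(da) > 0) t.test(mB[wi], mA[wi], paired = TRUE) else NULL
    data.frame(
      set = sn, n = length(wi), nDropped = dropped,
      meanControl = mean(mA[wi]), meanKnockout = mean(mB[wi]),
      meanDelta = mean(da),
      statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
      p = if (is.null(tt)) if (length(da) >= 2) 1 else NA_real_ else tt$p.value,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "perPromoter") <- perPromoter
  out
}

#' Relative H3K4me3 enrichment over a developmental timecourse
#'
#' For ordered conditions with a designated baseline, computes per promoter
#' set and condition the mean increase of enrichment relative to baseline
#' (with standard error), a two-sample t-test between the two sets at each
#' condition, and a one-way ANOVA across conditions per set (promoters are
#' the observational unit).
#'
#' @param qm \linkS4class{QuantMatrix} (kind \code{"group_mean"}, one
#'   column per condition, or \code{"log2_norm"} with one sample per
#'   condition).
#' @param promoterSets named list of gene-id vectors (typically two sets).
#' @param genes gene \code{GRanges}.
#' @param baseline column name of the baseline condition.
#' @return list with \code{summary} (set x condition means/SE),
#'   \code{pairwise} (t-test p per non-baseline condition between the
#'   first two sets) and \code{anova} (per-set one-way ANOVA p).
#' @export
enrichmentTimecourse <- function(qm, promoterSets, genes, baseline) {
  v <- quantValues(qm)
  stopifnot2(baseline %in% colnames(v), "baseline condition missing")
  conds <- setdiff(colnames(v), baseline)
  stopifnot2(length(conds) >= 1, "at least 2 ordered conditions are required")
  idx <- tssWindowIndex(genes, SummarizedExperiment::rowRanges(qm))
  names(idx) <- genes$gene_id
  rel <- lapply(promoterSets, function(ids) {
    wi <- idx[ids]; wi <- wi[!is.na(wi)]
    v[wi, conds, drop = FALSE] - v[wi, baseline]
  })
  summary <- do.call(rbind, lapply(names(rel), function(sn) {
    m <- rel[[sn]]
    data.frame(
      set = sn, condition = conds,
      meanIncrease = colMeans(m),
      se = apply(m, 2L, sd) / sqrt(nrow(m)),
      n = nrow(m), stringsAsFactors = FALSE
    )
  }))
  pairwise <- NULL
  if (length(rel) >= 2) {
    pairwise <- vapply(conds, function(cc) {
      t.test(rel[[1]][, cc], rel[[2]][, cc])$p.value
    }, numeric(1))
  }
  anovaP <- vapply(rel, function(m) {
    long <- data.frame(y = as.vector(m),
                       cond = rep(colnames(m), each = nrow(m)))
    if (length(unique(long$cond)) < 2) return(NA_real_)
    summary(stats::aov(y ~ cond, data = long))[[1]][["Pr(>F)"]][1]
  }, numeric(1))
  list(summary = summary, pairwise = pairwise, anova = anovaP)
}

#' Assemble a run manifest
#'
#' Records configuration, seed, package version, md5 checksums of every
#' stage output present in the run directory, and the headline statistics
#' read back from the stage tables (fraction of windows differential, DMR
#' direction split, DEG counts). Missing stage outputs are listed as
#' absent; the report is still produced.
#'
#' @param runDir directory holding pipeline outputs (as written by
#'   \code{\link{runStudyPipeline}}).
#' @return the manifest list, invisibly; also written to
#'   \code{manifest.json} in \code{runDir}.
#' @export
runReport <- function(runDir) {
  expected <- c("diff_windows.tsv", "dmr_calls.tsv", "deg_calls.tsv",
                "promoter_classes.tsv", "overlap_enrichment.tsv",
                "dimer_profiles.tsv", "config.json")
  present <- file.exists(file.path(runDir, expected))
  files <- expected[present]
  sums <- as.list(tools::md5sum(file.path(runDir, files)))
  names(sums) <- files
  headline <- list()
  readTsv <- function(f) data.table::fread(file.path(runDir, f), sep = "\t")
  if ("diff_windows.tsv" %in% files) {
    d <- readTsv("diff_windows.tsv")
    headline$nWindowsTested <- nrow(d)
    headline$nGain <- sum(d$direction == "gain")
    headline$nLoss <- sum(d$direction == "loss")
    headline$fractionDifferential <- (headline$nGain + headline$nLoss) / nrow(d)
  }
  if ("dmr_calls.tsv" %in% files) {
    d <- readTsv("dmr_calls.tsv")
    headline$nDmrHypo <- sum(d$direction == "hypo")
    headline$nDmrHyper <- sum(d$direction == "hyper")
  }
  if ("deg_calls.tsv" %in% files) {
    d <- readTsv("deg_calls.tsv")
    headline$nDegDown <- sum(d$direction == "down")
    headline$nDegUp <- sum(d$direction == "up")
  }
  manifest <- list(
    package = "epiwindows",
    version = as.character(packageVersion("epiwindows")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = files,
    absent = expected[!present],
    checksums = sums,
    headline = headline
  )
  jsonlite::write_json(manifest, file.path(runDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
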