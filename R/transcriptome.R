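#' FPKM from a count matrix
#'
#' FPKM = count / (merged exonic length in kb x library size in millions).
#'
#' @param counts matrix, genes x samples.
#' @param lengths gene lengths in bp (merged exonic models).
#' @param librarySizes per-sample totals; defaults to column sums.
#' @return numeric matrix of FPKM values.
#' @export
fpkm <- function(counts, lengths, librarySizes = colSums(counts)) {
  stopifnot2(all(lengths > 0), "gene lengths must be > 0")
  stopifnot2(all(librarySizes > 0), "empty library")
  counts / ((lengths / 1000) %o% (librarySizes / 1e6))
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factor: the median, over genes with nonzero
#' counts in every sample, of the ratio of the gene's count to its
#' geometric mean across samples.
#'
#' @param counts matrix, genes x samples.
#' @return named numeric vector of positive factors.
#' @export
sizeFactorsMedianOfRatios <- function(counts) {
  ok <- rowSums(counts == 0) == 0
  if (!any(ok)) {
    stop("no gene has nonzero counts in every sample; ",
         "size factors need at least one such gene", call. = FALSE)
  }
  logGeo <- rowMeans(log(counts[ok, , drop = FALSE]))
  sf <- apply(counts[ok, , drop = FALSE], 2L, function(x) {
    exp(median(log(x) - logGeo))
  })
  sf
}

#' Differential expression by a simplified negative-binomial Wald test
#'
#' A deliberately compact two-group negative-binomial test: counts are
#' normalized by median-of-ratios size factors; a per-gene moment
#' dispersion \eqn{\hat\alpha = \max((v - \mu)/\mu^2, 10^{-8})} (with v the
#' pooled within-group variance of normalized counts) is shrunk 50/50
#' toward a lowess mean-dispersion trend; the log2 fold change of group
#' means is tested by a Wald statistic with standard error
#' \eqn{\sqrt{(1/n_A)(1/\mu_A + \alpha) + (1/n_B)(1/\mu_B + \alpha)}} on
#' the log scale, referred to a Student t with \code{4(n - 2)} degrees of
#' freedom: the 50/50 trend shrinkage quarters the variance of the moment
#' dispersion estimator, so the moment-matched effective df is four times
#' the residual df. A gene is
#' called only if the adjusted p is below \code{alpha} \emph{and} the
#' absolute fold change exceeds \code{minFc} (i.e. |log2FC| > log2(minFc)).
#' All-zero genes are skipped.
#'
#' @param counts matrix, genes x samples (raw counts).
#' @param groups two-level factor; effects are second level minus first.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param minFc minimum fold change (default 2).
#' @return data.frame of class \code{"DegCalls"}: gene id,
#'   \code{baseMean}, \code{log2FC}, \code{p}, \code{q}, \code{direction}
#'   in up/down/none, \code{skipped}.
#' @export
nbDegTest <- function(counts, groups, alpha = 0.05, minFc = 2) {
  groups <- as.factor(groups)
  stopifnot2(nlevels(groups) == 2, "exactly two groups are required")
  stopifnot2(all(table(groups) >= 2), "at least 2 samples per group are required")
  sf <- sizeFactorsMedianOfRatios(counts)
  k <- sweep(counts, 2L, sf, "/")
  gA <- groups == levels(groups)[1]
  gB <- groups == levels(groups)[2]
  nA <- sum(gA); nB <- sum(gB)
  muA <- rowMeans(k[, gA, drop = FALSE])
  muB <- rowMeans(k[, gB, drop = FALSE])
  mu <- rowMeans(k)
  skipped <- rowSums(counts) == 0
  ssA <- rowSums((k[, gA, drop = FALSE] - muA)^2)
  ssB <- rowSums((k[, gB, drop = FALSE] - muB)^2)
  v <- (ssA + ssB) / (nA + nB - 2)
  dispRaw <- pmax((v - mu) / mu^2, 1e-8)
  use <- !skipped & mu > 0
  trend <- rep(NA_real_, length(mu))
  if (sum(use) >= 10) {
    lo <- suppressWarnings(lowess(log(mu[use]), dispRaw[use], f = 0.5, iter = 3))
    trend[use] <- pmax(approx(lo$x, lo$y, xout = log(mu[use]), rule = 2)$y, 1e-8)
  } else {
    trend[use] <- pmax(median(dispRaw[use]), 1e-8)
  }
  disp <- 0.5 * dispRaw + 0.5 * trend
  eps <- 0.5
  lfcLn <- log((muB + eps)) - log((muA + eps))
  seLn <- sqrt((1 / nA) * (1 / (muA + eps) + disp) +
               (1 / nB) * (1 / (muB + eps) + disp))
  wald <- lfcLn / seLn
  # reference df: the 50/50 shrinkage quarters the dispersion-estimator
  # variance, so the moment-matched effective df is 4x the residual df
  p <- 2 * pt(-abs(wald), df = 4 * (nA + nB - 2))
  p[skipped] <- NA_real_
  q <- bhAdjust(p)
  log2FC <- lfcLn / log(2)
  direction <- rep("none", length(mu))
  sig <- !skipped & !is.na(q) & q < alpha & abs(log2FC) > log2(minFc)
  direction[sig & log2FC > 0] <- "up"
  direction[sig & log2FC < 0] <- "down"
  out <- data.frame(
    id = rownames(counts), baseMean = mu,
    log2FC = log2FC, stat = wald, p = p, q = q,
    direction = direction, skipped = skipped, stringsAsFactors = FALSE
  )
  attr(out, "sizeFactors") <- sf
  class(out) <- c("DegCalls", "data.frame")
  out
}

#' Gene-set fold enrichment with a chi-square test
#'
#' Fold = (|query intersect reference| / |query|) / (|reference| / |universe|),
#' with a 2x2 chi-square (query membership x reference membership) over the
#' universe.
#'
#' @param query,reference,universe character vectors of gene ids;
#'   \code{query} and \code{reference} must be subsets of \code{universe}.
#' @return list with \code{fold}, \code{overlap}, \code{expected},
#'   \code{statistic}, \code{p}, \code{table}.
#' @export
geneSetFoldEnrichment <- function(query, reference, universe) {
  stopifnot2(length(query) > 0 && length(reference) > 0,
             "empty query or reference set")
  query <- unique(query); reference <- unique(reference); universe <- unique(universe)
  stopifnot2(all(query %in% universe) && all(reference %in% universe),
             "query and reference must be subsets of the universe")
  nOv <- sum(query %in% reference)
  fold <- (nOv / length(query)) / (length(reference) / length(universe))
  tab <- matrix(c(
    nOv, length(query) - nOv,
    length(reference) - nOv,
    length(universe) - length(query) - length(reference) + nOv
  ), nrow = 2, byrow = TRUE,
  dimnames = list(c("query", "notQuery"), c("inRef", "notInRef")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stat <- 0; p <- 1
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    stat <- unname(ct$statistic); p <- ct$p.value
  }
  list(fold = fold, overlap = nOv,
       expected = length(query) * length(reference) / length(universe),
       statistic = stat, p = p, table = tab)
}

#' Read gene models from a GTF, merging isoforms
#'
#' Imports exon records and unions, per gene id, all exons into a single
#' merged exonic model. The TSS is the 5'-most position respecting strand,
#' the promoter is TSS +/- 500 bp (clipped at chromosome ends when
#' sequence lengths are known).
#'
#' @param path GTF file.
#' @return \code{GRanges} of genes (span of the merged model) with mcols
#'   \code{gene_id}, \code{tss}, \code{exonLength}.
#' @export
readGeneModels <- function(path) {
  gtf <- rtracklayer::import(path, format = "gtf")
  ex <- gtf[gtf$type == "exon"]
  stopifnot2(length(ex) > 0, "no exon records in GTF")
  byGene <- S4Vectors::split(ex, as.character(ex$gene_id))
  merged <- GenomicRanges::reduce(byGene)
  exonLength <- sum(GenomicRanges::width(merged))
  gid <- as.character(ex$gene_id)
  first <- !duplicated(gid)
  ids <- gid[first]
  st <- tapply(GenomicRanges::start(ex), gid, min)[ids]
  en <- tapply(GenomicRanges::end(ex), gid, max)[ids]
  strand <- as.character(GenomicRanges::strand(ex))[first]
  out <- GenomicRanges::GRanges(
    as.character(GenomeInfoDb::seqnames(ex))[first],
    IRanges::IRanges(unname(st), unname(en)), strand = strand
  )
  S4Vectors::mcols(out)$gene_id <- ids
  S4Vectors::mcols(out)$tss <- unname(ifelse(strand == "-", en, st))
  S4Vectors::mcols(out)$exonLength <- as.integer(exonLength[ids])
  names(out) <- ids
  out[order(as.character(GenomeInfoDb::seqnames(out)), GenomicRanges::start(out))]
}

# Promoter intervals (TSS +/- half) for a gene GRanges carrying $tss.
promoterRanges <- function(genes, half = 500) {
  gr <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(genes),
    IRanges::IRanges(pmax(genes$tss - half, 1), genes$tss + half)
  )
  sl <- GenomeInfoDb::seqlengths(genes)
  if (!all(is.na(sl))) {
    lim <- sl[as.character(GenomeInfoDb::seqnames(gr))]
    GenomicRanges::end(gr) <- pmin(GenomicRanges::end(gr), lim,
                                   na.rm = TRUE)
  }
  names(gr) <- genes$gene_id
  gr
}
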