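#' RPKM quantitation of aligned reads over windows
#'
#' Counts, per window and sample, the reads whose midpoint falls in the
#' window (midpoint assignment partitions the library across a
#' non-overlapping tiling, so counts conserve the library size) and
#' converts to RPKM = count / (window length in kb x library size in
#' millions). Partial terminal windows use their true length.
#'
#' @param reads named list of \code{GRanges}, one per sample (aligned read
#'   intervals, e.g. from \code{\link{readBed}}).
#' @param windows window \code{GRanges}.
#' @param librarySizes optional named numeric; defaults to the number of
#'   reads per sample.
#' @return A \linkS4class{QuantMatrix} of kind \code{"rpkm"}.
#' @examples
#' w <- makeRunningWindows(c(chr1 = 10000), 5000)
#' rd <- GenomicRanges::GRanges("chr1", IRanges::IRanges(rep(100, 10), width = 75))
#' qm <- quantifyRpkm(list(s1 = rd), w, librarySizes = c(s1 = 1e6))
#' quantValues(qm)  # 10 / (5 * 1) = 2 RPKM in the first window
#' @export
quantifyRpkm <- function(reads, windows, librarySizes = NULL) {
  stopifnot2(is.list(reads) && !is.null(names(reads)),
             "reads must be a named list of GRanges")
  if (is.null(librarySizes)) {
    librarySizes <- vapply(reads, length, numeric(1))
  }
  stopifnot2(all(librarySizes > 0), "empty library")
  lenKb <- GenomicRanges::width(windows) / 1000
  counts <- vapply(names(reads), function(s) {
    r <- reads[[s]]
    mid <- floor((GenomicRanges::start(r) + GenomicRanges::end(r)) / 2)
    midGr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(r),
                                    IRanges::IRanges(mid, width = 1L))
    GenomicRanges::countOverlaps(windows, midGr, ignore.strand = TRUE)
  }, numeric(length(windows)))
  rpkm <- counts / (lenKb %o% (librarySizes[names(reads)] / 1e6))
  colnames(rpkm) <- names(reads)
  QuantMatrix(rpkm, windows, "rpkm", librarySizes)
}

# Two-anchor affine normalization of a log2 matrix: per sample, the median
# of values below the sample's 25th percentile (background anchor) and the
# median above its 75th percentile (enriched anchor) are mapped onto the
# cross-sample means of those anchors. Exactly idempotent.
anchorNormalize <- function(v) {
  q <- apply(v, 2L, quantile, probs = c(0.25, 0.75), names = FALSE)
  b <- vapply(seq_len(ncol(v)), function(j) median(v[v[, j] < q[1, j], j]), numeric(1))
  e <- vapply(seq_len(ncol(v)), function(j) median(v[v[, j] > q[2, j], j]), numeric(1))
  if (any(!is.finite(b)) || any(!is.finite(e)) || any(e - b < 1e-12)) {
    stop("degenerate enrichment distribution: background and enriched anchors coincide",
         call. = FALSE)
  }
  B <- mean(b); E <- mean(e)
  a <- (E - B) / (e - b)
  sweep(sweep(v, 2L, b, "-"), 2L, a, "*") + B
}

#' Enrichment normalization of RPKM
#'
#' Converts RPKM to \code{log2(RPKM + offset)} and applies, per sample, a
#' linear transform that maps two distribution anchors -- the median of
#' windows below the sample's 25th percentile (background) and the median
#' above its 75th percentile (enriched) -- onto the cross-sample mean
#' anchors. This aligns both the noise floor and the enriched signal range
#' across samples, making libraries of different global enrichment
#' comparable. The transform is idempotent.
#'
#' @param qm \linkS4class{QuantMatrix} of kind \code{"rpkm"} (or
#'   \code{"log2_norm"}, in which case only the anchor alignment is
#'   re-applied).
#' @param offset pseudo-RPKM added before log2 (default 0.1; keeps empty
#'   windows finite and compresses the noise floor).
#' @return \linkS4class{QuantMatrix} of kind \code{"log2_norm"}.
#' @export
enrichmentNormalize <- function(qm, offset = 0.1) {
  kind <- valueKind(qm)
  stopifnot2(kind %in% c("rpkm", "log2_norm"),
             "enrichmentNormalize expects an rpkm or log2_norm QuantMatrix")
  v <- quantValues(qm)
  if (kind == "rpkm") v <- log2(v + offset)
  out <- QuantMatrix(anchorNormalize(v), SummarizedExperiment::rowRanges(qm),
                     "log2_norm", librarySizes(qm))
  out
}

#' Signal-to-noise QC of ChIP libraries
#'
#' Scores each ChIP sample by the fraction of its total RPKM contained in
#' its top 10\% of windows (a flat, input-like library scores ~0.1; a
#' well-enriched one much higher). A sample is flagged as poorly enriched
#' if its score is below \code{factor} times the input score \emph{and} it
#' is the farthest-from-centroid sample in 1 - Pearson correlation space
#' (the hierarchical-clustering outlier criterion). With fewer than 3 ChIP
#' samples the outlier criterion is skipped and the score rule alone flags.
#' The report lists flags; it never drops samples itself.
#'
#' @param chipQm,inputQm \linkS4class{QuantMatrix} objects of kind
#'   \code{"rpkm"} over the same windows.
#' @param topFrac fraction of windows counted as "top" (default 0.1).
#' @param factor required ratio of ChIP score over input score (default 1.2).
#' @return list of class \code{"QcReport"}: per-sample \code{score},
#'   \code{inputScore}, correlation matrix, \code{outlier}, \code{flagged},
#'   and \code{pass} (no sample flagged).
#' @export
qcSignalToNoise <- function(chipQm, inputQm, topFrac = 0.1, factor = 1.2) {
  stopifnot2(valueKind(chipQm) == "rpkm" && valueKind(inputQm) == "rpkm",
             "QC expects rpkm QuantMatrix inputs")
  stopifnot2(identical(rownames(chipQm), rownames(inputQm)),
             "chip and input must share the same window universe")
  topShare <- function(x) {
    k <- max(1L, floor(length(x) * topFrac))
    s <- sum(x)
    if (s == 0) return(0)
    sum(sort(x, decreasing = TRUE)[seq_len(k)]) / s
  }
  scores <- apply(quantValues(chipQm), 2L, topShare)
  inputScore <- mean(apply(quantValues(inputQm), 2L, topShare))
  lowSnr <- scores < factor * inputScore
  lv <- log2(quantValues(chipQm) + 0.1)
  cm <- cor(lv)
  if (ncol(chipQm) >= 3L) {
    meanDist <- rowMeans(1 - cm) * ncol(cm) / (ncol(cm) - 1)
    outlier <- names(which.max(meanDist))
    flagged <- lowSnr & (names(scores) == outlier)
  } else {
    outlier <- NA_character_
    flagged <- lowSnr
  }
  structure(
    list(score = scores, inputScore = inputScore, correlation = cm,
         outlier = outlier, flagged = flagged, pass = !any(flagged)),
    class = "QcReport"
  )
}

#' @export
print.QcReport <- function(x, ...) {
  cat("ChIP QC report\n")
  cat(sprintf("  input top-share score: %.3f\n", x$inputScore))
  for (s in names(x$score)) {
    cat(sprintf("  %s: score %.3f%s\n", s, x$score[[s]],
                if (x$flagged[[s]]) "  ** FLAGGED **" else ""))
  }
  invisible(x)
}

#' Average replicates within groups
#'
#' @param qm \linkS4class{QuantMatrix} of kind \code{"log2_norm"}.
#' @param groups factor/character of length \code{ncol(qm)}.
#' @return \linkS4class{QuantMatrix} of kind \code{"group_mean"}, one
#'   column per group.
#' @export
averageReplicates <- function(qm, groups) {
  stopifnot2(valueKind(qm) == "log2_norm",
             "averageReplicates expects a log2_norm QuantMatrix")
  groups <- as.factor(groups)
  stopifnot2(length(groups) == ncol(qm), "groups must match the samples")
  stopifnot2(all(table(groups) >= 1), "empty group")
  v <- quantValues(qm)
  m <- matrix(NA_real_, nrow(v), nlevels(groups),
              dimnames = list(rownames(v), levels(groups)))
  for (g in levels(groups)) {
    m[, g] <- rowMeans(v[, groups == g, drop = FALSE])
  }
  QuantMatrix(m, SummarizedExperiment::rowRanges(qm), "group_mean")
}
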