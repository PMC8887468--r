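#' Read a Bismark coverage file
#'
#' Parses the standard Bismark coverage format (tab-separated: chromosome,
#' start, end, percent methylation, count methylated, count unmethylated;
#' 1-based positions). The percent column is recomputed from the counts and
#' checked against the file within 0.5 (tolerant of rounding); counts must
#' be non-negative and positions unique.
#'
#' @param path file path.
#' @return data.table of class \code{"CpGCallSet"} with columns
#'   \code{chrom}, \code{pos} (1-based), \code{meth}, \code{unmeth}.
#' @export
readBismarkCov <- function(path) {
  dt <- if (file.size(path) == 0) {
    data.table::data.table()
  } else {
    data.table::fread(path, header = FALSE, sep = "\t",
                      colClasses = list(character = 1))
  }
  if (nrow(dt) == 0L) {
    out <- data.table::data.table(chrom = character(), pos = integer(),
                                  meth = integer(), unmeth = integer())
    data.table::setattr(out, "class", c("CpGCallSet", class(out)))
    return(out)
  }
  if (ncol(dt) != 6L) stop("malformed Bismark coverage file: expected 6 columns")
  data.table::setnames(dt, c("chrom", "start", "end", "percent", "meth", "unmeth"))
  bad <- which(!is.finite(dt$start) | !is.finite(dt$meth) | !is.finite(dt$unmeth))
  if (length(bad)) stop(sprintf("malformed line %d in %s", bad[1], path))
  if (any(dt$meth < 0 | dt$unmeth < 0)) {
    stop(sprintf("negative counts at line %d in %s",
                 which(dt$meth < 0 | dt$unmeth < 0)[1], path))
  }
  cov <- dt$meth + dt$unmeth
  pct <- ifelse(cov > 0, 100 * dt$meth / cov, 0)
  off <- which(abs(pct - dt$percent) > 0.5)
  if (length(off)) {
    stop(sprintf("percent column disagrees with counts at line %d in %s",
                 off[1], path))
  }
  if (anyDuplicated(dt[, c("chrom", "start")])) {
    stop("duplicate CpG positions in ", path)
  }
  out <- data.table::data.table(chrom = dt$chrom, pos = as.integer(dt$start),
                                meth = as.integer(dt$meth),
                                unmeth = as.integer(dt$unmeth))
  data.table::setattr(out, "class", c("CpGCallSet", class(out)))
  out
}

#' Write a Bismark coverage file
#'
#' @param calls a CpG call set (columns \code{chrom}, \code{pos},
#'   \code{meth}, \code{unmeth}).
#' @param path output path.
#' @export
writeBismarkCov <- function(calls, path) {
  cov <- calls$meth + calls$unmeth
  out <- data.table::data.table(
    chrom = calls$chrom, start = calls$pos, end = calls$pos,
    percent = ifelse(cov > 0, round(100 * calls$meth / cov, 6), 0),
    meth = calls$meth, unmeth = calls$unmeth
  )
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Aggregate CpG calls into CpG windows
#'
#' Sums methylated/unmethylated read counts over each window's CpGs, per
#' sample. Windows failing the minimum-informative-CpG rule should already
#' have been excluded by \code{\link{makeCpgWindows}}.
#'
#' @param calls named list of per-sample CpG call sets.
#' @param windows CpG-window \code{GRanges} from \code{\link{makeCpgWindows}}.
#' @return list with integer matrices \code{meth} and \code{unmeth}
#'   (windows x samples) and \code{percent} (100 * meth / coverage).
#' @export
windowMethylation <- function(calls, windows) {
  nm <- names(calls)
  stopifnot2(!is.null(nm), "calls must be a named list")
  agg <- function(cs, col) {
    pos <- GenomicRanges::GRanges(cs$chrom, IRanges::IRanges(cs$pos, width = 1L))
    ov <- GenomicRanges::findOverlaps(windows, pos)
    x <- rep(0L, length(windows))
    if (length(ov)) {
      s <- tapply(cs[[col]][S4Vectors::subjectHits(ov)],
                  S4Vectors::queryHits(ov), sum)
      x[as.integer(names(s))] <- as.integer(s)
    }
    x
  }
  meth <- matrix(vapply(nm, function(s) agg(calls[[s]], "meth"),
                        integer(length(windows))),
                 nrow = length(windows), dimnames = list(names(windows), nm))
  unmeth <- matrix(vapply(nm, function(s) agg(calls[[s]], "unmeth"),
                          integer(length(windows))),
                   nrow = length(windows), dimnames = list(names(windows), nm))
  cov <- meth + unmeth
  list(meth = meth, unmeth = unmeth,
       percent = ifelse(cov > 0, 100 * meth / cov, NA_real_))
}

# Vectorized binomial-GLM likelihood-ratio statistic for a two-level group
# factor. Group totals are sufficient for the binomial GLM, so the
# replicate-level logistic-regression LRT equals the pooled 2x2
# G-statistic 2 * sum O * ln(O/E); computed in that closed form.
binomialLrt <- function(mA, uA, mB, uB) {
  nA <- mA + uA; nB <- mB + uB
  tot <- nA + nB
  p0 <- (mA + mB) / tot
  dev <- 2 * (xlogxy(mA, nA * p0) + xlogxy(uA, nA * (1 - p0)) +
              xlogxy(mB, nB * p0) + xlogxy(uB, nB * (1 - p0)))
  pmax(dev, 0)
}

#' DMR calling by binomial logistic regression
#'
#' Per CpG window, fits the binomial generalized linear model with logit
#' link (methylated count out of coverage ~ group) and tests the group term
#' by likelihood-ratio against the intercept-only model (1 df chi-square).
#' P-values are Benjamini-Hochberg adjusted across windows, and a window is
#' called a DMR only if additionally the absolute pooled-count methylation
#' difference exceeds \code{minDiff} percentage points. Windows with zero
#' total coverage in either group are skipped with a reason.
#'
#' @param meth,unmeth count matrices (windows x samples) from
#'   \code{\link{windowMethylation}}.
#' @param groups two-level factor over samples; effects are second level
#'   minus first (knockout minus control).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param minDiff minimum absolute percent difference (default 20).
#' @return data.frame of class \code{"DmrCalls"}: window id, per-group
#'   pooled percents, \code{diff} (percentage points), \code{deviance},
#'   \code{p}, \code{q}, \code{direction} in hypo/hyper/none, and
#'   \code{skipped} flag.
#' @export
dmrLogisticTest <- function(meth, unmeth, groups, alpha = 0.05, minDiff = 20) {
  groups <- as.factor(groups)
  stopifnot2(nlevels(groups) == 2, "exactly two groups are required")
  stopifnot2(all(table(groups) >= 1),
             "at least one sample per group is required (one = pooled counts)")
  gA <- groups == levels(groups)[1]
  gB <- groups == levels(groups)[2]
  mA <- rowSums(meth[, gA, drop = FALSE]); uA <- rowSums(unmeth[, gA, drop = FALSE])
  mB <- rowSums(meth[, gB, drop = FALSE]); uB <- rowSums(unmeth[, gB, drop = FALSE])
  covA <- mA + uA; covB <- mB + uB
  skipped <- covA == 0 | covB == 0
  dev <- rep(NA_real_, length(mA))
  dev[!skipped] <- binomialLrt(mA[!skipped], uA[!skipped], mB[!skipped], uB[!skipped])
  p <- pchisq(dev, df = 1, lower.tail = FALSE)
  q <- bhAdjust(p)
  pctA <- ifelse(covA > 0, 100 * mA / covA, NA_real_)
  pctB <- ifelse(covB > 0, 100 * mB / covB, NA_real_)
  diff <- pctB - pctA
  direction <- rep("none", length(diff))
  direction[!skipped & q < alpha & diff > minDiff] <- "hyper"
  direction[!skipped & q < alpha & diff < -minDiff] <- "hypo"
  out <- data.frame(
    id = rownames(meth),
    percentA = pctA, percentB = pctB, diff = diff,
    deviance = dev, p = p, q = q, direction = direction,
    skipped = skipped, stringsAsFactors = FALSE
  )
  names(out)[names(out) == "percentA"] <- paste0("percent_", levels(groups)[1])
  names(out)[names(out) == "percentB"] <- paste0("percent_", levels(groups)[2])
  class(out) <- c("DmrCalls", "data.frame")
  out
}

#' Methylation-timing comparison of window sets
#'
#' Compares pooled percent methylation of two window sets at an earlier
#' developmental timepoint by a 2x2 chi-square on the pooled
#' (methylated, unmethylated) read counts. Used to ask whether
#' hypomethylated DMRs correspond to regions that normally acquire
#' methylation late in oogenesis.
#'
#' @param setA,setB window \code{GRanges} (e.g. hypoDMR windows and a
#'   random set of methylated-domain windows).
#' @param earlierCalls CpG call set of the earlier-timepoint methylome.
#' @return list with \code{percentA}, \code{percentB}, pooled count
#'   \code{table}, \code{statistic} and \code{p}.
#' @export
methylationTimingComparison <- function(setA, setB, earlierCalls) {
  stopifnot2(length(setA) > 0 && length(setB) > 0, "empty window set")
  pooled <- function(set) {
    pos <- GenomicRanges::GRanges(earlierCalls$chrom,
                                  IRanges::IRanges(earlierCalls$pos, width = 1L))
    ov <- GenomicRanges::findOverlaps(set, pos)
    i <- unique(S4Vectors::subjectHits(ov))
    c(meth = sum(earlierCalls$meth[i]), unmeth = sum(earlierCalls$unmeth[i]))
  }
  a <- pooled(setA); b <- pooled(setB)
  tab <- rbind(A = a, B = b)
  if (identical(unname(a), unname(b)) || any(colSums(tab) == 0)) {
    stat <- 0; p <- 1
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    stat <- unname(ct$statistic); p <- ct$p.value
  }
  list(
    percentA = 100 * a[["meth"]] / sum(a),
    percentB = 100 * b[["meth"]] / sum(b),
    table = tab, statistic = stat, p = p
  )
}
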