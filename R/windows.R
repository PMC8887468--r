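#' Running windows over a genome
#'
#' Tiles each chromosome with fixed-width windows. With \code{step == size}
#' the tiling is non-overlapping (the default used for all statistics in
#' this package); \code{step < size} gives sliding windows for display
#' tracks. Terminal partial windows are retained and flagged.
#'
#' @param chromSizes named numeric vector, chromosome lengths in bp.
#' @param size window size in bp (default 5000, the analysis window).
#' @param step step in bp; must satisfy \code{0 < step <= size}.
#' @return A \code{GRanges} sorted by (chrom, start) with mcols \code{id}
#'   (stable ordinal), \code{partial} (terminal short window flag), and
#'   \code{metadata()} recording kind/size/step. Names are
#'   \code{"chrom:start-end"} window ids.
#' @examples
#' w <- makeRunningWindows(c(chr1 = 12000), size = 5000, step = 5000)
#' width(w)
#' @export
makeRunningWindows <- function(chromSizes, size = 5000, step = size) {
  stopifnot2(size > 0, "size must be > 0")
  stopifnot2(step > 0 && step <= size,
             "step must satisfy 0 < step <= size (gapped tiling not supported)")
  stopifnot2(!is.null(names(chromSizes)), "chromSizes must be named")
  pieces <- lapply(names(chromSizes), function(ch) {
    len <- chromSizes[[ch]]
    starts <- seq(1L, len, by = step)
    starts <- starts[starts <= len]
    ends <- pmin(starts + size - 1L, len)
    keep <- ends >= starts
    GenomicRanges::GRanges(ch, IRanges::IRanges(starts[keep], ends[keep]))
  })
  gr <- suppressWarnings(do.call(c, pieces))
  GenomeInfoDb::seqlengths(gr) <- chromSizes[GenomeInfoDb::seqlevels(gr)]
  gr <- GenomicRanges::sort(gr)
  S4Vectors::mcols(gr)$id <- seq_along(gr)
  S4Vectors::mcols(gr)$partial <- GenomicRanges::width(gr) < size
  names(gr) <- sprintf("%s:%d-%d", GenomeInfoDb::seqnames(gr),
                       GenomicRanges::start(gr), GenomicRanges::end(gr))
  S4Vectors::metadata(gr) <- list(kind = "fixed_bp", size = size, step = step)
  gr
}

#' Exclude mapping-artifact windows by input RPKM
#'
#' Drops windows whose RPKM exceeds \code{threshold} in \emph{any} input
#' sample, returning the remaining "valid" windows. The default threshold
#' of 4 corresponds to roughly 10x flat input coverage at mammalian genome
#' scale; see \code{\link{runStudyPipeline}} for the genome-size-aware
#' default used end to end.
#'
#' @param windows a window \code{GRanges} (as from
#'   \code{\link{makeRunningWindows}}).
#' @param inputQuant a \linkS4class{QuantMatrix} of kind \code{"rpkm"} over
#'   the same windows, one column per input sample.
#' @param threshold RPKM above which a window is excluded.
#' @return The retained windows (same representation as \code{windows}).
#' @export
filterArtifactWindows <- function(windows, inputQuant, threshold = 4) {
  stopifnot2(is(inputQuant, "QuantMatrix") && valueKind(inputQuant) == "rpkm",
             "inputQuant must be a QuantMatrix of kind 'rpkm'")
  stopifnot2(ncol(inputQuant) >= 1, "at least one input sample is required")
  idx <- match(names(windows), rownames(inputQuant))
  stopifnot2(!anyNA(idx), "inputQuant does not cover all windows")
  v <- quantValues(inputQuant)[idx, , drop = FALSE]
  keep <- apply(v, 1L, max) <= threshold
  windows[keep]
}

# Consecutive blocks of nCpg CpG positions per chromosome (step = block).
# Returns a GRanges spanning [first CpG, last CpG + 1] (the closing G of
# the last dimer), with the member CpG starts attached.
cpgBlocks <- function(cpgs, nCpg = 100) {
  stopifnot2(is(cpgs, "GRanges"), "cpgs must be a GRanges of CG positions")
  cpgs <- GenomicRanges::sort(cpgs)
  perChrom <- split(GenomicRanges::start(cpgs), as.character(GenomeInfoDb::seqnames(cpgs)))
  out <- lapply(names(perChrom), function(ch) {
    pos <- perChrom[[ch]]
    nb <- length(pos) %/% nCpg
    if (nb == 0L) return(NULL)
    idx <- seq_len(nb * nCpg)
    block <- rep(seq_len(nb), each = nCpg)
    first <- pos[(seq_len(nb) - 1L) * nCpg + 1L]
    last <- pos[seq_len(nb) * nCpg]
    gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(first, last + 1L))
    S4Vectors::mcols(gr)$id <- sprintf("%s_cw%05d", ch, seq_len(nb))
    S4Vectors::mcols(gr)$nCpgs <- nCpg
    S4Vectors::mcols(gr)$cpgStarts <- IRanges::IntegerList(
      split(pos[idx], block)
    )
    gr
  })
  out <- do.call(c, out[!vapply(out, is.null, logical(1))])
  names(out) <- S4Vectors::mcols(out)$id
  out
}

#' 100-CpG windows with an informative-coverage filter
#'
#' Groups the genome's CpG positions, chromosome by chromosome, into
#' consecutive non-overlapping blocks of \code{nCpg} CpGs (trailing
#' remainders are dropped) and retains a block only if \emph{every} sample
#' covers at least \code{minInformative} of its CpGs. An informative CpG
#' is one observed by at least one read in that sample.
#'
#' @param cpgs \code{GRanges} of all CG dinucleotide positions of the
#'   genome (one range per CpG, forward strand).
#' @param coverage list of per-sample CpG call sets (as returned by
#'   \code{\link{readBismarkCov}}); used only for the informative filter.
#'   May be \code{NULL} to skip filtering.
#' @param nCpg CpGs per window (default 100).
#' @param minInformative minimum covered CpGs per window per sample
#'   (default 10).
#' @return \code{GRanges} of retained CpG windows with mcols \code{id},
#'   \code{nCpgs} and \code{cpgStarts}.
#' @export
makeCpgWindows <- function(cpgs, coverage = NULL, nCpg = 100,
                           minInformative = 10) {
  blocks <- cpgBlocks(cpgs, nCpg)
  if (is.null(blocks) || length(blocks) == 0L) {
    return(GenomicRanges::GRanges())
  }
  if (!is.null(coverage)) {
    keep <- rep(TRUE, length(blocks))
    for (cs in coverage) {
      pos <- GenomicRanges::GRanges(cs$chrom, IRanges::IRanges(cs$pos, width = 1L))
      n <- GenomicRanges::countOverlaps(blocks, pos)
      keep <- keep & (n >= minInformative)
    }
    blocks <- blocks[keep]
  }
  blocks
}

#' Window / feature overlap
#'
#' Marks each window that shares at least 1 bp with any feature.
#'
#' @param windows query \code{GRanges}.
#' @param features subject \code{GRanges}.
#' @return list with \code{hit}, a logical vector over \code{windows}, and
#'   \code{pairs}, the (query, subject) index pairs.
#' @export
overlapsFeatures <- function(windows, features) {
  ov <- GenomicRanges::findOverlaps(windows, features, ignore.strand = TRUE)
  list(
    hit = seq_along(windows) %in% S4Vectors::queryHits(ov),
    pairs = cbind(
      query = S4Vectors::queryHits(ov),
      subject = S4Vectors::subjectHits(ov)
    )
  )
}

#' Uniform random window sets
#'
#' Samples \code{n} windows uniformly without replacement, deterministically
#' per seed, returning them in genomic order. Used as the random comparator
#' set for overlap-enrichment and composition statistics.
#'
#' @param universe window \code{GRanges} to sample from.
#' @param n number of windows.
#' @param seed integer seed.
#' @return \code{GRanges} subset of \code{universe}.
#' @export
sampleRandomWindows <- function(universe, n, seed) {
  stopifnot2(n <= length(universe), "n exceeds the size of the universe")
  idx <- withSeed(seed, sample.int(length(universe), n))
  GenomicRanges::sort(universe[idx])
}
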