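.DIMERS <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))

#' Genome background dinucleotide frequencies
#'
#' Frequency of each of the 16 dinucleotides among all overlapping dimers
#' of the forward strand of the genome; ambiguous bases are skipped.
#'
#' @param genome \code{DNAStringSet} (one entry per chromosome).
#' @return named numeric 16-vector summing to 1.
#' @export
genomeBackgroundDimers <- function(genome) {
  stopifnot2(is(genome, "DNAStringSet") && sum(Biostrings::width(genome)) > 1,
             "empty genome")
  cnt <- colSums(Biostrings::oligonucleotideFrequency(genome, width = 2))
  cnt <- cnt[.DIMERS]
  stopifnot2(sum(cnt) > 0, "empty genome")
  cnt / sum(cnt)
}

# Extract window sequences from a per-chromosome DNAStringSet.
windowSequences <- function(windows, genome) {
  ch <- as.character(GenomeInfoDb::seqnames(windows))
  stopifnot2(all(ch %in% names(genome)), "windows reference unknown chromosomes")
  seqs <- Biostrings::DNAStringSet(lapply(seq_along(windows), function(i) {
    Biostrings::subseq(genome[[ch[i]]],
                       start = GenomicRanges::start(windows)[i],
                       end = min(GenomicRanges::end(windows)[i],
                                 length(genome[[ch[i]]])))
  }))
  names(seqs) <- names(windows)
  seqs
}

#' Dinucleotide composition profile of a window set
#'
#' Per window, overlapping-dimer frequencies with a pseudocount added to
#' each dimer count, expressed as log2(observed/expected) against the
#' genome background; the profile is the mean over windows. Windows
#' shorter than 2 bp are skipped; duplicate windows are allowed and weigh
#' accordingly.
#'
#' @param windows window \code{GRanges}.
#' @param genome \code{DNAStringSet}.
#' @param background 16-vector from \code{\link{genomeBackgroundDimers}}
#'   (computed from \code{genome} if missing).
#' @param pseudocount added to each dimer count per window (default 0.5;
#'   keeps log ratios finite in kb-scale windows).
#' @return list of class \code{"DimerProfile"}: \code{profile} (mean log2
#'   obs/exp per dimer), \code{perWindow} (windows x 16 matrix),
#'   \code{nWindows}, \code{background}.
#' @export
dimerComposition <- function(windows, genome,
                             background = genomeBackgroundDimers(genome),
                             pseudocount = 0.5) {
  keep <- GenomicRanges::width(windows) >= 2
  windows <- windows[keep]
  stopifnot2(length(windows) > 0, "no windows of length >= 2")
  seqs <- windowSequences(windows, genome)
  cnt <- Biostrings::oligonucleotideFrequency(seqs, width = 2)[, .DIMERS, drop = FALSE]
  cnt <- cnt + pseudocount
  freq <- cnt / rowSums(cnt)
  lr <- log2(sweep(freq, 2L, background[.DIMERS], "/"))
  rownames(lr) <- names(windows)
  structure(
    list(profile = colMeans(lr), perWindow = lr,
         nWindows = length(windows), background = background),
    class = "DimerProfile"
  )
}

#' Difference between two dimer profiles
#'
#' Entrywise difference of mean log2 obs/exp (A - B); both profiles must
#' share the same background.
#'
#' @param profileA,profileB \code{DimerProfile} objects.
#' @return named numeric 16-vector.
#' @export
dimerDifference <- function(profileA, profileB) {
  stopifnot2(isTRUE(all.equal(profileA$background, profileB$background)),
             "profiles were computed against different backgrounds")
  profileA$profile - profileB$profile
}

#' CpG-content comparison of two window sets
#'
#' Compares the per-window CG log2(obs/exp) distributions of two window
#' sets by a two-sided Mann-Whitney U test.
#'
#' @param setA,setB window \code{GRanges}.
#' @param genome \code{DNAStringSet}.
#' @param background optional background vector.
#' @return list with per-window values \code{valuesA}, \code{valuesB},
#'   \code{statistic} (U) and \code{p}.
#' @export
cpgContentTest <- function(setA, setB, genome,
                           background = genomeBackgroundDimers(genome)) {
  stopifnot2(length(setA) > 0 && length(setB) > 0, "both window sets must be nonempty")
  a <- dimerComposition(setA, genome, background)$perWindow[, "CG"]
  b <- dimerComposition(setB, genome, background)$perWindow[, "CG"]
  if (length(unique(c(a, b))) == 1L) {
    return(list(valuesA = a, valuesB = b, statistic = length(a) * length(b) / 2, p = 1))
  }
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided", exact = FALSE))
  list(valuesA = a, valuesB = b, statistic = unname(wt$statistic), p = wt$p.value)
}
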