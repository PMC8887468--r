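# Shared fixtures. Heavy pipeline runs are computed once per test session
# and cached; unit tests use a reduced single-chromosome configuration.

.cache <- new.env(parent = emptyenv())

smallSimConfig <- function(seed = 1, ...) {
  simConfig(
    nChroms = 1, chromLength = 2e6, nGenes = 40, cpgIslandDensity = 40,
    nPlantedGainWindows = 10, nPlantedLossWindows = 10,
    nPlantedHypoDmrs = 8, nPlantedHyperDmrs = 1,
    nPlantedDegDown = 8, nPlantedDegUp = 8,
    chipDepth = 1e5, rnaDepth = 5e5, seed = seed, ...
  )
}

cachedRun <- function() {
  if (is.null(.cache$run)) {
    .cache$run <- suppressWarnings(runStudyPipeline(simConfig(seed = 1)))
  }
  .cache$run
}

cachedNullRun <- function() {
  if (is.null(.cache$nullRun)) {
    .cache$nullRun <- suppressWarnings(runStudyPipeline(nullSimConfig(seed = 1)))
  }
  .cache$nullRun
}

cachedSmallSim <- function() {
  if (is.null(.cache$smallSim)) {
    .cache$smallSim <- simulateOocyteEpigenome(smallSimConfig())
  }
  .cache$smallSim
}

# Independent brute-force oracles -------------------------------------------

# quadratic any-overlap scan (1-based closed intervals)
bruteOverlap <- function(aStart, aEnd, bStart, bEnd) {
  vapply(seq_along(aStart), function(i) {
    any(aStart[i] <= bEnd & bStart <= aEnd[i])
  }, logical(1))
}

# textbook BH step-up rejection set at level alpha
bruteStepUpReject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= alpha * seq_len(m) / m)
  rej <- logical(m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

# chi-square statistic sum((O-E)^2/E) on a 2x2 table
bruteChisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# G statistic 2 * sum O * ln(O/E) on a 2x2 table
bruteG <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  2 * sum(ifelse(tab > 0, tab * log(tab / E), 0))
}

# sliding dimer counts of a character sequence
bruteDimerCounts <- function(seqchar) {
  n <- nchar(seqchar)
  dimers <- substring(seqchar, seq_len(n - 1), seq(2, n))
  counts <- table(factor(dimers, levels = as.vector(
    outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)
  )))
  as.numeric(counts)
}
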