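test_that("background dimer frequencies match brute-force sliding counts", {
  g1 <- Biostrings::DNAStringSet(c(chr1 = "AAAA"))
  bg1 <- genomeBackgroundDimers(g1)
  expect_equal(unname(bg1["AA"]), 1)
  expect_equal(sum(bg1), 1)

  set.seed(17)
  toy <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  bg <- genomeBackgroundDimers(Biostrings::DNAStringSet(c(chr1 = toy)))
  brute <- bruteDimerCounts(toy)
  expect_equal(unname(bg), brute / sum(brute), tolerance = 1e-12)

  # uniform random megabase: each dimer ~ 1/16
  unif <- paste(sample(c("A", "C", "G", "T"), 1e6, replace = TRUE), collapse = "")
  bgU <- genomeBackgroundDimers(Biostrings::DNAStringSet(c(chr1 = unif)))
  expect_true(all(abs(bgU - 1 / 16) < 0.003))
  expect_error(genomeBackgroundDimers(Biostrings::DNAStringSet(c(chr1 = ""))),
               "empty")
})

test_that("window composition applies pseudocounts and averages over windows", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ACGCGAAAATTTTCCCCGGGG"))
  bg <- genomeBackgroundDimers(genome)
  w <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 5))  # "ACGCG"
  names(w) <- "w1"
  prof <- dimerComposition(w, genome, bg, pseudocount = 0.5)
  # oracle: counts AC=1, CG=2, GC=1 (+0.5 each), normalized, log2 vs bg
  cnt <- bruteDimerCounts("ACGCG") + 0.5
  oracle <- log2((cnt / sum(cnt)) / unname(bg))
  fin <- is.finite(oracle)
  expect_equal(unname(prof$profile)[fin], oracle[fin], tolerance = 1e-12)

  # the whole genome as one window converges to zero enrichment
  wAll <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 21))
  names(wAll) <- "all"
  profAll <- dimerComposition(wAll, genome, bg, pseudocount = 0)
  expect_true(all(abs(profAll$profile[is.finite(profAll$profile)]) < 1e-9))

  # mean over windows equals brute-force recomputation; order-invariant
  set.seed(18)
  big <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE), collapse = "")
  genome2 <- Biostrings::DNAStringSet(c(chr1 = big))
  bg2 <- genomeBackgroundDimers(genome2)
  starts <- seq(1, 4500, by = 500)
  ws <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, width = 400))
  names(ws) <- paste0("w", seq_along(ws))
  p1 <- dimerComposition(ws, genome2, bg2)
  # per-window frequencies are probability vectors before the log
  freq <- 2^p1$perWindow * matrix(bg2, nrow(p1$perWindow), 16, byrow = TRUE)
  expect_equal(unname(rowSums(freq)), rep(1, nrow(freq)), tolerance = 1e-12)
  perWin <- t(vapply(starts, function(s) {
    cnt <- bruteDimerCounts(substr(big, s, s + 399)) + 0.5
    log2((cnt / sum(cnt)) / unname(bg2))
  }, numeric(16)))
  expect_equal(unname(p1$profile), colMeans(perWin), tolerance = 1e-12)
  p2 <- dimerComposition(rev(ws), genome2, bg2)
  expect_equal(sort(p2$profile), sort(p1$profile), tolerance = 1e-12)
})

test_that("profile differences are antisymmetric and reverse-complement symmetric", {
  set.seed(19)
  big <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE,
                      prob = c(0.35, 0.2, 0.15, 0.3)), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = big))
  wA <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 801), width = 800))
  wB <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1601, 2401), width = 800))
  names(wA) <- c("a1", "a2"); names(wB) <- c("b1", "b2")
  pA <- dimerComposition(wA, genome)
  pB <- dimerComposition(wB, genome)
  expect_equal(dimerDifference(pA, pB), -dimerDifference(pB, pA))
  expect_equal(unname(dimerDifference(pA, pA)), rep(0, 16))

  # reverse-complementing the genome maps each dimer onto its RC partner
  rcGenome <- Biostrings::reverseComplement(genome)
  bgF <- genomeBackgroundDimers(genome)
  bgR <- genomeBackgroundDimers(rcGenome)
  rcName <- function(d) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(d, "")[[1]]), collapse = ""))
  }
  for (d in names(bgF)) expect_equal(unname(bgF[d]), unname(bgR[rcName(d)]))
})

test_that("CpG content test ranks planted gains above random windows", {
  # U statistic matches the brute-force all-pairs count on small sets
  set.seed(22)
  big <- paste(sample(c("A", "C", "G", "T"), 22000, replace = TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = big))
  sA <- GenomicRanges::GRanges("chr1", IRanges::IRanges(seq(1, 9501, 500), width = 400))
  sB <- GenomicRanges::GRanges("chr1", IRanges::IRanges(seq(10001, 19501, 500), width = 400))
  names(sA) <- paste0("a", seq_along(sA)); names(sB) <- paste0("b", seq_along(sB))
  r <- cpgContentTest(sA, sB, genome)
  u <- sum(outer(r$valuesA, r$valuesB, ">")) + 0.5 * sum(outer(r$valuesA, r$valuesB, "=="))
  expect_equal(r$statistic, u)

  same <- cpgContentTest(sA, sA, genome)
  expect_gt(same$p, 0.9)

  # planted gains are CpG-rich relative to random windows
  run <- cachedRun()
  expect_gt(median(run$cgTest$valuesA), median(run$cgTest$valuesB))
  expect_lt(run$cgTest$p, 0.01)
  expect_gt(dimerDifference(run$composition$gain, run$composition$random)["CG"], 0)
})
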