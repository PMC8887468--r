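test_that("Bismark coverage files parse, validate and round-trip", {
  f <- withr::local_tempfile(fileext = ".cov")
  writeLines("chr1\t101\t101\t75.0\t3\t1", f)
  cs <- readBismarkCov(f)
  expect_equal(as.data.frame(cs),
               data.frame(chrom = "chr1", pos = 101L, meth = 3L, unmeth = 1L))

  empty <- withr::local_tempfile(fileext = ".cov")
  file.create(empty)
  expect_equal(nrow(readBismarkCov(empty)), 0L)

  # round trip of a random call set
  set.seed(4)
  calls <- data.table::data.table(
    chrom = rep(c("chr1", "chr2"), each = 50),
    pos = c(sort(sample.int(1e5, 50)), sort(sample.int(1e5, 50))),
    meth = rpois(100, 4), unmeth = rpois(100, 4)
  )
  f2 <- withr::local_tempfile(fileext = ".cov")
  writeBismarkCov(calls, f2)
  back <- readBismarkCov(f2)
  expect_equal(as.data.frame(back), as.data.frame(calls))

  bad <- withr::local_tempfile(fileext = ".cov")
  writeLines("chr1\t10\t10\t50\t-1\t1", bad)
  expect_error(readBismarkCov(bad), "negative")
  mismatch <- withr::local_tempfile(fileext = ".cov")
  writeLines("chr1\t10\t10\t10.0\t3\t1", mismatch)
  expect_error(readBismarkCov(mismatch), "percent")
})

test_that("window aggregation sums counts over member CpGs", {
  pos <- seq(10, 1000, by = 10)[1:100]
  cpgs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, width = 2))
  w <- makeCpgWindows(cpgs, NULL, nCpg = 100)
  one <- structure(data.table::data.table(chrom = "chr1", pos = 10L,
                                          meth = 3L, unmeth = 1L),
                   class = c("CpGCallSet", "data.table", "data.frame"))
  agg <- windowMethylation(list(s = one), w)
  expect_equal(unname(agg$meth[1, 1]), 3L)
  expect_equal(unname(agg$percent[1, 1]), 75)

  # brute-force re-sum on a random call set
  set.seed(6)
  calls <- data.table::data.table(chrom = "chr1", pos = sample(pos, 60),
                                  meth = rpois(60, 5), unmeth = rpois(60, 5))
  agg2 <- windowMethylation(list(s = calls), w)
  expect_equal(unname(agg2$meth[1, 1]), sum(calls$meth))
  expect_equal(unname(agg2$unmeth[1, 1]), sum(calls$unmeth))
})

test_that("DMR likelihood-ratio test equals the binomial GLM and the G statistic", {
  # identical aggregates: deviance 0, p = 1
  m <- matrix(c(30, 30, 30, 30), 1, dimnames = list("w1", NULL))
  u <- matrix(c(70, 70, 70, 70), 1, dimnames = list("w1", NULL))
  r0 <- dmrLogisticTest(m, u, c("wt", "wt", "ko", "ko"))
  expect_equal(r0$deviance, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1)

  # pooled 2x2 closed form: WT 30/100 vs KO 10/100
  m1 <- matrix(c(30, 10), 1, dimnames = list("w1", NULL))
  u1 <- matrix(c(70, 90), 1, dimnames = list("w1", NULL))
  suppressWarnings(r1 <- dmrLogisticTest(m1, u1, factor(c("wt", "ko"), levels = c("wt", "ko")), minDiff = 0))
  gstat <- bruteG(rbind(c(30, 70), c(10, 90)))
  expect_equal(r1$deviance, gstat, tolerance = 1e-8)

  # independent oracle: stats::glm likelihood-ratio on replicate data
  set.seed(12)
  meth <- matrix(rbinom(24, 80, rep(c(0.7, 0.4), each = 12)), 4,
                 dimnames = list(paste0("w", 1:4), NULL))
  unmeth <- 80L - meth
  groups <- factor(rep(c("wt", "ko"), each = 3), levels = c("wt", "ko"))
  mine <- dmrLogisticTest(meth, unmeth, groups)
  for (i in 1:4) {
    fit <- glm(cbind(meth[i, ], unmeth[i, ]) ~ groups, family = binomial())
    dev <- fit$null.deviance - fit$deviance
    expect_equal(mine$deviance[i], dev, tolerance = 1e-8)
  }

  # a significant but small (-15 point) difference is not called
  m2 <- matrix(c(4500, 3000), 1, dimnames = list("w1", NULL))
  u2 <- matrix(c(5500, 7000), 1, dimnames = list("w1", NULL))
  suppressWarnings(r2 <- dmrLogisticTest(m2, u2, factor(c("wt", "ko"), levels = c("wt", "ko"))))
  expect_lt(r2$q, 0.001)
  expect_equal(r2$diff, -15)
  expect_equal(r2$direction, "none")

  # swapping group labels preserves p and negates the difference
  swapped <- dmrLogisticTest(meth, unmeth, factor(rep(c("wt", "ko"), each = 3),
                                                  levels = c("ko", "wt")))
  expect_equal(swapped$p, mine$p, tolerance = 1e-12)
  expect_equal(swapped$diff, -mine$diff, tolerance = 1e-12)
  expect_true(all(mine$diff >= -100 & mine$diff <= 100))
})

test_that("DMR test is calibrated on null binomial data", {
  # 3000 null windows, ~10x coverage per CpG aggregated over 100 CpGs
  set.seed(20)
  nw <- 3000; n <- 3
  p <- runif(nw, 0.05, 0.9)
  cov <- matrix(rpois(nw * 2 * n, 1000), nw)
  meth <- matrix(rbinom(nw * 2 * n, as.vector(cov), rep(p, 2 * n)), nw,
                 dimnames = list(paste0("w", seq_len(nw)), NULL))
  unmeth <- cov - meth
  res <- dmrLogisticTest(meth, unmeth, factor(rep(c("wt", "ko"), each = n),
                                              levels = c("wt", "ko")))
  rate <- mean(res$p < 0.05)
  expect_gt(rate, 0.035)
  expect_lt(rate, 0.065)
  expect_lte(sum(res$direction != "none"), 1)
})

test_that("timing comparison pools counts and applies the chi-square", {
  # hand oracle on the pooled table [[300,700],[500,500]]
  tab <- rbind(c(300, 700), c(500, 500))
  calls <- data.table::data.table(
    chrom = "chr1",
    pos = 1:2,
    meth = c(300L, 500L), unmeth = c(700L, 500L)
  )
  a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1))
  b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2, 2))
  r <- methylationTimingComparison(a, b, calls)
  expect_equal(r$statistic, bruteChisq(tab), tolerance = 1e-9)
  expect_equal(r$percentA, 30)
  expect_equal(r$percentB, 50)

  same <- methylationTimingComparison(a, a, calls)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(methylationTimingComparison(GenomicRanges::GRanges(), b, calls),
               "empty")
})

test_that("planted hypoDMRs are unmethylated at the earlier timepoint", {
  run <- cachedRun()
  expect_lt(run$timing$percentA, run$timing$percentB)
  expect_lt(run$timing$p, 0.05)
  # hypoDMRs sit in late-methylating domains: earlier percent near the floor
  expect_lt(run$timing$percentA, 20)
})
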