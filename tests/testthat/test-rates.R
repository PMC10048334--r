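test_that("per-offspring rate uses the diploid denominator", {
  expect_equal(perOffspringRate(5, 1e8), 2.5e-8)
  expect_equal(perOffspringRate(0, 1e8), 0)
  expect_error(perOffspringRate(1, 0), "undefined rate")
  # 106 mutations over 30 offspring at ~4.32e8 callable sites each
  m <- c(rep(4, 16), rep(3, 14))   # sums to 106
  expect_equal(sum(m), 106)
  rates <- perOffspringRate(m, rep(4.32e8, 30))
  expect_equal(mean(rates), 106 / (30 * 2 * 4.32e8))
  expect_lt(abs(mean(rates) - 4.09e-9), 0.01e-9)
})

test_that("bootstrap CI reproduces an independent brute-force rerun", {
  v <- c(1, 3, 4, 7, 8, 10, 12, 15, 18, 20)
  got <- bootstrapCI(v, B = 1000, seed = 42)
  want <- oracleBootstrap(v, B = 1000, seed = 42)
  expect_equal(got$mean, unname(want["mean"]))
  expect_equal(got$ciLow, unname(want["lo"]))
  expect_equal(got$ciHigh, unname(want["hi"]))

  const <- bootstrapCI(rep(2.5, 8), B = 1000, seed = 1)
  expect_equal(const$ciLow, 2.5)
  expect_equal(const$ciHigh, 2.5)
  expect_error(bootstrapCI(v, B = 20), "insufficient replicates")
  expect_error(bootstrapCI(numeric(0)), "non-empty")
})

test_that("bootstrap CI attains near-nominal coverage on normal samples", {
  trials <- 500
  n <- 30
  hits <- withr::with_seed(2024, {
    vapply(seq_len(trials), function(i) {
      x <- rnorm(n, mean = 5, sd = 2)
      ci <- bootstrapCI(x, B = 1000)
      ci$ciLow <= 5 && 5 <= ci$ciHigh
    }, logical(1))
  })
  expect_gt(mean(hits), 0.92)
  expect_lt(mean(hits), 0.98)
})

test_that("bootstrap CI width shrinks roughly as 1/sqrt(n)", {
  width <- function(n, seed) {
    x <- withr::with_seed(seed, rnorm(n, 10, 3))
    ci <- bootstrapCI(x, B = 1000, seed = seed)
    ci$ciHigh - ci$ciLow
  }
  w10 <- mean(vapply(1:10, function(s) width(10, s), numeric(1)))
  w40 <- mean(vapply(1:10, function(s) width(40, 100 + s), numeric(1)))
  expect_gt(w10 / w40, 1.5)
  expect_lt(w10 / w40, 2.8)
})

test_that("condition comparisons behave and match a hand-computed t-test", {
  expect_equal(compareConditions(c(2, 2, 2), c(2, 2, 2)), 1)
  expect_equal(compareConditions(c(2, 2, 2), c(2, 2, 2), "wilcoxon"), 1)
  expect_lt(compareConditions(c(1, 2, 3), c(101, 102, 103)), 0.001)
  a <- c(1.2, 3.4, 2.2, 4.8, 3.1)
  b <- c(5.0, 6.1, 4.9, 7.3)
  expect_equal(compareConditions(a, b), oracleWelchT(a, b))
  expect_error(compareConditions(1, c(1, 2)), "at least 2")
})

test_that("cross-species chi-square matches the definition and is monotone", {
  even <- crossSpeciesTest(c(100, 100), c(1e6, 1e6))
  expect_gt(even$p, 0.95)
  t1 <- crossSpeciesTest(c(50, 100), c(1e6, 1e6))
  tab <- cbind(c(50, 100), c(1e6 - 50, 1e6 - 100))
  expect_equal(t1$statistic, oracleChiSq(tab))
  t2 <- crossSpeciesTest(c(50, 200), c(1e6, 1e6))
  expect_lt(t2$p, t1$p)
  expect_error(crossSpeciesTest(c(5), c(100)), "two species")
  expect_error(crossSpeciesTest(c(5, 200), c(100, 100)), "exceed")
})

test_that("chromosome distribution test agrees with the ECDF-gap oracle", {
  lens <- c(chr1 = 4e5, chr2 = 6e5)
  calls <- withr::with_seed(5, {
    u <- runif(40)
    chrom <- ifelse(u < 0.4, "chr1", "chr2")
    pos <- ifelse(chrom == "chr1", ceiling(runif(40) * 4e5),
                  ceiling(runif(40) * 6e5))
    data.frame(chrom = chrom, pos = pos)
  })
  got <- chromosomeDistributionTest(calls, lens)
  offset <- ifelse(calls$chrom == "chr1", 0, 4e5)
  u <- (offset + calls$pos - 0.5) / 1e6
  expect_equal(got$statistic, oracleKS(u))

  clumped <- data.frame(chrom = "chr1", pos = rep(1, 50))
  expect_lt(chromosomeDistributionTest(clumped, lens)$p, 0.001)
  expect_error(chromosomeDistributionTest(clumped[1:3, ], lens), "at least 5")
})

test_that("uniformly placed mutations usually pass the K-S uniformity check", {
  lens <- c(chr1 = 5e5, chr2 = 5e5)
  ps <- vapply(1:20, function(s) {
    calls <- withr::with_seed(s, {
      g <- ceiling(runif(200) * 1e6)
      data.frame(chrom = ifelse(g <= 5e5, "chr1", "chr2"),
                 pos = ifelse(g <= 5e5, g, g - 5e5))
    })
    chromosomeDistributionTest(calls, lens)$p
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("stratified rate estimates partition and respect additivity", {
  exp <- denseExperiment(genomeLength = 1e5, nOffspring = 6, mu = 4e-5,
                         geneFraction = 0.4, seed = 66)
  cs <- callDnms(exp)
  r <- estimateRates(cs, "toy", B = 200, seed = 3)
  wg <- r[r$stratum == "whole_genome", ]
  gene <- r[r$stratum == "gene", ]
  inter <- r[r$stratum == "intergenic", ]
  expect_equal(gene$m + inter$m, wg$m)
  expect_equal(gene$callableTotal + inter$callableTotal, wg$callableTotal)
  expect_true(all(r$ciLow <= r$mean + 1e-15 & r$mean <= r$ciHigh + 1e-15))
  po <- attr(r, "perOffspring")
  expect_equal(mean(po$whole_genome), wg$mean)
  # per offspring, the whole-genome rate is a convex combination of the
  # gene and intergenic rates (exact when the denominators partition)
  expect_true(all(po$whole_genome >= pmin(po$gene, po$intergenic) - 1e-18))
  expect_true(all(po$whole_genome <= pmax(po$gene, po$intergenic) + 1e-18))
})
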