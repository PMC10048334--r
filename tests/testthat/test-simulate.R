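test_that("reference genome matches the configured GC content", {
  cfg <- simulationConfig(genomeLength = 1e4, gcContent = 0.5,
                          nChromosomes = 1, seed = 7)
  ref <- generateReference(cfg)
  expect_equal(sum(Biostrings::width(ref)), 1e4)
  gc <- sum(Biostrings::letterFrequency(ref, "GC"))
  expect_lt(abs(gc - 5000), 3 * sqrt(1e4 * 0.25))

  atOnly <- generateReference(simulationConfig(genomeLength = 2000,
                                               gcContent = 0, seed = 1))
  expect_equal(sum(Biostrings::letterFrequency(atOnly, "GC")), 0)
})

test_that("reference generation is deterministic and validates input", {
  cfg <- simulationConfig(genomeLength = 5000, seed = 99)
  expect_identical(as.character(generateReference(cfg)),
                   as.character(generateReference(cfg)))
  expect_error(simulationConfig(genomeLength = 0), "genomeLength")
  expect_error(simulationConfig(genomeLength = 2, nChromosomes = 5),
               "nChromosomes")
})

test_that("annotation tracks hit their genome fractions", {
  cfg <- simulationConfig(genomeLength = 1e6, geneFraction = 0.3,
                          cpgIslandFraction = 0.10, seed = 3)
  ref <- generateReference(cfg)
  ann <- generateAnnotation(cfg, ref)
  geneLen <- sum(GenomicRanges::width(ann$genes))
  expect_lt(abs(geneLen - 3e5), 1e4)
  cpgLen <- sum(GenomicRanges::width(ann$cpgIslands))
  expect_lt(abs(cpgLen / 1e6 - 0.10), 0.01)
  # non-overlapping within each track
  expect_equal(sum(GenomicRanges::width(GenomicRanges::reduce(ann$genes))),
               geneLen)

  none <- generateAnnotation(
    simulationConfig(genomeLength = 1e5, geneFraction = 0, seed = 3), ref)
  expect_length(none$genes, 0)
})

test_that("zero mutation rate and zero error give a silent family", {
  exp <- denseExperiment(genomeLength = 2e4, mu = 0, seqErrorRate = 0,
                         seed = 5)
  expect_equal(nrow(truthSet(exp)), 0)
  st <- siteTable(exp)
  gtCols <- grep("^GT\\.", names(st), value = TRUE)
  expect_true(all(st[gtCols] == "0/0"))
  expect_equal(nrow(dnmCalls(callDnms(exp))), 0)
})

test_that("truth DNM count follows the binomial expectation", {
  cfg <- simulationConfig(genomeLength = 1e7, nOffspring = 10, mu = 1e-6,
                          seed = 21)
  exp <- simulateTrio(cfg)   # sparse mode at this size
  expect_identical(exp@mode, "sparse")
  n <- nrow(truthSet(exp))
  expect_lt(abs(n - 200), 3 * sqrt(200))
})

test_that("every truth record appears heterozygous in the site table", {
  exp <- denseExperiment(genomeLength = 5e4, mu = 3e-5, seed = 13)
  tr <- truthSet(exp)
  expect_gt(nrow(tr), 0)
  st <- siteTable(exp)
  key <- paste(st$chrom, st$pos)
  for (j in seq_len(nrow(tr))) {
    i <- match(paste(tr$chrom[j], tr$pos[j]), key)
    expect_false(is.na(i))
    expect_identical(st[[paste0("GT.", tr$offspring[j])]][i], "0/1")
  }
  # positions unique per offspring
  expect_false(anyDuplicated(tr[, c("chrom", "pos", "offspring")]) > 0)
})

test_that("alt-read fraction at truth sites is binomial around one half", {
  exp <- denseExperiment(genomeLength = 1e5, nOffspring = 6, mu = 5e-5,
                         seed = 17)
  tr <- truthSet(exp)
  st <- siteTable(exp)
  key <- paste(st$chrom, st$pos)
  ad <- dp <- numeric(nrow(tr))
  for (j in seq_len(nrow(tr))) {
    i <- match(paste(tr$chrom[j], tr$pos[j]), key)
    ad[j] <- st[[paste0("AD.", tr$offspring[j])]][i]
    dp[j] <- st[[paste0("DP.", tr$offspring[j])]][i]
  }
  frac <- sum(ad) / sum(dp)
  se <- 0.5 / sqrt(sum(dp))
  expect_lt(abs(frac - 0.5), 3 * se)
  # depth sample mean near the configured mean
  dpCols <- grep("^DP\\.", names(st), value = TRUE)
  expect_lt(abs(mean(as.matrix(st[dpCols])) - 30), 0.5)
})

test_that("simulation is deterministic given the seed", {
  cfg <- simulationConfig(genomeLength = 3e4, nOffspring = 3, mu = 2e-5,
                          seed = 31)
  a <- simulateTrio(cfg)
  b <- simulateTrio(cfg)
  expect_identical(siteTable(a), siteTable(b))
  expect_identical(truthSet(a), truthSet(b))
  expect_identical(callableSites(a), callableSites(b))

  cfgS <- simulationConfig(genomeLength = 2e6, nOffspring = 3, mu = 1e-6,
                           seed = 31)
  a <- simulateTrio(cfgS)
  b <- simulateTrio(cfgS)
  expect_identical(a@mode, "sparse")
  expect_identical(siteTable(a), siteTable(b))
  expect_identical(callableSites(a), callableSites(b))
})

test_that("sparse callable mask agrees with dense enumeration in law", {
  # same config run dense: enumerated callable fraction should sit within
  # binomial noise of the analytic p_callable used by sparse mode
  cfg <- simulationConfig(genomeLength = 4e4, nOffspring = 3,
                          lowMqFraction = 0.02, seed = 19)
  exp <- simulateTrio(cfg, mode = "dense")
  cal <- callableSites(exp)
  p <- TrioDNM:::.pCallable(cfg)
  for (off in sampleLayout(exp)$offspring) {
    tot <- sum(cal$sites[cal$offspring == off])
    expect_lt(abs(tot - 4e4 * p), 4 * sqrt(4e4 * p * (1 - p)) + 1)
  }
})

test_that("truth strata are conserved and labelled consistently", {
  exp <- denseExperiment(genomeLength = 1e5, mu = 4e-5, seed = 23,
                         geneFraction = 0.4)
  tr <- truthSet(exp)
  expect_gt(nrow(tr), 0)
  expect_true(all(tr$baseClass ==
                  ifelse(tr$ref %in% c("C", "G"), "CG", "AT")))
  byStratum <- table(tr$region, tr$baseClass)
  expect_equal(sum(byStratum), nrow(tr))
})
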