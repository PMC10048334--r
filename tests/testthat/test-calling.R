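test_that("single-record filters reject for the documented reasons", {
  ly <- toyLayout()
  off <- ly$offspring[1]
  base <- function(...) toySite(ly, gt = setNames(list("0/1"), off), ...)

  low <- base(dp = setNames(list(9), off), ad = setNames(list(5), off))
  expect_identical(applyFilters(low, ly, off), "low_depth")

  frac <- base(dp = setNames(list(12), off), ad = setNames(list(3), off))
  expect_identical(applyFilters(frac, ly, off), "low_alt_fraction")

  mq <- base(mq = 19, dp = setNames(list(20), off),
             ad = setNames(list(10), off))
  expect_identical(applyFilters(mq, ly, off), "low_mq")

  lowq <- base(lowq = TRUE, dp = setNames(list(20), off),
               ad = setNames(list(10), off))
  expect_identical(applyFilters(lowq, ly, off), "caller_low_quality")

  multi <- base(nonref = 3, dp = setNames(list(20), off),
                ad = setNames(list(10), off))
  expect_identical(applyFilters(multi, ly, off), "multi_nonref_read")

  pardp <- base(dp = setNames(list(20, 8), c(off, "parent1")),
                ad = setNames(list(10), off))
  expect_identical(applyFilters(pardp, ly, off), "parent_alt_or_low_depth")

  parad <- base(dp = setNames(list(20), off),
                ad = setNames(list(10, 1), c(off, "parent2")))
  expect_identical(applyFilters(parad, ly, off), "parent_alt_or_low_depth")

  ok <- base(dp = setNames(list(15, 20, 20), c(off, "parent1", "parent2")),
             ad = setNames(list(7), off))
  expect_identical(applyFilters(ok, ly, off), "accept")
})

test_that("the first failing rule wins when several rules fail", {
  ly <- toyLayout()
  off <- ly$offspring[1]
  row <- toySite(ly, mq = 10, lowq = TRUE, nonref = 5,
                 gt = setNames(list("0/1"), off),
                 dp = setNames(list(5, 4), c(off, "parent1")),
                 ad = setNames(list(1), off))
  expect_identical(applyFilters(row, ly, off), "low_depth")
  row$MQ <- 10
  row[[paste0("DP.", off)]] <- 20L
  expect_identical(applyFilters(row, ly, off), "low_mq")
})

test_that("malformed records and inputs are rejected", {
  ly <- toyLayout()
  row <- toySite(ly, gt = setNames(list("0/1"), ly$offspring[1]))
  expect_error(applyFilters(row, ly, "nonexistent"), "malformed record")
  dup <- rbind(row, row)
  expect_error(callDnms(dup, ly), "malformed input")
  expect_error(callDnms(row, samples = NULL), "layout")
})

test_that("variants shared across offspring are rejected, single het accepted", {
  ly <- toyLayout(3)
  shared <- toySite(ly, pos = 10,
                    gt = setNames(list("0/1", "0/1"), ly$offspring[1:2]),
                    ad = setNames(list(15, 14), ly$offspring[1:2]))
  clean <- toySite(ly, pos = 20, gt = setNames(list("0/1"), ly$offspring[1]),
                   ad = setNames(list(14), ly$offspring[1]))
  hom <- toySite(ly, pos = 30, gt = setNames(list("1/1"), ly$offspring[2]),
                 ad = setNames(list(28), ly$offspring[2]))
  cs <- callDnms(toySites(ly, shared, clean, hom), ly)
  expect_equal(nrow(dnmCalls(cs)), 1)
  expect_equal(dnmCalls(cs)$pos, 20)
  expect_identical(dnmCalls(cs)$genotype, "0/1")
  rej <- rejectionLedger(cs)
  expect_setequal(rej$reason[rej$pos == 10], "shared_across_offspring")
  expect_setequal(rej$reason[rej$pos == 30], "not_heterozygous")
  # every rejected site carries exactly one reason
  expect_equal(anyDuplicated(rej[, c("chrom", "pos", "offspring")]), 0)
})

test_that("calls match a brute-force row-by-row oracle on simulated tables", {
  for (seed in c(101, 202)) {
    exp <- denseExperiment(genomeLength = 2e4, nOffspring = 5, mu = 1e-4,
                           seed = seed, lowMqFraction = 0.1,
                           lowQualityFraction = 0.05,
                           multiNonrefFraction = 0.05, seqErrorRate = 5e-3)
    st <- siteTable(exp)
    gtCols <- paste0("GT.", sampleLayout(exp)$offspring)
    cand <- st[rowSums(st[gtCols] != "0/0") > 0, , drop = FALSE]
    expect_gt(nrow(cand), 0)
    expect_lte(nrow(cand), 1000)
    got <- dnmCalls(callDnms(exp, annotate = FALSE))
    want <- oracleCallDnms(cand, sampleLayout(exp))
    expect_equal(nrow(got), nrow(want))
    expect_identical(paste(got$chrom, got$pos, got$offspring),
                     paste(want$chrom, want$pos, want$offspring))
    # per-record reasons agree too
    ly <- sampleLayout(exp)
    off <- ly$offspring[2]
    sub <- cand[seq_len(min(nrow(cand), 200)), , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      expect_identical(applyFilters(sub[i, ], ly, off),
                       oracleFilterReason(sub[i, ], ly, off))
    }
  }
})

test_that("perfect data gives perfect recall and no false calls", {
  exp <- denseExperiment(genomeLength = 1e5, nOffspring = 5, mu = 5e-5,
                         meanDepth = 100, seqErrorRate = 0,
                         lowMqFraction = 0, seed = 77)
  cs <- callDnms(exp)
  tr <- truthSet(exp)
  got <- paste(dnmCalls(cs)$chrom, dnmCalls(cs)$pos, dnmCalls(cs)$offspring)
  want <- paste(tr$chrom, tr$pos, tr$offspring)
  expect_setequal(got, want)
  expect_equal(nrow(dnmCalls(cs)), nrow(tr))
})

test_that("callable counting matches direct enumeration and partitions", {
  ly <- toyLayout(1)
  off <- ly$offspring[1]
  rows <- toySites(ly,
    toySite(ly, pos = 1, alt = NA),
    toySite(ly, pos = 2, alt = NA, dp = list(parent1 = 5)),
    toySite(ly, pos = 3, alt = NA, dp = list(parent2 = 9)),
    toySite(ly, pos = 4, alt = NA),
    toySite(ly, pos = 5, alt = NA))
  cal <- countCallable(rows, ly, off)
  expect_equal(sum(cal$sites), 3)

  exp <- denseExperiment(genomeLength = 5e4, geneFraction = 0.4, seed = 55)
  st <- siteTable(exp)
  lyE <- sampleLayout(exp)
  cal <- countCallable(st, lyE, lyE$offspring[1], genes = geneTrack(exp))
  whole <- countCallable(st, lyE, lyE$offspring[1])
  expect_equal(sum(cal$sites), sum(whole$sites))
  gene <- sum(cal$sites[cal$region == "gene"])
  expect_lt(abs(gene / sum(cal$sites) - 0.4), 0.03)
})

test_that("standing parental variation is filtered out of DNM calls", {
  exp <- denseExperiment(genomeLength = 3e4, nOffspring = 4, mu = 0,
                         standingHetRate = 5e-3, seqErrorRate = 0, seed = 9)
  st <- siteTable(exp)
  expect_gt(sum(st$`GT.parent1` == "0/1"), 0)
  cs <- callDnms(exp)
  expect_equal(nrow(dnmCalls(cs)), 0)
  expect_true(all(rejectionLedger(cs)$reason %in%
                  c("shared_across_offspring", "parent_alt_or_low_depth",
                    "low_alt_fraction", "low_depth", "low_mq")))
})
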