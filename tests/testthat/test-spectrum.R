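test_that("substitutions classify into the six strand-collapsed types", {
  expect_equal(classifyMutation("C", "T"),
               data.frame(type = "G:C->A:T", tsTv = "Ts",
                          stringsAsFactors = FALSE))
  expect_equal(classifyMutation("T", "G")$type, "A:T->C:G")
  expect_equal(classifyMutation("T", "G")$tsTv, "Tv")
  expect_equal(classifyMutation("G", "C")$type, "G:C->C:G")
  expect_equal(classifyMutation("G", "C")$tsTv, "Tv")
  expect_error(classifyMutation("N", "A"), "unsupported base")
  expect_error(classifyMutation("A", "A"), "must differ")
})

test_that("classification is invariant under strand complement", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (r in names(comp)) for (a in names(comp)) {
    if (r == a) next
    expect_identical(classifyMutation(r, a),
                     classifyMutation(comp[[r]], comp[[a]]),
                     info = paste(r, a))
  }
  # the 12 ordered pairs collapse to exactly 6 types, 2 pairs each
  pairs <- expand.grid(r = names(comp), a = names(comp),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$r != pairs$a, ]
  types <- classifyMutation(pairs$r, pairs$a)$type
  expect_equal(sort(unique(types)),
               sort(c("A:T->C:G", "A:T->G:C", "A:T->T:A",
                      "G:C->A:T", "G:C->C:G", "G:C->T:A")))
  expect_true(all(table(types) == 2))
})

test_that("an unbiased substitution model gives Ts/Tv = 0.5, shares = 1/6", {
  n <- 1e5
  draws <- withr::with_seed(808, {
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
    classifyMutation(ref, alt)
  })
  ts <- sum(draws$tsTv == "Ts")
  ratio <- ts / (n - ts)
  # Ts count ~ Binomial(n, 1/3); propagate 3 SE to the ratio
  seTs <- sqrt(n / 3 * 2 / 3)
  band <- c((n / 3 - 3 * seTs) / (2 * n / 3 + 3 * seTs),
            (n / 3 + 3 * seTs) / (2 * n / 3 - 3 * seTs))
  expect_gt(ratio, band[1])
  expect_lt(ratio, band[2])
  shares <- table(draws$type) / n
  se <- sqrt((1 / 6) * (5 / 6) / n)
  expect_true(all(abs(shares - 1 / 6) < 3 * se))
})

test_that("spectrum summary counts partition and rates add within class", {
  exp <- denseExperiment(genomeLength = 1e5, nOffspring = 6, mu = 4e-5,
                         seed = 99)
  cs <- callDnms(exp)
  s <- spectrumSummary(cs)
  expect_equal(s$ts + s$tv, sum(s$counts))
  expect_equal(unname(s$ts),
               unname(s$counts["A:T->G:C"] + s$counts["G:C->A:T"]))
  at <- c("A:T->C:G", "A:T->G:C", "A:T->T:A")
  expect_equal(unname(s$classRates["AT"]), sum(s$rates[at]))
  expect_equal(unname(s$classRates["CG"]), sum(s$rates[setdiff(names(s$rates),
                                                               at)]))
  expect_equal(nrow(dnmCalls(cs)), sum(s$counts))
})

test_that("an imposed transition excess at C/G sites is recovered", {
  exp <- denseExperiment(genomeLength = 2e5, nOffspring = 8, mu = 4e-5,
                         seed = 123, transitionBias = c(AT = 1 / 3, CG = 0.8),
                         seqErrorRate = 0, lowMqFraction = 0)
  tr <- truthSet(exp)
  cg <- tr[tr$baseClass == "CG", ]
  isTs <- classifyMutation(cg$ref, cg$alt)$type == "G:C->A:T"
  p <- mean(isTs)
  se <- sqrt(0.8 * 0.2 / nrow(cg))
  expect_lt(abs(p - 0.8), 3 * se)
})

test_that("CpG-island association matches the two-proportion oracle", {
  calls <- data.frame(chrom = "chr1", pos = seq_len(100),
                      mutationType = "G:C->A:T",
                      inCpgIsland = c(rep(TRUE, 10), rep(FALSE, 90)),
                      stringsAsFactors = FALSE)
  res <- cpgIslandAssociation(calls, genomeCpgFraction = 0.10)
  expect_equal(res$observed, 0.10)
  expect_gt(res$p, 0.95)

  enr <- calls
  enr$inCpgIsland <- TRUE
  res2 <- cpgIslandAssociation(enr, genomeCpgFraction = 0.10)
  expect_lt(res2$p, 0.001)
  want <- oracleTwoProp(100, 100, 10, 100)
  expect_equal(res2$p, unname(want["p"]))

  none <- calls[0, ]
  expect_error(cpgIslandAssociation(none), "undefined test")
})

test_that("context matrix orients the mutated base to C and profiles flanks", {
  # reference with a known motif: every call at the C of an ACG triplet
  seqs <- Biostrings::DNAStringSet(c(chr1 = paste(
    rep("TTTTTTTACGTTTTTTTTTT", 10), collapse = "")))
  pos <- 9 + 20 * (0:8)   # the C of each ACG, away from contig ends
  calls <- data.frame(chrom = "chr1", pos = pos, ref = "C",
                      stringsAsFactors = FALSE)
  cm <- contextMatrix(calls, seqs, flank = 5)
  expect_equal(dim(cm), c(4, 11))
  expect_equal(unname(cm["C", "0"]), 1)
  expect_equal(unname(cm["G", "1"]), 1)
  expect_equal(unname(cm["A", "-1"]), 1)
  expect_true(all(abs(colSums(cm) - 1) < 1e-12))
  expect_equal(attr(cm, "cgPlusOneFraction"), 1)

  # G-reference calls are reverse-complemented onto the C strand
  gcalls <- data.frame(chrom = "chr1", pos = pos + 1, ref = "G",
                       stringsAsFactors = FALSE)
  gm <- contextMatrix(gcalls, seqs, flank = 5)
  expect_equal(unname(gm["C", "0"]), 1)
  # the CpG dinucleotide reads C..G on the oriented strand
  expect_equal(unname(gm["G", "1"]), 1)
  expect_equal(unname(gm["A", "-1"]), 1)

  bad <- data.frame(chrom = "chr1", pos = 1, ref = "C")
  expect_error(suppressWarnings(contextMatrix(bad, seqs, flank = 5)))
  wrong <- data.frame(chrom = "chr1", pos = 10, ref = "C")  # actually G
  expect_error(contextMatrix(wrong, seqs, flank = 3), "mismatch")
})

test_that("null CG-dinucleotide fraction tracks the genome base composition", {
  cfg <- simulationConfig(genomeLength = 2e5, gcContent = 0.4, seed = 12)
  ref <- generateReference(cfg)
  # random C positions mimic an unbiased C:G->T:A call set
  chr <- as.character(ref[[1]])
  cpos <- withr::with_seed(3, sample(which(strsplit(chr, "")[[1]] == "C" &
                                           seq_len(nchar(chr)) > 10 &
                                           seq_len(nchar(chr)) <
                                             nchar(chr) - 10), 400))
  calls <- data.frame(chrom = names(ref)[1], pos = cpos, ref = "C",
                      stringsAsFactors = FALSE)
  cm <- contextMatrix(calls, ref)
  pG <- 0.2   # gcContent / 2
  se <- sqrt(pG * (1 - pG) / 400)
  expect_lt(abs(attr(cm, "cgPlusOneFraction") - pG), 3 * se)
})
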