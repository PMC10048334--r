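#' Spike synthetic heterozygous mutations into a trio experiment
#'
#' Emulates the read-level spike-in protocol at the site-table level: for
#' each of \code{nSites} positions drawn uniformly from non-variant genomic
#' positions (and a uniformly chosen offspring), \code{y ~ Binomial(x, 0.5)}
#' of the offspring's \code{x} reads are switched to a uniformly chosen
#' non-reference base and the offspring genotype is set heterozygous. The
#' modified experiment is then re-called with the ordinary pipeline and
#' recovery is scored per spike.
#'
#' In dense mode existing rows are modified (their originals are kept in the
#' ledger so \code{\link{unspike}} can restore the table bit-exactly); in
#' sparse mode new rows are synthesised at unoccupied positions with depth
#' and mapping quality drawn from the experiment's own model.
#'
#' @param experiment a \linkS4class{TrioExperiment}.
#' @param nSites number of spiked mutations (default 1000).
#' @param seed RNG seed.
#' @param excludeVariant exclude positions that already carry variant
#'   evidence (default TRUE).
#' @return list(experiment = spiked \linkS4class{TrioExperiment},
#'   ledger = data.frame(chrom, pos, offspring, x, y, alt)). The ledger
#'   carries the replaced original rows (dense mode) as attribute
#'   \code{"originalRows"}.
#' @export
spikeIn <- function(experiment, nSites = 1000L, seed = NULL,
                    excludeVariant = TRUE) {
  cfg <- experiment@config
  samples <- experiment@samples
  sites <- experiment@sites
  withSeed(seed, {
    if (experiment@mode == "dense") {
      isVariant <- !is.na(sites$alt)
      pool <- if (excludeVariant) which(!isVariant) else seq_len(nrow(sites))
      if (nSites > length(pool))
        .stopf("invalid config: nSites exceeds available sites (%d)",
               length(pool))
      rows <- sample(pool, nSites)
      originals <- sites[rows, , drop = FALSE]
      off <- sample(samples$offspring, nSites, replace = TRUE)
      x <- vapply(seq_len(nSites),
                  function(i) sites[[.dpCol(off[i])]][rows[i]], numeric(1))
      y <- rbinom(nSites, x, 0.5)
      altBase <- vapply(sites$ref[rows], function(r)
        sample(setdiff(.BASES, r), 1L), character(1))
      for (i in seq_len(nSites)) {
        sites$alt[rows[i]] <- altBase[i]
        sites[[.gtCol(off[i])]][rows[i]] <- "0/1"
        sites[[.adCol(off[i])]][rows[i]] <- y[i]
      }
      ledger <- data.frame(chrom = sites$chrom[rows], pos = sites$pos[rows],
                           offspring = off, x = x, y = y, alt = altBase,
                           stringsAsFactors = FALSE)
      attr(ledger, "originalRows") <- originals
    } else {
      lens <- setNames(Biostrings::width(experiment@reference),
                       names(experiment@reference))
      L <- sum(lens)
      if (nSites > L - nrow(sites))
        .stopf("invalid config: nSites exceeds available sites")
      occupied <- paste(sites$chrom, sites$pos)
      whole <- GenomicRanges::GRanges(names(lens),
                                      IRanges::IRanges(1, lens))
      got <- data.frame(chrom = character(), pos = integer())
      while (nrow(got) < nSites) {
        cand <- .samplePosInRanges(whole, 2L * (nSites - nrow(got)) + 8L)
        keep <- !(paste(cand$chrom, cand$pos) %in% occupied)
        got <- unique(rbind(got, cand[keep, , drop = FALSE]))
      }
      got <- got[seq_len(nSites), , drop = FALSE]
      got$ref <- .refBaseAt(experiment@reference, got$chrom, got$pos)
      off <- sample(samples$offspring, nSites, replace = TRUE)
      allSamples <- c(samples$parents, samples$offspring)
      nS <- length(allSamples)
      DP <- matrix(.drawDepth(nSites * nS, cfg@meanDepth,
                              cfg@depthDispersion),
                   nrow = nSites, dimnames = list(NULL, allSamples))
      AD <- matrix(0L, nSites, nS, dimnames = list(NULL, allSamples))
      if (cfg@seqErrorRate > 0)
        AD[] <- rbinom(nSites * nS, as.vector(DP), cfg@seqErrorRate)
      GT <- matrix("0/0", nSites, nS, dimnames = list(NULL, allSamples))
      x <- vapply(seq_len(nSites), function(i) DP[i, off[i]], numeric(1))
      y <- rbinom(nSites, x, 0.5)
      altBase <- vapply(got$ref, function(r)
        sample(setdiff(.BASES, r), 1L), character(1))
      newRows <- data.frame(chrom = got$chrom, pos = got$pos, ref = got$ref,
                            alt = altBase,
                            MQ = .mqDraw(nSites, cfg@lowMqFraction),
                            LOWQ = runif(nSites) < cfg@lowQualityFraction,
                            NONREF = 1L, stringsAsFactors = FALSE)
      newRows$NONREF[runif(nSites) < cfg@multiNonrefFraction] <- 3L
      for (i in seq_len(nSites)) {
        GT[i, off[i]] <- "0/1"
        AD[i, off[i]] <- y[i]
      }
      for (s in allSamples) {
        newRows[[.gtCol(s)]] <- GT[, s]
        newRows[[.dpCol(s)]] <- as.integer(DP[, s])
        newRows[[.adCol(s)]] <- as.integer(AD[, s])
      }
      sites <- rbind(sites, newRows)
      sites <- sites[order(match(sites$chrom, names(lens)), sites$pos), ,
                     drop = FALSE]
      rownames(sites) <- NULL
      ledger <- data.frame(chrom = got$chrom, pos = got$pos, offspring = off,
                           x = x, y = y, alt = altBase,
                           stringsAsFactors = FALSE)
      attr(ledger, "originalRows") <- NULL
    }
    spiked <- experiment
    spiked@sites <- sites
    list(experiment = spiked, ledger = ledger)
  })
}

#' Undo a spike-in, restoring the original site table
#'
#' @param experiment the spiked \linkS4class{TrioExperiment}.
#' @param ledger the ledger returned by \code{\link{spikeIn}}.
#' @return The experiment with the original site table restored.
#' @export
unspike <- function(experiment, ledger) {
  sites <- experiment@sites
  key <- paste(sites$chrom, sites$pos)
  spikedKey <- paste(ledger$chrom, ledger$pos)
  originals <- attr(ledger, "originalRows")
  if (is.null(originals)) {          # sparse: spiked rows were appended
    sites <- sites[!(key %in% spikedKey), , drop = FALSE]
  } else {                           # dense: spiked rows were modified
    idx <- match(spikedKey, key)
    sites[idx, ] <- originals
  }
  rownames(sites) <- NULL
  experiment@sites <- sites
  experiment
}

#' False-negative rate of the caller from a spike-in ledger
#'
#' FN = 1 - recovered/spiked, as a percentage rounded to one decimal.
#' A spike is recovered when a call matching its (chrom, pos, offspring)
#' appears in the re-called DNM set.
#'
#' @param ledger spike-in ledger.
#' @param calls calls data.frame (or \linkS4class{DnmCallSet}) from
#'   re-calling the spiked experiment.
#' @return FN percentage (1 decimal), with attributes \code{recovered},
#'   \code{n} and \code{fraction} (unrounded).
#' @examples
#' # 914 of 1000 spikes recovered -> 8.6
#' @export
falseNegativeRate <- function(ledger, calls) {
  if (!nrow(ledger)) .stopf("empty spike-in ledger")
  if (is(calls, "DnmCallSet")) calls <- calls@calls
  hit <- paste(ledger$chrom, ledger$pos, ledger$offspring) %in%
    paste(calls$chrom, calls$pos, calls$offspring)
  fn <- 1 - sum(hit) / nrow(ledger)
  structure(round(100 * fn, 1), recovered = sum(hit), n = nrow(ledger),
            fraction = fn)
}

#' Analytic false-negative rate under the simulation model
#'
#' Closed-form recovery probability of a spiked heterozygous mutation:
#' the site must draw mapping quality >= 20, the offspring and both parents
#' depth >= 10, the binomial alternate-read count y ~ Binomial(x, 0.5) must
#' reach 30% of depth x, and neither parent may carry an error read. Used as
#' the independent check of the measured spike-in FN.
#'
#' @param config the \linkS4class{SimulationConfig} of the spiked
#'   experiment.
#' @param thresholds see \code{\link{dnmThresholds}}.
#' @return Expected FN as a fraction.
#' @export
analyticFalseNegativeRate <- function(config, thresholds = dnmThresholds()) {
  pmf <- .depthPmf(config@meanDepth, config@depthDispersion)
  x <- pmf$x; px <- pmf$p
  # offspring: depth >= 10 and y/x >= altFraction
  yMax <- ceiling(thresholds$altFraction * x) - 1   # largest failing y
  pAltOk <- 1 - pbinom(yMax, x, 0.5)
  pOff <- sum(px[x >= thresholds$depth] * pAltOk[x >= thresholds$depth])
  # parent: depth >= 10 and zero alternate (error) reads
  pParent <- sum(px[x >= thresholds$depth] *
                 (1 - config@seqErrorRate)^x[x >= thresholds$depth])
  pMq <- 1 - config@lowMqFraction
  pLowq <- 1 - config@lowQualityFraction
  pNonref <- 1 - config@multiNonrefFraction
  1 - pMq * pLowq * pNonref * pOff * pParent^2
}

#' Sanger-verification positive rate
#'
#' 100 * confirmed / tested, rounded to the nearest integer percent.
#'
#' @param nConfirmed candidates confirmed as genuine mutations.
#' @param nTested candidates tested.
#' @return Integer percentage with attribute \code{fraction}.
#' @examples
#' positiveRate(79, 84)   # 94
#' @export
positiveRate <- function(nConfirmed, nTested) {
  if (nTested < 1L) .stopf("nTested must be >= 1")
  if (nConfirmed > nTested || nConfirmed < 0)
    .stopf("nConfirmed must lie in [0, nTested]")
  structure(round(100 * nConfirmed / nTested),
            fraction = nConfirmed / nTested)
}

#' Calibration-corrected mutation rate
#'
#' corrected = raw * truePositiveRate / (1 - falseNegativeRate). Off by
#' default in reporting; offered for sensitivity analysis.
#'
#' @param raw uncorrected rate.
#' @param tpRate true-positive fraction in (0, 1].
#' @param fnRate false-negative fraction in [0, 1).
#' @return Corrected rate.
#' @examples
#' correctedRate(4.09e-9, 0.94, 0.086)
#' @export
correctedRate <- function(raw, tpRate, fnRate) {
  if (tpRate <= 0 || tpRate > 1) .stopf("tpRate must be in (0, 1]")
  if (fnRate < 0 || fnRate >= 1)
    .stopf("undefined correction: fnRate must be in [0, 1)")
  raw * tpRate / (1 - fnRate)
}
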