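.sampleNames <- function(n)
  list(parents = c("parent1", "parent2"),
       offspring = sprintf("offspring%02d", seq_len(n)))

.gtCol <- function(s) paste0("GT.", s)
.dpCol <- function(s) paste0("DP.", s)
.adCol <- function(s) paste0("AD.", s)

# 2x2 site counts: region (gene/intergenic) x base class (AT/CG).
.strataCounts <- function(reference, genes) {
  total <- sum(Biostrings::width(reference))
  gcTotal <- sum(Biostrings::letterFrequency(reference, "GC"))
  geneLen <- 0
  geneGC <- 0
  if (length(genes)) {
    for (chr in names(reference)) {
      g <- genes[as.character(GenomicRanges::seqnames(genes)) == chr]
      if (!length(g)) next
      v <- Biostrings::Views(reference[[chr]],
                             start = GenomicRanges::start(g),
                             end = GenomicRanges::end(g))
      geneLen <- geneLen + sum(IRanges::width(v))
      geneGC <- geneGC + sum(Biostrings::letterFrequency(v, "GC"))
    }
  }
  m <- matrix(c(geneLen - geneGC, geneGC,
                (total - geneLen) - (gcTotal - geneGC), gcTotal - geneGC),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("gene", "intergenic"), c("AT", "CG")))
  m
}

.refBaseAt <- function(reference, chrom, pos) {
  out <- character(length(pos))
  for (chr in unique(chrom)) {
    i <- which(chrom == chr)
    out[i] <- as.character(Biostrings::extractAt(
      reference[[chr]], IRanges::IRanges(pos[i], width = 1)))
  }
  out
}

# Uniform positions within a GRanges track; returns data.frame(chrom, pos).
.samplePosInRanges <- function(gr, n) {
  if (n == 0L) return(data.frame(chrom = character(), pos = integer()))
  w <- GenomicRanges::width(gr)
  pick <- sample.int(length(gr), n, replace = TRUE, prob = w)
  off <- floor(runif(n) * w[pick])
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr))[pick],
             pos = GenomicRanges::start(gr)[pick] + as.integer(off))
}

# Choose alternate bases given reference bases, honouring the transition bias
# of the config (prob. of the transition; transversions split the rest).
.drawAltBase <- function(refBase, transitionBias) {
  tsOf <- c(A = "G", G = "A", C = "T", T = "C")
  n <- length(refBase)
  alt <- character(n)
  cls <- ifelse(refBase %in% c("C", "G"), "CG", "AT")
  pTs <- transitionBias[cls]
  isTs <- runif(n) < pTs
  alt[isTs] <- tsOf[refBase[isTs]]
  for (i in which(!isTs)) {
    tv <- setdiff(.BASES, c(refBase[i], tsOf[[refBase[i]]]))
    alt[i] <- tv[sample.int(2L, 1L)]
  }
  alt
}

.mqDraw <- function(n, lowFraction) {
  low <- runif(n) < lowFraction
  mq <- rep(60, n)
  if (any(low)) mq[low] <- sample(0:19, sum(low), replace = TRUE)
  mq
}

#' Simulate a full-sib trio sequencing experiment
#'
#' Generates per-site read evidence for two homozygous-reference parents and
#' \code{nOffspring} full-sib offspring. Each offspring acquires heterozygous
#' de novo mutations independently at per-site probability 2 x mu(stratum)
#' (two allele copies). Per-sample depth is Poisson (or negative binomial)
#' with mean \code{meanDepth}; at a true heterozygous site the
#' alternate-supporting read count is Binomial(depth, 0.5); at all other
#' sample/site combinations sequencing error contributes alternate reads at
#' \code{seqErrorRate} per read. Mapping quality is drawn per site, with a
#' configured fraction below 20.
#'
#' Two emission modes exist. \code{"dense"} materialises one row per genomic
#' site, so downstream callable-site counting enumerates the table directly;
#' it is intended for genomes up to a few hundred kb. \code{"sparse"} only
#' materialises rows that carry variant evidence (true mutations and standing
#' variants) and records callable-site counts by drawing, per offspring and
#' stratum, from Binomial(N_stratum, p_callable) with p_callable derived
#' from the identical depth/MQ model - the exact marginal distribution of
#' the enumerated count. Error-only sites (homozygous-reference genotypes
#' with stray alternate reads) are not materialised in sparse mode; they
#' cannot produce candidate calls, which require a non-reference genotype.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param reference optional genome; generated from \code{config} when NULL.
#' @param annotation optional list(genes, cpgIslands); generated when NULL.
#' @param mode \code{"auto"} (default), \code{"dense"} or \code{"sparse"}.
#'   Auto selects dense when sites x samples <= 6e6.
#' @return A \linkS4class{TrioExperiment}.
#' @examples
#' cfg <- simulationConfig(genomeLength = 5e4, nOffspring = 4, mu = 1e-5,
#'                         seed = 11)
#' exp <- simulateTrio(cfg)
#' exp
#' @export
simulateTrio <- function(config, reference = NULL, annotation = NULL,
                         mode = c("auto", "dense", "sparse")) {
  validObject(config)
  mode <- match.arg(mode)
  if (is.null(reference)) reference <- generateReference(config)
  if (is.null(annotation)) annotation <- generateAnnotation(config, reference)
  nS <- config@nOffspring + 2L
  L <- sum(Biostrings::width(reference))
  if (mode == "auto")
    mode <- if (L * nS <= 6e6) "dense" else "sparse"
  samples <- .sampleNames(config@nOffspring)
  withSeed(config@seed + 2L, {
    if (mode == "dense")
      .simulateDense(config, reference, annotation, samples)
    else
      .simulateSparse(config, reference, annotation, samples)
  })
}

.emptySites <- function(samples) {
  df <- data.frame(chrom = character(), pos = integer(), ref = character(),
                   alt = character(), MQ = numeric(), LOWQ = logical(),
                   NONREF = integer(), stringsAsFactors = FALSE)
  for (s in c(samples$parents, samples$offspring)) {
    df[[.gtCol(s)]] <- character()
    df[[.dpCol(s)]] <- integer()
    df[[.adCol(s)]] <- integer()
  }
  df
}

.emptyTruth <- function()
  data.frame(chrom = character(), pos = integer(), offspring = character(),
             ref = character(), alt = character(), region = character(),
             baseClass = character(), stringsAsFactors = FALSE)

.siteRegions <- function(chrom, pos, genes) {
  if (is.null(genes) || !length(genes))
    return(rep("intergenic", length(chrom)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1))
  hit <- IRanges::overlapsAny(q, genes, ignore.strand = TRUE)
  ifelse(hit, "gene", "intergenic")
}

.simulateDense <- function(config, reference, annotation, samples) {
  lens <- Biostrings::width(reference)
  chrom <- rep(names(reference), lens)
  pos <- unlist(lapply(lens, seq_len), use.names = FALSE)
  L <- length(pos)
  refChar <- unlist(strsplit(as.character(reference), ""), use.names = FALSE)
  region <- .siteRegions(chrom, pos, annotation$genes)
  cls <- ifelse(refChar %in% c("C", "G"), "CG", "AT")
  muSite <- config@mu[paste(region, cls, sep = "_")]

  allSamples <- c(samples$parents, samples$offspring)
  nS <- length(allSamples)
  MQ <- .mqDraw(L, config@lowMqFraction)
  LOWQ <- runif(L) < config@lowQualityFraction
  NONREF <- rep(1L, L)
  multi <- runif(L) < config@multiNonrefFraction
  NONREF[multi] <- 3L

  DP <- matrix(.drawDepth(L * nS, config@meanDepth, config@depthDispersion),
               nrow = L, ncol = nS, dimnames = list(NULL, allSamples))
  AD <- matrix(0L, L, nS, dimnames = list(NULL, allSamples))
  if (config@seqErrorRate > 0)
    AD[] <- rbinom(L * nS, as.vector(DP), config@seqErrorRate)
  GT <- matrix("0/0", L, nS, dimnames = list(NULL, allSamples))

  truth <- .emptyTruth()
  for (off in samples$offspring) {
    hit <- which(runif(L) < 2 * muSite)
    if (!length(hit)) next
    GT[hit, off] <- "0/1"
    AD[hit, off] <- rbinom(length(hit), DP[hit, off], 0.5)
    truth <- rbind(truth, data.frame(
      chrom = chrom[hit], pos = pos[hit], offspring = off,
      ref = refChar[hit], alt = NA_character_, region = region[hit],
      baseClass = cls[hit], stringsAsFactors = FALSE))
  }

  # one alternate base per site, shared by every sample with evidence there
  alt <- rep(NA_character_, L)
  needKey <- unique(which(rowSums(AD) > 0 | rowSums(GT != "0/0") > 0))
  if (length(needKey))
    alt[needKey] <- .drawAltBase(refChar[needKey], config@transitionBias)
  if (nrow(truth)) {
    gidx <- match(paste(truth$chrom, truth$pos),
                  paste(chrom, pos))
    truth$alt <- alt[gidx]
  }

  # optional parental standing heterozygosity (parent1), Mendelian inheritance
  if (config@standingHetRate > 0) {
    sv <- which(runif(L) < config@standingHetRate)
    for (i in sv) {
      if (is.na(alt[i])) alt[i] <- .drawAltBase(refChar[i],
                                                config@transitionBias)
      GT[i, samples$parents[1]] <- "0/1"
      AD[i, samples$parents[1]] <- rbinom(1, DP[i, samples$parents[1]], 0.5)
      for (off in samples$offspring) if (runif(1) < 0.5) {
        GT[i, off] <- "0/1"
        AD[i, off] <- rbinom(1, DP[i, off], 0.5)
      }
    }
  }

  sites <- data.frame(chrom = chrom, pos = pos, ref = refChar, alt = alt,
                      MQ = MQ, LOWQ = LOWQ, NONREF = NONREF,
                      stringsAsFactors = FALSE, check.names = FALSE)
  for (s in allSamples) {
    sites[[.gtCol(s)]] <- GT[, s]
    sites[[.dpCol(s)]] <- as.integer(DP[, s])
    sites[[.adCol(s)]] <- as.integer(AD[, s])
  }

  callable <- do.call(rbind, lapply(samples$offspring, function(off)
    countCallable(sites, samples, off, genes = annotation$genes)))
  new("TrioExperiment", reference = reference, genes = annotation$genes,
      cpgIslands = annotation$cpgIslands, sites = sites, samples = samples,
      truth = truth, callable = callable, config = config, mode = "dense")
}

# Marginal probability that a site is callable for one offspring under the
# simulation's depth/MQ model: per-site MQ >= 20 and depth >= 10 in the
# offspring and both parents (parents are homozygous reference throughout).
.pCallable <- function(config, thresholds = dnmThresholds()) {
  pmf <- .depthPmf(config@meanDepth, config@depthDispersion)
  pDepth <- sum(pmf$p[pmf$x >= thresholds$depth])
  (1 - config@lowMqFraction) * pDepth^3
}

.simulateSparse <- function(config, reference, annotation, samples) {
  genes <- annotation$genes
  N <- .strataCounts(reference, genes)
  lens <- Biostrings::width(reference)
  names(lens) <- names(reference)
  whole <- GenomicRanges::GRanges(names(lens), IRanges::IRanges(1, lens),
                                  seqlengths = lens)
  intergenic <- if (length(genes))
    GenomicRanges::setdiff(whole, genes, ignore.strand = TRUE) else whole
  tracks <- list(gene = genes, intergenic = intergenic)

  # truth DNMs: count ~ Binomial(N_stratum, 2 mu), positions uniform in the
  # stratum (rejection sampling on the base class)
  truth <- .emptyTruth()
  for (off in samples$offspring) {
    for (rg in rownames(N)) for (bc in colnames(N)) {
      nStr <- N[rg, bc]
      if (nStr == 0) next
      k <- rbinom(1L, nStr, min(1, 2 * config@mu[[paste(rg, bc, sep = "_")]]))
      if (k == 0L) next
      got <- .emptyTruth()[, c("chrom", "pos", "ref")]
      while (nrow(got) < k) {
        cand <- .samplePosInRanges(tracks[[rg]], 2L * (k - nrow(got)) + 4L)
        cand$ref <- .refBaseAt(reference, cand$chrom, cand$pos)
        keep <- ifelse(cand$ref %in% c("C", "G"), "CG", "AT") == bc
        got <- unique(rbind(got, cand[keep, , drop = FALSE]))
      }
      got <- got[seq_len(k), , drop = FALSE]
      truth <- rbind(truth, data.frame(
        chrom = got$chrom, pos = got$pos, offspring = off, ref = got$ref,
        alt = NA_character_, region = rg, baseClass = bc,
        stringsAsFactors = FALSE))
    }
  }

  # standing parental heterozygosity, if enabled
  standing <- NULL
  if (config@standingHetRate > 0) {
    k <- rbinom(1L, sum(N), config@standingHetRate)
    if (k > 0) {
      standing <- .samplePosInRanges(whole, k)
      standing$ref <- .refBaseAt(reference, standing$chrom, standing$pos)
    }
  }

  # materialise one row per distinct variant site
  key <- character(0)
  if (nrow(truth)) key <- paste(truth$chrom, truth$pos)
  siteKey <- unique(c(key, if (!is.null(standing))
    paste(standing$chrom, standing$pos)))
  allSamples <- c(samples$parents, samples$offspring)
  sites <- .emptySites(samples)
  if (length(siteKey)) {
    parts <- do.call(rbind, strsplit(siteKey, " "))
    chrom <- parts[, 1]
    pos <- as.integer(parts[, 2])
    o <- order(match(chrom, names(reference)), pos)
    chrom <- chrom[o]; pos <- pos[o]
    siteKey <- paste(chrom, pos)
    n <- length(pos)
    refBase <- .refBaseAt(reference, chrom, pos)
    alt <- .drawAltBase(refBase, config@transitionBias)
    MQ <- .mqDraw(n, config@lowMqFraction)
    LOWQ <- runif(n) < config@lowQualityFraction
    NONREF <- rep(1L, n)
    NONREF[runif(n) < config@multiNonrefFraction] <- 3L
    sites <- data.frame(chrom = chrom, pos = pos, ref = refBase, alt = alt,
                        MQ = MQ, LOWQ = LOWQ, NONREF = NONREF,
                        stringsAsFactors = FALSE)
    nS <- length(allSamples)
    DP <- matrix(.drawDepth(n * nS, config@meanDepth, config@depthDispersion),
                 nrow = n, dimnames = list(NULL, allSamples))
    AD <- matrix(0L, n, nS, dimnames = list(NULL, allSamples))
    if (config@seqErrorRate > 0)
      AD[] <- rbinom(n * nS, as.vector(DP), config@seqErrorRate)
    GT <- matrix("0/0", n, nS, dimnames = list(NULL, allSamples))
    if (nrow(truth)) {
      truth$alt <- alt[match(paste(truth$chrom, truth$pos), siteKey)]
      for (j in seq_len(nrow(truth))) {
        i <- match(paste(truth$chrom[j], truth$pos[j]), siteKey)
        off <- truth$offspring[j]
        GT[i, off] <- "0/1"
        AD[i, off] <- rbinom(1, DP[i, off], 0.5)
      }
    }
    if (!is.null(standing)) {
      for (j in seq_len(nrow(standing))) {
        i <- match(paste(standing$chrom[j], standing$pos[j]), siteKey)
        p1 <- samples$parents[1]
        GT[i, p1] <- "0/1"
        AD[i, p1] <- rbinom(1, DP[i, p1], 0.5)
        for (off in samples$offspring) if (runif(1) < 0.5) {
          GT[i, off] <- "0/1"
          AD[i, off] <- rbinom(1, DP[i, off], 0.5)
        }
      }
    }
    for (s in allSamples) {
      sites[[.gtCol(s)]] <- GT[, s]
      sites[[.dpCol(s)]] <- as.integer(DP[, s])
      sites[[.adCol(s)]] <- as.integer(AD[, s])
    }
  }

  # analytic callable mask: Binomial(N_stratum, p_callable) per offspring
  p <- .pCallable(config)
  callable <- do.call(rbind, lapply(samples$offspring, function(off) {
    do.call(rbind, lapply(rownames(N), function(rg)
      do.call(rbind, lapply(colnames(N), function(bc) data.frame(
        offspring = off, region = rg, baseClass = bc,
        sites = rbinom(1L, N[rg, bc], p), stringsAsFactors = FALSE)))))
  }))
  new("TrioExperiment", reference = reference, genes = genes,
      cpgIslands = annotation$cpgIslands, sites = sites, samples = samples,
      truth = truth, callable = callable, config = config, mode = "sparse")
}
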