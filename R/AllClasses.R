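#' @import methods
NULL

.MU_STRATA <- c("gene_AT", "gene_CG", "intergenic_AT", "intergenic_CG")

#' Configuration of a synthetic full-sib trio experiment
#'
#' Holds every parameter of the synthetic parents-progeny design: genome
#' composition, annotation fractions, family size, sequencing depth model,
#' error model and the true per-site per-generation mutation rates per
#' stratum (genomic region crossed with reference base class).
#'
#' @slot genomeLength total genome size in bp.
#' @slot gcContent expected G+C fraction of the reference.
#' @slot geneFraction fraction of the genome annotated as genic.
#' @slot cpgIslandFraction fraction of the genome inside CpG islands.
#' @slot nOffspring number of sequenced offspring in the family.
#' @slot meanDepth expected read depth per site per sample.
#' @slot depthDispersion negative-binomial size parameter of the depth
#'   distribution; \code{Inf} selects Poisson depths.
#' @slot seqErrorRate per-base per-read probability that a read supports the
#'   alternate allele at a non-mutated site.
#' @slot mu named numeric of true per-site per-generation mutation rates for
#'   the four strata \code{gene_AT, gene_CG, intergenic_AT, intergenic_CG}.
#' @slot nChromosomes number of chromosomes the genome is split into.
#' @slot lowMqFraction fraction of sites whose mapping quality falls below 20.
#' @slot lowQualityFraction fraction of sites flagged low-quality by the
#'   (emulated) caller.
#' @slot multiNonrefFraction fraction of sites where some read carries more
#'   than two non-reference positions.
#' @slot standingHetRate per-site probability that a parent carries standing
#'   heterozygous variation (0 = fully inbred parents).
#' @slot transitionBias named numeric (\code{AT}, \code{CG}): probability that
#'   a de novo mutation at that base class is the transition; the two
#'   transversions share the remainder equally. 1/3 gives an unbiased
#'   spectrum.
#' @slot geneMeanLength,cpgIslandMeanLength target interval lengths (bp) used
#'   when laying out the annotation tracks.
#' @slot seed integer seed driving every random draw of the simulation.
#' @export
setClass("SimulationConfig", representation(
  genomeLength = "numeric", gcContent = "numeric", geneFraction = "numeric",
  cpgIslandFraction = "numeric", nOffspring = "integer", meanDepth = "numeric",
  depthDispersion = "numeric", seqErrorRate = "numeric", mu = "numeric",
  nChromosomes = "integer", lowMqFraction = "numeric",
  lowQualityFraction = "numeric", multiNonrefFraction = "numeric",
  standingHetRate = "numeric", transitionBias = "numeric",
  geneMeanLength = "numeric", cpgIslandMeanLength = "numeric",
  seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (!(length(object@genomeLength) == 1L && is.finite(object@genomeLength) &&
        object@genomeLength >= 1))
    msg <- c(msg, "genomeLength must be a positive number")
  for (f in c("gcContent", "geneFraction", "cpgIslandFraction",
              "lowMqFraction", "lowQualityFraction", "multiNonrefFraction",
              "standingHetRate", "seqErrorRate"))
    if (!.isFraction(slot(object, f)))
      msg <- c(msg, paste0(f, " must be a fraction in [0, 1]"))
  if (!identical(sort(names(object@mu)), sort(.MU_STRATA)))
    msg <- c(msg, "mu must be named by the four strata")
  if (any(object@mu < 0) || any(object@mu > 1e-4))
    msg <- c(msg, "mu values must lie in [0, 1e-4]")
  if (object@nOffspring < 1L) msg <- c(msg, "nOffspring must be >= 1")
  if (object@meanDepth <= 0) msg <- c(msg, "meanDepth must be positive")
  if (length(msg) == 0 && object@genomeLength < object@nChromosomes)
    msg <- c(msg, "genomeLength must be >= nChromosomes")
  if (!identical(sort(names(object@transitionBias)), c("AT", "CG")) ||
      any(object@transitionBias < 0) || any(object@transitionBias > 1))
    msg <- c(msg, "transitionBias must be fractions named AT and CG")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' Defaults mirror the sequencing design of a silkworm parents-progeny
#' mutation study: a full-sib family with both parents and 30 offspring
#' sequenced to ~30x, CpG islands covering ~10% of the genome, a genome-wide
#' true rate near 4.1e-9 per site per generation, and a 2% share of
#' low-mapping-quality sites.
#'
#' @param genomeLength genome size in bp.
#' @param gcContent expected G+C fraction (silkworm-like default 0.38).
#' @param geneFraction fraction of the genome annotated genic.
#' @param cpgIslandFraction fraction of the genome inside CpG islands.
#' @param nOffspring number of offspring.
#' @param meanDepth mean per-sample read depth.
#' @param depthDispersion \code{Inf} for Poisson depths, otherwise the
#'   negative-binomial size parameter.
#' @param seqErrorRate per-read error probability toward the alternate base.
#' @param mu either a single rate applied to all four strata or a named
#'   numeric over \code{gene_AT, gene_CG, intergenic_AT, intergenic_CG}.
#' @param nChromosomes number of chromosomes.
#' @param lowMqFraction fraction of sites with mapping quality below 20.
#' @param lowQualityFraction fraction of sites flagged low quality.
#' @param multiNonrefFraction fraction of sites failing the
#'   multiple-non-reference-positions-per-read rule.
#' @param standingHetRate per-site probability of parental standing
#'   heterozygosity (default 0: inbred parents).
#' @param transitionBias scalar or named numeric (\code{AT}, \code{CG});
#'   probability a mutation is the transition (1/3 = no bias).
#' @param geneMeanLength,cpgIslandMeanLength annotation interval lengths.
#' @param seed integer RNG seed.
#' @return A \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(genomeLength = 1e5, nOffspring = 4, seed = 7)
#' cfg
#' @export
simulationConfig <- function(genomeLength = 1e6, gcContent = 0.38,
                             geneFraction = 0.35, cpgIslandFraction = 0.10,
                             nOffspring = 30, meanDepth = 30,
                             depthDispersion = Inf, seqErrorRate = 1e-3,
                             mu = 4.1e-9, nChromosomes = 4,
                             lowMqFraction = 0.02, lowQualityFraction = 0,
                             multiNonrefFraction = 0, standingHetRate = 0,
                             transitionBias = 1 / 3,
                             geneMeanLength = 5000,
                             cpgIslandMeanLength = 1000, seed = 1L) {
  if (length(mu) == 1L && is.null(names(mu)))
    mu <- setNames(rep(mu, 4L), .MU_STRATA)
  mu <- mu[.MU_STRATA]
  if (anyNA(mu)) .stopf("mu must cover all strata: %s",
                        paste(.MU_STRATA, collapse = ", "))
  if (length(transitionBias) == 1L && is.null(names(transitionBias)))
    transitionBias <- c(AT = transitionBias, CG = transitionBias)
  new("SimulationConfig", genomeLength = genomeLength, gcContent = gcContent,
      geneFraction = geneFraction, cpgIslandFraction = cpgIslandFraction,
      nOffspring = as.integer(nOffspring), meanDepth = meanDepth,
      depthDispersion = depthDispersion, seqErrorRate = seqErrorRate,
      mu = mu, nChromosomes = as.integer(nChromosomes),
      lowMqFraction = lowMqFraction, lowQualityFraction = lowQualityFraction,
      multiNonrefFraction = multiNonrefFraction,
      standingHetRate = standingHetRate,
      transitionBias = transitionBias[c("AT", "CG")],
      geneMeanLength = geneMeanLength,
      cpgIslandMeanLength = cpgIslandMeanLength, seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  genome: %s bp on %d chromosome(s), GC = %.3f\n",
              format(object@genomeLength, big.mark = ","),
              object@nChromosomes, object@gcContent))
  cat(sprintf("  annotation: gene %.2f, CpG island %.2f of genome\n",
              object@geneFraction, object@cpgIslandFraction))
  cat(sprintf("  family: 2 parents + %d offspring, depth ~%s\n",
              object@nOffspring, format(object@meanDepth)))
  cat(sprintf("  error: %.2g/read; low-MQ sites: %.2g\n",
              object@seqErrorRate, object@lowMqFraction))
  cat("  mu (per site per generation):\n")
  for (s in .MU_STRATA)
    cat(sprintf("    %-14s %.3g\n", s, object@mu[[s]]))
  cat(sprintf("  seed: %d\n", object@seed))
})

#' A synthetic (or imported) trio sequencing experiment
#'
#' Container tying together the reference genome, annotation tracks, the
#' multi-sample site table, the sample layout, the simulated truth set and
#' the callable-site mask.
#'
#' The site table is a wide data.frame with site-level columns
#' \code{chrom, pos, ref, alt, MQ, LOWQ, NONREF} and per-sample columns
#' \code{GT.<sample>, DP.<sample>, AD.<sample>} (AD = alternate-supporting
#' reads). In \code{"dense"} mode every genomic site has a row; in
#' \code{"sparse"} mode only sites carrying variant evidence are
#' materialised and callable-site counts are recorded analytically in the
#' \code{callable} slot.
#'
#' @slot reference a \link[Biostrings]{DNAStringSet} of chromosome sequences.
#' @slot genes,cpgIslands \link[GenomicRanges]{GRanges} annotation tracks.
#' @slot sites the wide site table (see Details).
#' @slot samples list with elements \code{parents} (length 2) and
#'   \code{offspring} (character vectors of sample names).
#' @slot truth data.frame of true de novo mutations
#'   (chrom, pos, offspring, ref, alt, region, baseClass).
#' @slot callable data.frame of callable-site counts per
#'   offspring x region x base class.
#' @slot config the generating \linkS4class{SimulationConfig}.
#' @slot mode \code{"dense"} or \code{"sparse"}.
#' @export
setClass("TrioExperiment", representation(
  reference = "ANY", genes = "ANY", cpgIslands = "ANY", sites = "data.frame",
  samples = "list", truth = "data.frame", callable = "data.frame",
  config = "ANY", mode = "character"))

setValidity("TrioExperiment", function(object) {
  msg <- character()
  if (!all(c("parents", "offspring") %in% names(object@samples)))
    msg <- c(msg, "samples must list 'parents' and 'offspring'")
  else if (length(object@samples$parents) != 2L)
    msg <- c(msg, "exactly two parents required")
  if (!object@mode %in% c("dense", "sparse"))
    msg <- c(msg, "mode must be 'dense' or 'sparse'")
  need <- c("chrom", "pos", "ref", "alt", "MQ", "LOWQ", "NONREF")
  if (nrow(object@sites) && !all(need %in% names(object@sites)))
    msg <- c(msg, "site table misses required columns")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TrioExperiment", function(object) {
  cat("TrioExperiment (", object@mode, " mode)\n", sep = "")
  cat(sprintf("  reference: %d chromosome(s), %s bp\n",
              length(object@reference),
              format(sum(Biostrings::width(object@reference)),
                     big.mark = ",")))
  cat(sprintf("  samples: 2 parents + %d offspring\n",
              length(object@samples$offspring)))
  cat(sprintf("  site table: %d row(s); truth DNMs: %d\n",
              nrow(object@sites), nrow(object@truth)))
  cat(sprintf("  callable sites (per offspring, mean): %s\n",
              format(round(sum(object@callable$sites) /
                           max(1L, length(object@samples$offspring))),
                     big.mark = ",")))
})

#' Result of de novo mutation calling on a trio site table
#'
#' @slot calls data.frame of accepted DNMs (chrom, pos, ref, alt, offspring,
#'   genotype and, once annotated, region, baseClass, inCpgIsland,
#'   mutationType, tsTv).
#' @slot rejections data.frame of rejected candidate sites with a single
#'   reason code each.
#' @slot callable callable-site mask used as the rate denominator.
#' @export
setClass("DnmCallSet", representation(
  calls = "data.frame", rejections = "data.frame", callable = "data.frame"))

setMethod("show", "DnmCallSet", function(object) {
  cat("DnmCallSet:", nrow(object@calls), "accepted DNM(s),",
      nrow(object@rejections), "rejected candidate site(s)\n")
  if (nrow(object@rejections)) {
    tab <- table(object@rejections$reason)
    for (r in names(tab)) cat(sprintf("   %-24s %d\n", r, tab[[r]]))
  }
})

#' Coalescent-clock parameters
#'
#' @slot theta population mutation parameter (theta = 4 Ne mu).
#' @slot tau divergence time in units of 4 Ne generations.
#' @slot muGen per-site per-generation mutation rate.
#' @slot generationsPerYear generations per year (e.g. 3 for reared
#'   silkworm; 365 / generation-days in general).
#' @export
setClass("ClockParams", representation(
  theta = "numeric", tau = "numeric", muGen = "numeric",
  generationsPerYear = "numeric"))

setValidity("ClockParams", function(object) {
  v <- c(object@theta, object@tau, object@muGen, object@generationsPerYear)
  if (any(!is.finite(v)) || any(v <= 0))
    "all clock parameters must be strictly positive" else TRUE
})

#' @rdname ClockParams-class
#' @param theta,tau,muGen,generationsPerYear see slot documentation.
#' @return A \linkS4class{ClockParams}.
#' @examples
#' clockParams(theta = 0.034, tau = 0.0035, muGen = 0.41e-8,
#'             generationsPerYear = 3)
#' @export
clockParams <- function(theta, tau, muGen, generationsPerYear)
  new("ClockParams", theta = theta, tau = tau, muGen = muGen,
      generationsPerYear = generationsPerYear)

setMethod("show", "ClockParams", function(object) {
  cat(sprintf(
    "ClockParams: theta = %g, tau = %g, mu = %g /site/generation, %g gen/yr\n",
    object@theta, object@tau, object@muGen, object@generationsPerYear))
})

## ---- accessors -------------------------------------------------------------

#' @export
setGeneric("siteTable", function(x) standardGeneric("siteTable"))
#' @export
setGeneric("truthSet", function(x) standardGeneric("truthSet"))
#' @export
setGeneric("callableSites", function(x) standardGeneric("callableSites"))
#' @export
setGeneric("sampleLayout", function(x) standardGeneric("sampleLayout"))
#' @export
setGeneric("referenceGenome", function(x) standardGeneric("referenceGenome"))
#' @export
setGeneric("geneTrack", function(x) standardGeneric("geneTrack"))
#' @export
setGeneric("cpgIslandTrack", function(x) standardGeneric("cpgIslandTrack"))
#' @export
setGeneric("simConfig", function(x) standardGeneric("simConfig"))
#' @export
setGeneric("dnmCalls", function(x) standardGeneric("dnmCalls"))
#' @export
setGeneric("rejectionLedger", function(x) standardGeneric("rejectionLedger"))

#' Accessors for TrioExperiment and DnmCallSet
#'
#' \code{siteTable} returns the wide multi-sample site table;
#' \code{truthSet} the simulated true DNMs; \code{callableSites} the
#' callable-site mask (offspring x region x base class);
#' \code{sampleLayout} the parents/offspring name list;
#' \code{referenceGenome}, \code{geneTrack}, \code{cpgIslandTrack} the
#' genome and annotation; \code{simConfig} the generating configuration;
#' \code{dnmCalls} and \code{rejectionLedger} the accepted calls and the
#' per-site rejection reasons of a \linkS4class{DnmCallSet}.
#'
#' @param x a \linkS4class{TrioExperiment} or \linkS4class{DnmCallSet}.
#' @return The corresponding slot, as a data.frame, list or Bioconductor
#'   object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("siteTable", "TrioExperiment", function(x) x@sites)
#' @rdname accessors
#' @export
setMethod("truthSet", "TrioExperiment", function(x) x@truth)
#' @rdname accessors
#' @export
setMethod("callableSites", "TrioExperiment", function(x) x@callable)
#' @rdname accessors
#' @export
setMethod("callableSites", "DnmCallSet", function(x) x@callable)
#' @rdname accessors
#' @export
setMethod("sampleLayout", "TrioExperiment", function(x) x@samples)
#' @rdname accessors
#' @export
setMethod("referenceGenome", "TrioExperiment", function(x) x@reference)
#' @rdname accessors
#' @export
setMethod("geneTrack", "TrioExperiment", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("cpgIslandTrack", "TrioExperiment", function(x) x@cpgIslands)
#' @rdname accessors
#' @export
setMethod("simConfig", "TrioExperiment", function(x) x@config)
#' @rdname accessors
#' @export
setMethod("dnmCalls", "DnmCallSet", function(x) x@calls)
#' @rdname accessors
#' @export
setMethod("rejectionLedger", "DnmCallSet", function(x) x@rejections)
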