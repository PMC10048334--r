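#' Hard-filter thresholds for candidate de novo mutations
#'
#' The defaults are the five-rule criterion used for trio SNV filtering:
#' minimum read depth 10, minimum mapping quality 20, minimum
#' alternate-read fraction 0.30, and at most 2 non-reference positions on
#' any supporting read; parents must be homozygous reference with no
#' alternate-supporting read and depth >= 10.
#'
#' @param depth minimum read depth per sample.
#' @param mapQuality minimum (site-level) mapping quality.
#' @param altFraction minimum fraction of reads supporting the mutation.
#' @param nonrefPerRead maximum non-reference positions per supporting read.
#' @return A named list of thresholds.
#' @export
dnmThresholds <- function(depth = 10, mapQuality = 20, altFraction = 0.30,
                          nonrefPerRead = 2)
  list(depth = depth, mapQuality = mapQuality, altFraction = altFraction,
       nonrefPerRead = nonrefPerRead)

.REASONS <- c("low_depth", "low_mq", "caller_low_quality",
              "low_alt_fraction", "multi_nonref_read",
              "parent_alt_or_low_depth", "shared_across_offspring",
              "not_heterozygous")

# Vectorised first-failing-rule evaluation for one offspring over all rows.
# Returns NA_character_ for rows passing every rule. Rules are applied in
# the listed order; assignment runs from lowest to highest priority so the
# earliest rule wins.
.filterReasons <- function(sites, samples, offspring,
                           thresholds = dnmThresholds()) {
  need <- c(.gtCol(offspring), .dpCol(offspring), .adCol(offspring),
            unlist(lapply(samples$parents, function(p)
              c(.gtCol(p), .dpCol(p), .adCol(p)))))
  if (!all(need %in% names(sites)))
    .stopf("malformed record: missing sample columns (%s)",
           paste(setdiff(need, names(sites)), collapse = ", "))
  dp <- sites[[.dpCol(offspring)]]
  ad <- sites[[.adCol(offspring)]]
  p1 <- samples$parents[1]; p2 <- samples$parents[2]
  reason <- rep(NA_character_, nrow(sites))
  parentBad <- sites[[.gtCol(p1)]] != "0/0" | sites[[.gtCol(p2)]] != "0/0" |
    sites[[.adCol(p1)]] > 0 | sites[[.adCol(p2)]] > 0 |
    sites[[.dpCol(p1)]] < thresholds$depth |
    sites[[.dpCol(p2)]] < thresholds$depth
  reason[parentBad] <- "parent_alt_or_low_depth"
  reason[sites$NONREF > thresholds$nonrefPerRead] <- "multi_nonref_read"
  reason[dp > 0 & ad / dp < thresholds$altFraction] <- "low_alt_fraction"
  reason[sites$LOWQ] <- "caller_low_quality"
  reason[sites$MQ < thresholds$mapQuality] <- "low_mq"
  reason[dp < thresholds$depth] <- "low_depth"
  reason
}

#' Apply the de novo mutation filters to one trio site record
#'
#' Evaluates the five filtering rules in order for the named offspring and
#' returns either \code{"accept"} or the first failing rule's reason code:
#' \code{low_depth} (depth < 10), \code{low_mq} (mapping quality < 20),
#' \code{caller_low_quality}, \code{low_alt_fraction} (alternate reads /
#' depth < 0.30), \code{multi_nonref_read} (> 2 non-reference positions on
#' a supporting read), or \code{parent_alt_or_low_depth} (a parent carries
#' an alternate allele or read, or has depth < 10).
#'
#' @param record a one-row site table (see \linkS4class{TrioExperiment}).
#' @param samples sample layout list(parents, offspring).
#' @param offspring name of the offspring being evaluated.
#' @param thresholds see \code{\link{dnmThresholds}}.
#' @return \code{"accept"} or a reason code.
#' @examples
#' exp <- simulateTrio(simulationConfig(genomeLength = 2e4, nOffspring = 3,
#'                                      mu = 1e-5, seed = 5))
#' st <- siteTable(exp)
#' if (nrow(st) > 0)
#'   applyFilters(st[1, ], sampleLayout(exp), sampleLayout(exp)$offspring[1])
#' @export
applyFilters <- function(record, samples, offspring,
                         thresholds = dnmThresholds()) {
  if (!is.data.frame(record) || nrow(record) != 1L)
    .stopf("malformed record: expected a single site row")
  r <- .filterReasons(record, samples, offspring, thresholds)
  if (is.na(r)) "accept" else r
}

#' Call de novo mutations from a trio site table
#'
#' A site yields an accepted DNM when exactly one offspring carries the
#' alternate allele, its genotype is heterozygous, it passes all filters of
#' \code{\link{applyFilters}}, and both parents are clean homozygous
#' reference (no alternate allele or read, depth >= 10). Sites where more
#' than one offspring carries the alternate allele are rejected with reason
#' \code{shared_across_offspring}; a single homozygous-alternate carrier is
#' rejected with \code{not_heterozygous}. Every rejected candidate site is
#' recorded with exactly one reason code.
#'
#' @param x a \linkS4class{TrioExperiment} or a wide site table data.frame.
#' @param samples sample layout (taken from \code{x} when it is an
#'   experiment).
#' @param thresholds see \code{\link{dnmThresholds}}.
#' @param annotate when \code{x} is an experiment, annotate accepted calls
#'   with region, base class, CpG-island membership and mutation type.
#' @return A \linkS4class{DnmCallSet}.
#' @examples
#' exp <- simulateTrio(simulationConfig(genomeLength = 5e4, nOffspring = 4,
#'                                      mu = 2e-5, seqErrorRate = 0,
#'                                      lowMqFraction = 0, seed = 2))
#' callDnms(exp)
#' @export
callDnms <- function(x, samples = NULL, thresholds = dnmThresholds(),
                     annotate = TRUE) {
  exp <- NULL
  if (is(x, "TrioExperiment")) {
    exp <- x
    sites <- x@sites
    samples <- x@samples
  } else {
    sites <- x
    if (is.null(samples)) .stopf("a sample layout is required")
  }
  if (anyDuplicated(sites[, c("chrom", "pos")]))
    .stopf("malformed input: duplicate (chrom, pos) rows in site table")
  calls <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), offspring = character(),
                      genotype = character(), stringsAsFactors = FALSE)
  rej <- data.frame(chrom = character(), pos = integer(),
                    offspring = character(), reason = character(),
                    stringsAsFactors = FALSE)
  if (nrow(sites)) {
    offs <- samples$offspring
    gt <- sapply(offs, function(o) sites[[.gtCol(o)]])
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(sites))
    hasAlt <- gt %in% c("0/1", "1/0", "1/1")
    dim(hasAlt) <- dim(gt)
    nCarrier <- rowSums(hasAlt)

    shared <- which(nCarrier >= 2)
    if (length(shared)) {
      who <- apply(hasAlt[shared, , drop = FALSE], 1,
                   function(z) paste(offs[z], collapse = ","))
      rej <- rbind(rej, data.frame(
        chrom = sites$chrom[shared], pos = sites$pos[shared],
        offspring = who, reason = "shared_across_offspring",
        stringsAsFactors = FALSE))
    }

    single <- which(nCarrier == 1)
    if (length(single)) {
      carrier <- offs[apply(hasAlt[single, , drop = FALSE], 1, which)]
      for (off in unique(carrier)) {
        rows <- single[carrier == off]
        g <- sites[[.gtCol(off)]][rows]
        hom <- g == "1/1"
        if (any(hom))
          rej <- rbind(rej, data.frame(
            chrom = sites$chrom[rows[hom]], pos = sites$pos[rows[hom]],
            offspring = off, reason = "not_heterozygous",
            stringsAsFactors = FALSE))
        het <- rows[!hom]
        if (!length(het)) next
        reason <- .filterReasons(sites[het, , drop = FALSE], samples, off,
                                 thresholds)
        ok <- is.na(reason)
        if (any(!ok))
          rej <- rbind(rej, data.frame(
            chrom = sites$chrom[het[!ok]], pos = sites$pos[het[!ok]],
            offspring = off, reason = reason[!ok], stringsAsFactors = FALSE))
        if (any(ok))
          calls <- rbind(calls, data.frame(
            chrom = sites$chrom[het[ok]], pos = sites$pos[het[ok]],
            ref = sites$ref[het[ok]], alt = sites$alt[het[ok]],
            offspring = off, genotype = "0/1", stringsAsFactors = FALSE))
      }
    }
  }
  o <- order(calls$chrom, calls$pos)
  calls <- calls[o, , drop = FALSE]
  rownames(calls) <- NULL
  rownames(rej) <- NULL
  if (annotate && !is.null(exp) && nrow(calls))
    calls <- annotateDnms(calls, exp@genes, exp@cpgIslands)
  callable <- if (!is.null(exp)) exp@callable else
    data.frame(offspring = character(), region = character(),
               baseClass = character(), sites = numeric())
  new("DnmCallSet", calls = calls, rejections = rej, callable = callable)
}

#' Annotate DNM calls with region, base class, CpG membership and type
#'
#' @param calls data.frame of calls (chrom, pos, ref, alt, ...).
#' @param genes,cpgIslands \link[GenomicRanges]{GRanges} tracks (may be
#'   NULL/empty).
#' @return The calls with columns \code{region}, \code{baseClass},
#'   \code{inCpgIsland}, \code{mutationType}, \code{tsTv} added.
#' @export
annotateDnms <- function(calls, genes = NULL, cpgIslands = NULL) {
  if (!nrow(calls)) return(calls)
  calls$region <- .siteRegions(calls$chrom, calls$pos, genes)
  calls$baseClass <- ifelse(calls$ref %in% c("C", "G"), "CG", "AT")
  if (!is.null(cpgIslands) && length(cpgIslands)) {
    q <- GenomicRanges::GRanges(calls$chrom,
                                IRanges::IRanges(calls$pos, width = 1))
    calls$inCpgIsland <- IRanges::overlapsAny(q, cpgIslands,
                                              ignore.strand = TRUE)
  } else calls$inCpgIsland <- FALSE
  cl <- classifyMutation(calls$ref, calls$alt)
  calls$mutationType <- cl$type
  calls$tsTv <- cl$tsTv
  calls
}

#' Count callable sites for one offspring
#'
#' A site is callable for an offspring when the offspring and both parents
#' have depth >= 10, the site mapping quality is >= 20, and both parents are
#' homozygous reference. Counts are stratified by genomic region (when a
#' gene track is supplied) and by reference base class. The site table must
#' enumerate every genomic site (dense mode); for sparse simulations use the
#' mask stored in the \linkS4class{TrioExperiment}.
#'
#' @param sites dense wide site table.
#' @param samples sample layout.
#' @param offspring offspring sample name.
#' @param genes optional \link[GenomicRanges]{GRanges} gene track.
#' @param thresholds see \code{\link{dnmThresholds}}.
#' @return data.frame(offspring, region, baseClass, sites); regions are
#'   \code{gene}/\code{intergenic} (or \code{all}), base classes
#'   \code{AT}/\code{CG}.
#' @export
countCallable <- function(sites, samples, offspring, genes = NULL,
                          thresholds = dnmThresholds()) {
  p1 <- samples$parents[1]; p2 <- samples$parents[2]
  pass <- sites[[.dpCol(offspring)]] >= thresholds$depth &
    sites$MQ >= thresholds$mapQuality &
    sites[[.dpCol(p1)]] >= thresholds$depth &
    sites[[.dpCol(p2)]] >= thresholds$depth &
    sites[[.gtCol(p1)]] == "0/0" & sites[[.gtCol(p2)]] == "0/0"
  region <- if (is.null(genes)) rep("all", nrow(sites)) else
    .siteRegions(sites$chrom, sites$pos, genes)
  cls <- ifelse(sites$ref %in% c("C", "G"), "CG", "AT")
  regions <- if (is.null(genes)) "all" else c("gene", "intergenic")
  out <- expand.grid(offspring = offspring, region = regions,
                     baseClass = c("AT", "CG"), stringsAsFactors = FALSE)
  out$sites <- mapply(function(rg, bc)
    sum(pass & region == rg & cls == bc), out$region, out$baseClass)
  out[order(out$region, out$baseClass), , drop = FALSE]
}
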