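.SIX_TYPES <- c("A:T->C:G", "A:T->G:C", "A:T->T:A",
                "G:C->A:T", "G:C->C:G", "G:C->T:A")

#' Classify a single-nucleotide substitution
#'
#' Collapses strands so that a substitution and its reverse complement map
#' to the same class (e.g. T->C and A->G are both A:T->G:C), giving the six
#' classes A:T->C:G, A:T->G:C, A:T->T:A, G:C->A:T, G:C->C:G, G:C->T:A.
#' Transitions are purine<->purine or pyrimidine<->pyrimidine changes
#' (C<->T and G<->A).
#'
#' @param ref,alt reference and alternate bases (vectors of equal length).
#' @return data.frame(type, tsTv) with tsTv in \code{c("Ts", "Tv")}.
#' @examples
#' classifyMutation("C", "T")   # G:C->A:T, Ts
#' classifyMutation("T", "G")   # A:T->C:G, Tv
#' @export
classifyMutation <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (length(ref) != length(alt)) .stopf("ref and alt differ in length")
  if (!all(ref %in% .BASES) || !all(alt %in% .BASES))
    .stopf("unsupported base: ref/alt must be A, C, G or T")
  if (any(ref == alt)) .stopf("ref and alt must differ")
  # canonical pyrimidine-reference representation
  flip <- ref %in% c("A", "G")
  r <- ifelse(flip, .COMP[ref], ref)
  a <- ifelse(flip, .COMP[alt], alt)
  key <- paste0(r, a)
  type <- c(CT = "G:C->A:T", CA = "G:C->T:A", CG = "G:C->C:G",
            TC = "A:T->G:C", TA = "A:T->T:A", TG = "A:T->C:G")[key]
  tsTv <- ifelse(key %in% c("CT", "TC"), "Ts", "Tv")
  data.frame(type = unname(type), tsTv = tsTv, stringsAsFactors = FALSE)
}

#' Mutation-spectrum summary with per-type rates
#'
#' Counts the six strand-collapsed mutation types, transitions and
#' transversions, and converts counts to rates by dividing each type count
#' by twice the callable sites of its origin base class (summed over
#' offspring). The A/T (C/G) class rate is by construction the sum of its
#' three type rates.
#'
#' @param callSet a \linkS4class{DnmCallSet} with annotated calls, or a
#'   calls data.frame carrying \code{mutationType}/\code{tsTv} columns (then
#'   \code{callable} must be given).
#' @param callable optional callable mask data.frame
#'   (offspring, region, baseClass, sites).
#' @return list with \code{counts} (named 6-vector), \code{ts}, \code{tv},
#'   \code{tsTv} ratio, \code{rates} (per type), \code{classRates}
#'   (\code{AT}, \code{CG}) and \code{callable} (diploid-unadjusted site
#'   totals per class).
#' @export
spectrumSummary <- function(callSet, callable = NULL) {
  if (is(callSet, "DnmCallSet")) {
    calls <- callSet@calls
    if (is.null(callable)) callable <- callSet@callable
  } else calls <- callSet
  if (is.null(callable) || !nrow(callable))
    .stopf("a callable mask with base-class strata is required")
  if (nrow(calls) && !"mutationType" %in% names(calls)) {
    cl <- classifyMutation(calls$ref, calls$alt)
    calls$mutationType <- cl$type
    calls$tsTv <- cl$tsTv
  }
  counts <- setNames(integer(6), .SIX_TYPES)
  if (nrow(calls)) {
    tab <- table(factor(calls$mutationType, levels = .SIX_TYPES))
    counts[] <- as.integer(tab)
  }
  ts <- sum(counts[c("A:T->G:C", "G:C->A:T")])
  tv <- sum(counts) - ts
  calClass <- c(AT = sum(callable$sites[callable$baseClass == "AT"]),
                CG = sum(callable$sites[callable$baseClass == "CG"]))
  if (any(calClass <= 0))
    .stopf("undefined rate: zero callable sites in a base class")
  origin <- ifelse(startsWith(.SIX_TYPES, "A:T"), "AT", "CG")
  rates <- counts / (2 * calClass[origin])
  classRates <- c(AT = sum(rates[origin == "AT"]),
                  CG = sum(rates[origin == "CG"]))
  list(counts = counts, ts = ts, tv = tv,
       tsTv = if (tv > 0) ts / tv else NA_real_,
       rates = rates, classRates = classRates, callable = calClass)
}

#' CpG-island association of G:C->A:T mutations
#'
#' Two-sample proportion test (chi-square with continuity correction, as in
#' R's \code{prop.test}) comparing the observed fraction of C:G->T:A
#' (equivalently G:C->A:T) mutations falling inside CpG islands against the
#' fraction expected under a length-weighted uniform placement (the CpG
#' island share of the genome, ~0.10).
#'
#' @param calls annotated calls data.frame; rows are filtered to
#'   \code{mutationType == "G:C->A:T"} unless already filtered.
#' @param cpgIslands \link[GenomicRanges]{GRanges} CpG-island track (used
#'   when the calls lack an \code{inCpgIsland} column).
#' @param genomeCpgFraction expected fraction of the genome in CpG islands.
#' @return list(observed, expected, p, nCalls, inCpg).
#' @export
cpgIslandAssociation <- function(calls, cpgIslands = NULL,
                                 genomeCpgFraction = 0.10) {
  if ("mutationType" %in% names(calls))
    calls <- calls[calls$mutationType == "G:C->A:T", , drop = FALSE]
  n <- nrow(calls)
  if (n < 1L) .stopf("undefined test: no qualifying G:C->A:T calls")
  if (!"inCpgIsland" %in% names(calls)) {
    if (is.null(cpgIslands)) .stopf("a CpG-island track is required")
    q <- GenomicRanges::GRanges(calls$chrom,
                                IRanges::IRanges(calls$pos, width = 1))
    calls$inCpgIsland <- IRanges::overlapsAny(q, cpgIslands,
                                              ignore.strand = TRUE)
  }
  x <- sum(calls$inCpgIsland)
  expCount <- round(n * genomeCpgFraction)
  ht <- suppressWarnings(prop.test(c(x, expCount), c(n, n)))
  list(observed = x / n, expected = genomeCpgFraction, p = ht$p.value,
       nCalls = n, inCpg = x)
}

#' Flanking-sequence context matrix around C:G-origin mutations
#'
#' Extracts \code{flank} bases either side of each mutated site, oriented so
#' the mutated base reads C (reverse-complementing when the reference base
#' is G), and returns per-position base frequencies. Calls closer than
#' \code{flank} to a contig end are dropped with a warning.
#'
#' @param calls calls data.frame with chrom, pos, ref (ref must be C or G;
#'   other rows are dropped with a warning).
#' @param reference the genome \link[Biostrings]{DNAStringSet}.
#' @param flank bases of context per side (default 10).
#' @return 4 x (2 flank + 1) matrix of base frequencies (rows A, C, G, T;
#'   columns \code{-flank..+flank}); attribute \code{"cgPlusOneFraction"}
#'   holds the frequency of G at position +1 (the CpG dinucleotide
#'   fraction) and attribute \code{"n"} the number of calls used.
#' @export
contextMatrix <- function(calls, reference, flank = 10L) {
  ok <- calls$ref %in% c("C", "G")
  if (any(!ok)) {
    warning(sum(!ok), " call(s) with A/T reference dropped")
    calls <- calls[ok, , drop = FALSE]
  }
  if (!nrow(calls)) .stopf("no C/G-reference calls to profile")
  lens <- setNames(Biostrings::width(reference), names(reference))
  inRange <- calls$pos > flank & calls$pos + flank <= lens[calls$chrom]
  if (any(!inRange)) {
    warning(sum(!inRange), " call(s) within ", flank,
            " bp of a contig end dropped")
    calls <- calls[inRange, , drop = FALSE]
  }
  if (!nrow(calls)) .stopf("all calls too close to contig ends")
  seqs <- vector("list", nrow(calls))
  for (chr in unique(calls$chrom)) {
    i <- which(calls$chrom == chr)
    ss <- Biostrings::extractAt(reference[[chr]], IRanges::IRanges(
      calls$pos[i] - flank, calls$pos[i] + flank))
    seqs[i] <- as.list(ss)
  }
  ctx <- Biostrings::DNAStringSet(seqs)
  center <- as.character(Biostrings::subseq(ctx, flank + 1L, flank + 1L))
  if (!all(center == calls$ref))
    .stopf("reference mismatch at %d call site(s)",
           sum(center != calls$ref))
  isG <- calls$ref == "G"
  if (any(isG)) ctx[isG] <- Biostrings::reverseComplement(ctx[isG])
  cm <- Biostrings::consensusMatrix(ctx, baseOnly = TRUE)[.BASES, ,
                                                          drop = FALSE]
  freq <- sweep(cm, 2, colSums(cm), "/")
  colnames(freq) <- as.character(seq(-flank, flank))
  structure(freq, cgPlusOneFraction = freq["G", as.character(1)],
            n = length(ctx))
}
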