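#' Generate a synthetic reference genome
#'
#' Draws an i.i.d. nucleotide sequence with the configured GC content and
#' splits it into \code{nChromosomes} chromosomes of (near-)equal length.
#' Deterministic for a fixed \code{config@seed}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \link[Biostrings]{DNAStringSet} named \code{chr1..chrN} whose
#'   widths sum to \code{genomeLength}.
#' @examples
#' ref <- generateReference(simulationConfig(genomeLength = 1e4, seed = 3))
#' Biostrings::letterFrequency(ref, "GC")
#' @export
generateReference <- function(config) {
  validObject(config)
  L <- as.numeric(config@genomeLength)
  if (L <= 0) .stopf("invalid config: genomeLength must be positive")
  withSeed(config@seed, {
    gc <- config@gcContent
    prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    idx <- sample.int(4L, L, replace = TRUE, prob = prob)
    raw <- as.raw(c(65L, 67L, 71L, 84L))[idx]  # "ACGT"
    lens <- .chromLengths(L, config@nChromosomes)
    ends <- cumsum(lens)
    starts <- ends - lens + 1
    seqs <- vapply(seq_along(lens),
                   function(i) rawToChar(raw[starts[i]:ends[i]]), character(1))
    ref <- Biostrings::DNAStringSet(seqs)
    names(ref) <- paste0("chr", seq_along(lens))
    ref
  })
}

.chromLengths <- function(L, n) {
  base <- floor(L / n)
  lens <- rep(base, n)
  lens[n] <- lens[n] + (L - base * n)
  if (any(lens < 1)) .stopf("invalid config: genomeLength < nChromosomes")
  lens
}

#' Generate gene and CpG-island annotation tracks
#'
#' Lays out non-overlapping intervals per chromosome so that each track's
#' total length matches its configured genome fraction exactly (up to 1 bp
#' rounding per chromosome). Interval lengths equal the configured mean
#' length, with one remainder interval per chromosome; gaps between
#' intervals are drawn multinomially, so placement is random but the
#' covered fraction is fixed. The two tracks are laid out independently and
#' may overlap each other (as gene bodies and CpG islands do).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param reference the genome from \code{\link{generateReference}}.
#' @return A list with \code{genes} and \code{cpgIslands}, each a
#'   \link[GenomicRanges]{GRanges} (0 rows when the fraction is 0).
#' @export
generateAnnotation <- function(config, reference) {
  validObject(config)
  if (missing(reference) || is.null(reference))
    .stopf("a reference genome is required")
  lens <- Biostrings::width(reference)
  names(lens) <- names(reference)
  withSeed(config@seed + 1L, list(
    genes = .layoutTrack(lens, config@geneFraction, config@geneMeanLength),
    cpgIslands = .layoutTrack(lens, config@cpgIslandFraction,
                              config@cpgIslandMeanLength)))
}

# Place non-overlapping intervals totalling round(fraction * chromLength)
# bp on each chromosome: k full-length intervals plus one remainder
# interval, separated by multinomially drawn gaps.
.layoutTrack <- function(chromLengths, fraction, meanLength) {
  if (fraction > 1) .stopf("invalid config: track fraction exceeds capacity")
  gr <- GenomicRanges::GRanges(seqlengths = chromLengths)
  if (fraction <= 0) return(gr)
  pieces <- lapply(names(chromLengths), function(chr) {
    Lc <- chromLengths[[chr]]
    total <- round(fraction * Lc)
    if (total < 1) return(NULL)
    len <- min(meanLength, total)
    widths <- rep(len, floor(total / len))
    rem <- total - sum(widths)
    if (rem > 0) widths <- c(widths, rem)
    k <- length(widths)
    gapTotal <- Lc - total
    gaps <- as.vector(stats::rmultinom(1, gapTotal, rep(1, k + 1)))
    starts <- cumsum(gaps[seq_len(k)] + c(0, widths[-k])) + 1
    GenomicRanges::GRanges(chr, IRanges::IRanges(start = starts,
                                                 width = widths),
                           seqlengths = chromLengths)
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (!length(pieces)) return(gr)
  sort(do.call(c, pieces))
}
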