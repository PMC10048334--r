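#' Per-offspring mutation rate
#'
#' rate = m / (2 * callable sites): the diploid convention divides the DNM
#' count by two callable allele copies per site.
#'
#' @param m DNM count(s) for the offspring (and stratum).
#' @param callable callable site count(s), same length as \code{m}.
#' @return Per-site per-generation rate(s).
#' @examples
#' perOffspringRate(5, 1e8)   # 2.5e-8
#' @export
perOffspringRate <- function(m, callable) {
  if (any(!is.finite(callable)) || any(callable <= 0))
    .stopf("undefined rate: callable sites must be positive")
  m / (2 * callable)
}

#' Percentile bootstrap confidence interval for a mean rate
#'
#' Resamples the per-offspring values with replacement \code{B} times, takes
#' the mean of each resample, sorts the \code{B} estimates ascending and
#' reports the 2.5% and 97.5% order statistics (the 25th and 975th of 1000).
#'
#' @param values per-offspring observed rates.
#' @param B number of bootstrap resamples (default 1000).
#' @param seed optional RNG seed making the interval reproducible.
#' @return list(mean, ciLow, ciHigh, B).
#' @examples
#' bootstrapCI(c(1, 2, 3, 4, 5), B = 1000, seed = 1)
#' @export
bootstrapCI <- function(values, B = 1000L, seed = NULL) {
  if (!length(values)) .stopf("values must be non-empty")
  if (B < 40L) .stopf("insufficient replicates: B must be >= 40")
  n <- length(values)
  est <- withSeed(seed, {
    idx <- sample.int(n, n * B, replace = TRUE)
    colMeans(matrix(values[idx], nrow = n, ncol = B))
  })
  s <- sort(est)
  list(mean = mean(values), ciLow = s[max(1L, floor(0.025 * B))],
       ciHigh = s[ceiling(0.975 * B)], B = B)
}

.RATE_STRATA <- c("whole_genome", "gene", "intergenic", "AT", "CG")

#' Estimate stratified mutation rates with bootstrap confidence intervals
#'
#' Computes, for each stratum (whole genome, gene, intergenic, A/T bases,
#' C/G bases and the six strand-collapsed mutation types), the per-offspring
#' observed rates m_i / (2 * callable_i), their unweighted mean across
#' offspring, and the percentile bootstrap 95% interval of the mean.
#'
#' @param callSet a \linkS4class{DnmCallSet} whose calls are annotated and
#'   whose callable mask is stratified by region and base class.
#' @param condition label attached to the output rows.
#' @param B bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @param types also estimate rates for the six mutation types (denominator:
#'   callable sites of the type's origin base class).
#' @return data.frame(condition, stratum, mean, ciLow, ciHigh, nOffspring,
#'   m, callableTotal) with attribute \code{"perOffspring"}: a list of
#'   per-offspring observed rate vectors per stratum.
#' @export
estimateRates <- function(callSet, condition = "condition", B = 1000L,
                          seed = NULL, types = FALSE) {
  calls <- callSet@calls
  cal <- callSet@callable
  if (!nrow(cal)) .stopf("callable mask is empty")
  offs <- unique(cal$offspring)
  strata <- .RATE_STRATA
  if (types) strata <- c(strata, .SIX_TYPES)

  calFor <- function(off, stratum) {
    z <- cal[cal$offspring == off, , drop = FALSE]
    switch(stratum,
      whole_genome = sum(z$sites),
      gene = sum(z$sites[z$region == "gene"]),
      intergenic = sum(z$sites[z$region == "intergenic"]),
      AT = sum(z$sites[z$baseClass == "AT"]),
      CG = sum(z$sites[z$baseClass == "CG"]),
      { # six-type stratum: origin base class callable
        cls <- if (startsWith(stratum, "A:T")) "AT" else "CG"
        sum(z$sites[z$baseClass == cls])
      })
  }
  mFor <- function(off, stratum) {
    if (!nrow(calls)) return(0L)
    z <- calls[calls$offspring == off, , drop = FALSE]
    switch(stratum,
      whole_genome = nrow(z),
      gene = sum(z$region == "gene"),
      intergenic = sum(z$region == "intergenic"),
      AT = sum(z$baseClass == "AT"),
      CG = sum(z$baseClass == "CG"),
      sum(z$mutationType == stratum))
  }

  perOff <- list()
  rows <- lapply(strata, function(st) {
    m <- vapply(offs, mFor, numeric(1), stratum = st)
    cs <- vapply(offs, calFor, numeric(1), stratum = st)
    if (any(cs <= 0)) .stopf("undefined rate: zero callable sites in '%s'",
                             st)
    r <- perOffspringRate(m, cs)
    perOff[[st]] <<- setNames(r, offs)
    bs <- bootstrapCI(r, B = B, seed = seed)
    data.frame(condition = condition, stratum = st, mean = bs$mean,
               ciLow = bs$ciLow, ciHigh = bs$ciHigh,
               nOffspring = length(offs), m = sum(m), callableTotal = sum(cs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "perOffspring") <- perOff
  out
}

#' Compare observed per-offspring rates between two conditions
#'
#' Two-sided test on the observed per-offspring rates (not on bootstrap
#' estimates). \code{"t"} is the two-sample t-test (Welch by default);
#' \code{"wilcoxon"} the rank-sum test. Two identical constant groups are
#' defined to give p = 1.
#'
#' @param a,b numeric vectors of per-offspring rates (length >= 2 each).
#' @param method \code{"t"} or \code{"wilcoxon"}.
#' @param varEqual use the pooled-variance Student t instead of Welch.
#' @return The two-sided p-value.
#' @examples
#' compareConditions(c(1, 2, 3), c(101, 102, 103))
#' @export
compareConditions <- function(a, b, method = c("t", "wilcoxon"),
                              varEqual = FALSE) {
  method <- match.arg(method)
  if (length(a) < 2L || length(b) < 2L)
    .stopf("both groups need at least 2 values")
  if (stats::var(c(a, b)) == 0) return(1)
  if (method == "t") {
    if (stats::var(a) == 0 && stats::var(b) == 0)
      return(if (mean(a) == mean(b)) 1 else 0)
    t.test(a, b, var.equal = varEqual)$p.value
  } else {
    suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
  }
}

#' Chi-square homogeneity test of mutation counts across species
#'
#' Builds a species x {mutant, non-mutant} contingency table from per-species
#' mutation counts and diploid callable totals and tests the null of a
#' uniform per-site mutation probability across species.
#'
#' @param counts per-species mutation counts.
#' @param callableTotals per-species diploid callable site totals
#'   (must exceed the counts).
#' @param correct continuity correction (only applies to 2x2 tables).
#' @return list(statistic, df, p, lowExpected) where \code{lowExpected}
#'   flags any expected cell below 1.
#' @export
crossSpeciesTest <- function(counts, callableTotals, correct = FALSE) {
  if (length(counts) < 2L) .stopf("need at least two species")
  if (any(callableTotals <= counts))
    .stopf("callable totals must exceed mutation counts")
  tab <- cbind(mutant = counts, nonmutant = callableTotals - counts)
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, lowExpected = any(ht$expected < 1))
}

#' Kolmogorov-Smirnov test of mutation positions against uniformity
#'
#' Maps each call to its normalised position within the concatenated genome
#' and tests the sample against the Uniform(0, 1) distribution implied by a
#' random placement proportional to chromosome lengths.
#'
#' @param calls data.frame with \code{chrom} and \code{pos} columns.
#' @param chromLengths named vector of chromosome lengths.
#' @return list(statistic, p, n).
#' @export
chromosomeDistributionTest <- function(calls, chromLengths) {
  if (nrow(calls) < 5L) .stopf("need at least 5 calls")
  if (is.null(names(chromLengths)))
    .stopf("chromLengths must be named by chromosome")
  if (!all(calls$chrom %in% names(chromLengths)))
    .stopf("calls on chromosomes absent from chromLengths")
  offset <- c(0, cumsum(as.numeric(chromLengths)))[
    match(calls$chrom, names(chromLengths))]
  u <- (offset + calls$pos - 0.5) / sum(as.numeric(chromLengths))
  ht <- suppressWarnings(ks.test(u, "punif"))
  list(statistic = unname(ht$statistic), p = ht$p.value, n = nrow(calls))
}
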