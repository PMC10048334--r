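# Independent brute-force re-implementations used as oracles. These are
# deliberately written as plain row-by-row logic, sharing no code with the
# package internals.

oracleFilterReason <- function(row, samples, off, depthMin = 10, mqMin = 20,
                               altFracMin = 0.30, nonrefMax = 2) {
  g <- function(f, s) row[[paste0(f, ".", s)]]
  if (g("DP", off) < depthMin) return("low_depth")
  if (row$MQ < mqMin) return("low_mq")
  if (row$LOWQ) return("caller_low_quality")
  if (g("AD", off) / g("DP", off) < altFracMin) return("low_alt_fraction")
  if (row$NONREF > nonrefMax) return("multi_nonref_read")
  for (p in samples$parents)
    if (g("GT", p) != "0/0" || g("AD", p) > 0 || g("DP", p) < depthMin)
      return("parent_alt_or_low_depth")
  "accept"
}

# Row-by-row DNM caller: returns data.frame(chrom, pos, offspring) of
# accepted calls.
oracleCallDnms <- function(sites, samples) {
  out <- list()
  for (i in seq_len(nrow(sites))) {
    row <- sites[i, , drop = FALSE]
    carriers <- character(0)
    for (o in samples$offspring)
      if (row[[paste0("GT.", o)]] %in% c("0/1", "1/0", "1/1"))
        carriers <- c(carriers, o)
    if (length(carriers) != 1L) next
    if (row[[paste0("GT.", carriers)]] == "1/1") next
    if (oracleFilterReason(row, samples, carriers) == "accept")
      out[[length(out) + 1L]] <- data.frame(
        chrom = row$chrom, pos = row$pos, offspring = carriers,
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), pos = integer(),
                      offspring = character()))
  do.call(rbind, out)
}

# Percentile bootstrap re-run as an explicit loop over resamples.
oracleBootstrap <- function(values, B, seed) {
  set.seed(seed)
  n <- length(values)
  est <- numeric(B)
  for (b in seq_len(B)) est[b] <- mean(values[sample.int(n, n,
                                                         replace = TRUE)])
  s <- sort(est)
  c(mean = mean(values), lo = s[floor(0.025 * B)], hi = s[ceiling(0.975 * B)])
}

# Pearson chi-square statistic from a contingency table, by the definition.
oracleChiSq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Kolmogorov-Smirnov statistic against Uniform(0,1) as the maximum ECDF gap.
oracleKS <- function(u) {
  u <- sort(u)
  n <- length(u)
  max(pmax(seq_len(n) / n - u, u - (seq_len(n) - 1) / n))
}

# Two-sample proportion chi-square with Yates continuity correction,
# computed from the textbook formula.
oracleTwoProp <- function(x1, n1, x2, n2) {
  p <- (x1 + x2) / (n1 + n2)
  num <- (abs(x1 / n1 - x2 / n2) - 0.5 * (1 / n1 + 1 / n2))
  num <- max(0, num)
  stat <- num^2 / (p * (1 - p) * (1 / n1 + 1 / n2))
  c(statistic = stat, p = 1 - pchisq(stat, df = 1))
}

# Welch two-sample t-test from first principles.
oracleWelchT <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * pt(-abs(t), df)
}
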