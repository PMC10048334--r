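# Toy wide site tables built in code. Samples default to two parents and
# three offspring; every per-sample field can be overridden per site.

toyLayout <- function(nOffspring = 3)
  list(parents = c("parent1", "parent2"),
       offspring = sprintf("offspring%02d", seq_len(nOffspring)))

# One site row. `gt`, `dp`, `ad` are named by sample; unnamed samples get
# clean homozygous-reference defaults (GT 0/0, DP 30, AD 0).
toySite <- function(samples, chrom = "chr1", pos = 1L, ref = "A", alt = "G",
                    mq = 60, lowq = FALSE, nonref = 1L,
                    gt = NULL, dp = NULL, ad = NULL) {
  row <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                    alt = alt, MQ = mq, LOWQ = lowq,
                    NONREF = as.integer(nonref), stringsAsFactors = FALSE)
  for (s in c(samples$parents, samples$offspring)) {
    row[[paste0("GT.", s)]] <- if (!is.null(gt) && s %in% names(gt))
      gt[[s]] else "0/0"
    row[[paste0("DP.", s)]] <- if (!is.null(dp) && s %in% names(dp))
      as.integer(dp[[s]]) else 30L
    row[[paste0("AD.", s)]] <- if (!is.null(ad) && s %in% names(ad))
      as.integer(ad[[s]]) else 0L
  }
  row
}

toySites <- function(samples, ...) {
  rows <- list(...)
  do.call(rbind, rows)
}

# A small dense simulated experiment reused across tests.
denseExperiment <- function(genomeLength = 5e4, nOffspring = 4, mu = 2e-5,
                            seed = 42, ...) {
  simulateTrio(simulationConfig(genomeLength = genomeLength,
                                nOffspring = nOffspring, mu = mu,
                                seed = seed, ...))
}
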