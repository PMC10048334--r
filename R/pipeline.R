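#' Three-condition full-sib study design
#'
#' Returns the default simulation configurations for a normal-temperature
#' family (30 offspring) and two temperature-stress families (10 offspring
#' each), with true per-class mutation rates set to published silkworm
#' estimates: normal A/T 3.60e-9 and C/G 4.58e-9; high temperature 3.80e-9 /
#' 8.14e-9; low temperature 3.76e-9 / 7.85e-9 per site per generation.
#'
#' @param genomeLength genome size per condition (default 5e6; the package
#'   simulates read evidence, not reads, so larger genomes stay cheap).
#' @param seed base RNG seed; each condition is offset deterministically.
#' @param ... further arguments passed to \code{\link{simulationConfig}}.
#' @return Named list of \linkS4class{SimulationConfig} objects
#'   (\code{normal}, \code{high}, \code{low}).
#' @export
silkwormDesign <- function(genomeLength = 5e6, seed = 1L, ...) {
  classMu <- function(at, cg)
    c(gene_AT = at, gene_CG = cg, intergenic_AT = at, intergenic_CG = cg)
  list(
    normal = simulationConfig(genomeLength = genomeLength, nOffspring = 30,
                              mu = classMu(3.60e-9, 4.58e-9),
                              seed = seed, ...),
    high = simulationConfig(genomeLength = genomeLength, nOffspring = 10,
                            mu = classMu(3.80e-9, 8.14e-9),
                            seed = seed + 1000L, ...),
    low = simulationConfig(genomeLength = genomeLength, nOffspring = 10,
                           mu = classMu(3.76e-9, 7.85e-9),
                           seed = seed + 2000L, ...))
}

#' Run the full synthetic-benchmark pipeline
#'
#' For each condition: simulate the family, call de novo mutations, estimate
#' stratified rates with bootstrap confidence intervals, summarise the
#' mutation spectrum, test CpG-island association and the chromosome
#' distribution, and calibrate the false-negative rate by spike-in. Stress
#' conditions are then compared against the first (reference) condition on
#' the observed per-offspring rates (t and Wilcoxon tests), and the
#' reference condition's mean rate drives a molecular-clock report. All
#' stages are deterministic given \code{seed}; every table is written as
#' headered TSV plus JSON for the scalar reports, and a manifest records
#' the seed, thresholds and package version. Partial outputs are removed
#' when a stage fails.
#'
#' @param configs named list of \linkS4class{SimulationConfig}, one per
#'   condition (first = reference condition); see
#'   \code{\link{silkwormDesign}}.
#' @param outDir output directory, created if needed.
#' @param seed integer seed for every stochastic stage.
#' @param B bootstrap replicates.
#' @param nSpikes spike-in size per condition (0 skips calibration).
#' @param clock list(theta, tau, generationsPerYear) for the clock stage
#'   (NULL skips it).
#' @param thresholds see \code{\link{dnmThresholds}}.
#' @return Invisibly, a list with per-condition results (\code{experiments},
#'   \code{callSets}, \code{rates}, \code{spectra}, \code{calibration}),
#'   \code{comparisons}, \code{clock} and \code{files}.
#' @export
runPipeline <- function(configs, outDir, seed = 1L, B = 1000L,
                        nSpikes = 1000L,
                        clock = list(theta = 0.034, tau = 0.0035,
                                     generationsPerYear = 3),
                        thresholds = dnmThresholds()) {
  if (is.null(names(configs)) || any(names(configs) == ""))
    .stopf("configs must be a named list of conditions")
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  written <- character(0)
  emit <- function(obj, name, json = FALSE) {
    p <- file.path(outDir, name)
    if (json) jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                                   pretty = TRUE, null = "null")
    else write.table(obj, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, p)
    p
  }
  res <- tryCatch({
    experiments <- list(); callSets <- list(); spectra <- list()
    calibration <- list(); rateRows <- list(); tests <- list()
    for (i in seq_along(configs)) {
      cond <- names(configs)[i]
      cfg <- configs[[i]]
      cfg@seed <- as.integer(seed + (i - 1L) * 101L)
      exp <- simulateTrio(cfg)
      cs <- callDnms(exp, thresholds = thresholds)
      rates <- estimateRates(cs, condition = cond, B = B,
                             seed = seed + 7000L + i)
      spec <- spectrumSummary(cs)
      experiments[[cond]] <- exp; callSets[[cond]] <- cs
      spectra[[cond]] <- spec; rateRows[[cond]] <- rates
      calls <- dnmCalls(cs)
      tests[[cond]] <- list(
        cpgIsland = if (sum(calls$mutationType == "G:C->A:T") >= 1)
          cpgIslandAssociation(calls, cpgIslandTrack(exp),
                               cfg@cpgIslandFraction) else NULL,
        chromDistribution = if (nrow(calls) >= 5)
          chromosomeDistributionTest(calls, setNames(
            Biostrings::width(referenceGenome(exp)),
            names(referenceGenome(exp)))) else NULL)
      if (nSpikes > 0) {
        sp <- spikeIn(exp, nSites = nSpikes, seed = seed + 9000L + i)
        recalled <- callDnms(sp$experiment, thresholds = thresholds,
                             annotate = FALSE)
        fn <- falseNegativeRate(sp$ledger, recalled)
        calibration[[cond]] <- list(
          nSpikes = nSpikes, recovered = attr(fn, "recovered"),
          fnPercent = as.numeric(fn),
          fnAnalytic = 100 * analyticFalseNegativeRate(cfg, thresholds))
      }
      emit(dnmCalls(cs), sprintf("dnm_calls_%s.tsv", cond))
      emit(rejectionLedger(cs), sprintf("rejections_%s.tsv", cond))
      emit(callableSites(cs), sprintf("callable_%s.tsv", cond))
      emit(truthSet(exp), sprintf("truth_%s.tsv", cond))
    }
    ratesAll <- do.call(rbind, unname(rateRows))
    # report columns in the conventional 1e-9 units, 2 decimals
    ratesAll$mean_1e9 <- round(ratesAll$mean * 1e9, 2)
    ratesAll$ciLow_1e9 <- round(ratesAll$ciLow * 1e9, 2)
    ratesAll$ciHigh_1e9 <- round(ratesAll$ciHigh * 1e9, 2)
    emit(ratesAll, "rates.tsv")
    specTab <- do.call(rbind, lapply(names(spectra), function(cond) {
      s <- spectra[[cond]]
      data.frame(condition = cond, type = names(s$counts),
                 count = as.integer(s$counts), rate = as.numeric(s$rates),
                 tsTv = s$tsTv, stringsAsFactors = FALSE)
    }))
    emit(specTab, "spectrum.tsv")

    comparisons <- NULL
    if (length(configs) > 1) {
      refCond <- names(configs)[1]
      refRates <- attr(rateRows[[refCond]], "perOffspring")
      comparisons <- do.call(rbind, lapply(names(configs)[-1], function(cond) {
        po <- attr(rateRows[[cond]], "perOffspring")
        do.call(rbind, lapply(.RATE_STRATA, function(st) data.frame(
          condition = cond, reference = refCond, stratum = st,
          pT = compareConditions(po[[st]], refRates[[st]], "t"),
          pWilcoxon = compareConditions(po[[st]], refRates[[st]], "wilcoxon"),
          stringsAsFactors = FALSE)))
      }))
      emit(comparisons, "comparisons.tsv")
    }
    if (length(calibration)) emit(calibration, "calibration.json",
                                  json = TRUE)
    clockOut <- NULL
    if (!is.null(clock)) {
      wg <- rateRows[[1]][rateRows[[1]]$stratum == "whole_genome", ]
      if (wg$mean > 0) {
        ci <- c(wg$ciLow, wg$ciHigh)
        clockOut <- clockReport(
          clockParams(clock$theta, clock$tau, wg$mean,
                      clock$generationsPerYear),
          muCi = if (all(ci > 0)) ci else NULL)
        emit(clockOut, "clock.json", json = TRUE)
      } else message("no DNM calls in the reference condition; ",
                     "clock stage skipped")
    }
    manifest <- list(
      package = "TrioDNM",
      version = as.character(packageVersion("TrioDNM")),
      seed = seed, bootstrapB = B, nSpikes = nSpikes,
      thresholds = thresholds,
      conditions = lapply(configs, function(cfg) list(
        genomeLength = cfg@genomeLength, nOffspring = cfg@nOffspring,
        meanDepth = cfg@meanDepth, seqErrorRate = cfg@seqErrorRate,
        mu = as.list(cfg@mu), seed = cfg@seed)))
    emit(manifest, "manifest.json", json = TRUE)
    list(experiments = experiments, callSets = callSets, rates = ratesAll,
         spectra = spectra, calibration = calibration, tests = tests,
         comparisons = comparisons, clock = clockOut, files = written)
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
  invisible(res)
}

#' Published single-nucleotide mutation-rate estimates for five insects
#'
#' Per-site per-generation rates from parents-offspring sequencing studies
#' of the silkworm (normal rearing conditions), fruit fly, postman
#' butterfly, honeybee and buff-tailed bumblebee, bundled as package data
#' for fold-comparison examples.
#'
#' @return data.frame(species, rate) with rates per site per generation.
#' @examples
#' r <- publishedInsectRates()
#' max(r$rate) / min(r$rate)
#' @export
publishedInsectRates <- function() {
  read.delim(system.file("extdata", "insect_rates.tsv", package = "TrioDNM"),
             stringsAsFactors = FALSE)
}

#' Published silkworm mutation-rate table by stratum and condition
#'
#' Mean rates and bootstrap 95% confidence bounds (units of 1e-9 per site
#' per generation) for whole genome, gene, intergenic, A/T and C/G strata
#' under normal, high-temperature and low-temperature rearing.
#'
#' @return data.frame(stratum, condition, mean, ciLow, ciHigh), 1e-9 units.
#' @export
publishedSilkwormRates <- function() {
  read.delim(system.file("extdata", "silkworm_rate_table.tsv",
                         package = "TrioDNM"), stringsAsFactors = FALSE)
}
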