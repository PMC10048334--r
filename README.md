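# TrioDNM

Estimation of the spontaneous single-nucleotide mutation rate from
parents–progeny (trio) whole-genome sequencing, with the downstream analyses
such a study needs: mutation-spectrum summaries, caller calibration by
spike-in, and molecular-clock dating. The package targets full-sib family
designs of the kind used to measure the germline mutation rate of the
domestic silkworm (*Bombyx mori*) under normal and temperature-stress
rearing, but every stage is generic trio arithmetic and works for any
diploid species.

## What it computes

* **De novo mutation (DNM) calling.** A candidate site table (two parents +
  N offspring, with per-sample genotype, depth, alternate-read count and
  site mapping quality) is filtered by five hard rules: depth ≥ 10, mapping
  quality ≥ 20, no caller low-quality flag, alternate-read fraction ≥ 30%,
  at most 2 non-reference positions per supporting read, and clean
  homozygous-reference parents (no alternate allele or read, depth ≥ 10).
  A DNM is a heterozygous variant carried by exactly one offspring. Every
  rejected candidate is ledgered with a single reason code.
* **Rate estimation.** Per offspring *i*, µ̂ᵢ = mᵢ / (2·Cᵢ) where mᵢ is the
  DNM count and Cᵢ the callable sites (diploid denominator). The family
  rate is the unweighted mean across offspring; its 95% CI is a percentile
  bootstrap (1000 resamples; 25th and 975th order statistics). Rates are
  stratified by genome region (gene/intergenic) and reference base class
  (A/T vs C/G). Condition contrasts use t / Wilcoxon tests on the observed
  per-offspring rates; cross-species contrasts use a χ² test of mutant vs
  non-mutant site counts; positional uniformity uses a K-S test.
* **Spectrum.** Six strand-collapsed substitution types (e.g. G:C→A:T),
  Ts/Tv ratio (0.5 under no bias), per-type rates conditioned on the origin
  base class, CpG-island association of G:C→A:T calls (two-sample
  proportion test), and a ±10 bp flanking-context matrix oriented so the
  mutated base reads C.
* **Calibration.** False negatives by spike-in: at random sites/offspring,
  y ~ Binomial(depth, 0.5) reads are flipped to a non-reference base and
  the pipeline re-run; FN = 1 − recovered/spiked. An analytic closed form
  of the same probability cross-checks the measurement. True-positive rate
  is confirmed/tested arithmetic; an optional corrected rate is
  raw·TP/(1−FN).
* **Molecular clock.** µ per year = µ per generation × generations/year;
  Ne = θ/(4µ); divergence time T = 4τNe. With θ = 0.034, τ = 0.0035,
  µ = 0.41×10⁻⁸ and 3 generations/year this dates silkworm domestication
  to 9700 years (nearest hundred).
* **Synthetic data.** `simulateTrio()` generates a full trio experiment
  (reference FASTA, gene/CpG-island BED-style tracks, per-site read
  evidence, known truth set) so the entire pipeline is testable with exact
  ground truth; see the methods vignette for the generative model.

## Worked example

```r
library(TrioDNM)

cfg <- simulationConfig(genomeLength = 5e7, nOffspring = 30, mu = 4.1e-9,
                        seed = 2024)
exp <- simulateTrio(cfg)
cs  <- callDnms(exp)
rates <- estimateRates(cs, condition = "normal", B = 1000, seed = 7)
rates[, c("stratum", "mean", "ciLow", "ciHigh", "m", "callableTotal")]
#>        stratum     mean    ciLow   ciHigh m callableTotal
#> 1 whole_genome 3.06e-09 1.36e-09 4.76e-09 9      1.47e+09
#> 2         gene 2.92e-09 0.00e+00 5.83e-09 3      5.14e+08
#> 3   intergenic 3.14e-09 1.05e-09 5.23e-09 6      9.55e+08
#> 4           AT 2.74e-09 1.10e-09 4.94e-09 5      9.11e+08
#> 5           CG 3.58e-09 8.95e-10 7.16e-09 4      5.59e+08
```

Nine DNMs over 30 offspring × ~4.9×10⁷ callable sites each give a
whole-genome rate of 3.1×10⁻⁹ per site per generation with a bootstrap 95%
CI of (1.4–4.8)×10⁻⁹ — consistent with the simulated truth of 4.1×10⁻⁹
(at 50 Mb the per-family mutation count is small, so intervals are wide;
real whole-genome studies use ~9× more sites). Feeding the estimate into
the clock and calibrating the caller by spike-in:

```r
wg <- rates[rates$stratum == "whole_genome", ]
clockReport(clockParams(theta = 0.034, tau = 0.0035, muGen = wg$mean,
                        generationsPerYear = 3), muCi = c(wg$ciLow, wg$ciHigh))
#> mu/year = 9.18e-09, Ne = 9.26e+05, T = 13000 years (CI 8300-29200)

sp <- spikeIn(exp, nSites = 1000, seed = 11)
falseNegativeRate(sp$ledger, callDnms(sp$experiment, annotate = FALSE))
#> spike-in FN = 10.3% (analytic 9.1%)
```

The measured false-negative rate sits within sampling error of the
closed-form expectation (mapping-quality dropout, depth dropout, and the
binomial allele-balance filter).

A three-condition study (normal + two stress families, rate tables,
comparisons, spectrum, calibration, clock) runs end to end with
`runPipeline(silkwormDesign(genomeLength = 5e6, seed = 1), "outdir")`, or
from a shell via `inst/scripts/run_pipeline.R`.

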