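---
title: "Estimating germline mutation rates from trio sequencing: methods and design"
author: "TrioDNM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating germline mutation rates from trio sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TrioDNM)
```

# The estimation problem

A parents–progeny design sequences both parents of a full-sib family and N
offspring, each to moderate depth (~30×), and asks how many single-nucleotide
variants arose de novo in one generation. The estimator is

µ̂ᵢ = mᵢ / (2 Cᵢ)

per offspring *i*: mᵢ accepted de novo mutations (DNMs) divided by twice the
callable sites Cᵢ, because each callable site carries two allele copies in a
diploid. The family estimate is the unweighted mean of the per-offspring
rates, matching a bootstrap over offspring in which each resample's statistic
is the mean of N redrawn per-offspring values. Both the numerator and the
denominator are deliberately conservative: a DNM must survive hard filters,
and a site only counts as callable if the same filters *could* have detected
a DNM there.

The method assumes (i) parents are homozygous reference at candidate sites —
a reasonable approximation in inbred laboratory strains, enforced by filters
rather than trusted; (ii) true heterozygous sites present alternate alleles
in half the reads on average; (iii) sites are exchangeable within a stratum.
It makes no genotype-likelihood model: all decisions are hard thresholds,
which makes the pipeline auditable (every rejected candidate carries exactly
one reason code) at the cost of statistical efficiency.

# Candidate filtering

`applyFilters()` evaluates, in order, for the candidate offspring:

1. `low_depth` — read depth < 10;
2. `low_mq` — site mapping quality < 20;
3. `caller_low_quality` — flagged low-quality by the upstream caller;
4. `low_alt_fraction` — alternate reads / depth < 0.30;
5. `multi_nonref_read` — more than 2 non-reference positions on a
   supporting read (a read-level signal precomputed into the site table,
   since the table itself has no reads);
6. `parent_alt_or_low_depth` — either parent not homozygous reference,
   carrying any alternate-supporting read, or under depth 10.

The first failing rule is reported, keeping the rejection ledger
single-reason. `callDnms()` additionally requires the carrier to be unique —
a variant in two or more offspring is rejected as
`shared_across_offspring` — and heterozygous (`not_heterozygous`
otherwise). "Present in only one offspring" is interpreted at the genotype
level: other offspring must not *carry* the alternate allele in their
genotype. Stray alternate reads in another sample (sequencing error) do not
veto a candidate; the read-level veto applies only to parents, where the
filter list is explicit about reads. At a per-read error rate of 10⁻³ and
30 sibling samples of ~30 reads each, a read-level veto across all samples
would discard roughly a quarter of all true mutations, which is
incompatible with the false-negative rates such pipelines actually measure
(~9–12%).

`countCallable()` applies the symmetric denominator rule: offspring and
both parents at depth ≥ 10, site MQ ≥ 20, parents homozygous reference.
Mapping quality is modelled per site (as GATK reports it), so the parental
MQ requirement is automatically symmetric. Counts are stratified by region
(gene vs intergenic) and reference base class (A/T vs C/G) so that every
stratified rate has its own denominator; the strata partition the total
exactly.

# The synthetic-data generator

`simulateTrio()` emulates the study design, not the reads:

* **Reference**: i.i.d. bases at a configurable GC content (default 0.38,
  silkworm-like), split into `nChromosomes` chromosomes.
* **Annotation**: non-overlapping gene intervals totalling `geneFraction`
  of the genome (default 0.35) and CpG islands totalling
  `cpgIslandFraction` (default 0.10, the share reported for the silkworm
  genome). Interval lengths default to 5 kb (genes) and 1 kb (islands);
  placement is random but the covered fraction is exact.
* **Mutations**: each offspring, independently at each site, acquires a
  heterozygous DNM with probability 2µ(stratum) — two allele copies, at
  most one mutation per site (collisions are negligible at realistic µ).
  `mu` is a map over region × base class; the transition share of new
  mutations is configurable per base class (1/3 = unbiased spectrum).
* **Read evidence**: per-sample depth is Poisson(`meanDepth`, default 30)
  or negative binomial when overdispersion is requested; the
  alternate-read count at a true heterozygous site is Binomial(depth, ½);
  every other sample/site pair receives alternate reads with probability
  `seqErrorRate` per read (default 10⁻³, Illumina-like). Site mapping
  quality falls below 20 at a configurable 2% of sites (default), which
  makes the MQ filter exercisable.
* **Standing variation**: off by default (inbred parents); a switch makes
  parent 1 heterozygous at a configurable rate with Mendelian inheritance,
  to exercise the parental and sharing filters.

Two emission modes trade memory for fidelity of representation, not of
distribution. *Dense* mode materialises every site and is used for genomes
up to a few hundred kb; callable counts are then literal enumerations.
*Sparse* mode materialises only rows with variant evidence (the only rows
that can ever become candidate calls, since candidacy requires a
non-reference genotype) and draws each offspring × stratum callable count
from Binomial(N_stratum, p_callable), where p_callable multiplies the MQ
pass probability by the cube of the depth pass probability — exactly the
marginal law of the enumerated count under the same model. This is what
makes a 5×10⁷-site, 32-sample family simulable in seconds. The cost is
that per-offspring callable counts are drawn marginally (their tiny
cross-offspring correlation through shared parental depths is dropped) and
that error-only rows are not materialised. Neither affects any downstream
statistic the package computes: denominators have coefficient of variation
~10⁻⁴, and error-only rows cannot produce calls.

What passing tests on this generator do **not** show about real data:
alignment artefacts, indel-adjacent miscalls, depth heterogeneity along
the genome (GC bias, repeats), batch differences between families, or
caller-specific genotype errors. The generator's role is to verify the
arithmetic and the filter logic against exact ground truth, and to expose
each filter to inputs that trigger it.

# Bootstrap confidence intervals

`bootstrapCI()` implements the percentile bootstrap over offspring: B =
1000 resamples of size N with replacement, each summarised by its mean;
the interval is the 25th and 975th order statistics of the sorted
estimates (general B uses ⌊0.025 B⌋ and ⌈0.975 B⌉; B < 40 is refused
because the 2.5% order statistic would not exist). On Gaussian data with
N = 30 the interval attains near-nominal coverage (the test suite checks
93–98% over 500 trials).

At very low expected counts the percentile bootstrap undercovers. In the
package's own recovery benchmark — µ = 4×10⁻⁹ over 5×10⁷ bp and 10
offspring, i.e. a family total of ~3.6 expected mutations — the interval
covers the true rate in only ~80–90% of replicates (the acceptance script
reports the realised fraction as `recovery_ci_coverage`): with a family
total of 0 or 1 observed mutations the upper bound cannot reach the truth,
and with ≥ 7 the lower bound exceeds it. This is a property of percentile
intervals on tiny discrete counts, not of the caller; at the mutation
counts of a real whole-genome study (hundreds of DNMs over ~4×10⁸ callable
sites × 30 offspring) the discreteness vanishes. Readers comparing
designs should treat the CI as honest at study scale and indicative only
at toy scale.

# Hypothesis tests

Condition contrasts (`compareConditions()`) act on the observed
per-offspring rates, never on bootstrap replicates. The default t-test is
Welch's (R's own default; a pooled-variance switch exists); the rank-sum
alternative uses the normal approximation so that ties — frequent among
small integer counts — are handled. Two identical constant groups are
defined to give p = 1 rather than an error. No multiple-testing adjustment
is applied; reported p-values are raw, and the output metadata says so by
omission of any adjustment field. Cross-species homogeneity
(`crossSpeciesTest()`) forms the species × {mutant, non-mutant} table from
counts and diploid callable totals and applies Pearson's χ²; expected
cells below 1 set a warning flag. Positional uniformity
(`chromosomeDistributionTest()`) maps calls to normalised positions in the
concatenated genome — the uniform null implied by chromosome lengths — and
applies the K-S test.

The CpG-island association test follows the two-sample proportion
construction (χ² with continuity correction): observed in-island fraction
of G:C→A:T calls against the island share of the genome under a
length-weighted uniform null. The expected count is rounded to an integer
because the test compares two samples of equal size; with ≥ tens of calls
the rounding is immaterial.

# Spike-in calibration

The original protocol edits reads in FASTQ and realigns; at the site-table
level the equivalent operation (`spikeIn()`) sets, at each of 1000 random
non-variant positions and a random offspring, y ~ Binomial(x, ½) of the x
reads to a uniformly chosen non-reference base and marks the genotype
heterozygous. Recovery is judged by re-running the ordinary caller, so a
spike can fail for exactly the reasons a real mutation can: depth or MQ
dropout, allele-balance below 30%, or a contaminated parent.
`analyticFalseNegativeRate()` integrates those probabilities over the
depth distribution in closed form, giving an independent expectation the
measured FN must match within binomial error — a self-consistency check
the test suite enforces. Spiked sites that were uncallable pre-spike stay
in the denominator (recovery is judged after the full pipeline). Dense
spikes modify rows reversibly (`unspike()` restores the table
bit-exactly); sparse spikes append rows.

# Molecular clock

With θ and τ taken as external coalescent estimates, Ne = θ/(4µ) and
T = 4τNe. The package accepts µ per year directly or µ per generation plus
generations/year; the two pathways agree algebraically (T = τθ/µ_year) and
the tests check both. For reared silkworm, 3 generations/year converts the
per-generation rate for domestication dating; cross-species per-year
comparisons use 365/generation-days. Headline times are reported raw and
rounded to the nearest 100 years; with θ = 0.034, τ = 0.0035,
µ = 0.41×10⁻⁸ and 3 generations/year the report gives 9700 years. Rate
CIs propagate monotonically (T decreases in µ, so the lower rate bound
gives the upper time bound).

# Numerical and design choices

* Filter order is fixed and first-failure-reported; reordering would only
  relabel multi-fault rejections.
* The depth distribution is Poisson by default because the study design
  specifies only a mean depth; a negative-binomial switch covers
  overdispersed libraries.
* The six-type spectrum uses an origin-pair notation (G:C→A:T); internally
  classification canonicalises to the pyrimidine-reference strand, which
  makes strand involution exact by construction.
* Flank-context extraction drops calls within one flank of a contig end
  (with a warning) — only relevant on toy genomes.
* `estimateRates()` refuses zero callable denominators rather than
  emitting NaN; `bootstrapCI()` on constant input returns a degenerate
  interval.
* The pipeline's power check for a doubled mutation rate simulates at a
  baseline of 2×10⁻⁸ over 5×10⁷ bp × 30 offspring: chosen a priori so the
  two-sample t-test has high power for a 2× effect at that family size
  (expected counts 60 vs 120 per family), while remaining desk-scale.
* Default stratified rates in `silkwormDesign()` are the published
  silkworm per-class estimates (A/T 3.60, C/G 4.58; stress families 3.80/
  8.14 and 3.76/7.85, all ×10⁻⁹), so the default three-condition run
  emulates the study's effect sizes.
* Test and acceptance problem sizes: dense fixtures 2×10⁴–2×10⁵ bp;
  sparse recovery runs 5×10⁷ bp × 10 offspring × 20 replicates; spike-in
  calibration 10⁶–3×10⁶ bp with 500–1000 spikes; spectrum nulls 10⁵
  mutations. These sizes keep the full suite within minutes while leaving
  every statistic in its asymptotic regime except where discreteness is
  itself under discussion (see the bootstrap section).

# Limitations

No reads are simulated (no FASTQ/BAM), so alignment- and
library-preparation artefacts are out of reach; no indels, multi-nucleotide
or structural variants; no genotype likelihoods; sites are independent, so
clustered mutation processes and depth autocorrelation are not modelled;
the sharing rule's genotype-level interpretation is a modelling decision
(documented above) that a read-level pipeline could tighten; and percentile
bootstrap intervals should not be trusted below ~10 expected mutations per
family. The clock takes θ and τ as fixed inputs — no coalescent inference
is performed, and uncertainty in those parameters is not propagated.
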