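---
title: "UMI-aware forensic SNP genotyping: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{UMI-aware forensic SNP genotyping: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Massively parallel sequencing of large forensic SNP panels (thousands of
markers) promises genotypes from very small amounts of DNA, but at low
input the read counts stop being honest evidence: PCR duplicates inflate
the apparent depth of whatever molecules happened to amplify first, and
polymerase or sequencing substitutions masquerade as alleles. Unique
molecular indices (UMIs) — short random tags ligated to each template
molecule before amplification — let the analysis reason at the molecule
level. Reads sharing a UMI descend from one template; a consensus over
each UMI family removes most amplification and sequencing errors, and the
number of distinct families estimates the number of template molecules
actually sampled.

`umisnp` implements that analysis end to end: UMI grouping and consensus,
allele-read-frequency (ARF) genotype calling, the matched-threshold
comparison of UMI versus raw-read counting on the same reads, DNA-mixture
detection and deconvolution, kinship likelihood ratios with gene-dropping
simulation, and naive-Bayes biogeographic ancestry. Because raw forensic
sequencing data is not publicly distributable, the package carries a
molecule-level simulator that generates the read data all of this runs
on; every analysis function is agnostic to whether its reads came from
the simulator or from an upstream mapper's per-locus export.

## Genotype calling model

At each biallelic locus the ARF is the depth of the most-read allele
divided by the total depth (so ARF >= 0.5). Calling is threshold-based,
following standard forensic practice rather than probabilistic genotype
likelihoods:

* total depth below `min_coverage` (default 10x): no call, low coverage;
* ARF >= `hom_arf` (default 0.95): homozygote for the major allele;
* ARF <= `het_arf` (default 0.80): heterozygote of the two most-read
  alleles;
* anything between: no call, imbalance;
* major or second allele outside the panel's ref/alt pair: no call,
  off-panel. An `other` bucket absorbs non-ACGT observations; it counts
  toward depth but can never be called.

Bounds are inclusive exactly as written. Three profiles ship: `default`
(0.95/0.80), `liberal` (0.90/0.85; more calls, slightly more errors) and
`deconvolution` (0.90/0.55; conservative heterozygote bound for residual
reads after mixture subtraction). Base quality is a per-read filter at
the SNP site (default Q >= 15) applied before any counting, a choice
that composes identically with both counting modes; an alternative
variant-level interpretation would filter after consensus. Hemizygous
loci (Y; X in males) call a single allele at the homozygote bound.

The consensus rule is strict majority (> 50% of family members, exact
ties ambiguous), with `min_family_size = 1` by default — permissive
singleton passthrough, matching the default behaviour of the commercial
pipelines this mirrors, whose internal parameters are not published.
Ambiguous families are dropped rather than split. An optional
directional merge absorbs UMI groups within Hamming distance 1 of a
>= 10x larger group; it is off by default because tag-error correction
is a separate design decision from consensus calling.

## The simulator

The generator reproduces the stages of a UMI-tagged multiplex assay at
the locus-summary level (reads carry only the SNP-site base — read-level
alignment is out of scope):

1. **Genotypes.** Hardy-Weinberg sampling from population allele
   frequencies, or gene dropping through an explicit pedigree. With a
   genetic map, meioses follow a Haldane crossover process
   (r = (1 − e^(−2d/100))/2 per adjacent map distance d cM); without
   one, loci segregate independently.
2. **Templates.** Each allele copy contributes
   Poisson(`library_efficiency` × mass / (2 × 3.3 pg) × capture)
   UMI-tagged molecules. 3.3 pg per haploid genome is the standard
   forensic constant. `library_efficiency` (default 0.3) is the fraction
   of input molecules converted into amplifiable library; ligation-based
   preps convert a minority of molecules, and this conversion loss — not
   the input mass itself — is what drives allele drop-out at low input.
   `capture` is a per-locus lognormal weight (sd `capture_bias_sigma`,
   default 0.7) modelling locus-to-locus variation in conversion and
   primer efficiency, the reason call rates decay gradually rather than
   cliff-like along a dilution series. Both default values were fixed
   once, on library-prep literature grounds, before any comparison was
   run; setting `library_efficiency = 1, capture_bias_sigma = 0`
   recovers the idealised mass-to-copies conversion.
3. **Amplification.** Early cycles (default 8 of 25 total; 6 target
   enrichment + 19 universal cycles motivate the total) are an explicit
   branching process: each molecule duplicates with probability
   `pcr_efficiency` (0.9), and each duplication substitutes the SNP base
   with probability `pcr_error_rate` (1e-5, uniform over the other three
   bases), founding a mutant lineage inside the UMI family — the error
   mode consensus exists to defeat. Later cycles multiply every lineage
   by the same deterministic factor, which cancels in read sampling;
   this keeps runtime linear in molecules while preserving the
   early-cycle phenomenon. A per-locus lognormal amplification weight
   (sd 0.3) models differential amplification.
4. **Sequencing.** `reads_target` reads are drawn multinomially over
   lineages; each suffers an independent substitution with probability
   `seq_error_rate` (1e-3) and receives a rounded-normal Phred quality
   (mean 30, sd 6, truncated to 0..41). The published assay reports no
   quantitative PCR or sequencing error rates, so these are documented
   plausible defaults, not reconstructions.
5. **Mixtures.** Contributor template means scale with the mixture
   proportions; capture weights are shared across contributors within a
   library, as they would be physically.

Every stage draws from a deterministic substream of one master seed, so
identical configurations give byte-identical read streams.

What the simulator does *not* model: adaptor dimers, index hopping,
strand artifacts, DNA degradation and deamination, and fragment-length
effects. Passing tests on synthetic data therefore demonstrate the
internal consistency and calibration of the analysis, not its behaviour
on those real-data pathologies.

## The UMI-vs-raw comparison

The comparison analyses the *same* simulated reads twice: UMI mode
counts consensus reads per molecule; raw mode counts all quality-passing
reads, duplicates included. Raw depth is inflated relative to molecule
count, so fixed coverage thresholds are not comparable across modes.
Following the matched-threshold design, `match_call_rate()` scans
integer raw coverage thresholds and picks the one whose call rate is
nearest the UMI call rate (ties to the larger, more conservative
threshold) so error rates can be compared; `match_error_rate()` matches
the error rate (ties broken by call-rate distance, then threshold) so
call rates can be compared. "Similar" is operationalised as
nearest-achievable because no tighter definition exists for integer
thresholds. The directional hypothesis — UMIs improve accuracy at
matched call rate and call rate at matched error rate — is tested with a
one-sided paired t-test across replicate samples; the statistic is
computed in closed form so the degenerate all-zero-difference series is
defined (t = 0, p = 0.5).

The packaged study conditions (`dilution_experiment()` defaults) are a
6-point dilution series of 10, 1, 0.5, 0.25, 0.125 and 0.06 ng with
three replicates over a 5,000-SNP panel and 1.5 million reads per
sample. At these sizes the whole experiment runs in about a minute on
one CPU. Because genotype errors at moderate input are individually
rare events, per-amount accuracy differences are compared as replicate
means, and the decisive low-input contrast pools the amounts at and
below 0.25 ng, where molecule scarcity makes the benefit of
molecule-level counting visible.

## Mixture detection and deconvolution

A two-person mixture inflates the apparent heterozygosity of called
autosomal genotypes. The detector compares the observed heterozygosity
rate against the single-source expectation (mean 2pq over panel loci)
with a binomial null standard deviation and flags z > 3 — an explicit,
testable statistic standing in for the visual inspection forensic
analysts perform on ARF density plots (`plot_arf_density()` draws the
corresponding figure; the two-contributor ceiling mean(1 − p⁴ − q⁴) is
reported alongside). Balanced and 1:10 mixtures are detected this way;
1:50 and 1:100 are not, because a ~1–2% minor contributor shifts ARF
too little to change calls.

Quantitative deconvolution assumes the mixture proportion and one known
contributor: at each locus round(proportion × depth) reads are removed —
all from the known allele if homozygous, split equally (odd remainder to
the lexicographically first allele) if heterozygous, floored at zero
with un-removable excess discarded. The equal split is the expectation
under balanced amplification; the flooring prevents negative counts.
The residual depths are called with the conservative deconvolution
profile. Rounding uses floor(x + 0.5) for platform-stable half-up
behaviour.

## Kinship and ancestry

Pairwise relationships are parameterised by IBD coefficients
(κ0, κ1, κ2); the LR is the standard identity-by-descent decomposition
under HWE with zero mutation rate, so any opposite-homozygote duo (or
impossible trio) zeroes the combined LR. `lr_summary()` therefore
reports both the strict result and the LR with exclusions dropped,
reproducing the practice of flagging the inconsistent marker and
recomputing. Frequencies are floored at 1e-3 to avoid degenerate zero
or one frequencies, the same safeguard common kinship software applies.

Simulation studies gene-drop explicit pedigrees (half siblings share a
father; cousins share grandparents), guaranteeing the correct joint IBD
process along chromosomes when a genetic map is supplied. The LR itself
still assumes linkage equilibrium — the per-locus product — which is
why linked simulations widen the LR distributions without shifting the
H2 mean; a full linkage-aware likelihood is out of scope. Distribution
separation is summarised as the overlap at LR = 1, the mean of the two
misclassification rates, which increases monotonically from 2nd-degree
(half siblings) to 5th-degree (second cousins) relationships.

Two caveats discovered while testing are worth recording. First, the
pruned H2 likelihood ratio (exclusions dropped) is *positively* biased —
removing the zero-LR loci removes the strongest evidence against the
relationship — which is precisely why inconsistency counts, not pruned
LRs, carry the evidential weight when the tested relationship is false.
Second, while E[LR | H2] = 1 per locus exactly (a martingale property
the tests verify by Monte Carlo), the dual identity E[1/LR | H1] equals
1 − 2p²q², not 1, because exclusion states carry H2 mass but no H1
mass.

Ancestry prediction is a naive Bayes classifier: per reference
population, the log-likelihood sums log HWE genotype probabilities over
called autosomal ancestry markers at that population's (floored)
frequencies; the posterior normalises prior × likelihood, uniform prior
by default. The bundled generator builds seven meta-population frequency
tables under a Balding–Nichols model (Fst 0.15) around shared ancestral
frequencies, giving the well-separated reference panels such classifiers
assume.

## Numerical and interface choices

* Coordinates are 1-based inclusive throughout (VCF convention); the
  VCF writer emits a minimal v4.2 subset (GT:AD:DP, `./.` no-calls,
  records sorted by chromosome and position) that standard parsers read
  back, with DP equal to the sum of AD by construction.
* Ties on the maximum-depth allele break lexicographically; the ARF
  value itself is unaffected.
* Matched-threshold scans round rate differences to 1e-9 before ranking
  so the tie-to-larger-threshold rule is not defeated by floating-point
  noise.
* TSV dialect: tab-separated, UTF-8, mandatory header, `#` comments;
  parse errors name the offending line. Missing frequencies for a
  queried locus are an error, never an implicit zero.
* UMI tags are uniform random sequences (default length 12, the common
  8–12 nt range; the exact commercial tag length is not published).
  Collisions are left to the grouping stage, which merges them as real
  pipelines do.

## Known limitations

Threshold calling ignores genotype likelihoods and contamination
models; the mixture machinery covers two contributors with one known;
no mutation model, silent alleles or co-ancestry correction in the
kinship LRs; X-chromosomal kinship and phenotype prediction are out of
scope. The simulator's call-rate decay along the dilution series is
qualitatively faithful but not calibrated to any particular instrument
or kit — absolute call rates at a given mass depend on
`library_efficiency` and `capture_bias_sigma`, which real laboratories
would estimate from their own validation data.
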