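---
title: "Methods: mutation enrichment at differential 5hmC loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation enrichment at differential 5hmC loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetmut)
```

## The problem

TET enzymes oxidize 5-methylcytosine (5mC) stepwise to 5hmC, 5fC and 5caC;
the latter two are excised by TDG and repaired by base excision repair,
closing the cytosine-modification cycle. When TET2 is lost, loci where TET2
normally performs the *further* oxidation of 5hmC are expected to appear as
loci that **gain** a 5hmC peak in the knockout, and — if incomplete
demethylation is mutagenic — to accumulate somatic mutations at an elevated
rate. `tetmut` implements the statistics of that question: locus
classification from peak dynamics, footprint-normalized mutation enrichment,
mutation-spectrum and CpG-proximity summaries, fluctuation-assay frequencies
and cohort burden comparisons, plus a seeded synthetic-data generator so the
entire pipeline is testable without any external data.

## Locus classification

Inputs are four peak sets (5hmC and 5mC, wild-type and knockout), each a
tibble of 0-based half-open intervals. All internal arithmetic uses this one
convention; conversion to VCF's 1-based coordinates happens only at I/O
boundaries, which removes a whole class of off-by-one errors.

Peaks are compared at the **whole-peak** level: a knockout 5hmC peak is
"gained" if its overlap with the (merged) wild-type set is below
`min_overlap_fraction` of its own length. The default fraction of 0 means
*any* overlap disqualifies a peak — the most conservative reproducible rule
when no threshold is dictated by the data, and the fraction remains a
configuration knob because peak-level versus base-level classification is a
genuinely open choice. Whole-peak calls are then reduced to base-level
footprints:

* `hmc_gain` — bases of knockout-only 5hmC peaks;
* `hmc_loss_or_mc_gain` — bases of wild-type-only 5hmC peaks *or*
  knockout-only 5mC peaks (the sites that needed TET2 for the first
  oxidation step);
* `no_change` — bases where wild-type and knockout 5hmC peaks intersect.

Disjointness is guaranteed by precedence (`hmc_gain` >
`hmc_loss_or_mc_gain` > `no_change`): higher categories are subtracted from
lower ones. Two deliberate asymmetries: 5mC *loss* is not a category (such
regions simply fall out of the classification), and bases outside all three
categories form an implicit background stratum that is reported (as
`unassigned` variants) but excluded from the three-way test.

## Enrichment test

Each variant is represented by a single base: the substituted base for an
SNV, the first changed base for a left-aligned indel (the base after the
anchor). Counts per category are tested with Pearson's chi-squared
goodness-of-fit against expected counts proportional to category footprint
in bp. Footprint normalization is the only defensible null when categories
differ in size; per-category rates are additionally reported as
variants/Mb, so both normalized and raw views are available. The test
requires at least two categories with positive footprint; with no variants
the pipeline reports zero counts and marks the tests not applicable rather
than failing.

TET2-binding association is assessed two ways: a chi-squared test of
independence on the category × covered/uncovered **base** table (base-level
units are the default; peak-level overlap is available through
`feature_fold_enrichment()`), and the fraction of in-locus mutations whose
assigned base lies strictly inside a binding peak.

## Statistical kernels

The kernels wrap the reference implementations in `stats`, and every exact
claim is cross-checked in the test suite against independent brute-force
oracles (full hypergeometric enumeration for Fisher; enumeration of all
group assignments for the rank-sum test; per-base boolean masks for interval
arithmetic):

* Fisher's exact test, two-sided by the minimum-likelihood rule (sum of
  tables with probability not exceeding the observed table's) — the dominant
  convention.
* Chi-squared goodness-of-fit and independence, without continuity
  correction.
* Wilcoxon rank-sum: exact permutation null when the pooled sample size is
  at most 12 with no ties; otherwise the normal approximation with midranks,
  tie-corrected variance and continuity correction. The switchover and tie
  handling are standard and reproducible.

No multiple-testing correction is applied inside the kernels; the 13-locus
panel wrapper reports raw per-locus significance by default (reproducing the
convention of single-panel reporting) with Bonferroni and Benjamini–Hochberg
available by flag.

## Mutation spectrum and CpG proximity

Substitutions are collapsed onto the pyrimidine reference (G>A ≡ C>T, A>C ≡
T>G, …) into six classes; C>T and T>C are the transitions. The indel
spectrum records +1 insertions and −1 deletions explicitly — the sizes of
interest for polymerase slippage at repair intermediates — and folds longer
indels into `other_indels`. Proportions are over all variants and sum to 1.

A mutation is *CpG-proximal* if its assigned base lies within `window_bp`
(default 30) of **either** base of a CpG dinucleotide, inclusive; the
dinucleotide has no natural anchor, so measuring to both bases avoids an
arbitrary choice. The expected proximal fraction under "mutations ignore
CpGs" comes from a spacing null with mean inter-CpG distance λ (default
100 bp):

* `exponential_gap` (default): CpGs as a Poisson process; a uniform position
  is proximal with probability $1 - e^{-(2w+2)/\lambda}$ — the CpG occupies
  2 bp, hence the $2w + 2$ window. At w = 30, λ = 100 this is ≈ 0.462.
* `fixed_spacing`: perfectly regular CpGs, $\min(1, (2w+2)/\lambda)$ = 0.62
  at the defaults — an upper-bound-style variant, since how such an
  expectation is derived from a stated mean spacing is ambiguous (regular
  spacing gives ≈ 62%, Poisson spacing ≈ 46%).
* `empirical_shuffle`: Monte-Carlo placement of uniform positions on a
  supplied genome.

Both analytic models are provided precisely because the derivation is
underdetermined; the exponential-gap model is the default as the natural
stochastic null, and on the package's simulated genomes (which plant CpGs
with exponential gaps) the empirical shuffle agrees with it to within ±0.02.

## Fluctuation assay

The HPRT 6-thioguanine assay frequency is the normalized ratio
$f = (\text{colonies}_{6TG}/\text{cells plated})/PE$. Replicate dishes are
pooled (colonies and cells summed) by default because the estimand is
defined through totals; a per-dish mode reporting mean ± sd is provided for
dispersion diagnostics. A plating-efficiency above 1 warns rather than
errors (miscounting happens); zero PE colonies is an error because the
frequency is then undefined. No Luria–Delbrück correction is applied: the
estimand here is the simple normalized frequency, not a per-division
mutation rate, and simulation shows the estimator's relative bias at
f = 1e-5 is under 10% (the only bias source is the convexity of 1/PE, about
0.2% at 500 plated cells).

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated; its defaults are fixed, not tuned:

* **Genome** — 1 Mb (tests use 50 kb–4 Mb as noted below), GC fraction 0.4,
  CpGs planted with exponential gaps of mean 100 bp after removing
  incidental background CpGs, so the realized spacing matches the analytic
  null. No N bases are emitted.
* **Peaks** — non-adjacent regions (min gap 500 bp, lengths ~N(1000, 200²)
  bp) realizing each category through WT/KO presence patterns; the
  loss-or-gain category alternates between its two mechanisms. Non-adjacency
  makes the category truth unambiguous. TET2-binding peaks cover regions
  with per-category probability (0.2, 0.2, 0.7) — concentrated on 5hmC-gain
  loci, where roughly two-thirds of in-locus mutations then fall inside
  binding sites.
* **Mutations** — 600 variants with per-bp rate multipliers (1, 1, 3, 1)
  over (no-change, loss-or-gain, gain, background): the 3× gain-category
  rate is the planted effect. Substitution classes are drawn from weights
  0.35 C>T, 0.23 T>C, 0.38 transversions (split evenly), 0.04 ±1 indels
  with deletions more common (0.025 vs 0.015), each placed on a compatible
  reference base. With probability 0.5 an SNV is additionally constrained to
  lie within ±30 bp of a CpG; combined with the ≈ 0.46 background this
  yields ≈ 0.73 proximal overall.
* **Cohort** — 41 "mutated" vs 154 "wild-type" samples; negative-binomial
  burdens (size 8, wild-type mean 10) with a 1.5× mean ratio.
* **Assay** — triplicate 5×10⁵ cells/dish under selection, 500 cells for
  plating efficiency (PE 0.5); 6-TG colonies Poisson with mean
  cells × f × PE, PE colonies binomial.

A single root seed deterministically derives per-stage substreams, so any
stage can be regenerated independently and all outputs are byte-stable.

What the generator does **not** emulate: local mutation-rate covariates
(replication timing, expression), trinucleotide signature structure,
sequencing error, adjacency/boundary ambiguity between peaks, and N-base or
repeat content. Passing tests therefore demonstrate the statistical
machinery is correct and calibrated under the stated generative model — not
that real peak callers or variant callers are error-free.

## Numerical choices and problem sizes

* Interval arithmetic is exact to the base (via IRanges reduce/intersect/
  setdiff behind a tibble interface) and verified against per-base boolean
  masks on 10-kb genomes.
* The classifier and enrichment tests use problem sizes chosen so sampling
  error is well below the assertion tolerances: spectrum recovery at
  n = 10,000 variants (±0.02), rate-ratio recovery at ~1 Mb/category with
  n = 600 (ratio within 3 ± 0.5), null calibration with 2,000 replicates of
  600 variants on a ~100-kb landscape (Kolmogorov–Smirnov p > 0.01), power
  checks over 200 seeds.
* Chi-squared p-values from discrete counts are only asymptotically
  uniform; the calibration fixture uses jittered peak lengths (irregular
  footprints), which keeps the statistic's support rich enough for the KS
  check to be meaningful.
* Degenerate inputs: all-zero contingency tables, empty variant sets,
  zero-footprint categories and zero-margin tables raise explicit domain
  errors (or produce "not applicable" report fields at the pipeline level);
  a locus with zero genotyped cells is skipped with a warning rather than
  poisoning the panel.

## Known limitations

* Peak calling, read alignment and variant calling are out of scope; the
  package starts from BED/VCF.
* The classifier's whole-peak rule with fraction 0 is conservative; truly
  adjacent or partially overlapping peaks are classified by precedence, and
  near-boundary bases can legitimately be argued either way. The overlap
  fraction is exposed for sensitivity analysis.
* The burden comparison takes pre-filtered nonsynonymous counts; consequence
  annotation is the caller's responsibility.
* The fluctuation module estimates frequency, not rate; converting to
  per-division rates would require a fluctuation-model estimator that is
  deliberately not implemented.
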