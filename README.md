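# tetmut

Loss of the TET2 dioxygenase — one of the most frequently mutated genes in
myeloid malignancies — leaves 5-methylcytosine (5mC) oxidation incomplete and
is associated with genome-wide hypermutability in haematopoietic
stem/progenitor cells. `tetmut` is an R package for the downstream statistics
of that observation: it classifies genomic loci by how their
5-hydroxymethylcytosine (5hmC) and 5mC peaks change between wild-type and
knockout conditions, asks whether somatic mutations are enriched at loci that
*gain* 5hmC (the sites where TET2 would normally perform the further
oxidation of 5hmC), and quantifies the accompanying mutation spectrum,
CpG-proximity, fluctuation-assay and cohort-burden statistics.

It is aimed at epigenomics/regulatory-genomics analysts who have peak sets
(BED), somatic variants (site-only VCF) and a reference (FASTA) and want the
full analysis to run reproducibly — including on purely synthetic,
truth-labelled data generated by the package itself.

## The statistics at the core

* **Locus classification** — with 5hmC peak sets $H_{WT}, H_{KO}$ and 5mC
  peak sets $M_{WT}, M_{KO}$, loci are partitioned (base-level, disjoint)
  into: *no change* (5hmC peak in both conditions), *5hmC loss or 5mC gain*
  (sites needing TET2 for the first oxidation step), and *5hmC gain*
  (KO-only 5hmC peaks; sites where TET2 normally oxidizes 5hmC onward).
  A whole peak counts as gained/lost only if its overlap with the other
  condition is below a configurable fraction of its length (default: any
  overlap disqualifies).
* **Footprint-normalized enrichment** — variant counts $O_k$ per category are
  tested against expected counts $E_k \propto \mathrm{footprint}_k$ (uniform
  per-bp rate null) with Pearson's $X^2 = \sum_k (O_k - E_k)^2 / E_k$,
  $df = k - 1$; per-category rates are reported as variants/Mb.
* **Spectrum** — substitutions are collapsed onto the pyrimidine reference
  (G>A ≡ C>T, …) into six classes; ±1-bp indels are tallied separately.
* **CpG proximity** — the fraction of mutations within ±w bp of a CpG is
  compared against a spacing null: with CpGs as a Poisson process of mean
  spacing λ, a uniform mutation is proximal with probability
  $1 - e^{-(2w+2)/\lambda}$ (≈ 46.2% at w = 30, λ = 100; a regular-spacing
  variant and an empirical shuffle are also provided).
* **Fluctuation assay** — HPRT 6-thioguanine mutation frequency
  $f = (\text{colonies}_{6TG} / \text{cells plated}) / PE$ with plating
  efficiency $PE = \text{colonies}/\text{cells}$ from the unselected dish.
* **Cohort tests** — per-locus two-sided Fisher exact tests for single-cell
  mutant fractions, Wilcoxon rank-sum for per-patient mutational burden, and
  lineage-proportion summaries.

## Worked example (fully synthetic)

```r
library(tetmut)

cfg <- sim_config(seed = 3)          # defaults mirror the study conditions
fx  <- simulate_all(cfg, "fixture")  # FASTA + BEDs + VCF + TSVs + truth

report <- analyze_files(
  fx$paths$genome, fx$paths$hmc_wt, fx$paths$hmc_ko,
  fx$paths$mc_wt, fx$paths$mc_ko, fx$paths$vcf,
  tet2_bed = fx$paths$tet2
)
report
#> tetmut analysis report
#>   600 variants; category footprints (bp): no_change=30247, hmc_loss_or_mc_gain=29345, hmc_gain=28237
#>   enrichment: X-squared = 32.7, df = 2, p = 7.92e-08
#>   CpG proximity: 442/600 (73.7%) within 30 bp; null expectation 46.2%
#>   TET2 overlap: 47 of 90 in-locus mutations inside binding peaks
```

The enrichment line is the footprint-normalized chi-squared test across the
three locus categories: under the generator's defaults the 5hmC-gain
category carries a 3× per-bp mutation rate, and the test recovers it
(p ≈ 8e-8). The CpG-proximity line shows 73.7% of mutations within ±30 bp of
a CpG against the 46.2% expected if mutations ignored CpGs at the genome's
mean CpG spacing of 100 bp. Every piece is a tibble away:

```r
tidy(report$enrichment)     # per-category counts, footprints, rates/Mb
glance(report$enrichment)   # method, statistic, df, p_value
autoplot(report$spectrum)   # spectrum bar chart (ggplot)

burden <- run_cohort(fx$paths$cohort)   # 41 mutated vs 154 wild-type samples
glance(burden)
#> Wilcoxon rank-sum (normal approximation): p = 4.19e-06

run_assay(fx$paths$assay, control = "control")  # plating-efficiency-normalized
```

A thin command-line wrapper with `simulate`, `analyze`, `cohort` and `assay`
subcommands is in `inst/cli/tetmut.R`.

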