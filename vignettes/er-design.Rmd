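---
title: "Simulating and evaluating evolve-and-resequence designs"
author: "erdesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and evaluating evolve-and-resequence designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erdesign)
```

## The question the package answers

In an evolve-and-resequence (E&R) experiment a laboratory population is
founded from standing genetic variation (typically a panel of inbred
isofemale lines), evolved under selection for tens of generations in several
replicate cages, and sequenced before and after. The analysis then asks which
of the millions of segregating variants changed frequency consistently across
replicates. Before committing years of fly work and sequencing budget, an
experimenter wants to know how detection power depends on the design knobs:
number of replicates, census size, duration, founder diversity, coverage.

`erdesign` answers this by simulation: a forward Wright–Fisher simulator of
whole chromosomes with multilocus selection, a generator of synthetic founder
panels, the Cochran–Mantel–Haenszel (CMH) detection layer used by Pool-Seq
pipelines, and ROC-based scoring of entire designs.

## The model

**Population.** `N` diploid hermaphrodites with non-overlapping generations;
`N` is constant. Individuals are pairs of haplotypes over a shared list of
biallelic SNPs. There is no mutation, migration or demography: all response
comes from standing variation, so an allele that is lost (or fixed) stays
lost (or fixed).

**Fitness.** Each beneficial locus carries a selection coefficient $s$ and a
dominance coefficient $h$; genotype fitnesses are $w_{11}=1$,
$w_{12}=1+hs$, $w_{22}=1+s$, counting copies of the beneficial allele.
Fitness is multiplicative across loci; above 50 loci the product is
accumulated in log space so 150 loci at $s=0.5$ lose no precision.

**Reproduction (fecundity selection).** For each of the `N` offspring, two
distinct parents are drawn with probability proportional to fitness
(the second is redrawn until it differs from the first, excluding selfing),
and each parent contributes one gamete. Nothing else distinguishes
individuals, so with no selected loci the model reduces to Wright–Fisher
drift: the per-generation variance of a neutral allele frequency is
$p(1-p)/2N$ and heterozygosity decays by $(1-\frac{1}{2N})$ per generation —
both are asserted against their closed forms in the test suite. The scheme
(independent fitness-proportional draws per offspring, exclusion of the
individual rather than its line) is the simplest one consistent with
fecundity selection without selfing; couples may recur across offspring.

**Recombination.** The map is supplied in windows of arbitrary size with
rates in cM/Mb. For hermaphrodite simulations of species without male
recombination (`sex_mode = TRUE`) the female rate is halved. Per chromosome
the crossover count of a gamete is Poisson with mean equal to the effective
map length in Morgans; breakpoints fall uniformly in genetic distance (no
interference) and chromosomes assort independently. With a zero-length map
whole haplotypes are transmitted intact, so linkage within a chromosome is
never broken — a property test pins this down.

## The synthetic founder panel

Coalescent founder panels are emulated directly rather than imported: within
each genome window the expected SNP count is $L\,\theta\,H_{n-1}$ (with
$H_{n-1}=\sum_{i<n} 1/i$, so that realized pairwise diversity per site
matches the window's $\theta$), derived-allele counts follow the neutral
$1/i$ frequency spectrum, carriers are uniform random subsets, and positions
are uniform. Two things this deliberately does **not** reproduce:

* **founder LD** — sites are generated independently, so the panel carries no
  coalescent linkage structure. In the experiments the package targets, LD is
  dominated by the inbred-line expansion (50 lines in 1000 individuals leave
  massive block LD regardless of the panel) and by drift during the
  experiment, which the simulator does produce. Users who need coalescent LD
  can feed haplotypes from any external simulator through the plain-text
  haplotype format (`read_haplotypes()`).
* **real-genome ascertainment** — diversity and recombination are whatever
  the window file says; no X chromosome, no low-recombination masking.

Founder panels expand into base populations in two modes: `n_haploid < 2N`
replicates each haplotype into `N/n_haploid` identical homozygous
individuals (inbred isofemale lines; 50 founders at $N=1000$ put every
genome into 20 homozygous flies), and `n_haploid = 2N` pairs haplotypes at
random into heterozygotes (an idealised outbred population).

Beneficial loci are picked by a three-step sampler: a segregating site is
drawn uniformly, one of its two alleles is assigned the beneficial role by a
fair coin, and the draw is rejected and repeated if that allele already
exceeds the 80% starting-frequency cap (configurable; capped at `1000 * n`
draws). Because polarity is decided before the cap is applied, low- and
high-frequency derived alleles are treated symmetrically.

## Detection layer

Exact allele counts (`2N` chromosomes per population) are taken for the base
population and each evolved replicate; Pool-Seq is modelled on top as
binomial read sampling at the population frequency with fixed or
Poisson-distributed depth. The CMH test aggregates the $2\times2\times k$
base-vs-evolved tables across replicates without continuity correction — the
large-count regime of whole-population or Pool-Seq data, and the form that
matches the closed-form statistic used as an independent oracle in the
tests. SNPs monomorphic in every stratum are kept with $p=1$ and flagged
rather than dropped, so the set of evaluated SNPs (the FPR denominator) does
not shift between designs. A heterozygosity-based per-SNP
$F_{ST}=(\pi_T-\pi_S)/\pi_T$, averaged over (base, replicate) pairs and
without sample-size correction, is provided as a descriptive companion
statistic; "average pairwise FST" admits several estimators and this choice
is recorded in the function's documentation.

## Scoring a design

A true positive is a selected site detected *at the nucleotide level*:
linked hitchhikers count as false positives, which is exactly the
difficulty of E&R. ROC curves sweep the unique p-values in ascending order
with all tied SNPs entering together; the partial AUC integrates the curve
over FPR $\in [0, 0.01]$ by trapezoids (raw area, or normalized by the FPR
bound so a perfect classifier scores 1). Beneficial alleles lost during a
drift phase stay in the positive set and count as false negatives — allele
loss is a real cost of pre-experiment neutral propagation and should show up
in the score. Boundary ties in top-$n$ counts are broken by a seeded
shuffle so results are reproducible.

`run_design()` evaluates a whole design: per repetition it draws fresh
founders and loci, runs an optional neutral drift phase, evolves `k`
replicates from the same base population, applies the CMH test and reports
pAUC, TPR at the FPR bound and top-$n$ true positives, with means and 95%
confidence intervals across repetitions. Loci are picked (and the frequency
cap applied) before the drift phase; the CMH base counts are taken after it,
which is what an experimenter sequencing at the start of selection would
see. `eval_generations` and `eval_replicates` score nested designs from the
same simulations, mirroring how design grids share a base population.

## Numerical and reproducibility choices

* Allele calls are stored as one byte (raw 0/1) with nucleotide labels kept
  once per site; a panel of 2,000 genomes by 4 million SNPs fits in 8 GB.
* The simulator core is C++ (Rcpp) and draws from R's RNG, so a single
  `set.seed()` makes entire runs reproducible. `run_design()` and the CLI
  derive independent named sub-streams (founders, loci, each replicate,
  Pool-Seq) from one master seed: changing coverage never perturbs the
  trajectories.
* Coordinates are 1-based for sites, recombination windows are 0-based
  half-open, so 100-kb tilings are exact; all alleles are reported on the
  forward strand.
* p-values are floored at the smallest positive double so downstream code
  can always take logs.

## Default problem sizes

The package defaults describe a deliberately scaled-down single chromosome
(1 Mb at $\theta = 0.005$) so that examples and the test suite run on a
laptop; the simulator itself handles the full-genome regime (tested with
$10^5$ sites, $N=1000$, 60 generations, 3 replicates in well under five
minutes, and sized for millions of sites). The design-response checks in the
test suite use a 5-Mb chromosome carrying a 50-cM female map — the genetic
length of a major *Drosophila* autosome arm — because a scaled chromosome
must preserve map length, not per-base rate: at a literal 2 cM/Mb a 5-Mb
genome would be one low-recombination block, a regime in which linked false
positives swamp the design signal and which genome-scale studies mask out.
They likewise use weak selection ($s = 0.05$), the regime in which duration,
replication and census size matter most; strong selection saturates small
genomes early, compressing the differences between designs.

## Known limitations

* No epistasis, no sexually antagonistic or frequency-dependent selection,
  no quantitative-trait model; no separate sexes, overlapping generations,
  migration or variable census size.
* Founder panels lack coalescent LD (see above); conclusions about LD decay
  *within* the founder panel should use imported haplotypes.
* The CMH layer tests each SNP marginally; time-series statistics are out of
  scope.
* Negative `s` is accepted for generality but the package's validation
  targets beneficial-allele scans.
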