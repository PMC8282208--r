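---
title: "Statistical methods behind radpopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind radpopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radpopgen)
```

# Scope and data model

radpopgen analyses diploid SNP genotype catalogs of the kind produced by
reduced-representation sequencing (RAD-seq / ddRAD-seq) of structured
populations — for example, clonally propagated crop varieties genotyped
against a single reference cultivar. The data model has two levels:

* **RAD loci**: fixed-length genomic fragments (150 bp by default) that are
  either sequenced in an individual or not. Missingness is therefore
  *locus-level*: if a restriction-site mutation causes allele dropout, every
  SNP on that locus is missing together in that individual. The
  `genotype_matrix()` constructor enforces this invariant and rejects
  catalogs with partially missing loci.
* **SNP sites**: positions within a locus (`column` 0–149) with a reference
  allele and one or more alternative alleles. Genotypes are unordered allele
  pairs; calls outside `{ref, alt}` are rejected.

Individuals are assigned to named sub-populations by a *population map*,
either varietal (many groups) or a two-group phenotype contrast
(e.g. disease-resistant vs susceptible accessions).

# Per-site statistics

For one population at one site, let $N$ be the number of individuals with
the locus called, $n = 2N$ the number of sampled alleles, and $p_i$ the
sample frequency of allele $i$. `site_stats()` reports:

* **Observed heterozygosity** $H_{obs}$: fraction of called individuals
  that are heterozygous; $Hom_{obs} = 1 - H_{obs}$.
* **Expected heterozygosity** $H_{exp} = 1 - \sum_i p_i^2$ (general
  multi-allelic form); $Hom_{exp} = 1 - H_{exp}$.
* **Nucleotide diversity** $\pi = \frac{n}{n-1} H_{exp}$: the unbiased,
  sample-size-corrected form, identical to the mean pairwise difference
  over all $\binom{n}{2}$ allele pairs (this identity is tested by brute
  force for every configuration with $N \le 5$).
* **Inbreeding coefficient** $F_{IS} = (\pi - H_{obs})/\pi$, defined as 0
  when $\pi = 0$. $F_{IS} = 1$ exactly when a polymorphic site has no
  heterozygotes; negative values indicate heterozygote excess (bounded
  below by $-1$ only in the infinite-sample limit; with the $\pi$
  denominator a two-individual site of two heterozygotes gives $-0.5$).

Two allele-frequency columns are reported because they answer different
questions: `p_ref` is the frequency of the reference nucleotide (the
convention used in per-site catalog report tables, where it can fall below
0.5), and `p_major` is the within-population major-allele frequency (the
quantity averaged in population summaries). Ties in the major allele are
broken alphabetically by nucleotide so that results are deterministic.

`N` is always the per-site *called* count, never the nominal population
size; with RAD dropout the two routinely differ.

## Population summaries and the heterozygosity deviation test

`population_summary()` averages the per-site statistics over a site set —
by default the *variant* sites, i.e. those with at least two alleles
observed in the whole metapopulation (an `all`-sites mode exists).
Deviation of mean observed from mean expected heterozygosity is scored
with

$$\chi^2 = N \left[ \frac{(H_{obs}-H_{exp})^2}{H_{exp}} +
  \frac{(Hom_{obs}-Hom_{exp})^2}{Hom_{exp}} \right]$$

on 1 degree of freedom, with the p-value bucketed as `>0.9`, `>0.5` or
`<=0.5`. When $H_{exp} \in \{0, 1\}$ the statistic is undefined; the
function returns 0 with a `degenerate` flag and a warning rather than
dividing by zero. Note this is a mean-level screening statistic, not a
per-locus exact Hardy–Weinberg test (deliberately out of scope).

# Private and common alleles

Classification (`classify_alleles()`) is by carrier-population count over
called individuals:

* **private**: a non-reference allele observed (≥ 1 copy) in exactly one
  sub-population;
* **common**: observed in two or more sub-populations.

Every observed non-reference allele receives exactly one call — the two
categories partition the observed alleles, a law the test suite checks
against exhaustive enumeration. Two consequences of the definition worth
keeping in mind: merging sub-populations can only shrink the private set
(tested as a monotonicity property), and removing individuals can remove
an allele from the catalog but never convert a common allele into one
"absent everywhere".

`diagnostic_filter()` keeps the private alleles usable as variety markers:
those whose carrier population is uniformly homozygous for the allele
(`fixed_homozygous`) or uniformly heterozygous (`all_heterozygous`),
evaluated over called members only. `universal_locus_filter()` restricts
calls to loci sequenced in at least a chosen fraction of all individuals
(default 1.0, i.e. loci present in every accession).

## Two-group contrast scan

For a resistant/susceptible style contrast, `group_contrast()` reports
alleles that are absent in one group and frequent in the other. The
default criterion is the **alternative-allele frequency among called
alleles strictly exceeding the threshold** (default 0.5). Two alternative
criteria are provided as switches: `carrier-nominal` (carriers over the
nominal group size, inclusive $\ge$) and `carrier-called` (carriers over
called individuals). The alt-frequency criterion is the default because
it is the one under which a low-coverage locus carried by a minority of
the group (e.g. 3 homozygous carriers among 8 members, but 6 of 10 called
alleles) still registers — frequency among called alleles is also the
quantity that per-site statistics are built from. Group absence is exact:
a single copy in the other group disqualifies the site.

# Differentiation

`pairwise_fst()` computes pairwise $F_{ST}$ between all sub-populations:

* **weir-cockerham** (default): the two-population variance-components
  estimator; per-site, per-allele components $a$ (among populations), $b$
  (among individuals) and $c$ (within individuals) are summed over all
  shared sites and alleles, and $F_{ST} = \sum a / \sum (a+b+c)$
  (ratio-of-sums, which is far less biased than averaging per-site
  ratios).
* **hudson**: the between/within nucleotide-diversity estimator for
  biallelic sites, also ratio-of-sums.

A pair contributes a site only if both populations have at least
`min_called` (default 2) individuals called there; a pair with no shared
sites yields `NA`, never a silent 0. Limiting cases are tested: identical
allele frequencies give estimates near 0 (the estimators are unbiased
around zero and can be slightly negative), fixed differences give exactly
1, and simulated island-model divergence is recovered within Monte-Carlo
tolerance. `allele_sharing_dist()` supplies a simple identity-by-state
distance between individuals for clustering.

# The simulator

`simulate_genotypes()` generates catalogs with known truth for validation.
Its defaults are study-shaped: nine varietal sub-populations of sizes
2–8 (33 accessions), 500 loci of 150 bp placed on eleven chromosomes
proportionally to length, a Poisson(2) number of SNPs per locus
(truncated at 10, zero-SNP loci are monomorphic), and ancestral
alternative-allele frequencies drawn from a Beta(0.8, 3.2) prior —
right-skewed with mean 0.2, reflecting the preponderance of
low-frequency variants in a catalog called against one cultivar's
reference.

Per population, genotypes at a site with alternative frequency $q$ and
inbreeding coefficient $F$ are drawn with probabilities
$\{p^2 + Fpq,\; 2pq(1-F),\; q^2 + Fpq\}$; for negative $F$ the value is
truncated at $\max(F, -p/q, -q/p)$ so the probabilities stay valid.
Between-population divergence uses the Balding–Nichols construction:
population frequencies are drawn from
$\mathrm{Beta}\!\left(q\frac{1-d}{d},\,(1-q)\frac{1-d}{d}\right)$, so the
`divergence` parameter $d$ is the expected $F_{ST}$.

Design choices worth noting:

* **Per-locus deterministic substreams.** Each locus derives its RNG seed
  from the run seed and locus index, so the same seed gives byte-identical
  catalogs and *extending* `n_loci` preserves all earlier loci unchanged.
* **Planted truth.** `n_private` reserves loci that carry a private allele
  for a chosen population at their first site (with profile
  `fixed_homozygous`, `all_heterozygous` or `mixed`) and are monomorphic
  reference elsewhere, enabling exact recall/precision accounting against
  `truth$private_alleles`. Drawn ancestral frequencies are recorded in
  `truth$site_freqs` so distributional tests compare against what was
  actually drawn, not the prior plus binomial noise.
* **Locus-level dropout.** `locus_dropout_rate` removes whole loci per
  individual, mirroring restriction-site allele dropout.

Scope limits: no linkage or recombination model (loci are independent),
no sequencing-error or genotype-uncertainty model, no selection, and
divergence is exchangeable across populations (no phylogeny). The
simulator validates estimators; it does not emulate a sequencer.

# Reporting pipeline

`rp_run()` (and the `inst/cli/radpopgen` script) exposes subcommands
`simulate`, `stats`, `private-alleles`, `common-alleles`,
`group-contrast`, `fst` and `density`. All outputs are UTF-8 TSV in the
catalog-table layout (`locus_id chr bp col pop p_nuc q_nuc n p obs_het
obs_hom exp_het exp_hom pi fis`), plus a JSON manifest recording inputs,
parameters and result counts. Statistics are kept at full precision
internally and rounded only at serialisation (default 4 decimals).
Re-running a subcommand with identical inputs produces byte-identical
files. VCF input is parsed with the vcfR package; locus structure is
taken from `LOCUS`/`COL`/`LSTART` INFO keys when present, otherwise sites
within 150 bp are grouped into a locus. The `density` subcommand tabulates
loci and SNPs per chromosome with loci-per-Mb densities, reporting both
the mean of per-chromosome densities and the overall loci-per-Mb ratio
(the two differ whenever chromosome lengths differ).

# Worked example

```{r example}
cfg <- sim_config(seed = 42, n_loci = 200, f_is = 0.05,
                  locus_dropout_rate = 0.1,
                  n_private = c(Allahverdi = 0, "Çakıldak" = 0,
                                "Karafındık" = 0, Mincane = 0, Palaz = 2,
                                "Sarıfındık" = 0, Sivri = 0, Tombul = 0,
                                Yomra = 0))
res <- simulate_genotypes(cfg)
summary_tab <- population_summary(res$genotypes, res$popmap)
summary_tab

calls <- classify_alleles(res$genotypes, res$popmap)
table(calls$category)
diagnostic_filter(calls, res$genotypes, res$popmap)[,
  c("locus_id", "allele", "carrier_populations", "diagnostic_class")]
```

# Limitations

* Statistics assume diploid, biallelic-to-few-allele SNP data called
  against a single reference; there is no support for polyploids or
  genotype likelihoods.
* The $\chi^2$ screening statistic operates on population means and should
  not be read as a per-locus Hardy–Weinberg test.
* $F_{ST}$ is computed per population pair independently; no global
  multi-population estimator or significance testing is provided.
* Small nominal sample sizes (2–8 individuals per variety) make every
  per-population statistic high-variance; the package reports exactly
  what the data support and leaves significance interpretation to the
  analyst.
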