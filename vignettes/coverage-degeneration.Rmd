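---
title: "Diagnosing Y-chromosome degeneration from coverage: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing Y-chromosome degeneration from coverage: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ydegen)
```

This vignette is the package's own account of its science: the models each
stage assumes, the tunable parameters and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and the
design decisions taken where the methodology was genuinely open.

## 1. The coverage model of degeneration

In an XY system whose Y has degenerated, a male carries one copy of an
X-linked gene and a female two, while autosomal genes are diploid in both
sexes. If sequencing depth per gene is proportional to copy number, the
expected per-gene depth is `per-copy depth x copies x library factor`. Two
nuisance factors stand between that expectation and raw data: individuals
are sequenced to different total depths, and populations may be sequenced
on different machines or runs. The package deals with the first by
normalizing every individual by its own autosomal baseline, and with the
second by computing ratios within each population before pooling.

**Normalization statistic.** Each individual's per-gene depths are divided
by that individual's *median* depth over autosomal genes, making the
autosomal baseline exactly 1. The median (rather than the mean) is robust
to the long right tail of repetitive or collapsed genes and to sex-linked
copy-number itself; a mean variant is exposed (`stat = "mean"` in
`normalize_dataset()`) because the choice is not forced by theory.
Normalization is idempotent, and any per-individual rescaling of raw
depths cancels exactly.

**Ratio pooling.** M/F, M/A and F/A ratios are computed per population
from the sex-specific means of normalized coverage, and the pooled scope
is the *equal-weight mean of per-population ratios* over the populations
where the ratio is defined. Equal weighting prevents one deeply sampled
population from dominating, at the cost of giving small populations equal
say; an `all_individuals` pooling mode is available when that trade-off is
wrong for the data at hand. A gene whose female mean is 0 yields a no-call
(`NA`) rather than an infinite ratio: no pseudo-counts are added anywhere.

**Quality filters.** Genes are *flagged*, never deleted, with
machine-readable reasons, and downstream stages skip flagged genes:

| flag | rule | default |
|---|---|---|
| `missing_in_some_individuals` | any individual lacks a value | on |
| `low_mean_count` | mean depth per individual does not exceed the minimum | 10 |
| `extreme_high_count` | mean exceeds a multiple of the median gene mean | 20x |
| `low_female_coverage` | pooled female normalized coverage too low | 0.1 |

The first two cuts mirror standard targeted-genotyping inclusion rules
(every individual genotyped; mean count above 10). The high-count
multiplier and the female-coverage floor formalize exclusions that are
usually described only qualitatively (repetitive sequence; genes whose
ratio is meaningless because females have essentially no signal); 20x and
0.1 are our choices and are config-exposed.

## 2. Sexing from X/A ratios

An individual's X/A ratio is its median normalized coverage over candidate
X-linked genes — near 0.5 in males and 1 in females when most of the X is
hemizygous in males. The classifier is a fixed pair of thresholds: male
at or below 0.70, female at or above 0.85, unassigned between. The two
clusters in real data are widely separated, so any cut in the gap works;
0.70 echoes the observation that autosomal ratio distributions contain
almost no values below 0.7, and the asymmetric gap (0.70–0.85) reflects
that the male cluster is the one whose tail matters for
misclassification. A 1-D two-means split (`method = "kmeans"`) is provided
for cohorts whose clusters sit elsewhere (e.g. different ploidy or heavy
GC bias). Unassigned individuals are excluded from all sexed scopes
downstream, mirroring the practice of analysing only reliably sexed
samples. At least 10 usable X-linked genes are required — below that the
median is too noisy for a confident call.

## 3. Gene classes, regions, and the PAR boundary

The biologically anchored reference values are 0.5 (hemizygous), 1
(diploid) and a duplication cut at M/F > 1.4. The class windows —
hemizygous 0.3–0.7, diploid 0.8–1.2, both closed — formalize "close to
0.5" and "close to 1"; ratios between windows are `ambiguous`, undefined
ratios are `no-call`. The windows partition `[0, Inf)` with no overlap,
and the boundary cases (0.7, 0.8, 1.2, 1.4) are tested explicitly.

**Region contrasts** use a two-sided Mann–Whitney test. Ratio data are
bounded, skewed and occasionally tied, so a rank test is safer than a
t-test. For `min(n) <= 8` the p-value is computed by full enumeration of
rank assignments using midranks, which stays exact under ties (the
standard exact algorithm refuses ties); enumeration is capped at
5 x 10^5 assignments, beyond which the normal approximation with
continuity correction takes over.

**Cross-population consistency.** True degeneration produces the same
hemizygous signal in every population, whereas mapping artefacts and
population-private duplications do not. `consistency_table()` records, per
gene and class, the pattern of populations making the call — the
tabulation behind an upset plot — and counts genes called in all
populations.

**PAR boundary.** The expected M/F profile along the chromosome is a step
function: 0.5 over the degenerated region, 1 over the PAR. The boundary is
the least-squares change-point against those *fixed* levels, which is the
maximum-likelihood change-point under Gaussian noise and exactly the
biological hypothesis being tested; a free-level variant (segment means)
is provided for QC, e.g. to notice when the proximal level is nowhere near
0.5. Ties are broken toward the most distal position, so in the degenerate
all-PAR case the boundary lands at 0 rather than anywhere in the interior.
Genes are ordered by annotation start, ties by gene id.

## 4. Divergence estimation and dating

Nei–Gojobori (1986) counting with equal weighting of mutational pathways
is used because it is assumption-light and matches standard
desktop-software behaviour. Two stop-codon details matter:

* *Site counts*: single-nucleotide changes that create a stop are excluded
  from the denominator at that position (so e.g. TGG has 0 synonymous
  sites even though one of its nine neighbours is a stop).
* *Difference counts*: for codon pairs differing at 2–3 positions, the
  2 or 6 substitution orderings are averaged; orderings that pass through
  a stop codon are dropped and the remaining weights renormalized. In the
  rare case where *every* ordering crosses a stop, each differing position
  contributes by majority vote of its per-position synonymy evaluated in
  both codon contexts (ties split 0.5/0.5), preserving the invariant that
  pathway-averaged Sd + Nd equals the nucleotide difference count.

*Complete deletion* is applied at codon granularity: any codon column with
a gap or ambiguity in either sequence — or a stop codon, e.g. a terminal
stop — is dropped entirely, and all measures (including the all-sites K)
are computed over the retained columns. Whether per-site or per-codon
deletion is used for the all-sites measure is a genuinely open convention;
per-codon keeps every statistic on the same denominator and is what we
use.

The Jukes–Cantor correction `d = -(3/4) ln(1 - 4p/3)` handles multiple
hits; `p >= 0.75` is a hard saturation error naming the offending gene,
not a silent `NA`. Confidence intervals are percentile bootstrap over
codons (default 1000 replicates, seed required), implemented as
multinomial column weights — the same resampling distribution as drawing
codons with replacement, but a single matrix multiply. Replicates that hit
saturation are excluded and counted. An analytic variance would be
faster, but the bootstrap makes no distributional assumption and is
reproducible from a seed.

Dating treats Ks as *total* (two-branch) divergence, so the time back to
the common ancestor is `t = Ks / (2 mu)`; with Ks = 0.054 and
mu = 1e-9 per site per generation this gives 27 million generations. The
per-gene neutrality flag is set when the bootstrap CI of Ka/Ks contains 1.

## 5. Sex-linkage inference from genotypes

**Progeny sexing.** At a marker whose Y copy is lost, a son shows exactly
one allele (a dam allele) and a daughter two (dam + paternal X). A progeny
is called male only when *every* informative hemizygous-mode marker shows
a single dam allele, female when at least one shows two alleles and none
shows the male pattern, and `unassigned` with a conflict note when both
kinds of evidence occur. The conflict rule is deliberately conservative: a
daughter whose paternal X happens to carry a dam allele produces exactly
this mixed pattern, and we report rather than guess. A single allele
absent from the dam is flagged `non_mendelian` and excluded.

**Paternity.** Each daughter's non-dam allele per marker is her paternal X
allele; daughters are grouped by *compatibility* of their multi-marker
paternal haplotypes (transitive closure; no likelihood model), and the
number of groups is the minimum sire count. Exact-identity grouping
matches how multi-sire broods are resolved by hand; it can undercount
sires sharing haplotypes.

**Marker classes.** With the sire X (from daughters) and Y (the other
sire allele, or the sons' modal paternal allele) in hand, a recombinant is
a son carrying the sire-X allele or a daughter carrying the sire-Y allele.
`complete_sex_linked` requires zero recombinants among at least 5
informative progeny (below 5 the call is `uninformative` — a zero out of
three says little); `partial_sex_linked` covers recombinant fractions in
(0, 0.3); fractions at or above 0.3 fall to an exact binomial test against
0.5, with non-rejection giving `autosomal_like`. The 0.3 cut and the 5
progeny minimum are our formalization of what is usually a verbal
classification. Microsatellite alleles differing by 2 bp or less trigger
a *warning note* — never a silent merge — because such pairs are easy to
mis-score; and an all-homozygous male sample is annotated as also being
consistent with common null alleles.

**Population samples** complement pedigrees: females fixed for one allele
while heterozygous males carry male-specific alleles indicates an X-fixed
allele with a polymorphic, non-recombining Y
(`complete_sex_linked_Y_polymorphic`); an overall-polymorphic marker at
which no male is ever heterozygous is consistent with male hemizygosity
(`hemizygous_consistent`); males heterozygous for female-shared alleles
indicate ongoing recombination (`partial_sex_linked_like`). Male-specific
alleles found with fewer than 10 sampled females are flagged
low-confidence — with a handful of females, "male-specific" is usually
just "rare". Family and population classes are reported side by side and
never forced to agree.

## 6. What the simulator does and does not emulate

`simulate_coverage_dataset()` draws per-gene mean depths directly —
Poisson, negative-binomial (mean/dispersion parameterization; Poisson is
the infinite-dispersion limit) or deterministic for exactness tests — with
copy numbers 1/2/3 by sex and class, per-population depth multipliers,
and misassembled genes whose copy number varies independently of sex.
Simulating depths rather than reads is deliberate: the analysis consumes
depths, and read-level effects (mapping bias, GC bias, mappability) are
upstream of this package. Those effects are real — GC-rich PAR genes can
map poorly in both sexes, depressing M/A and F/A without touching M/F — so
passing tests demonstrate correctness of the *inference given the depth
model*, not robustness to mapping artefacts. Per-population depth
multipliers are our abstraction of between-population sequencing
differences.

`simulate_family()` specifies progeny counts per sire and sex exactly
(they are design variables, not random), draws dam alleles uniformly, and
swaps paternal X/Y alleles with a per-marker recombination probability.

`simulate_diverged_cds()` inverts the Jukes–Cantor map to an expected
number of synonymous and nonsynonymous substitution events, then places
them at random eligible positions alternating between the two branches,
rejecting changes that create stops. Each nucleotide site receives at most
one substitution, and untouched codons are preferred (substitutions
sharing a codon entangle the pathway decomposition), so the realized
difference proportion matches the JC-inverted target in expectation and
the estimator's JC correction recovers the target divergence; at extreme
targets, codon sharing becomes unavoidable and recovery degrades
gracefully. Targets are limited to `[0, 0.7)` — beyond that the observed
proportion approaches the JC saturation bound of 0.75.

All randomness flows from one integer seed through named per-operation
streams, so adding draws to one stage never perturbs another.

## 7. Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive base pairs throughout.
* Zero female coverage gives a no-call; all-zero autosomal coverage for an
  individual is a hard error ("cannot normalize").
* `classify_gene` boundary cases: 0.3 and 0.7 are hemizygous, 0.8 and 1.2
  diploid, 1.4 ambiguous, strictly above 1.4 duplicated.
* `detect_boundary` needs at least 4 usable genes; on noise-free step data
  it recovers every boundary position exactly, including both extremes.
* Bootstrap CIs need at least 10 retained codons and 100 replicates;
  degenerate identical pairs give the CI (0, 0).
* Pipeline problem sizes in the bundled tests (hundreds of genes, tens of
  individuals, 100-replicate simulation studies) were chosen to make the
  statistical checks sharp at desk scale; all defaults scale to
  genome-sized inputs unchanged.

## 8. Known limitations

* Coverage inference assumes depth proportional to copy number;
  systematic mapping bias between sexes (e.g. reads from a diverged Y
  copy failing to map) shifts M/F ratios in ways the model cannot see.
* Equal-weight pooling over populations is sensitive to a single
  aberrant small population.
* The NG86/JC pipeline is appropriate for closely related sequences
  (Ks below ~0.2); for deeper divergences a codon-model maximum
  likelihood estimator should replace it.
* Paternity clustering by haplotype compatibility gives a *minimum* sire
  count.
* Raw divergence includes ancestral polymorphism, so `ks_to_generations`
  overestimates the split time by an unknown margin when ancestral
  diversity was substantial; no net-divergence correction is attempted
  because it needs diversity estimates the data typically lack.
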