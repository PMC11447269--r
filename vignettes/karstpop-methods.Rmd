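---
title: "karstpop: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{karstpop: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem this package addresses

Critically endangered populations with a few dozen surviving individuals —
the motivating case is a karst-restricted langur with fewer than 100
animals — leave characteristic marks on their genomes: depressed
nucleotide diversity, long runs of homozygosity (ROH), elevated
inbreeding coefficients, and an excess of deleterious alleles exposed in
homozygous state. With only a handful of sequenced genomes per
population, every statistic must be squeezed out of a single multi-sample
VCF against two or three related background populations and one outgroup
individual. `karstpop` implements that analysis chain as a reusable,
tested library: diversity and heterozygosity profiling, PLINK-style ROH
detection with excess-homozygosity F, GERP-based masked/realized genetic
load with snpEff impact categories, ABBA-BABA D-statistics, a
three-method selective-sweep consensus, private non-synonymous variant
screens and KING kinship classification.

Because the real data for such studies are typically access-restricted
and far too large for continuous testing, the package is built around a
synthetic-data generator whose outputs carry exact ground truth. Every
estimator in the package is exercised against that truth in the test
suite; this vignette records the models, the tunable parameters and the
design decisions that were genuinely open.

# Data model

All readers produce three aligned objects: a `variant_table` (chrom, pos,
ref, alt, ancestral, GERP score, most severe effect annotation, with the
full annotation set attached), a `genotype_matrix` (sites x individuals,
codes 0/1/2/NA, plus per-individual callable lengths in bp) and a popmap
(individual, population, role = target/background/outgroup). Coordinates
are 1-based inclusive throughout, the native convention of VCF, GFF3 and
IRanges; this deliberately deviates from a half-open internal convention
because the package leans on GenomicRanges for all interval arithmetic
and a second convention would invite off-by-one bugs at every boundary.

Site-level filters mirror the upstream genotyping practice for this kind
of study: indels and multi-allelic records are excluded and a site is
dropped when more than 10% of genotypes are missing. GATK-style hard
filters act upstream of this package's inputs and are intentionally not
re-implemented.

Effect annotations are parsed from a pipe-delimited `ANN` field
(`effect|impact|detail|gene|transcript`). The effect-term to coding-class
map is fixed, versioned data (`coding_class_map()`, version 1):
missense/stop-gained/stop-lost/start-lost are non-synonymous,
synonymous/stop-retained are synonymous, everything else is `other`.
Multi-effect sites are represented in tallies by their most severe impact
(HIGH > MODERATE > LOW > MODIFIER); all annotations are retained for
gene-level screens.

# The synthetic-data generator

The generator is genealogy-free. Each site draws a derived-allele
frequency at the ingroup root from Beta(0.5, 2) — a skew toward rare
derived alleles that loosely mimics a neutral frequency spectrum — and
drifts it along the fixed population tree
`((target, (backgroundA, backgroundB)), outgroup)` with Balding–Nichols
steps. The drift parameters (target 0.20; internal split 0.05; each
background branch 0.15) were chosen once to reflect species that diverged
roughly a million years ago with small effective sizes, i.e. strong but
not saturating differentiation; they are configuration, not tuning knobs,
and the tests never adjust them. Individuals are drawn at Hardy–Weinberg
equilibrium within populations as two independent haplotypes per site, so
phased output is available by construction. The single outgroup
individual is homozygous ancestral at a configurable fraction (default
0.98, contract ≥ 0.95) of sites and homozygous derived at the rest —
never heterozygous — which makes outgroup polarization exact except where
the generator deliberately plants exceptions.

Structured signals are planted on top:

* **Runs of homozygosity.** For a target fraction f of the genome, 200-kb
  tiles are sampled uniformly and haplotype 1 is copied over haplotype 2
  inside them; adjacent tiles merge into longer intervals, so every
  planted interval is at least 200 kb and the total is within one tile of
  f x genome. `target_f_roh = 1` homogenizes whole chromosomes.
* **Sweeps.** Inside a region, one haplotype is copied into k − 1 others
  with k = round(n·sqrt(1 − d)) for diversity-reduction factor d. The
  fraction of haplotype pairs left distinct — and hence regional π —
  then scales by ≈ d. (Copying into a raw fraction (1 − d) of haplotypes,
  the more obvious rule, reduces π by 1 − (1 − d)² ≈ 2d, which
  contradicts the intended "π falls to d of its pre-sweep value"
  semantics; the square-root calibration restores them.) Every sweep
  region is guaranteed to host at least one fully contained gene, so
  "the planted sweep gene" is always well defined for recovery tests.
* **Migration.** With migration m, each target allele draw comes from the
  backgroundA frequency with probability m, creating the derived-allele
  sharing that the D-statistic detects. Migration is genome-wide in this
  model, so combining it with sweep regions is refused (confounded
  truth).
* **Annotations.** Genes are placed on a non-overlapping grid with evenly
  spaced exons whose lengths are multiples of 3; each coding SNP gets a
  codon context with the reading frame tracked from the CDS start, and
  its effect term is derived from the actual codon change, so
  `coding_class` is consistent with a codon-table oracle by construction.
* **Screen truth.** A configurable number of non-synonymous sites are
  forced homozygous-alternate in all target individuals with background
  frequency 0 (private) or ≈ 6% (fixed tier); one planted private site is
  converted into a genuine premature stop codon (TAT→TAA). The truth file
  then *re-scans* the emitted genotypes, so sites that qualify by chance
  are part of the recorded truth rather than test noise.
* **Conservation scores.** Neutral sites are uniform on [−2, 3.9] and
  deleterious ones on [4, 8], so the GERP ≥ 4 deleteriousness threshold
  separates the mixture exactly by construction.

What the generator does **not** emulate: linkage disequilibrium between
sites (sites are independent given frequencies, except inside planted
ROH/sweep intervals), recombination maps, mutation-rate heterogeneity,
sequencing error, reference bias, and realistic gene structure
(UTRs, splice sites, strand). A green test therefore establishes that an
estimator implements its definition correctly and recovers planted
signals at realistic effect sizes — not that it is robust to every
artifact of real resequencing data.

All randomness flows from the single config seed through `with_seed()`,
which saves and restores the caller's RNG state; the same config is
byte-identical across runs, and `data.vcf` is written uncompressed so
that byte-level determinism is not broken by compression-header
timestamps (readers are gzip-aware regardless).

# Methods and their parameters

## Diversity

Per-site π uses the unbiased frequency form 2j(n−j)/(n(n−1)), which
equals the mean pairwise difference over haplotypes; the window statistic
divides the summed site π by the *fixed* window size (50 kb default),
matching the vcftools `--window-pi` convention, with a `callable`
denominator available behind a flag. Heterozygosity is reported per
1000 bp of callable length; coding/non-coding strata assume uniform
callability and split the callable length proportionally to the CDS share
of the genome, because per-stratum callability tracks are rarely
available. An individual "has" a variant for the NS/S ratio when it
carries at least one alternate allele (het or hom); the ratio is
undefined (NA, flagged) when the synonymous count is zero.

## Runs of homozygosity and F

The ROH caller follows the PLINK rule set: 20-SNP windows sliding one SNP
at a time, a window "homozygous" with at most one heterozygote, per-SNP
hit rate ≥ 0.05 over the windows covering it, maximal in-run stretches
split at gaps > 100 kb, and segments kept at ≥ 50 SNPs, ≥ 100 kb and
≥ 1 SNP per 50 kb. Two choices deserve note. First, the quoted allowance
of 50 missing calls per 20-SNP window is internally inconsistent; the
effective cap is min(50, window size), i.e. missingness never breaks a
window, and the quoted value is kept in the parameter object for
provenance. Second, segment boundaries are the first/last in-run SNP
positions (not window edges), the reference tool's convention. The caller
is verified segment-identical against a brute-force oracle that applies
the rules literally.

The inbreeding coefficient is F = (O − E)/(N − E) per individual over its
called sites, with E = Σ(1 − 2p(1−p)·n/(n−1)) using sample allele
frequencies and the small-sample correction — the quoted tool's method.
The gene-overlap fraction counts genes with ≥ 50% of their span inside
segments; the threshold is exposed because the source convention is
unstated.

## Genetic load

Sites are polarized by the outgroup (ancestral = the allele carried
homozygously by all called outgroup individuals; heterozygous, missing or
polymorphic outgroups exclude the site, counted and logged). After
removing sites monomorphic across the three ingroup species, masked load
is the sum of GERP scores of deleterious (GERP ≥ 4) derived alleles in
heterozygous genotypes and realized load the same sum for homozygous
derived genotypes, each divided by the individual's called genotypes.
The two quoted denominators ("called genotypes" vs "all called sites")
are treated as the same quantity by default — the per-individual count of
non-missing genotypes over the analyzed table — with a
`deleterious_only` denominator mode available; nothing in the source
material indicates the denominators actually differed. Derived-allele
frequency is not capped. At every deleterious derived site an individual
contributes to exactly one of masked/realized/neither, and raising the
threshold is monotonically load-decreasing; both properties are tested.

Impact-category proportions divide carrier counts (het-or-hom in mode
`all`, hom-alt in mode `homozygous_only`) by called genotypes. Population
comparisons use the classic one-way ANOVA F with pairwise Welch t
contrasts, unadjusted by default (matching the practice of reporting raw
pairwise p values) with Benjamini–Hochberg behind a flag.

## D-statistics

Pattern weights are frequency-weighted (population mode):
abba = (1−p1)p2p3(1−pO), baba = p1(1−p2)p3(1−pO) over derived-allele
frequencies polarized by the outgroup (which therefore has pO = 0 at
informative sites). Significance uses a weighted (Busing-style) delete-one
block jackknife with blocks of 5 Mb by default (configurable; at least 10
non-empty blocks are required, otherwise the error instructs a smaller
block size), Z = D/se. When every block is identical the variance
collapses; a floating-point residue below machine epsilon is clamped to
zero and Z flagged infinite. The X²-style aggregation across quartets
reported in the motivating study is not reproduced — its exact
construction is unspecified — and per-quartet Z is the primary inference;
a sum of Z² across independent quartets can be formed by the caller.

## Selection consensus

* θπ log-ratio: sliding 40 kb / 20 kb windows; value = ln(π_A/π_B) with
  the candidate population in the denominator, so sweeps in the candidate
  give large positive values; windows with < 20 variable sites (union of
  both populations) are excluded; outliers are the top 5% of retained
  windows, threshold inclusive; π_B = 0 yields +Inf, which is an outlier
  by construction.
* XP-EHH: EHH at distance x from a core SNP is the fraction of haplotype
  pairs identical at all SNPs beyond the core up to x, each direction
  separately, with EHH(core) = 1 by definition (the core's own alleles
  are not conditioned on — the unstandardized cross-population variant).
  iHH integrates the decay by trapezoids until the first point below the
  0.05 cutoff (that bounding trapezoid included, so identical populations
  get identical iHH and raw XP-EHH exactly 0). Raw scores
  ln(iHH_candidate/iHH_background) are computed at every SNP core
  (compiled code; cores where either iHH is 0 are excluded), Z-transformed
  genome-wide, aggregated to the same 40-kb window grid by the maximum Z,
  and the top 5% of windows (inclusive) are outliers. Per-SNP outlier
  calling was rejected because single outlier SNPs scattered at 5% density
  flag far too many genes.
* Ka/Ks: Nei–Gojobori (1986) counting with Jukes–Cantor correction
  (d = −¾ ln(1 − 4p/3)); synonymous site fractions from the standard
  codon table averaged over both sequences, multi-difference codons
  averaged over stop-avoiding mutational paths, mutations to stop codons
  counted as non-synonymous, p ≥ 0.75 flagged as saturated, Ks = 0 makes
  the ratio undefined. A richer codon model (transition/transversion and
  codon-frequency aware) was considered and rejected: the consensus rule
  dominates sweep calls, and the estimator is pluggable. On synthetic
  data, per-gene pseudo-CDS sequences are built from each population's
  majority alleles over coding variants (`kaks_gene_flags()`); real-data
  Ka/Ks requires externally supplied CDS alignments.

A gene is a consensus sweep iff at least two methods flag it; windows and
outlier SNPs map to genes by any-bp overlap (parameterized). XP-EHH
requires phase: the reader recovers haplotypes from fully phased VCFs,
and unphased input must go through `pseudo_phase()`, which randomizes
heterozygote phase within individuals and warns loudly, since it
attenuates haplotype statistics.

## Screens and kinship

A screen hit must (1) be non-synonymous by the most severe annotation,
(2) be homozygous-alternate in every called target individual (any
uncalled target makes the site ineligible), and (3) have background
alternate-allele frequency exactly 0 (private) or at most the ceiling
(fixed tier; the study's observed maximum 28.95% is the default and the
boundary is inclusive). The stop-codon screen additionally restricts to
`stop_gained` terms and an optional candidate gene list.

Kinship is the within-population KING estimator
φ = (N_het,het − 2·N_opposing-hom)/(N_het(i) + N_het(j)). Degree bins
follow the standard thresholds with lower-closed intervals
(φ = 0.354 and 0.177 fall in 1st degree, 0.0884 in 2nd), except that
φ ≤ 0.0442 is classified unrelated, resolving the overlapping printed
interval endpoints in favor of the explicit "≤ 0.0442 → unrelated" rule.
Pairs with fewer than 100 jointly called sites are flagged low-confidence.

# Numerical and testing choices

Window sums conserve the genome-wide total to 1e-12 by construction
(plain summation, asserted in tests). Truth loads are computed by the
generator with separate straight-line code in the same site order as the
estimator, so the equality test is exact (bit-identical), not
tolerance-based. Stochastic acceptance criteria (ROH recovery, load
contrast, D calibration and power, sweep recovery) run under fixed seed
sets chosen a priori, which makes them deterministic; the D-statistic
power criterion uses ~60k-site genomes — comfortably above its stated
20,000-informative-site floor — because the criterion fixes migration at
0.1 and the per-seed Z tail at 40k sites sits too close to the 90/100
requirement for a reliable margin. Simulation sizes throughout the suite
are desk-scale (1–10 Mb genomes, 21 individuals) to keep the full run
around ten minutes on one CPU.

# Known limitations

* No linkage disequilibrium in the generator outside planted intervals;
  haplotype statistics are validated on planted structure only.
* Ka/Ks on real data needs external CDS alignments; the package only
  automates it for synthetic bundles.
* The reader keeps the first ALT allele's string for multi-allelic
  records solely so the biallelic filter can drop them; multi-allelic
  analysis is unsupported.
* `heterozygosity_rate` strata assume uniform callability across
  coding/non-coding space.
* The D-statistic X² aggregate across quartets and f-branch style local
  introgression scans are out of scope.
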