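---
title: "Models and methods behind ClonalHybrids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ClonalHybrids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ClonalHybrids analyses populations of clonal fungi in which haploid strains
occasionally fuse into stable, highly heterozygous diploid hybrids. This
vignette explains the models the package implements, the defaults it ships,
the choices made where the design was genuinely open, and what the
synthetic-data generator does and does not emulate.

## The population model

The generator assumes a **strictly clonal** species: reproduction is
mitotic, every locus shares one genealogy, and the only genetic exchange is
the rare fusion of two whole haploid genomes into an F1 diploid that never
undergoes meiosis. Concretely:

* **Lineages.** A pure-birth (Yule) genealogy is drawn over the haploid
  lineages and rescaled so that the mean pairwise path length equals the
  target `divergence` (default 0.03, i.e. 3% — the 2–4% range separating
  hybridizing lineages of the black yeasts this package models).
  A Yule process was preferred over a coalescent because the downstream
  readouts depend only on the tree being bifurcating with heterogeneous
  pairwise distances, not on a demographic interpretation.
* **Mutations.** Poisson along branches over `genomeLength` sites under
  the **infinite-sites** model: a global used-site pool guarantees every
  site mutates at most once in the whole simulated history. This keeps
  every locus biallelic, makes four-gamete and r² oracles exact, and
  matches the assumptions of the SNP-matrix consumers.
* **Hybridization events.** Each event fuses two *distinct* lineages; its
  diploid descendants accumulate private mutations at
  `postDivergence` (default 5 × 10⁻⁴, i.e. 0.05%) — two orders of
  magnitude below the between-lineage divergence, a separation of scales
  that makes event recovery well-posed. Subgenomes never recombine with
  each other (no meiosis; hybrids stay at the F1 stage). An optional
  `founderDivergence` gives each event founder private mutations; the
  default is 0, but a positive value is the only way two events on the
  *same* lineage pair can be distinguishable, since otherwise both copy
  identical parental haplotypes.
* **Depth.** Sequencing depth is negative-binomial (default dispersion
  10), not Poisson, because real short-read coverage is overdispersed.
  Values are drawn per small bin (default 100 bp) rather than per
  nucleotide: the NB dispersion abstraction is scale-free and finer tracks
  would add size without information. Planted aneuploid segments and
  deletion-LOH tracts scale the NB mean by `copy / ploidy`.
* **Assembly statistics.** Per-ploidy normal draws centred on the
  published black-yeast assembly statistics (haploid 26.52 ± 1.47 Mbp,
  9,519 ± 665 genes; diploid 49.30 ± 1.74 Mbp, 20,417 ± 1,709 genes;
  tetraploid centred on 94.67 Mbp / 46,596 genes). Core-BUSCO mean copy
  numbers are N(1.00, 0.03), N(1.70, 0.08), N(3.10, 0.20): the printed
  duplicated-BUSCO percentages have SDs dominated by a minority of poorly
  assembled genomes, which the generator deliberately does not emulate, so
  modest dispersions around the canonical 1×/1.7×/3.1× values were chosen
  a priori.

**What the generator does not emulate:** read-level errors and mapping
artefacts, selection, demography beyond constant size, genuinely
multiallelic sites, recurrent mutation, structural variation other than
whole-segment copy-number change, and assembly fragmentation. Passing
tests on synthetic data therefore demonstrate the *inferential machinery*
— they do not certify behaviour on real data with reference bias or
low-quality calls.

## Linkage disequilibrium

r² is the squared Pearson correlation of ploidy-scaled dosages over
strains typed at both loci — the genotype-correlation estimator, chosen
because field VCFs are unphased; on phased haploid data it reduces exactly
to the classical D²/(p_A(1−p_A)p_B(1−p_B)) formula (property-tested).
Loci enter the analysis when biallelic and non-singleton, with
"non-singleton" read as minor-allele carriers ≥ 2 — the natural
interpretation of "present in at least 2 genomes" for a dosage matrix.

The decay curve bins pairs at `binWidth` (default 100 bp) up to `maxDist`
(default 10,000 bp) and smooths bin means with a pair-count-weighted
tricube local mean (span = 0.2 of the distance range). A local smoother
stands in for a generalized additive model fit; the readout — the smallest
bin midpoint where the smoothed curve drops below half of its maximum —
is a threshold crossing of a slowly varying curve and is robust to the
smoother family. "Not reached" is itself the informative outcome: it is
the clonal signature.

The forward Wright–Fisher simulator provides the calibration contrast:
with `recombinationRate = 0` offspring are clonal copies and the smoothed
curve stays above half-max across the full 10 kbp; with crossovers
(Poisson per genome per generation) the crossing becomes finite.

## Ploidy classification

The three criteria (genome size, predicted genes, core-BUSCO mean copy)
are applied **jointly**: a call of 1 or 2 requires all three criteria in
the corresponding band, the tetraploid band (size ≥ 80 Mbp and genes ≥
36,000, checked first) requires both of its criteria, and any value
between bands or any mixed pattern yields `unclear`. The tetraploid
thresholds are this package's own — only a single tetraploid strain has
ever been observed, so no published band exists; the defaults sit midway
between the diploid and observed tetraploid values and are configurable.
Core BUSCOs are those present in every strain of the set, including the
strain being classified.

A known property of this rule under the published statistics: the diploid
gene-count band starts at 18,000 while diploid gene models are distributed
20,417 ± 1,709, i.e. the threshold sits only 1.4 SD below the mean. A
normal emulation therefore labels a several-percent tail of true diploids
`unclear` even when draws are truncated at ±2 SD; the acceptance suite
measures exactly this (haploid recovery is effectively perfect, diploid
recovery is not ≥ 99%). This is a property of the published band/statistic
combination, not of the implementation.

## Region trees, concordance, and event grouping

Regions are kept when every strain contributes exactly `ploidy` sequences
and no sequence exceeds the gap-fraction threshold (0.15 by default, 0.25
as the lenient variant for fragmented assemblies); the `n = 50` longest
survivors are used. Per-region trees are neighbor joining on p-distances
with pairwise gap deletion, negative branch lengths clamped to zero.
**NJ replaces maximum-likelihood inference** — the one major
methodological substitution in the package: the downstream readouts
(Robinson–Foulds concordance, clade support, distance-threshold grouping)
depend on topology and approximate lengths only, and NJ is consistent on
the simulator's infinite-sites data.

Concordance is the mean over tree pairs of 1 − normalized RF distance.
It should be read on trees whose leaves are resolvable: subgenomes of the
same event differ by only ~0.05%, so their within-cluster arrangement is
noise and drags the score down without being evidence of recombination.
The clonality check therefore uses lineage-level trees (score ≳ 0.95 in
simulations with 3-kbp regions), while clade support over the full
multilabeled leaf set quantifies which groupings are stable. Clade support
is computed on trees rooted at a common reference leaf (the
lexicographically first label), so a split appears as the clade on the
far side of the root; the strict majority consensus keeps clades with
support > 0.5.

Subgenome assignment clusters the cross-region average p-distance matrix
by single linkage at τ_lineage, defaulting to **0.5 × the median distance
between haploid strains**. Clusters are named after a haploid member when
one exists; close sister lineages can legitimately share a cluster, which
renames but does not merge their events, because event grouping applies a
second, much tighter threshold: diploids with the same parental-pair key
are linked only when both matched subgenome pairs are within τ_event,
defaulting to **5 × the median nearest-neighbour distance among diploid
subgenomes within a cluster**. That nearest neighbour is almost always a
same-event sibling, so the default estimates the post-hybridization scale
from the data itself. Subgenomes nearly equidistant to two clusters are
flagged ambiguous and their strains reported as unplaced, never silently
dropped. Because the correct number of events for two same-pair events
with no founder drift is genuinely unidentifiable, the package exposes
τ_event rather than resolving such cases silently.

## Karyotype windows

Depth windows are 30 kbp, heterozygosity windows 25 kbp, both normalized
by the genome-wide median so baseline copy number maps to ratio 1. The
window statistic is the median (robust to within-window outliers); the
mean is available by flag. Band assignment (k/ploidy ± 0.15) followed by
run-length calling (≥ 5 windows, i.e. ≥ 150 kbp) makes explicit the visual
procedure of reading windows off the haploid/triploid expectation lines;
both knobs are this package's own quantification and are surfaced
prominently because no published numeric criterion for "large segment"
exists. For LOH classification the depth track is resampled onto the
25-kbp heterozygosity grid by interval-weighted mean; segment depth near
0.5 means deletion, near 1.0 copy-neutral, anything else `ambiguous`.

## Enrichment

Group-by-habitat and group-by-continent tables are tested with Fisher's
exact test. Beyond 2×2 the exact enumeration is impractical, so the
package uses the standard simulated p-value: `nSim` tables with the
observed margins (Patefield's algorithm via `r2dtable`) and the add-one
estimator p = (1 + #{P(sim) ≤ P(obs)}) / (nSim + 1), which is biased
slightly upward and never returns zero. Default nSim = 10,000 with a
mandatory seed. The exact 2×2 enumeration is retained as an oracle, with
a 10⁻⁷ relative tolerance on probability ties, matching common practice.
Raw p-values are reported; with two fields per species no multiplicity
correction is applied.

## Numerical and interface conventions

* Coordinates are 0-based half-open internally; VCF positions are
  converted on read/write. Windows are `[k·w, (k+1)·w)`.
* All randomness flows through per-call seeds; `runPipeline()` derives
  stage seeds from one top-level seed by hashing stage labels, so adding a
  stage does not shift the others' streams.
* Ties in region selection are broken by region id; NJ inherits `ape`'s
  deterministic agglomeration; identical sequences yield zero-length
  branches, which is accepted rather than jittered.
* Degenerate inputs fail fast with named errors: all-zero depth tracks,
  haploid strains in heterozygosity windows, empty core-BUSCO sets,
  degenerate contingency margins, fewer than three sequences per region.

## Problem sizes

The shipped tests and the acceptance script run at sizes chosen to make
the statistical claims sharp while staying desk-scale: Wright–Fisher
populations of N = 200 over 100-kbp genomes for 2,000 generations
(≥ 2,000 segregating sites in a 40-haplotype sample, five replicates);
hybrid populations of 12 lineages × 7 events over 150-kbp genomes with 50
regions of 3 kbp; 20 replicates for event and karyotype recovery; 1,000
draws per ploidy for classifier recovery. Unit tests use smaller
configurations of the same generators.

## Known limitations

* Event grouping assumes consistent subgenome labels across regions, which
  the simulator provides; for real phased data a per-region majority vote
  over cluster assignments would be needed and is not implemented.
* The concordance score penalizes unresolvable near-identical leaves (see
  above); interpret it on lineage-level trees.
* The ploidy classifier inherits the published bands; near-threshold
  assemblies are `unclear` by design, and the diploid gene-count band
  overlaps the realistic diploid distribution (see the classification
  section).
* LD r² on unphased diploids is the genotype-correlation estimator, which
  differs from haplotype r² when phase matters; the phased-haploid path is
  exact.
* The dissimilarity matrix uses ploidy-normalized dosages so haploids and
  diploids share one scale; allele-count-based variants of the distance
  would weight diploids differently.
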