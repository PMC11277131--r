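---
title: "Delimiting cryptic species with karyotypes and DNA barcodes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting cryptic species with karyotypes and DNA barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyodelim)
```

## The inference model

`karyodelim` treats a putative species complex as a set of samples, each
carrying up to two marker observations from physically unlinked genomes:

* a **karyotype**: the haploid bivalent count *n* at first meiotic
  metaphase (possibly approximate, flagged `"ca"`), a qualitative
  structure signature counting the large and medium marker bivalents
  (e.g. `2L+2M`), and whether multivalents were seen;
* a **mitochondrial barcode**: one sequence from an aligned *COI*
  fragment (conventionally 658 bp).

The core assumption is that under intraspecific polymorphism the two
marker systems recombine freely across generations, so within one
locality every karyotype-haplogroup combination should occur at the
frequencies expected under independence, and hybrids between count
races should appear as multivalent-bearing heterozygotes. Between
reproductively isolated species neither happens: combinations are stable
("mimicked linkage disequilibrium") and heterozygotes are absent. In
allopatry, where the co-occurrence test is unavailable, the criterion
falls back to fixed differences: karyotype structure differences or
count gaps too large for intraspecific variation, and fixed diagnostic
substitutions or barcode distance for sublineage differentiation.

### Group formation

Barcodes are clustered into haplogroups by single-linkage components at
threshold θ on the pairwise p-distance graph; karyotypes are grouped
into classes by chaining counts whose differences are below Δ within
each structure signature. A *group* (putative taxon) is the set of
samples sharing one (karyotype class, haplogroup) combination. Samples
with only one marker are attached conservatively: karyotype-only
samples join a group with the same class (preferring one observed at
their locality); sequence-only samples join by haplogroup only when the
match is unambiguous.

### The decision rules

For every pair of groups, evidence (sympatry, karyotype relation,
association p-value, pair-level stable-combination flag, heterozygotes,
barcode differentiation) feeds a fixed-order rule table; exactly one
rule fires:

1. **R1** sympatric + significant within-site association + the two
   groups differ in *both* markers + no heterozygotes → distinct
   species.
2. **R2** sympatric + (heterozygotes or association not significant) →
   single polymorphic species.
3. **R3** allopatric + fixed karyotype difference → distinct species;
   if the pair is *not* barcode-differentiated the verdict carries an
   introgression flag (barcode identity across a deep chromosomal gap
   is better explained by mitochondrial capture than by ancestry,
   because chromosome numbers evolve slowly relative to barcode
   divergence).
4. **R4** allopatric + karyotypes compatible + barcode-differentiated →
   conspecific subspecies (distinct phylogeographic sublineages).
5. **R5** allopatric + karyotypes indistinguishable + no barcode
   differentiation → synonym.
6. **R6** anything else → unresolved. Unresolved is a first-class
   outcome: the engine never forces a rank.

The association significance for a pair is taken from the *site-level*
test (all co-occurring samples pooled into one karyotype-class ×
haplogroup table), because single-taxon sample sizes at a shared
locality are often tiny while the community-level table carries the
signal. The stable-combination requirement, by contrast, is evaluated
*pair-level*: the two groups must be disjoint in both their karyotype
classes and their haplogroups. An earlier design reused the site-level
one-to-one flag for every pair at the site, but one species whose wide
count range is sampled sparsely can split into two karyotype classes
sharing a haplogroup, and that single artifact would then veto the
species status of every other pair at the locality. The pair-level flag
confines the damage to the artifactual pair itself (which lands in R6).

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| θ (`theta`) | 0.02 | p-distance | conventional 2% barcode-gap clustering threshold; a formalization (the original analyses read clusters off a tree), not an estimated value |
| Δ (`delta`) | 3 | bivalents | smallest count gap treated as a fixed, species-level difference; chosen so the published subspecific gap of 1 (*n* = 67–72 vs 73–75) and specific gap of 4 (*n* = 86 vs 90) fall on opposite sides |
| α (`alpha`) | 0.05 | — | association-test significance; conventional |
| `n_permutations` | 9999 | — | sampled-null resolution (minimum p ≈ 1e-4); exact enumeration replaces sampling whenever the label multiset has ≤ 10,000 distinct permutations |
| `radius_km` | 0 | km | sympatry merge radius; 0 means exact named-locality match, appropriate for gazetteer-style records; haversine merging is available for coordinate data |
| `seed` | — | — | mandatory; every permutation and simulation is reproducible |

Δ is deliberately a single global constant. Whether highly variable
species (count ranges of 5–6) should widen Δ adaptively is an open
scientific question; the package keeps the rule transparent instead.

## Statistical notes

* **p-distance** is mismatches over comparable sites, where both
  sequences show unambiguous `A/C/G/T` (pairwise deletion). A pair with
  zero comparable sites has an *undefined* distance (`NA`), never 0.
* **G statistic**: `2 Σ O log(O/E)`; empty cells contribute 0. The
  exact null enumerates all tables with the observed margins under
  multivariate hypergeometric weights — equivalent to enumerating label
  permutations — and p is the total probability of tables with G at
  least the observed (the observed table always counts, so exact p > 0).
  The sampled path uses the add-one estimator `(b+1)/(m+1)`, which is
  valid (never anti-conservative) for exchangeable labels.
* **Degenerate tables** (one class *and* one haplogroup) return p = 1
  with a warning rather than an error, so data-poor sites never crash a
  run.
* **Neighbor joining** follows the standard Q-criterion agglomeration.
  Two behaviors that differ between published implementations are pinned
  down for determinism: Q-ties join the pair whose sorted smallest leaf
  labels are lexicographically least, and negative branch lengths are
  clamped to zero with the deficit moved to the sister branch so the
  joined path length is preserved. The tree is reporting output; no
  verdict depends on it.
* **Modal counts** break ties toward the smaller value,
  deterministically. Exact and approximate counts are summarized as
  separate ranges and never merged; a comparison that had to fall back
  to an approximate-only range is annotated low-confidence.
* Alignment positions are 1-based everywhere, so reported diagnostic
  sites can be read directly against published positions (e.g. a T/A
  fixed difference at position 411 of the *COI* fragment).

## What the simulator emulates — and what it does not

`simulate_dataset()` generates complexes whose defaults are the study
conditions used throughout the tests: four species with haploid counts
78±1, 79, 74±1 and 32±2 and structures `1L+1M`, `1L+0M`, `2L+2M`,
`0L+0M` — a community like the four species found in complete sympatry
at one Armenian locality — with 658 bp barcodes, 20 fixed differences
per species pair (~3% divergence, a typical congeneric *COI* gap and
safely above θ), within-species mutation at 0.002 per site, 35% of
counts emitted as approximate (the proportion in the worked table), one
fully sympatric locality and two allopatric satellites.

Design choices, made once:

* **Star phylogeny**: every species pair differs at exactly
  `n_fixed_diffs` shared diagnostic columns, at which all species carry
  mutually distinct bases. This gives exact control of pairwise
  divergence (the invariant `min p-distance = n_fixed_diffs/seq_length`
  at mutation 0) at the cost of supporting at most four species — the
  alphabet size — when fixed differences are requested.
* **Uniform integer count noise** within `[base − spread, base + spread]`:
  the empirical observation is a range, not a fission/fusion process, so
  no process model is imposed.
* **Introgression as whole-barcode capture**: the recipient's consensus
  is replaced by the donor's before within-species noise, reproducing
  the observed pattern of barcode identity between chromosomally
  distinct taxa.

What passing tests on this generator show is that the pipeline's logic
is correct *under its own assumptions*: clean species boundaries, no
gene flow in the nuclear markers, no sequencing error, no missing data,
single-locus mitochondrial signal. Real barcizing projects additionally
face NUMTs, heteroplasmy, incomplete lineage sorting and paraphyletic
haplogroups — none of which the generator produces, so perfect recovery
on synthetic data is a necessary, not sufficient, correctness check.

Ground truth for a simulation is derived from the generating
configuration (configured ranges, structures, layout and introgression
pairs run through the same decision logic), never from pipeline output.
One consequence is recorded rather than hidden: a *sympatric*
introgressed pair is expected as `single_polymorphic_species`, because
shared haplotypes blind the sympatric criterion — exactly the failure
mode the combined method is designed to avoid for allopatric pairs.

## Known limitations

* Sympatric rules precede karyotype rules, so a sympatric pair whose
  within-site association is underpowered (e.g. a single sample of one
  of the taxa at the shared site) is called a single polymorphic species
  even when karyotype structures differ. The worked analysis
  (`analysis/03_delimit.R`) surfaces one such case; the remedy is
  replication at the shared site, not a rule change.
* Haplogroup clustering is a distance heuristic standing in for tree
  clusters; at divergences near θ the partition can differ from a
  phylogenetic reading. Bayesian tree inference and posterior supports
  are out of scope.
* Phenotype is outside the evidence model. A pair kept apart in the
  literature purely on wing pattern (with identical karyotypes and
  unproven barcode monophyly) will come out `synonym`/`unresolved`
  here; that divergence is by design.
* The karyotype-class chaining inherits Δ; sparse sampling of a wide
  intraspecific range can still split one species into two classes
  (affecting only that artifactual pair, see above).

## Problem sizes

The test suite and the acceptance script run the full pipeline on
complexes of ~30 samples across 100 seeds, 30 introgression scenarios,
1000 simulated independence tables for type-I error calibration, and
brute-force oracle comparisons (exhaustive column scans, range
enumerations, quartet topology enumeration) at small n — all chosen to
exercise every code path at desk scale.
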