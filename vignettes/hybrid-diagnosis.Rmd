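---
title: "Diagnosing natural hybrids from fixed interspecific differences"
author: "hybdiag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing natural hybrids from fixed interspecific differences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybdiag)
```

## The problem

Many plant groups — *Cotoneaster* (Rosaceae) is a textbook case — mix
hybridization, polyploidy and apomixis (asexual seed production).  A
morphologically intermediate population may be a swarm of recent hybrids,
a single clonal lineage descended from one F1, or an old apomictic
microspecies.  Phylogenetic trees are of limited help: apomictic
polyploids produce comb-like topologies, and most congeners cannot be
sampled.  The approach implemented here instead works from *fixed
interspecific differences* at a handful of sequenced loci:

1. Sequence population samples of the two putative parents, the
   candidate hybrids, and any co-occurring relatives at several low-copy
   nuclear genes and chloroplast regions (direct Sanger sequencing;
   heterozygous positions appear as superimposed chromatogram peaks and
   are encoded as IUPAC ambiguity codes).
2. Find the alignment columns at which the two parental population
   samples are each monomorphic for different bases (*fixed
   substitutions*), and the shared gap runs fixed in one parent
   (*fixed indels*).
3. A first-generation hybrid must show *chromatogram additivity* — the
   IUPAC code for the union of the two parental bases — at every fixed
   difference, carry one parental haplotype from each side at every
   nuclear locus, and match one parent's chloroplast haplotype exactly
   (chloroplasts are maternally inherited, so this identifies the seed
   parent).
4. Identical multilocus genotypes across all candidates are consistent
   with apomictic propagation of a single initial F1.
5. Relative ploidy, estimated by flow cytometry against an internal
   standard, independently corroborates the hybrid's genome constitution.

The package implements every step as composable functions plus a thin
command-line wrapper (`exec/hybdiag`), and ships two data sources: a
seeded synthetic generator covering the whole study design, and a
bundled reference dataset (`cotoneaster_alignments()`) encoding the
published per-taxon states of the *C. dielsianus* × *C. glaucophyllus*
system (five nuclear genes: DUF, NA1, NA2, UPF, WD; six chloroplast
regions; 36 + 14 fixed substitutions, 1 + 3 fixed indels).

## Fixed-difference detection

`find_fixed_substitutions()` declares a column diagnostic only when
*every* parentA sample carries one unambiguous base, *every* parentB
sample another, and no parental sample shows a gap or ambiguity code
there.  This is deliberately exact fixation, not a statistical
differentiation test: with 18–26 individuals per parental taxon the
probability that a polymorphic site masquerades as fixed is small, and
the inferential logic ("the hybrid must be additive at *every* such
site") depends on fixation, not on allele-frequency contrast.

Two tunables matter:

* `min_per_taxon` (default 2) — below two samples per taxon "fixed" is
  meaningless, and panels of 2–4 emit a warning.
* `max_missing_frac` (default 0, strict) — a parental `N` disqualifies a
  column; lenient mode tolerates a configurable fraction of missing
  parental calls.  Published studies of this design rarely state a
  missing-data rule, so strictness is the safe default.

`find_fixed_indels()` treats a gap run of any length as **one**
mutational event, and requires the run to be identical across all
individuals of the gapped taxon: if one sample's gap stops a column
short, the whole run is rejected.  Indel polarity (insertion versus
deletion) is not called — that would require outgroup rooting, which the
design does not include.  Terminal gap runs often reflect short reads
rather than deletion alleles; `trim_end_gaps()` recodes them as missing
data when flanks are incomplete.

A FASTA row cannot represent a *heterozygous* indel ("allele/gap") in
one string.  The convention used throughout: the row carries the
full-length allele, and a sidecar table in the taxon map (sample, locus,
start, end) flags the heterozygosity.  `score_additivity()` then reports
such indels as `heterozygous`, the additive state for an indel.

## Additivity and classification

Per diagnostic site a candidate is `additive`, `parentA_like`,
`parentB_like`, or `other`; 3-fold codes, `N` and gaps can never satisfy
a two-parent additivity test and are always `other`.  Per locus, the
verdict vector reduces to a genotype class (`AB`, `AA`, `BB`, `mixed`),
and the multilocus pattern to the final call: all `AB` = F1; `AB` mixed
with one parent's homozygous class = backcross toward that parent; all
one parent = parental; anything else = complex.  Any locus with `other`
verdicts beyond `tolerance` (default 0) makes the sample `ambiguous`, and
a backcross call requires at least one `AB` locus *and* one homozygous
parental locus — a single-locus dataset can never support one.

Two modelling caveats are intentional.  Dosage is not inferred: a
Sanger consensus cannot distinguish AABB from ABBB in a tetraploid, so
classes are defined by allele presence/absence only, and later-generation
hybrids (F2, Fn) are not separable from F1s without dosage.  And clone
groups (`assess_clonality()`: byte-identical phased multilocus genotypes)
are reported as "consistent with a single clonal lineage" — independent
F1s of identical genotype cannot be excluded by identity alone.

## Phasing

`phase_sample()` performs deterministic parsimony anchoring rather than
statistical (EM or coalescent) phasing: the inference this pipeline
needs is only whether a hybrid's two haplotypes match the parental ones,
and a deterministic rule makes outputs exactly reproducible and
testable.  The `k` heterozygous items of a row (2-fold IUPAC columns
plus flagged het-indel runs) admit `2^(k-1)` haplotype pairs; the pair
minimising the summed Hamming distance of each member to its closest
parental reference wins.  A non-unique minimum is flagged
`unphaseable` — no guess is ever made, which matters for taxa (like the
co-occurring *C. franchetii* here) whose haplotypes are not anchored by
either parent.  The enumeration is capped (`max_het`, default 12) because
it is exponential; distances are evaluated over heterozygous items only
(the homozygous backbone contributes a constant), so the cap is a safety
valve, not a performance crutch.  Analyses of the bundled dataset pass
`max_het = 16` explicitly because the hybrid's DUF row is heterozygous at
all 14 diagnostic columns.

Chloroplast loci are concatenated and treated as one haploid system; an
ambiguity code in a chloroplast row raises an error rather than being
phased, since heteroplasmy would violate the maternal-inheritance
assumption the maternity test rests on.  Maternal assignment is exact
sequence matching against the parental chloroplast inventories; a match
to a single-carrier variant is still an assignment (with a
`rare_variant` note — in the reference system the hybrid carries the
minor parental haplotype), a match to both parents is `uninformative`.

## Median-joining networks

Haplotype relationships are summarised as a median-joining network over
the recoded character matrix: each registered indel event collapses to
one binary presence/absence character, remaining gaps are a fifth
character state, constant columns are dropped.  The iteration follows
the classic scheme — minimum spanning network (MSN), quasi-medians of
connected triples, add the best median, repeat, prune — with these
concrete choices:

* **Connection rule.** An MSN link is kept when its length does not
  exceed the minimax connection cost of its endpoints plus `epsilon`
  (default 0, the common published default; at 0 the network is exactly
  the union of all minimum spanning trees, so an MST is always embedded).
* **Candidate medians.** For every triple with one node MSN-adjacent to
  the other two, the per-column majority consensus; columns where all
  three states differ expand over all three (quasi-medians), capped at
  3^7 combinations per triple (larger triples are skipped).
* **Greedy objective.** The candidate reducing the total spanning cost
  of the node set the most is added; ties resolve to the
  lexicographically smallest state vector.  At the fixed point, median
  vectors whose removal leaves the spanning cost unchanged are pruned in
  lexicographic order.

All tie-breaking is deterministic, so networks are reproducible and the
whole procedure can be checked against an independent brute-force
enumeration on small instances (the test suite does exactly this on
1,000 seeded random instances of up to 5 haplotypes × 8 characters).
Published network-software settings (epsilon, character weights) are
rarely reported, so figure-for-figure topology matching is not an
acceptance surface; the structural facts the analysis uses — two
parental haplotype clusters separated by at least the fixed-difference
count, hybrids holding one haplotype in each cluster — are.

## Ploidy from flow cytometry

`find_peaks()` locates the two fluorescence peaks by kernel-density mode
finding on log fluorescence, then refines each mean as a trimmed mean
within ±2 SD of the mode — trimmed, because instrument debris tails bias
raw means and the original instrument software's estimator is unknown.
The internal standard (chicken erythrocyte nuclei, 2.5 pg/2C, the
standard anchor in this literature) is identified by a configured
channel window.  `estimate_2c()` is plain ratio arithmetic, and
`infer_ploidy()` is explicitly *relative*: ploidy = nearest integer of
`reference_ploidy × sample_2c / reference_2c`, anchored on a
chromosome-counted reference taxon, with calls deviating more than 0.25
from an integer flagged low-confidence.  Overlapping peaks (separation
below 2 pooled SD) or a single mode are errors, not guesses.

## The synthetic generator

`simulate_dataset()` emulates the study design end to end: two parental
taxa separated by configured numbers of fixed substitutions and indels
per locus; shallow within-taxon diversity (variant haplotypes are
single-substitution neighbours of each taxon founder, matching the short
connecting lines such systems show in networks); homozygous parental
individuals; candidates composed of F1 clones, independent F1s,
backcrosses and mislabeled parentals; chloroplasts copied from the
configured maternal parent; a truth table recording every sample's
class, maternal parent and clone group.  Defaults mirror the reference
study: 5 nuclear loci (14/4/6/5/7 fixed substitutions, one 6-bp indel)
plus 6 chloroplast loci (14 substitutions, indels of 1/18/13 bp), 18 and
26 parental samples, 30 F1 clones, maternal parent B, per-taxon
haplotype counts giving 9 and 10 haplotypes across the 11-locus system,
and flow peaks at 2.05/2.02/1.09 pg against the 2.5 pg standard at
CV 3%.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: alignment error, paralogous
amplification, allele dropout correlated across sites (the dropout
option is i.i.d. per site), recombination within loci, chloroplast
heteroplasmy, and coalescent-realistic within-taxon genealogies.  The
generator's background composition is uniform i.i.d.; real base
composition and mutation-rate heterogeneity do not affect the exact
set-arithmetic the pipeline performs, which is why this simplification
is acceptable for validating logic, though not for power analyses.

Everything is seeded; the same seed reproduces every file byte for
byte.

## Numerical and degenerate-input choices

* Haplotype labels are assigned per locus by decreasing carrier count,
  ties broken lexicographically by sequence — stable across runs.
* `collapse_bases()`/`expand_iupac()` are exact inverses on 1- and
  2-base sets; gap is a state, never a base.
* Empty candidate sets, single-locus datasets, single-haplotype
  networks, and zero-character matrices all return well-formed empty or
  degenerate results rather than errors; genuinely uninterpretable
  inputs (no parental samples, unresolvable peaks, chloroplast
  ambiguity) raise informative errors.
* Test and acceptance runs use deliberately small problem sizes — the
  bundled 96-sample reference system, simulated datasets of 3–11 loci
  with 5–26 samples per taxon, 10,000-event flow streams, networks of up
  to ~10 nodes — chosen to exercise every code path while keeping the
  whole suite fast; all scale linearly or better in samples × columns
  except the phasing enumeration (capped) and network median search
  (bounded by the expansion cap).

## Known limitations

Beyond the dosage and clone-identity caveats above: the fixed-difference
logic assumes the sampled parental populations represent the taxa (a
private allele in an unsampled deme can break "fixation"); additivity
cannot distinguish an F1 from a somatic chimera or a sample mixture;
and the chloroplast maternity test is only as strong as the parental
chloroplast inventories are complete.  The bundled reference dataset
embeds the published per-taxon states at their printed positions where
those are reliable; a handful of published chloroplast coordinates are
typographically unreadable in the source and are encoded at nominal
positions with counts and states preserved, so coordinate-level
comparisons should use the nuclear loci.
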