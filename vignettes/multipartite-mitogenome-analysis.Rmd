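---
title: "Multipartite mitogenome population analysis: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multipartite mitogenome population analysis: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitopartite)
```

This vignette is the package's own account of the science it implements: the
models and their assumptions, the parameters that matter, what the synthetic
data generator does and does not emulate, and the design choices made where
the design was genuinely open.

## The study system

Plant mitochondrial genomes are structurally dynamic. Rather than one master
circle, they often exist as a set of autonomous molecules — subgenomic
circles and linear chromosomes — interconverted by homologous recombination
between long (> 1 kb) repeat copies. The marama bean (*Tylosema esculentum*)
is an extreme case: two co-inherited cytotypes ("germplasm types") segregate
in wild populations, differing in molecule structure, at hundreds of
sequence loci, and by a 2,108 bp fragment exclusive to one type. Both types
carry a 9,798 bp chloroplast-derived insertion (an MTPT) in the mitogenome,
and low-frequency heteroplasmy — the coexistence of both mitogenome types in
one plant — is detectable at the loci that distinguish the types.

The package turns each analysis of such a population into a tested function:
structure (repeats, recombination conformations, coverage-based copy number,
linear-end degradation), sequence variation (filtered variant and
heteroplasmy calls, germplasm typing, population summary tables), the
insertion's mutational history (quartet parsimony), marker-based phylogeny
(Jukes–Cantor + neighbor joining), and microsatellite content.

## The synthetic-population forge

Real input would be per-sample pileup summaries from whole-genome resequencing
mapped to a reference mitogenome. The forge (`forge_population()`) generates
populations with the study's structure and known ground truth, so every
downstream stage is testable without external data. Its defaults are the
study conditions, chosen once:

* **Reference (type 1) genome**: two circular molecules, LS1 = 250,000 bp and
  LS2 = 149,572 bp (total 399,572 bp — the type 1 assembly total; the LS1/LS2
  split is not published, so lengths were fixed near the positions the survey
  prints, e.g. variant coordinates up to 217 kb on LS1). GC content 44.8 %,
  the genome-wide value. Planted repeat pairs: a 2 kb direct pair and a
  1.5 kb inverted pair on LS1 (flanking a 12,846 bp segment, the length of
  the documented inversion), and a 35 bp direct pair on LS2 (the length of
  the documented short-repeat fusion).
* **Type 2 genome**: derived from type 1 by the differential loci (below), a
  2,108 bp exclusive marker fragment inserted in LS2 with the published
  typing primer sites planted so the 990 bp and 289 bp junction products
  amplify in silico, and a 97,120 bp linear chromosome (M3) whose halves copy
  LS1/LS2 segments — reproducing the observed multicopy coverage regions.
* **Differential loci**: 254 loci (143 SNP / 52 insertion / 59 deletion)
  with the published per-chromosome, per-class segregation structure
  (`locus_plan_default()`): 230 alternate alleles exclusive to type 2, 16
  exclusive to type 1, nine alleles shared across types, four deletions
  polymorphic within type 2, and one locus carrying distinct type-1- and
  type-2-exclusive alleles — the unique decomposition consistent with the
  published count cells.
* **Insertion variants**: 20 type-differential variants planted on the
  quartet's terminal branches (13 mitochondrial / 7 chloroplast, with the
  published class mix) plus 72 ancestral mitochondrial-lineage variants
  shared by both types.
* **Population**: 45 type 1 + 39 type 2 samples; one type 1 sample is
  heteroplasmic with a 4 % minor genome (the published A11-like case); all
  others have fraction 0 (sub-2 % heteroplasmy in the survey is rare in the
  mitogenome and is dominated by homologous-sequence artifacts, which the
  decoy models instead).
* **Sequencing summaries**: per-locus depth ~ Poisson(coverage), default
  100×; minor-genome allele counts ~ Binomial(depth, fraction); substitution
  errors at 0.1 %; strands fair-coin; reads 150 bp. Plastome-derived reads
  over the shared insertion at 10× the mitogenome coverage (plastomes are
  vastly over-represented in total DNA; the exact ratio only needs to keep
  the two organelle alleles separable by frequency).
* **Linear ends**: each copy of a linear molecule loses an independent
  Uniform(0, 18,000) bp stretch from each end. The survey observed decay
  over "up to 18 kb" but not its shape; the uniform model is a stand-in
  chosen because it yields a closed-form expected depth
  (coverage·x/taper_max at distance x from the end) that tests can check
  exactly, not a biological claim.
* **Decoy**: one "nuclear" contig copying a 5 kb mitogenome segment at 1 %
  divergence, to exercise homology masking.

Randomness: one seed in the configuration; every sample draws from a
deterministic sub-stream, so adding samples never shifts earlier samples'
draws and any sample can be regenerated alone.

What the forge deliberately does not emulate: read mapping (counts are
generated directly, so mapping bias and mapping-quality artifacts are out of
scope), indel sequencing errors (substitutions only; indel alleles appear
only as planted variants, matching the filters' focus), replication-slippage
microsatellites (a random-base genome carries essentially none, so the SSR
analysis demonstrates on planted sequence), and PacBio error profiles.
Passing tests therefore show the *procedures* are correct under the stated
noise model — not that real-data artifacts beyond that model are handled.

## Structure analyses

**Repeats.** `find_long_repeats()` reports all maximal exact repeated pairs
≥ `min_len` (default 1,000 bp), both orientations, within and between
molecules, seeded with 31-mers and merged along alignment diagonals. Exact
matching is deliberate: the repeats that mediate recombination in this
system are described as identical copies, and v1 does not attempt diverged
repeat families. Molecules are scanned linearly; a repeat spanning a
circular origin would be missed (rotate the sequence to check).

**Conformations.** `enumerate_conformations()` applies one event per
conformation (depth-1): a direct pair on one circle splits it (products'
lengths sum exactly to the parent's; each retains one repeat copy); a direct
pair across two circles fuses them; an inverted pair reverse-complements the
intervening segment (an involution). Composite structures are reachable by
iterating on products but are not enumerated by default — the analysis
reasons one event at a time. Junction signatures are anchor + full repeat
copy + anchor (anchor 30 bp): for both direct and inverted events the novel
adjacency is only diagnostic if a read spans an entire repeat copy, which is
why long-repeat events are honestly unresolvable from short reads — the
support counter reports zero and the frequency is a no-call rather than an
assertion.

**Copy number.** `copy_number_segments()` smooths depth/baseline with a
running median (window 501 bp), rounds to the nearest positive integer with
halves away from zero (a 1.5× ratio flags copy 2 for review), and merges
constant-copy runs, absorbing segments under 1,000 bp. The window and
minimum segment length sit below the shortest multicopy unit in the emulated
genome (≈ 4 kb), so real regions survive smoothing.

**End taper.** `detect_linear_taper()` fits an isotonic (monotone inward)
curve to each end's depth, finds where the fit first reaches 90 % of the
interior median, and divides by 0.9 to debias under the linear ramp of the
uniform-truncation model. An end is "tapered" when that length is ≥ 1 kb
and the outermost 500 bp average under half the interior median. On forged
profiles the 18 kb truth is recovered well within ±20 %.

## Variant and heteroplasmy calling

The recording rule for a minor allele is: frequency ≥ 2 % of quality-passing
depth at the locus, at least one supporting read on each strand, and the
locus outside the homology mask. Three readings were open and are fixed as
follows: the 2 % threshold denominates over quality-passing depth at the
locus (the natural denominator when counts are already filtered); the Phred
≥ 20 floor applies at count time, upstream of this package's tables (the
`min_phred` field documents it); and the frequency test is applied before
the strand test — the order is switchable but does not change which records
pass, since both are per-allele conjuncts. "Presence in both strands" is
read literally as ≥ 1 read per orientation, not a proportion.

Variant calls are majority-allele calls against the reference at ≥ 10×
depth, with zero-depth and sub-threshold loci recorded as no-calls, distinct
from reference matches. Deletions are anchored at the first deleted base and
insertions after their anchor base; rendered matrices show insertions by
their first two inserted bases, deletions as "D", and reference-matching
cells as dashes.

Typing is a majority vote across differential loci of whether the sample's
major allele equals the type 2 allele, with the marker fragment's relative
coverage (≥ 0.5× the genome median) as an independent flag; a vote/marker
discordance is reported, never silently resolved. Exclusivity in the
population summary is per alternate allele: an allele is type-exclusive when
it is the major allele in at least one sample of exactly one type.

## Insertion origin by quartet parsimony

A single ancestral chloroplast→mitochondrion transfer predating the cytotype
split fixes the unrooted quartet ((chloro_t1, chloro_t2), (mito_t1,
mito_t2)). This topology is an *assumption*, supported by the insertion's
presence in every sampled individual, and the package treats it as one — it
is hard-coded, not inferred. For a binary Ref/Alt pattern at one locus,
Fitch parsimony gives: single-Alt or single-Ref patterns → one change on the
odd terminal branch (the call names that organelle); the two patterns that
split along the internal edge → one internal change, reported `Ambiguous`
because the mutation predates the split; the four patterns that split across
the tree → two changes, `Conflict`. The parsimony score is always reported
so a reader can judge the strength of each call. Indel loci are binary
presence/absence characters in the same machinery. A state polymorphic
within a type is treated as Alt for parsimony and flagged, mirroring how the
survey tabulated its one such locus; consensus-based recovery from read
counts cannot resolve such a locus when carriers are a minority, and the
recovery tests exclude it from the "resolvable" denominator for exactly that
reason.

The chloroplast and mitochondrial states at each locus are separated by read
frequency (`split_insert_alleles()`): the majority allele is attributed to
the plastome copy and the strongest minor allele ≥ 2 % to the mitogenome
copy. This works because plastome coverage dwarfs mitogenome coverage; it
would fail if the ratio approached 1.

## Marker phylogeny

Each differential locus contributes a 40 bp window of reference sequence
centered on the locus anchor (positions −19…+20) with the sample's allele
substituted; insertions lengthen and deletions shorten a sample's window.
Centering was chosen over left-anchoring (the convention was unstated in the
emulated design); both are parameters. Indel loci are handled by per-locus
right-padding with gaps to the block maximum — preserving per-locus
comparability without a multiple-alignment dependency; gapped sites are
excluded pairwise from distances. Windows overlapping at adjacent loci are
merged once, with a warning.

Distances are Jukes–Cantor, d = −¾·ln(1 − 4p⁄3), undefined at p ≥ 0.75.
`nj_tree()` is a canonical Saitou–Nei implementation with a deterministic
tie-break (lowest original taxon indices among Q-minimal pairs) so results
are reproducible to the byte; it is exact on additive matrices, and the test
suite checks it against both a least-squares quartet oracle and an
independent implementation. Neighbor joining is implemented here as the
verification path; likelihood and Bayesian inference are out of scope.

## Microsatellites

`find_ssrs()` reports maximal perfect tandem runs of primitive 1–6 bp motifs
meeting the class minima 10/6/5/5/5/5, truncated to whole motif units
(`total length = motif length × repeat count` holds for every record).
Primitivity prevents an AT run from also being reported as ATAT; when
qualifying runs overlap, the longer wins (tie: earlier start). Compound and
interrupted microsatellites are out of scope. Scanning is linear; a run
spanning a circular origin is not joined. Canonical groups merge a motif
with its rotations and its reverse complement's rotations, labelled A/T and
G/C for mononucleotides.

## Problem sizes and numerical choices

The test suite exercises the full study scale — 84 samples, 254 loci, 100×
coverage, molecules up to 250 kb — for the end-to-end guarantees (typing
accuracy, heteroplasmy recovery within binomial error, two-clade tree,
copy-number and taper recovery), and small constructed instances for exact
oracle comparisons: brute-force repeat enumeration on ≤ 6 kb sequences,
200 random 2 kb sequences for the SSR oracle, all 16 binary quad patterns
against exhaustive branch-placement, 4–8-taxon additive matrices for NJ.
Statistical assertions use 3-standard-error bands (and a 99 % binomial band
for junction frequencies); estimators that would be biased by a reporting
threshold — the mean of filtered heteroplasmy records is left-truncated at
2 % — are checked on raw frequencies instead.

Degenerate inputs are defined errors, not silent results: all-zero depth
profiles, p ≥ 0.75 distances, gap-only site sets, non-symmetric distance
matrices, overlapping repeat copies, non-binary quad patterns.

## Known limitations

Exact repeat matching only; depth-1 conformation enumeration; no
mapping-layer artifacts in the forge; the insertion's frequency-based
allele split assumes a large plastome:mitogenome coverage ratio; SSR and
repeat scans do not wrap circular origins; heteroplasmy below the 2 %
reporting floor is invisible by design, matching the emulated filters.
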