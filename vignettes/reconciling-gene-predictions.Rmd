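---
title: "Reconciling gene predictions between assembly versions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconciling gene predictions between assembly versions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneRecon)
```

# The reconciliation problem

Two gene predictions of the same genome, made on successive assembly
versions, disagree in systematic ways: loci predicted as one model in the
older version appear as several in the newer one (or vice versa), models
fuse neighbouring genes, whole assembly segments are inverted, and
scaffolds move between the artificial unknown chromosome, random
pseudo-chromosomes and proper chromosomal positions. geneRecon makes the
correspondence between the two catalogs explicit, gene by gene, so that
annotation attached to the old identifiers can be transferred with a known
confidence level.

Throughout, version **A** denotes the older assembly's prediction and
version **B** the newer one. The pipeline's core assumption is that true
counterparts are near-identical at the nucleotide level (the two versions
describe the same individual genome), so matching can be run at very high
stringency and everything below that stringency is treated as noise,
paralogy, or genuine absence.

# Matching

## Stringency filter

`filterHits()` retains a hit only when percent identity is **strictly**
above `minIdentity` (default 95) and the e-value **strictly** below
`maxEvalue` (default 1e-20); per query only the `topK` (default 4) best
hits by bit score survive. The strict inequalities are deliberate: a hit at
exactly the threshold is rejected. Ties in bit score are broken by higher
identity, then longer alignment, then lexicographic subject id, so the
truncation is deterministic regardless of input order. In EST mode, where
transcript evidence is matched and neighbour-gene context is unavailable,
an additional inclusive minimum alignment length (`minAlnLengthEst`,
default 100 bp) compensates; the e-value bound is kept at the same 1e-20
since "much less than" is not otherwise quantifiable.

## The internal aligner

For desk-scale inputs the package provides its own local aligner
(`alignSets()`, `alignSmall()`): exact k-mer seeds (k = 16, query sampling
stride 8) select candidate (query, subject, strand, diagonal) triples, and
each candidate diagonal is scanned for its maximal-scoring ungapped segment
under a +1/−2 match/mismatch scale — equivalent to an X-drop extension run
to optimality on that diagonal. The aligner is ungapped by design: the
synthetic generator mutates by substitution only, the package's intended
scale is gene-sized sequences from the *same* genome, and anything needing
gapped heuristics should arrive as externally computed tabular hits, which
always take precedence. The e-value is a Karlin–Altschul-style surrogate
computed from fixed parameters (λ = 1.28, K = 0.46) on query length ×
total subject length; it is a comparable stringency scale, not a Megablast
statistic. Tests hold the aligner to within 0.5 identity points of a full
dynamic-programming local alignment on random substitution-mutated pairs.

Sequences above `lengthCap` (50 kb) are rejected with instructions to
supply external hits.

## Neighbour-gene consistency

Absolute coordinates are not comparable between assemblies, so putative
identities are validated by local gene order: a candidate pair is
*consistent* when the pair plus at least one adjacent pair map
consecutively on both sides. "Adjacent" tolerates up to `skip` (default 1)
intervening unmatched genes — newly predicted or dropped genes would
otherwise break every neighbourhood — while an intervening *matched* gene
always breaks adjacency. A gene with no matched neighbour in reach (e.g.
alone on a scaffold) is *untestable*, which is evidence of nothing, not of
inconsistency.

# Cardinality classification

`classifyCardinality()` walks the connected components of the bipartite
match graph. One-to-one components are `OK`; a neighbour-inconsistent pair
is still `OK` unless its score falls below the low-score floor, in which
case it is `low_score` ("Ls"). The floor is the 5th percentile
(`lowScoreQuantile`) of the *length-normalised* scores (hit bits divided by
the perfect self-match bits of the shorter gene) of the neighbour-consistent
one-to-one pairs. Normalising by length is this package's choice: raw bit
scores scale with gene length, so a floor on raw scores would tag short but
perfect matches — exactly the genes that moved between chromosomes and
therefore fail the neighbour test — as low-scoring.

One-to-many components hinge on whether the partners cover the *same* or
*different* portions of their hub gene (`samePortion()`): pairwise
reciprocal overlap of the hub-side interval hulls, against a threshold
fraction of the shorter interval (default 0.5). Same-portion multiplicity
on the B side is `redundant` (tandem copies collapsed in A). Different
portions trigger the protein-evidence decision, with two predicates:

* **distinct-per-part** — every part is matched by its own evidence
  protein, the hit covering at least `proteinCoverMin` (default 0.6) of
  that protein's length, and regions claimed by different proteins
  overlapping by less than `partOverlapMax` (default 0.2) of the shorter
  region;
* **single-spans** — one protein's hit covers at least `proteinCoverMin`
  of the union of the matched intervals.

Distinct-per-part is evaluated *first*. The order matters: a chimera
fusing one long and one short gene has a long-part protein covering well
over 60 % of the union, so testing single-spans first would misread such
chimeras as incorrect splits. With distinct proteins the component is
`split` (B-side hub: `to_split`, an artificial chimera with an attached
split proposal); with a spanning protein it is `overlap` (B-side hub:
`merged`); with missing or ambiguous evidence the call is `unresolved` —
the structural call is recorded as undecidable rather than guessed.
Evidence is restricted by default to proteins flagged as having existence
demonstrated at the protein level (`flaggedEvidenceOnly`).

Components with at least two genes on *both* sides — including every
compound case planted by the generator — are `multiple`; no precedence
order among structural predicates is applied to them. The recurrent
two-by-two compound topology has exactly three admissible resolutions,
which `enumerateResolutions()` emits with the protein evidence that would
decide each.

Multiple A-side genes matching one B gene on the same portion are *not*
interpreted as redundancy in A (the newer prediction is presumed better):
the B gene keeps its best-scoring partner as a one-to-one pair and the
remaining partners are left unmatched.

`proposeSplits()` turns each k-part chimera into k − 1 new gene records
suffixed `_2`, `_3`, … (the first part keeps the source id). Proposals
whose parts overlap beyond `overlapTolerance` (default 0.2 of the shorter
part) are rejected and the source downgraded, not repaired.

# Positional analysis

Gene positions are compared as midpoint percentages of chromosome length
(lengths supplied, or inferred as the maximum gene end). Pairs partition
into same-chromosome, unknown-involved (which takes precedence) and
different-or-random. Placement modifications distinguish genes newly
placed from the unknown chromosome, newly placed from a random
pseudo-chromosome onto its own base chromosome, and genuine
reassignments (including random-to-different-chromosome flows).

Inversions are detected as maximal contiguous runs, in B order, of
strictly decreasing A order, with a minimum run length (`minRun`,
default 3) rather than a windowed rank correlation: the signal of an
inverted assembly segment is exact order reversal, and a hard minimum run
length is the transparent guard against chance reversals of two genes.
Unmatched and non-one-to-one genes never break a run because only
validated pairs enter the scan. Reversing both versions' coordinate
systems leaves the scan invariant, so a globally flipped chromosome is not
reported as an inversion. Display conventions (shrinking random
chromosomes, magnifying the unknown chromosome) are applied only in
`plotPairPositions()`, never in computation.

# Integration

`unifyGeneSets()` partitions genes across any number of sources into
equivalence groups (union–find over the supplied cross-matches), seeds the
unified set with the highest-priority source and appends the unmatched
genes of each successive source; the unique id is always the id from the
highest-priority source present. `transferAnnotation()` copies prior
annotation onto clean one-to-one records and flags every gene with a
cardinality issue — or no match at all — for independent re-review; a
conflicting annotation between grouped lower-priority sources resolves to
the higher-priority source's text. The four-group classification
(known function / unknown function / viral-TE / no hit) is keyword-driven;
the default TE/viral keyword list (transposon, retrotransposon,
transposase, gag, pol, polyprotein, integrase, reverse transcriptase,
viral, virus) is configurable, since the class is defined by curation
practice rather than a formal rule. `catalogRollup()` validates category
codes against the catalog (levels 1–8, parent level + 1, at most 7
categories per gene — excess is rejected, never truncated) and counts each
gene once per distinct ancestor category.

# The synthetic generator

`simulateAssemblyPair()` draws an ancestral complement (gene lengths
log-uniform 300–3000 bp, spacing uniform 200–2000 bp, uppercase ACGT) and
plants events on **disjoint** gene sets: splits, merges, tandem
expansions, chimeras in either version (2 or 3 genes, always adjacent),
contiguous inverted blocks, relocations, unplacements, per-version drops,
and optionally compound three-gene cases realising the two-by-two
topology. Split breakpoints stay at least `minPartLength` (default
150 bp) from each end, so every part clears the e-value bound and the
95 % identity filter at the supported divergence range. Divergence d
(substitutions only, 0 ≤ d < 0.05) is applied to every emitted B
sequence, making expected identity 100(1 − d) analytically — the reason
indels are excluded. Evidence sequences are the ancestral coding
sequences, emitted per gene with probability `evidenceRate` and flagged as
protein-level; cross-species protein divergence is emulated at the
predicate level (coverage and overlap fractions), not at the amino-acid
level.

The default configuration is the package's reference condition:
2 chromosomes × 250 genes; 20 events per structural class with 5 of the
20 B-side chimeras triple; 3 inverted blocks of 5–12 genes; 10
relocations; 30 unplacements; 10 drops per side; d = 0; full evidence.
The drop counts are this package's realistic addition so that the
unmatched class carries signal. Identical configuration and seed give
byte-identical output.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: indels and rearrangements within genes,
paralogous gene families (every ancestral sequence is random and unique,
so there is no confounding web of cross-family hits), alternative
transcripts, fragmented or partial models, assembly base errors beyond
uniform substitution, and biased placement of short scaffolds. On real
catalogs the same-portion threshold and the evidence fractions interact
with paralogy and protein divergence, and the residual `multiple` and
`unresolved` classes are expected to be far more populated.

# Numerical choices and degenerate inputs

Coordinates are 1-based inclusive everywhere (GFF3 convention), in both
versions. The unknown chromosome label (default `chrUn`) and the random
suffix (default `_random`) are configurable because assembly naming
schemes vary. Empty hit tables flow through every step as empty results;
a zero-length chromosome is rejected in position normalisation; readers
reject malformed coordinates, duplicate ids, wrong column counts and
out-of-range values with the offending row number rather than coercing.
All randomness in the generator is governed by a single seed.

# Problem sizes

The test suite validates the full pipeline on the reference condition
(500 ancestral genes, all event classes, internal aligner) and its
divergence variant at d = 0.02 across five seeds, alongside exhaustive
small-component checks (all connected bipartite topologies of up to six
genes against an independent rule oracle), brute-force neighbour-order
scans on 50-gene fixtures, and 100 random alignment pairs of up to 2 kb
against a dynamic-programming oracle. These sizes were chosen as the
smallest at which every event class, boundary and interaction is
exercised with comfortable multiplicity.

# Known limitations

* The classifier resolves one-to-many components only through protein
  evidence; transcript (mRNA) support is accepted as an additional
  evidence source tag but has no defined priority against protein calls.
* Inversion runs are maximal order-reversal stretches; no attempt is made
  to merge nearby runs separated by collinear genes, and breakpoints are
  resolved only to gene order, not base pairs.
* `unresolved` and `multiple` components are surfaced, never
  auto-resolved; on real data they require curation.
* The aligner is ungapped and capped at 50 kb; genome-scale matching
  should use a dedicated aligner and feed the tabular output in.
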