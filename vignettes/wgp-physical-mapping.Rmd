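---
title: "Sequence-tag physical mapping with wgpmap: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-tag physical mapping with wgpmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgpmap)
```

# The problem

Physical maps order large-insert clones (BACs, ~100 kb) along a genome
before any sequence assembly exists. Whole genome profiling (WGP) does
this with sequence tags instead of electrophoretic fingerprints: BAC
DNA is pooled, double-digested with *Hind*III and *Mse*I, sequenced
from the *Hind*III cut end, and the leading 51 nt of each read is a
*tag*. A clone's fingerprint is its set of tags; two clones that
genuinely overlap share the tags of the overlap region. For genomes
that are mostly repetitive — the regime this package targets, with an
85% default repeat fraction — tag identity is far more discriminating
than fragment mobility, but repeats still produce coincidental tag
sharing, and the statistics below exist to control exactly that.

`wgpmap` implements the whole chain as testable, seedable components:
genome and library simulation, digestion and tag extraction, 3-D pool
deconvolution, and FPC-style assembly. Every stage can be run against
simulated ground truth, so each inference step (deconvolution,
overlap-calling, burying, seriation) is validated by construction
rather than by anecdote.

# Synthetic data: what is modelled, and what is not

## Genome

`generate_genome()` builds one linear chromosome. Repeat families
(default 20, consensus lengths 500–5000 bp) are laid down left to
right, each copy followed by a background gap drawn from an exponential
law with mean `L_family × (1 − f) / f`, so realized repeat coverage
concentrates on the target `f` (±~1% at Mbp scale) without any
rejection stalls even at `f = 0.85`. Each copy carries independent
substitutions at `copy_mutation_rate` (default 0.02 = 2% divergence,
typical of young LTR retrotransposon families). This matters
downstream: at 2% divergence a 51-nt tag has a ~36% chance of matching
its family consensus exactly, so some repeat copies share identical
tags (defeating deconvolution and creating false overlaps) while
others do not — precisely the failure modes the pipeline must handle.
Multi-chromosome genomes are handled by concatenation at the caller's
level; coordinates are 0-based, half-open throughout.

Not modelled: nested/fragmented repeats, GC structure, segmental
duplications, tandem microsatellites. Passing tests on this generator
show the *algorithms* behave correctly under controlled repeat-induced
ambiguity; they do not certify performance on any particular real
genome's repeat landscape.

## Library

`sample_bac_library()` draws clone starts uniformly and insert lengths
from a normal law truncated to `[mean/2, genome length]` (the mean is
the only published quantity; dispersion is a free parameter, default
0). Defaults are a 95,000-bp mean insert and 6.7-fold coverage, the
scale of a real pea-class BAC library. A `chimera_rate` fraction of
clones (default 0, as the true rate is unknown) gets two independently
placed segments splitting the insert at a uniform point in its middle
half; chimeric inserts are digested as one concatenated molecule, as a
physical chimera would be.

## Reads

`simulate_pool_reads()` emits `Poisson(depth_mean)` reads per (pool,
clone, tag occurrence) — or a fixed count with `fixed_depth = TRUE`,
the degenerate case used by noiseless tests — with independent per-base
substitutions at `error_rate`. No quality scores, adapter chemistry,
PCR duplicates or empirical error profiles: the substitution-only model
is enough to exercise the read-support threshold in deconvolution,
which is the only place read quality enters the method.

# Digestion and tags

`double_digest()` merges exact top-strand matches of the palindromic
sites (AAGCTT, TTAA; `N` never matches) into a fragment partition.
Cuts are modelled blunt at `site_start + 1`: the 4-nt 5′ overhangs are
ignored because tag identity only requires a consistent coordinate
convention, not thermodynamic fidelity. The two sites cannot produce
the same cut coordinate, so no tie-break is needed.

`extract_tags()` keeps only *Hind*III-anchored tags — sequencing runs
from the *Hind*III adapter, so *Mse*I ends are never read. A fragment
with *Hind*III at both ends yields two tags (flag-controlled, on by
default; the commercial assay's behaviour here is unpublished).
Fragments shorter than `min_fragment_bp` (default = tag length, 51 nt)
and tags containing `N` are skipped and counted. Tag identity is the
exact 51-mer string; there is no mismatch-tolerant clustering —
sequencing noise is handled instead by the per-pool read-support
threshold, which is where the real protocol's unspecified "quality
filtering" has its effect.

# Pooling and deconvolution

`build_pooling_design()` fills 384-well plates (16 × 24) in row-major
well order, groups them into 6-plate blocks, and forms three pool
dimensions per block: row pools spanning a plate pair (24 × 2 = 48
clones), column pools spanning a plate triple (16 × 3 = 48), and 8 × 8
split-box pools (64). A full block therefore has 48 + 48 + 36 = 132
pools, every clone lies in exactly one pool per dimension, and the
pool triple identifies the clone uniquely (the box pool fixes the
plate, resolving the two-plate ambiguity a row/column intersection
leaves). The real provider's block layout is proprietary; this is one
consistent realization of the 48/48/64 constraint, and the filling
order is documented so triples are reproducible. `design_from_table()`
rebuilds a design from a plain membership TSV for real-data runs.

`deconvolve()` applies the rule per block and per distinct tag: a pool
*detects* a tag at `min_reads_per_pool` reads (default 2 — the
published protocol filters "for sequencing quality" without detail, so
the threshold lives here); the tag is assigned iff exactly one pool
per dimension detects it and the triple resolves to a clone. A tag may
be assigned to one clone in *each* of several blocks — without
per-block assignment, any locus covered by more than one clone library-
wide would be undeconvolvable at 6.7× coverage, and shared tags (the
entire basis of assembly) could never arise.

Two structural consequences are worth stating because they shape every
simulation in the test suite:

* **Blocks must outnumber coverage.** A tag shared by two clones *in
  the same block* is lost (some dimension detects two pools). Tags
  survive deconvolution only where each block holds at most one
  covering clone, so useful designs keep the number of blocks much
  larger than the fold-coverage — a 295,680-clone library is ~128
  blocks against 6.7× coverage. Desk-scale simulations preserve this
  regime by shrinking the plate geometry (e.g. 1 × 2-well plates, 12-
  clone blocks for a 35-clone library) rather than by changing the
  48/48/64 structure of the full-scale default.
* **Support-threshold monotonicity is conditional.** With homogeneous
  per-pool depths, raising `min_reads_per_pool` can only shrink the
  assignment set. With heterogeneous depths it can *add* assignments:
  a weakly covered second pool drops below support and an
  `AMBIGUOUS_DIMENSION` tag flips to `ASSIGNED`. The property test
  pins the fixed-depth regime and checks the underlying (tag, pool)
  detection relation, which is monotone unconditionally.

With no sequencing errors the rule is sound by construction — an
assignment requires all three detected pools to coincide with one
clone's triple, which no combination of co-covering clones can fake —
and the suite verifies 100% recovery of per-block-unique tags with
zero false assignments against simulator provenance.

# Assembly

## Overlap score

The clone-overlap test is the classical fingerprint coincidence score
adapted to exact tag matching: `p = nH/N` is the chance a random tag of
the smaller fingerprint matches the larger one in a universe of `N`
tags, and the score is the binomial upper tail `P(X ≥ m)` with
`X ~ Bin(nL, p)` (computed via `pbinom`; the independent test oracle
enumerates outcomes directly). There is no band-size tolerance window —
tags match exactly or not at all, which is the entire point of
sequence-based fingerprinting. `N` defaults to the count of distinct
tags in the input, with an override for experiment-wide universes.
`m = 0` scores 1; a degenerate universe (`p ≥ 1`) scores 1 with a
warning rather than an error, since single-clone layouts legitimately
reach it.

## Burying

Similarity is `|A∩B| / min(|A|,|B|)` — a small clone fully contained
in a larger one scores 1 regardless of the size difference, matching
the FPC convention that burying is about redundancy, not symmetry.
Clones are processed in descending tag count (ties by id) and buried
into the first retained clone at ≥ 75% similarity, `=` when identical,
`~` otherwise; SuperBACs carry the union of their members' tags.
Buried clones follow their parent into contig/singleton accounting, so
`members-in-contigs + singletons + buried = FPC-ready` holds exactly
while reported BAC totals include buried members.

## Stepwise cutoff relaxation

Assembly starts with full single linkage at the most stringent cutoff
(default 1e-50) and then walks the schedule (1e-40 … 1e-01): at each
step, only *end clones* — the `end_clone_window = 3` outermost clones
of each contig's CB map — are tested against end clones of other
contigs, and scoring pairs merge their contigs until none remain at
that cutoff. Restricting relaxed-cutoff merges to contig ends mimics
FPC end-merging and limits repeat-driven chimeric joins in the middle
of contigs. A singleton is treated as a one-clone contig whose clone
is an end clone: without this, a stringent first pass that yields only
singletons could never form any contig, and well-overlapping pairs
whose scores sit between two schedule steps would be lost. The
partition provably coarsens monotonically along the schedule (merging
is the only operation), and the suite checks this on the recorded
partition trace.

## CB maps

Each tag receives one integer consensus-band coordinate. The layout is
built by greedy seriation — seed with the best-scoring pair, then
repeatedly place the clone with the largest overlap with the placed
tags, inserting its unshared tags as a block on whichever side of its
shared span keeps the *total clone span* (sum over clones of CB span
widths) smaller. Local improvement then re-inserts clone-exclusive
blocks to convergence and, for layouts of ≤ 16 tags, runs a
first-improvement descent over short block relocations and segment
reversals, restarting from the three best seed pairs. The total clone
span is the natural seriation objective: it equals the sum of
fingerprint sizes exactly when every clone is contiguous
(consecutive-ones layout), and the acceptance suite verifies the
heuristic reaches the brute-force permutation optimum on small
consecutive-ones-feasible instances. Contig length in CB units is the
number of occupied coordinates (= distinct tags); conversion to Mbp
multiplies by the mean inter-tag distance (`genome length / tag
anchors`, or a user constant in real-data mode). The exact algorithm
inside the commercial FPC derivative is unpublished; this module is a
documented re-interpretation, not a clone of it.

## Determinism

Every tie is broken lexicographically (clone ids, tag strings, pair
order), every stochastic stage takes an explicit seed, and the
pipeline derives stage seeds from one global seed — two runs of
`run_pipeline()` with the same configuration produce byte-identical
tabular artifacts, which the suite asserts by checksum.

# Problem sizes used in validation

The suite and acceptance script run entirely from simulation at sizes
chosen to keep each property's evidence strong while the whole run
stays desk-scale: 0.5-Mbp genomes (35 clones) for deconvolution
recovery, a 5-Mbp genome at 50% repeats (353 clones, ~1,700 distinct
tags) for assembly recovery, 1-Mbp runs for pipeline determinism,
exhaustive enumeration up to 6-element fingerprints in 30-tag
universes for the score, and brute-force permutation search up to
8-tag layouts for CB optimality. The published pea-scale statistics
are reproduced through the metrics arithmetic from their printed input
totals, not by re-running a 1,800-million-read experiment.

# Known limitations

* Tag identity is exact; a single substitution in a repeat copy
  separates tags that mobility-based fingerprinting would have merged.
  This is deliberate but means sequencing error rates interact with
  `min_reads_per_pool`, not with tag clustering.
* The burial similarity, end-merge window and CB seriation are faithful
  to FPC *conventions* but cannot be byte-compatible with the
  unpublished commercial implementation.
* Contigs-per-Mbp and Mbp sizes inherit the uncertainty of the CB→bp
  conversion constant; on real data supply a measured mean inter-tag
  distance.
* The simulator's repeat model is stationary; highly clustered or
  nested repeat architectures may produce deconvolution loss patterns
  the tests do not exercise.
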