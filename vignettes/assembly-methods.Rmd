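---
title: "Assembling noisy long reads with lrasm: models and methods"
author: "lrasm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling noisy long reads with lrasm: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

lrasm is an overlap-layout-consensus (OLC) assembler for long
single-molecule reads with 5--20% error dominated by insertions and
deletions (PacBio CLR / Oxford Nanopore style). This vignette explains the
models behind each stage, the parameters that matter, the numerical
choices made where the design was genuinely open, and what the bundled
simulator does and does not emulate.

## The pipeline at a glance

```{r}
library(lrasm)
cfg <- simConfig(seed = 1L)
genome <- simulateGenome(cfg)
sim <- simulateReads(genome, cfg)

ov  <- overlapReads(sim$reads)           # all-vs-all overlap discovery
tr  <- trimReads(sim$reads, ov)          # end clipping + chimera removal
lay <- layoutReads(tr$overlaps, tr$trim) # Best-Overlap-Graph unitigs
ctg <- consensusContigs(lay, sim$reads)  # DAG consensus polishing
```

`runPipeline()` wires the four stages together with resumable
intermediate files; `inst/scripts/lrasm.R` exposes the same pipeline from
the shell.

## Overlap discovery

### Homopolymer-compressed seeding

All seeding happens on homopolymer-compressed (HPC) strings: every run of
identical bases collapses to one base, with a monotone coordinate map
back to the raw read. Run-length errors -- the single largest error class
of these instruments -- become invisible in HPC space, which roughly
halves the effective per-base error rate seen by exact-match seeds.

The index stores canonical k-mers (the smaller of a k-mer and its reverse
complement under the 2-bit encoding A=0 < C=1 < G=2 < T=3; palindromes
count as unflipped) of length `k = 16`. Two memory controls follow the
original design: k-mers occurring more than `maxKmerCount = 500` times
are dropped, and only the quarter of k-mers whose splitmix64 hash is 0
modulo `subsampleDenominator = 4` is kept. A seed array records
(read, strand, HPC position) for every retained occurrence.

Candidates for a query are the (target, strand) groups of seed matches
whose *coverage length* -- the query extent spanned from the first to the
last shared seed -- exceeds `minCandidateCoverage = 300` HPC bases. The
span, not the union of seed intervals, is what measures how much of the
read an overlap covers: between two reads that are both noisy, exact
16-mers survive only in scattered windows, and demanding 300 bases of
union coverage would reject nearly every true 2--3 kb overlap at the
default subsampling rate. The top `maxCandidates = 500` candidates are
kept, ranked by repeat-weighted coverage (next section).

### Repeat-depth weighting

Reads from repetitive regions attract large numbers of false candidates.
Each query base receives a weight from its candidate seed depth: 1 at
depth <= `lowDepth` (10), 0 at depth >= `highDepth` (100), linearly
interpolated between (the interpolation shape is a design choice; only
the endpoints are fixed). Candidate ranking integrates these weights over
the seed span, so repeat-heavy candidates fall out of the top-500 cut
while unique-sequence candidates are unaffected. Increasing a region's
depth can only decrease weighted coverage (a property the tests assert).

### z-mer chaining in windows

Within a candidate pair, short z-mers (`zmerLength = 10` -- long enough to
be specific, short enough that two 12%-error reads still share a dense
set) are matched exactly and merged into maximal runs (anchors). The
query is tiled into consecutive `windowSize = 800` HPC-base windows.
Anchors in a window are first grouped by diagonal (bin width 64, each
group spanning three adjacent bins): random spurious matches scatter
across diagonals and would otherwise interrupt the chain of the true,
indel-jittered diagonal. Each group is chained with the block recurrence

  S[1] = L[1],  S[i+1] = S[i] + L[i+1] - Distance(i, i+1)

where Distance = |Δtpos - Δqpos| is the collinearity drift between
adjacent anchors. Drift, not raw spacing, is what carries signal here:
indels make the spacing between surviving z-mers highly variable, but
collinear anchors drift only by the local indel imbalance, while
off-diagonal jumps pay their full magnitude and close the block. The
greedy pass is Kadane's maximum-subarray scheme, so the returned block
(the run ending at the score peak) provably equals exhaustive enumeration
of all contiguous anchor runs -- an oracle the tests exercise.

Windows whose best block covers fewer than `minWindowMatch = 200` query
bases are discarded; surviving windows, summarized as super-anchors, are
chained again with the same recurrence, and the candidate survives only
if the selected windows' matched bases exceed `minChainTotal = 300`.

### Piecewise banded alignment

The chained anchors become waypoints for the final alignment in raw
coordinates. Anchor positions are exact in HPC space but their raw
expansions can differ in run lengths, so anchor interiors are banded-
aligned like the gaps between them rather than emitted as matches
verbatim. Segments between waypoints (thinned to roughly 256 HPC bases
apart) use a band from the doubling schedule `bandMin = 50`, 100, ...,
`bandMax = 3200`, chosen from the segment length difference and doubled
on band-boundary contact. Both ends are then extended toward the read
ends with band `endBand = 800`, stopping when either read is exhausted.

The aligner is a banded affine-gap (Gotoh) global DP: match +2, mismatch
-4, gap of length L costs 4 + 2L; N mismatches everything. These
values are configurable; with a band at least as wide as the longer
sequence the result equals unbanded DP exactly, which the tests verify
against an independent implementation. Overlaps with stitched identity
below `minOverlapIdentity = 0.65` are discarded. Each unordered pair is
reported once, in PAF-style records on the forward strand of both reads.

## Trimming

For each read, the overlap intervals touching it are piled up. The kept
interval is the longest stretch with depth >= `clipMinDepth = 2`
(unsupported read ends carry the highest error and no corroboration).

Chimeric junction detection uses spur statistics. A terminus counts as
junction evidence only when the alignment ends internally (more than
`spurMargin = 50` bases from the ends) on *both* reads: an overlap that
stops at its partner's extremity is simply that partner's complete
alignment, and every dovetail partner necessarily leaves one such
benign terminus. Termini are clustered within the margin; a cluster is a
spur structure when at least `spurMinReads = 3` alignments terminate
together (a real junction at 30x shows 15--30). With m the depth of
overlaps crossing the spur and n the terminating count, the read is
chimeric iff m < avgDepth/2, or n > avgDepth, or n > m/2, with avgDepth
the mean pileup depth over the read's overlap-graph component.

A structural check follows: a read is discarded when it is a cut vertex
of the overlap graph whose removal splits its component into two parts of
at least 3 reads each. Genuine linear tilings are immune because adjacent
reads also overlap each other directly, providing the bypass path a
chimera lacks.

Surviving overlaps are clipped to the kept intervals, the partner side
mapped linearly through the alignment span (an approximation: the edit
script is not re-walked), and dropped below `minClippedSpan = 300` bases.

## Layout

Clipped overlaps are classified with dovetail slack `laySlack = 100`:
contained reads are set aside, internal overlaps excluded, dovetails
become edges of the Best-Overlap-Graph. Per read end, the candidate set
holds edges scoring at least `layRatio = 0.95` of the end's best score,
and the *longest* candidate is selected -- near-best-by-score but
longest-by-span, which keeps bubble arms from being merged while still
preferring long overlaps. An edge survives only as the mutual selection
of both endpoints, so each end carries at most one edge and the graph
decomposes into simple paths (unitigs).

Contained reads are re-inserted at their container's position, iterating
so containment chains resolve (at 30x most reads are contained, and
genome-end regions are tiled almost entirely by such chains). Redundant
unitigs are dropped when the union of projected overlap intervals to a
longer unitig covers more than `layRedundancy = 0.40` of their length;
projecting intervals (rather than counting whole reads) distinguishes a
duplicated island from a unitig that merely abuts its neighbour at a
junction. Unitigs still connected by at least three overlap records
agreeing on a placement within 300 bases are merged -- a single missing
mutual-best edge otherwise splits one true tiling in two. Finally the
outermost read of each unitig end is extended to its full raw extent:
end clipping protects junctions, but at a contig terminus the terminal
read's tail is the only observation of that part of the genome.

## Consensus

Each unitig's backbone is stitched from the tiling reads, with every
junction spliced by aligning the backbone tail into the incoming read:
layout offsets carry tens of bases of error after clipping, and
arithmetic splicing would duplicate that many bases per junction --
duplications that consensus cannot repair, because reads split their
support between the two copies.

Member reads are homopolymer-compressed and aligned to the compressed
backbone (band `cnsBand = 800`, reads under `cnsMinIdentity = 0.5`
excluded), then threaded through a backbone-anchored alignment DAG whose
nodes are (position, insertion offset, base). Three details matter:

* **Gap normalization.** Indel runs in each alignment are shifted to
  their leftmost score-equivalent position before threading, so
  equivalent placements in repeat context land on the same node.
* **Majority pruning.** The consensus path maximizes coverage-adjusted
  node scores, support - 0.4 x local depth, and skipping a position is
  charged the same way. Summing raw edge weights instead lets a minority
  branch of two light edges beat one heavy skip edge, so correlated
  minority variants would enter and persist. The 0.4 factor sits between
  the evidence levels of true run extensions (discounted to ~0.6--0.8 of
  depth because both copies must survive in a read) and uncorrelated
  noise (below ~0.3).
* **Run-length calling.** Because the DAG works in HPC space, each node
  tallies the raw run lengths of its supporting reads and the consensus
  expands to the modal length. Run-length errors never enter the
  base-level graph, and each run is called from the full spanning pileup
  rather than from alignment-split insertion evidence.

Two rounds are run (`cnsRounds = 2`): against a raw backbone, reads place
gaps inconsistently around clustered backbone errors and one pass leaves
a few percent uncorrected; against the round-1 consensus the alignments
become consistent and the second pass converges. After each round,
low-agreement windows (support under 0.55 of depth) are re-called by
plurality vote over the whole read segments spanning them: where the
local truth differs from the backbone by two or more edits, reads carry
the true string verbatim but represent it with heterogeneous mixes of
mismatches and indels, and per-column voting stalls.

## The simulator

`simulateReads()` draws uniform start positions and strands, truncated-
normal lengths (mean 5000, sd 1500, minimum 500), and applies per-base
substitution/insertion/deletion errors, a +/-1 run-length error with
probability `homopolymerNoise` per homopolymer run of length >= 2,
tripled error rates in the first and last `badEndLength = 100` bases, and
an optional fraction of chimeric reads joining two independent fragments
at a uniform junction. Defaults model the target regime: a 50 kb
repeat-free genome at 30x with 12% error (6% ins / 4% del / 2% sub) and
homopolymer noise 0.1.

What the simulator does **not** emulate: instrument-specific error
profiles (no quality values, no signal-level correlations), sequence-
dependent error hotspots, coverage biases, or adapter artifacts. Passing
tests on simulated data therefore demonstrate the algorithmic contracts
-- sensitivity of seeding and chaining at the stated error rates, chimera
detection against the stated junction model, consensus convergence --
not performance on any particular real instrument.

## Problem sizes and limitations

The test and acceptance workloads run the full pipeline on 50 kb genomes
at 30x (around 300 reads), a scale where an all-vs-all overlap pass takes
a few minutes on one core. The implementation is not engineered for more
than ~10^4 reads: the index is in-memory, the candidate loop is
single-threaded, and no disk-backed structures are used.

Known limitations, measured on the simulator at the default noisy
conditions:

* Consensus identity converges to ~98.7--99.0%. The ceiling has two
  parts: backbone-anchored column-plus-window voting tops out near 99.0%
  even under idealized uniform coverage (compound error sites entangle
  per-read alignments), and contigs keep the single-coverage raw tails of
  their terminal reads (~2.5% of length at raw-read identity) because
  those tails are the only observation of the genome ends.
* Repeat resolution is limited to what the Best-Overlap-Graph and the
  repeat-depth weighting provide; no repeat phasing or scaffolding is
  attempted.
* Chimera detection assumes junctions are visible as clustered partial
  alignments; chimeras joining near-identical loci evade it.
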