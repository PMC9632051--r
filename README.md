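# lrasm

An overlap-layout-consensus (OLC) assembler for noisy long
single-molecule reads, written as an R package with an Rcpp core. It
targets PacBio CLR / Oxford Nanopore style data: 5–20% error dominated
by insertions and deletions, read lengths in the kilobases, and no
pre-correction of the raw reads.

## Who this is for

Researchers who want a compact, fully tested, desk-scale implementation
of the classic noisy-long-read OLC stack — to assemble small simulated or
real datasets (up to a few thousand reads), to study how the individual
stages behave, or to reuse the pieces (HPC k-mer indexing, anchor
chaining, banded alignment, alignment-DAG consensus) as library
functions.

## The method

Assembly runs in four stages, each exposed as an exported function and
glued together by `runPipeline()`:

1. **Overlap** (`overlapReads`). Reads are homopolymer-compressed (HPC);
   a canonical k-mer index (k = 16, occurrence cap K = 500, 1/4 hash
   subsampling) proposes candidate pairs whose shared-seed span exceeds
   d = 300 HPC bases, ranked by repeat-depth-weighted coverage (weights
   1 → 0 over depths 10 → 100, "-q 100"). Within a pair, exact z-mers
   (z = 10) are chained in y = 800-base windows under the block
   recurrence `S[i+1] = S[i] + L[i+1] − Distance(i,i+1)` with Distance
   the collinearity drift |Δt − Δq|; windows below 200 matched bases are
   dropped and chains must cover > 300 bases. The chained anchors guide
   a piecewise banded affine-gap alignment (dynamic band 50–3200, 800 bp
   end extension) that yields PAF-style overlap records.
2. **Trim** (`trimReads`). Per-read overlap pileups clip unsupported
   ends (depth ≥ 2 kept); clustered partial-alignment termini ("spurs")
   classify a read as chimeric iff `m < avgDepth/2` or `n > avgDepth` or
   `n > m/2` (m = crossing depth, n = terminating alignments); cut
   vertices bridging two subgraphs of ≥ 3 reads are discarded.
3. **Layout** (`layoutReads`). Dovetail overlaps (slack w = 100) form a
   Best-Overlap-Graph: per read end, the longest edge within ratio
   r = 0.95 of the best score, kept only when mutually selected. Maximal
   simple paths become unitigs; contained reads are re-inserted;
   unitigs sharing > 40% of their length with a longer one are dropped.
4. **Consensus** (`consensusContigs`). Each unitig's backbone is
   stitched with alignment-verified splices; reads are realigned and
   threaded through a backbone-anchored alignment DAG (PBDAG-Con style)
   in HPC space with per-node run-length tallies; the maximum-weight
   path under majority pruning, refined by windowed plurality re-calls
   and a second round, is emitted as the contig.

A seeded simulator (`simulateGenome`, `simulateReads`, `trueOverlaps`)
generates genomes and reads with tunable substitution/indel rates,
homopolymer run-length noise, low-quality read ends and chimeric reads,
together with ground-truth coordinates — the substrate for every test.

The methods vignette (`vignettes/assembly-methods.Rmd`) documents the
models, parameter meanings and numerical choices in detail.

## A worked example

```r
library(lrasm)

cfg <- simConfig(genomeLength = 20000L, coverage = 15,
                 readLengthMean = 2000L, readLengthSd = 400L,
                 subRate = 0, insRate = 0, delRate = 0,
                 homopolymerNoise = 0, badEndLength = 0L, seed = 101L)
genome <- simulateGenome(cfg)
sim    <- simulateReads(genome, cfg)

ov  <- overlapReads(sim$reads)
tr  <- trimReads(sim$reads, ov)
lay <- layoutReads(tr$overlaps, tr$trim)
ctg <- consensusContigs(lay, sim$reads)

ov
#> OverlapSet: 1821 overlaps over 150 reads
#>   mean identity 0.999 , mean span 1219 bp

assemblyStats(ctg, genome)
#> $totalLength
#> [1] 19839
#> $nContigs
#> [1] 1
#> $largest
#> [1] 19839
#> $n50
#> [1] 19839
#> $l50
#> [1] 1
#> $coveredFraction
#> [1] 0.9919873
#> $identity
#> [1] 1
```

150 error-free 2 kb reads at 15× coverage of a 20 kb genome produce 1821
overlaps, a single unitig, and one contig that reproduces 99.2% of the
genome at identity 1.0 (the outermost stretches are covered by no read).
With the default noisy profile (12% error: 6% insertion, 4% deletion, 2%
substitution, homopolymer noise 0.1) the same pipeline on a 50 kb, 30×
dataset yields a single contig covering ~99.3% of the genome at ~98.7%
consensus identity, against a raw-read identity of ~88%.

There is also a thin command-line driver:

```sh
Rscript inst/scripts/lrasm.R simulate -o sim --seed 7
Rscript inst/scripts/lrasm.R run -i sim.reads.fa -o asm
Rscript inst/scripts/lrasm.R stats -i asm.fa --reference sim.genome.fa
```

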