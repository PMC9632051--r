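# Shared fixtures, built once per test run and memoized. All data are
# generated programmatically under fixed seeds.

.fix <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fix, inherits = FALSE))
    assign(name, build(), envir = .fix)
  get(name, envir = .fix)
}

randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

# small error-free dataset: 20 kb genome, 15x, 2 kb reads
smallClean <- function() memo("smallClean", function() {
  cfg <- simConfig(genomeLength = 20000L, coverage = 15, readLengthMean = 2000L,
                   readLengthSd = 400L, subRate = 0, insRate = 0, delRate = 0,
                   homopolymerNoise = 0, badEndLength = 0L, seed = 101L)
  g <- simulateGenome(cfg)
  sim <- simulateReads(g, cfg)
  ov <- overlapReads(sim$reads)
  list(cfg = cfg, genome = g, reads = sim$reads, truth = sim$truth, ov = ov)
})

# study-scale error-free dataset (acceptance conditions)
accClean <- function() memo("accClean", function() {
  cfg <- simConfig(subRate = 0, insRate = 0, delRate = 0,
                   homopolymerNoise = 0, badEndLength = 0L, seed = 7L)
  g <- simulateGenome(cfg)
  sim <- simulateReads(g, cfg)
  ov <- overlapReads(sim$reads)
  tr <- trimReads(sim$reads, ov)
  lay <- layoutReads(tr$overlaps, tr$trim)
  contigs <- consensusContigs(lay, sim$reads)
  list(cfg = cfg, genome = g, reads = sim$reads, truth = sim$truth,
       ov = ov, tr = tr, lay = lay, contigs = contigs)
})

# study-scale noisy dataset: 12% error (6/4/2), homopolymer noise 0.1
accNoisy <- function() memo("accNoisy", function() {
  cfg <- simConfig(seed = 11L)
  g <- simulateGenome(cfg)
  sim <- simulateReads(g, cfg)
  ov <- overlapReads(sim$reads)
  tr <- trimReads(sim$reads, ov)
  lay <- layoutReads(tr$overlaps, tr$trim)
  contigs <- consensusContigs(lay, sim$reads)
  list(cfg = cfg, genome = g, reads = sim$reads, truth = sim$truth,
       ov = ov, tr = tr, lay = lay, contigs = contigs)
})

# noisy dataset with 5% injected chimeric junction reads
accChimera <- function() memo("accChimera", function() {
  cfg <- simConfig(chimeraRate = 0.05, seed = 23L)
  g <- simulateGenome(cfg)
  sim <- simulateReads(g, cfg)
  ov <- overlapReads(sim$reads)
  tr <- trimReads(sim$reads, ov)
  list(cfg = cfg, genome = g, reads = sim$reads, truth = sim$truth,
       ov = ov, tr = tr)
})

# exhaustive-enumeration oracle for the chain recurrence: best contiguous
# anchor block, score = S over the block; ties -> smallest end, then start
chainOracle <- function(anchors) {
  n <- nrow(anchors)
  if (n == 0L) return(list(start = 0L, end = 0L, score = 0))
  best <- -Inf; bs <- 0L; be <- 0L
  for (j in seq_len(n)) {
    for (a in seq_len(j)) {
      S <- unname(anchors[a, 3])
      if (a < j) for (i in (a + 1):j) {
        d <- abs((anchors[i, 2] - anchors[i - 1, 2]) -
                 (anchors[i, 1] - anchors[i - 1, 1]))
        S <- S + anchors[i, 3] - d
      }
      if (S > best) { best <- S; bs <- a; be <- j }
    }
  }
  list(start = bs, end = be, score = unname(best))
}

# unbanded global alignment score oracle (Biostrings, same scoring scheme)
oracleGlobalScore <- function(a, b, match = 2, mismatch = -4,
                              gapOpen = 4, gapExtend = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    substitutionMatrix = mat, gapOpening = gapOpen,
    gapExtension = gapExtend, type = "global"))
}
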