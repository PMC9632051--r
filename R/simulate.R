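#' Simulation configuration
#'
#' Study conditions for the bundled genome/read simulator. Defaults model
#' a desk-scale noisy long-read run: a 50 kb repeat-free genome at 30-fold
#' coverage with 5 kb mean reads carrying 12% indel-dominated error
#' (6% insertion, 4% deletion, 2% substitution) plus homopolymer
#' run-length noise, the regime the assembler targets.
#'
#' @param genomeLength genome size in bases.
#' @param repeatFraction fraction of the genome occupied by copies of one
#'   repeat element.
#' @param repeatUnit repeat element length in bases.
#' @param coverage fold coverage of emitted reads.
#' @param readLengthMean,readLengthSd read length distribution (truncated
#'   normal, minimum `minReadLength`).
#' @param minReadLength shortest emitted read.
#' @param subRate,insRate,delRate per-base error probabilities.
#' @param homopolymerNoise probability of a +/-1 run-length error per
#'   homopolymer run (runs of length >= 2).
#' @param chimeraRate fraction of reads formed by joining two independent
#'   fragments.
#' @param badEndLength bases at each read end with tripled error rates.
#' @param seed RNG seed (integer).
#' @return a named list of simulation parameters.
#' @export
simConfig <- function(genomeLength = 50000L, repeatFraction = 0,
                      repeatUnit = 2000L, coverage = 30,
                      readLengthMean = 5000L, readLengthSd = 1500L,
                      minReadLength = 500L, subRate = 0.02, insRate = 0.06,
                      delRate = 0.04, homopolymerNoise = 0.1,
                      chimeraRate = 0, badEndLength = 100L, seed = 42L) {
  stopifnot(genomeLength > 0, repeatFraction >= 0, repeatFraction <= 1,
            coverage > 0, subRate >= 0, subRate <= 1, insRate >= 0,
            insRate <= 1, delRate >= 0, delRate <= 1,
            homopolymerNoise >= 0, homopolymerNoise <= 1,
            chimeraRate >= 0, chimeraRate <= 1)
  as.list(environment())
}

#' Simulate a genome
#'
#' Uniform random sequence with, optionally, `repeatFraction` of its
#' length occupied by copies of a single `repeatUnit`-length element
#' pasted at random positions. Deterministic under `config$seed`.
#'
#' @param config from [simConfig()].
#' @return character(1) genome sequence.
#' @export
simulateGenome <- function(config = simConfig()) {
  set.seed(config$seed)
  L <- config$genomeLength
  g <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  nCopies <- round(config$repeatFraction * L / config$repeatUnit)
  if (nCopies > 0) {
    unit <- sample(c("A", "C", "G", "T"), config$repeatUnit, replace = TRUE)
    starts <- sample.int(L - config$repeatUnit, nCopies)
    for (s in starts) g[s:(s + config$repeatUnit - 1L)] <- unit
  }
  paste(g, collapse = "")
}

# apply per-base substitution / insertion / deletion errors (vectorized)
mutateBases <- function(v, sub, ins, del) {
  n <- length(v)
  if (n == 0L) return(v)
  code <- match(v, c("A", "C", "G", "T")) - 1L
  doSub <- runif(n) < sub
  if (any(doSub)) {
    shift <- sample.int(3L, sum(doSub), replace = TRUE)
    code[doSub] <- (code[doSub] + shift) %% 4L
  }
  v <- c("A", "C", "G", "T")[code + 1L]
  keep <- runif(n) >= del
  v <- v[keep]
  n <- length(v)
  insHere <- runif(n + 1L) < ins
  if (any(insHere)) {
    at <- which(insHere) - 1L  # boundary before position at+1
    newb <- sample(c("A", "C", "G", "T"), length(at), replace = TRUE)
    ordKey <- c(seq_len(n), at + 0.5)
    v <- c(v, newb)[order(ordKey)]
  }
  v
}

# +/-1 run-length noise on homopolymer runs of length >= 2
homopolymerJitter <- function(v, p) {
  if (p <= 0 || length(v) == 0L) return(v)
  r <- rle(v)
  idx <- which(r$lengths >= 2L)
  hit <- idx[runif(length(idx)) < p]
  if (length(hit)) {
    delta <- sample(c(-1L, 1L), length(hit), replace = TRUE)
    r$lengths[hit] <- pmax(1L, r$lengths[hit] + delta)
  }
  inverse.rle(r)
}

mutateRead <- function(s, config) {
  v <- strsplit(s, "")[[1]]
  v <- homopolymerJitter(v, config$homopolymerNoise)
  n <- length(v)
  be <- min(config$badEndLength, n %/% 3L)
  headIdx <- seq_len(be)
  tailIdx <- if (be > 0L) seq.int(n - be + 1L, n) else integer(0)
  midIdx <- setdiff(seq_len(n), c(headIdx, tailIdx))
  out <- c(mutateBases(v[headIdx], min(1, 3 * config$subRate),
                       min(1, 3 * config$insRate), min(1, 3 * config$delRate)),
           mutateBases(v[midIdx], config$subRate, config$insRate,
                       config$delRate),
           mutateBases(v[tailIdx], min(1, 3 * config$subRate),
                       min(1, 3 * config$insRate), min(1, 3 * config$delRate)))
  paste(out, collapse = "")
}

#' Simulate noisy long reads with ground truth
#'
#' Draws approximately `coverage * genomeLength / readLengthMean` reads
#' with uniform start positions and strands, truncated-normal lengths,
#' per-base substitution/insertion/deletion errors, homopolymer run-length
#' jitter, tripled error rates in the first and last `badEndLength` bases,
#' and a `chimeraRate` fraction of reads formed by joining fragments from
#' two independent loci. Deterministic under `config$seed`.
#'
#' @param genome character(1) from [simulateGenome()].
#' @param config from [simConfig()].
#' @return list with `reads` (named `DNAStringSet`) and `truth`
#'   (data.frame readId, start, end, strand, isChimera, junction,
#'   start2, end2, strand2; intervals 0-based half-open on the genome).
#' @export
simulateReads <- function(genome, config = simConfig()) {
  set.seed(config$seed + 1L)
  L <- nchar(genome)
  nReads <- round(config$coverage * L / config$readLengthMean)
  drawFragment <- function(len) {
    len <- min(len, L)
    s <- sample.int(L - len + 1L, 1L) - 1L
    c(s, s + len)
  }
  drawLen <- function() {
    max(config$minReadLength,
        min(L, round(rnorm(1, config$readLengthMean, config$readLengthSd))))
  }
  seqs <- character(nReads)
  truth <- data.frame(readId = seq_len(nReads) - 1L, start = 0L, end = 0L,
                      strand = "+", isChimera = FALSE, junction = NA_integer_,
                      start2 = NA_integer_, end2 = NA_integer_,
                      strand2 = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nReads)) {
    chim <- runif(1) < config$chimeraRate
    if (!chim) {
      len <- drawLen()
      iv <- drawFragment(len)
      strand <- sample(c("+", "-"), 1L)
      frag <- substr(genome, iv[1] + 1L, iv[2])
      if (strand == "-") frag <- revcompChar(frag)
      seqs[i] <- mutateRead(frag, config)
      truth$start[i] <- iv[1]; truth$end[i] <- iv[2]
      truth$strand[i] <- strand
    } else {
      len <- drawLen()
      l1 <- max(config$minReadLength %/% 2L, round(len * runif(1, 0.3, 0.7)))
      l2 <- max(config$minReadLength %/% 2L, len - l1)
      iv1 <- drawFragment(l1); iv2 <- drawFragment(l2)
      s1 <- sample(c("+", "-"), 1L); s2 <- sample(c("+", "-"), 1L)
      f1 <- substr(genome, iv1[1] + 1L, iv1[2])
      if (s1 == "-") f1 <- revcompChar(f1)
      f2 <- substr(genome, iv2[1] + 1L, iv2[2])
      if (s2 == "-") f2 <- revcompChar(f2)
      m1 <- mutateRead(f1, config); m2 <- mutateRead(f2, config)
      seqs[i] <- paste0(m1, m2)
      truth$start[i] <- iv1[1]; truth$end[i] <- iv1[2]; truth$strand[i] <- s1
      truth$isChimera[i] <- TRUE
      truth$junction[i] <- nchar(m1)
      truth$start2[i] <- iv2[1]; truth$end2[i] <- iv2[2]
      truth$strand2[i] <- s2
    }
  }
  reads <- DNAStringSet(seqs)
  names(reads) <- sprintf("sim%05d", seq_len(nReads) - 1L)
  list(reads = reads, truth = truth)
}

#' True overlap pairs from simulation truth
#'
#' All unordered pairs of non-chimeric reads whose source intervals on the
#' genome intersect by at least `minSpan` bases.
#'
#' @param truth truth table from [simulateReads()].
#' @param minSpan minimum intersection in genome bases (default 2000).
#' @return data.frame with columns `idA`, `idB` (idA < idB) and `span`.
#' @export
trueOverlaps <- function(truth, minSpan = 2000L) {
  t <- truth[!truth$isChimera, , drop = FALSE]
  if (nrow(t) < 2L)
    return(data.frame(idA = integer(0), idB = integer(0), span = integer(0)))
  ir <- IRanges(start = t$start + 1L, end = t$end)
  hits <- findOverlaps(ir, minoverlap = minSpan, drop.self = TRUE,
                       drop.redundant = TRUE)
  qi <- queryHits(hits); si <- subjectHits(hits)
  span <- width(pintersect(ir[qi], ir[si]))
  a <- t$readId[qi]; b <- t$readId[si]
  data.frame(idA = pmin(a, b), idB = pmax(a, b), span = as.integer(span))
}
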