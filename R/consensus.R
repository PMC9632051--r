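#' Backbone sequence of a unitig
#'
#' Stitches the tiling reads' oriented, trimmed sequences by their layout
#' offsets: each read contributes the suffix extending past the backbone
#' built so far. The splice point is refined by aligning the backbone tail
#' into the incoming read (layout offsets carry tens of bases of
#' uncertainty after trimming; splicing by arithmetic alone would
#' duplicate or drop that many bases at every junction, and duplicated
#' stretches cannot be repaired by consensus because reads split their
#' support between the two copies). The result is the uncorrected contig
#' the member reads are realigned to.
#'
#' @param tiling tiling data.frame of one unitig (readId, strand, offset,
#'   start, end).
#' @param seqs character vector of raw read sequences (id order).
#' @param params scoring parameters for the splice alignment.
#' @return character(1) backbone sequence.
#' @export
backboneOf <- function(tiling, seqs, params = pipelineConfig()) {
  if (nrow(tiling) == 0L) stop("empty unitig")
  t <- tiling[order(tiling$offset, tiling$readId), , drop = FALSE]
  backbone <- ""
  curEnd <- 0
  for (i in seq_len(nrow(t))) {
    s <- substr(seqs[t$readId[i] + 1L], t$start[i] + 1L, t$end[i])
    if (t$strand[i] == "-") s <- revcompChar(s)
    off <- t$offset[i]
    rl <- nchar(s)
    if (curEnd == 0L || off >= curEnd) {
      # first read, or a genuine tiling gap: append verbatim
      backbone <- paste0(backbone, s)
      curEnd <- nchar(backbone)
      next
    }
    cut <- curEnd - off  # arithmetic splice estimate
    # offsets carry error accumulated along containment chains, so whether
    # a read is fully spanned is decided by the splice alignment, not by
    # offset arithmetic; only clearly spanned reads are skipped
    if (cut >= rl + 1200L) next
    Tlen <- min(cut - 100L, rl - 600L, 2000L)
    spliced <- FALSE
    attempted <- Tlen >= 100L
    if (attempted) {
      a <- substr(backbone, curEnd - Tlen + 1L, curEnd)
      b0 <- max(0L, cut - Tlen - 1200L)
      b1 <- min(rl, cut + 1200L)
      b <- substr(s, b0 + 1L, b1)
      r <- align_banded_cpp(a, b, 1600L, 2L, params$match, params$mismatch,
                            params$gapOpen, params$gapExtend)
      if (r$ncols > 0 && r$nmatch / r$ncols >= 0.6) {
        cut <- b0 + r$bend
        spliced <- TRUE
      }
    }
    # a read whose splice was attempted but failed must not re-enter on a
    # thin arithmetic margin (it is likely spanned); short overlaps that
    # cannot host a probe are trusted arithmetically
    if (attempted && !spliced && off + rl <= curEnd + 800L) next
    if (cut < rl) {
      backbone <- paste0(backbone, substr(s, cut + 1L, rl))
      curEnd <- nchar(backbone)
    }
  }
  backbone
}

#' Align one read against its backbone region
#'
#' Banded alignment of the read's oriented, trimmed sequence against the
#' backbone window `[offset - pad, offset + readLength + pad]` (clipped to
#' the backbone), global in the read and free at both window ends.
#'
#' @param readSeq oriented read sequence (character).
#' @param backbone backbone sequence.
#' @param offset the read's layout offset on the backbone.
#' @param band band half-width and window pad (default 800).
#' @param params scoring parameters ([pipelineConfig()]).
#' @return list with `tstart` (backbone start of the alignment), `cigar`,
#'   `identity`, `score`.
#' @export
alignToBackbone <- function(readSeq, backbone, offset, band = 800L,
                            params = pipelineConfig()) {
  L <- nchar(backbone)
  n <- nchar(readSeq)
  ws <- max(0L, as.integer(offset) - band)
  we <- min(L, as.integer(offset) + n + band)
  win <- substr(backbone, ws + 1L, we)
  r <- align_banded_cpp(readSeq, win, band, 2L, params$match,
                        params$mismatch, params$gapOpen, params$gapExtend)
  list(tstart = ws + r$bstart, cigar = r$cigar,
       identity = if (r$ncols > 0) r$nmatch / r$ncols else 0,
       score = r$score)
}

#' Call a consensus from backbone-anchored read alignments
#'
#' Threads the backbone and every read alignment through the alignment
#' DAG (nodes: backbone position / insertion offset / base; edge weights:
#' read support) and returns the maximum-weight source-to-sink path, ties
#' resolved toward the backbone base.
#'
#' @param backbone character backbone sequence.
#' @param alignments list of `list(seq, tstart, cigar)` read alignments
#'   (as from [alignToBackbone()]; `seq` is the oriented read). When
#'   `backboneRuns` is given, `seq` is an HPC string and each element also
#'   carries `runs`, the per-HPC-base raw run lengths.
#' @param backboneRuns optional integer vector of the backbone's raw run
#'   lengths (HPC mode): the DAG then works on HPC strings, every node
#'   tallies the raw run lengths of its supporting reads, and the returned
#'   consensus expands each node to the modal run length. Run-length
#'   errors never enter the base-level graph this way, and each run is
#'   called from the full spanning pileup.
#' @return list with `seq` (consensus), `support` (per-base read support),
#'   and DAG diagnostics (`totalWeight`, `nNodes`, `nEdges`).
#' @export
callConsensus <- function(backbone, alignments = list(),
                          backboneRuns = NULL) {
  consensus_dag_cpp(backbone, alignments, backboneRuns)
}

#' Consensus stage: polish every unitig of a layout
#'
#' For each unitig, builds the backbone ([backboneOf()]), aligns each
#' tiling read to its hinted backbone region ([alignToBackbone()]),
#' excludes reads aligning below `cnsMinIdentity`, and calls the
#' heaviest-path consensus ([callConsensus()]). The call runs for
#' `cnsRounds` rounds (default 2): the first round's consensus replaces
#' the raw stitched backbone for a second pass. With an uncorrected
#' backbone at indel-heavy error rates, read-to-backbone alignments place
#' gaps inconsistently around clustered backbone errors and a single pass
#' leaves a few percent of them uncorrected; against the round-1
#' consensus the alignments become consistent and the second pass
#' converges.
#'
#' @param layout a [Layout-class].
#' @param reads `DNAStringSet` or character vector of raw reads.
#' @param params parameter list from [pipelineConfig()] (uses `cnsBand`,
#'   `cnsMinIdentity`, `cnsRounds`).
#' @return a `DNAStringSet` of contigs (named by unitig id) with
#'   `meanSupport` and `nReads` in `mcols`.
#' @export
consensusContigs <- function(layout, reads, params = pipelineConfig()) {
  seqs <- as.character(reads)
  us <- layout@unitigs
  out <- character(0)
  sup <- numeric(0)
  nr <- integer(0)
  for (u in us) {
    backbone <- backboneOf(u$tiling, seqs)
    n <- nrow(u$tiling)
    # oriented trimmed reads, homopolymer-compressed: the DAG works in HPC
    # space and calls run lengths from the per-node pileup
    hseqs <- character(n)
    runsL <- vector("list", n)
    for (i in seq_len(n)) {
      t <- u$tiling[i, ]
      s <- substr(seqs[t$readId + 1L], t$start + 1L, t$end)
      if (t$strand == "-") s <- revcompChar(s)
      h <- hpc_compress_cpp(s)[[1]]
      hseqs[i] <- h$hseq
      runsL[[i]] <- as.integer(h$runs)
    }
    cns <- NULL
    hints <- NULL
    for (round in seq_len(max(1L, params$cnsRounds))) {
      bbH <- hpc_compress_cpp(backbone)[[1]]
      ratio <- nchar(bbH$hseq) / nchar(backbone)
      if (is.null(hints)) hints <- u$tiling$offset * ratio
      alns <- list()
      newHints <- hints
      for (i in seq_len(n)) {
        a <- alignToBackbone(hseqs[i], bbH$hseq, as.integer(round(hints[i])),
                             params$cnsBand, params)
        newHints[i] <- a$tstart
        if (a$identity < params$cnsMinIdentity) next
        alns[[length(alns) + 1L]] <- list(seq = hseqs[i],
                                          tstart = a$tstart,
                                          cigar = a$cigar,
                                          runs = runsL[[i]])
      }
      cns <- callConsensus(bbH$hseq, alns, as.integer(bbH$runs))
      cns$nReads <- length(alns)
      cns <- patchShakyWindows(cns, alns, nchar(bbH$hseq))
      # next round: realign against this consensus, rescaling the HPC
      # hints for the (small, roughly uniform) length change
      newBbH <- hpc_compress_cpp(cns$seq)[[1]]
      hints <- newHints * nchar(newBbH$hseq) / nchar(bbH$hseq)
      backbone <- cns$seq
    }
    out <- c(out, setNames(cns$seq, u$id))
    sup <- c(sup, mean(cns$support))
    nr <- c(nr, cns$nReads)
  }
  res <- DNAStringSet(out)
  mcols(res) <- DataFrame(meanSupport = sup, nReads = nr)
  res
}

# Windowed plurality repair of low-agreement consensus stretches. At sites
# where the local truth differs from the backbone by two or more edits in
# a short window, reads represent the same true string with heterogeneous
# mixes of mismatches and indels, so no single DAG node collects a
# majority and per-column voting stalls. Each shaky window is re-called by
# voting on the whole read segments spanning it.
patchShakyWindows <- function(cns, alns, L, frac = 0.55, minCov = 6,
                              pad = 2L, mergeGap = 4L, maxWin = 40L) {
  hp <- cns$hpos; ho <- cns$hoff
  shaky <- cns$hsupport < frac * cns$hcov & cns$hcov >= minCov
  if (!any(shaky)) return(cns)
  # group shaky path nodes into backbone-coordinate windows
  at <- which(shaky)
  grp <- cumsum(c(1L, (hp[at[-1]] - hp[at[-length(at)]]) > mergeGap))
  winL <- winR <- integer(0)
  for (g in unique(grp)) {
    p <- hp[at[grp == g]]
    lo <- max(0L, min(p) - pad)
    hi <- min(L, max(p) + pad + 1L)
    if (hi - lo > maxWin || hi <= lo) next
    winL <- c(winL, lo); winR <- c(winR, hi)
  }
  if (length(winL) == 0L) return(cns)
  votes <- window_vote_cpp(alns, as.integer(winL), as.integer(winR))
  # apply patches right to left so indices stay valid
  ord <- order(winL, decreasing = TRUE)
  hseqV <- strsplit(cns$hseq, "")[[1]]
  hruns <- cns$hruns; hsup <- cns$hsupport; hcov <- cns$hcov
  hposV <- hp; hoffV <- ho
  for (k in ord) {
    v <- votes[[k]]
    if (is.null(v) || v$voters < minCov) next
    if (v$votes < max(3, 0.35 * v$voters)) next
    # path slice replaced by the window: column nodes in [winL, winR-1],
    # insertion nodes anchored in [winL-1, winR-2]
    sel <- (hoffV == 0L & hposV >= winL[k] & hposV <= winR[k] - 1L) |
           (hoffV >= 1L & hposV >= winL[k] - 1L & hposV <= winR[k] - 2L)
    if (!any(sel)) next
    i0 <- min(which(sel)); i1 <- max(which(sel))
    if (!all(sel[i0:i1])) next  # non-contiguous slice: leave it alone
    cur <- paste(hseqV[i0:i1], collapse = "")
    if (identical(cur, v$winner)) next
    if (abs(nchar(v$winner) - (i1 - i0 + 1L)) > 20L) next
    wb <- strsplit(v$winner, "")[[1]]
    nw <- length(wb)
    hseqV <- c(hseqV[seq_len(i0 - 1L)], wb, hseqV[-seq_len(i1)])
    hruns <- c(hruns[seq_len(i0 - 1L)], v$runs, hruns[-seq_len(i1)])
    hsup <- c(hsup[seq_len(i0 - 1L)], rep(v$votes, nw), hsup[-seq_len(i1)])
    hcov <- c(hcov[seq_len(i0 - 1L)], rep(v$voters, nw), hcov[-seq_len(i1)])
    hposV <- c(hposV[seq_len(i0 - 1L)], rep(winL[k], nw), hposV[-seq_len(i1)])
    hoffV <- c(hoffV[seq_len(i0 - 1L)], rep(0L, nw), hoffV[-seq_len(i1)])
  }
  cns$hseq <- paste(hseqV, collapse = "")
  cns$hruns <- hruns; cns$hsupport <- hsup; cns$hcov <- hcov
  cns$hpos <- hposV; cns$hoff <- hoffV
  cns$seq <- paste(rep(hseqV, pmax(1L, hruns)), collapse = "")
  cns$support <- rep(hsup, pmax(1L, hruns))
  cns
}
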