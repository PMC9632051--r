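#' All-vs-all overlap discovery
#'
#' The overlap stage: builds the HPC k-mer index over all reads, then for
#' every read as query finds repeat-weighted candidates, chains z-mer
#' anchors in sliding windows, and aligns the chained pairs piecewise with
#' a dynamic band. Each unordered read pair is reported at most once
#' (qid < tid); the result is deterministic for fixed parameters.
#'
#' @param reads a named `DNAStringSet` (or named character vector).
#' @param params parameter list from [pipelineConfig()].
#' @param verbose emit progress messages (default FALSE).
#' @return an [OverlapSet-class].
#' @export
overlapReads <- function(reads, params = pipelineConfig(), verbose = FALSE) {
  seqs <- as.character(reads)
  n <- length(seqs)
  nms <- names(seqs)
  if (is.null(nms)) nms <- paste0("read", seq_len(n) - 1L)
  lens <- nchar(seqs)
  hf <- hpc_compress_cpp(seqs)
  for (i in seq_len(n)) hf[[i]]$rawlen <- lens[i]
  # reverse-complement HPC views, built lazily per target
  rcSeqs <- character(n)
  hr <- vector("list", n)
  idx <- buildKmerIndex(seqs, k = params$k, maxCount = params$maxKmerCount,
                        subsampleDenominator = params$subsampleDenominator)
  out <- vector("list", n)
  for (q in seq_len(n)) {
    cand <- find_candidates_cpp(idx@ptr, hf[[q]]$hseq, q - 1L,
                                params$minCandidateCoverage,
                                params$maxCandidates, params$lowDepth,
                                params$highDepth, TRUE)$hits
    if (nrow(cand) == 0L) next
    cand <- cand[cand$tid > q - 1L, , drop = FALSE]
    recs <- vector("list", nrow(cand))
    for (ci in seq_len(nrow(cand))) {
      t <- cand$tid[ci] + 1L
      strand <- cand$strand[ci]
      if (strand == "+") {
        th <- hf[[t]]
        torseq <- seqs[t]
      } else {
        if (is.null(hr[[t]])) {
          rcSeqs[t] <- revcompChar(seqs[t])
          hr[[t]] <- hpc_compress_cpp(rcSeqs[t])[[1]]
          hr[[t]]$rawlen <- lens[t]
        }
        th <- hr[[t]]
        torseq <- rcSeqs[t]
      }
      anchors <- extract_anchors_cpp(hf[[q]]$hseq, th$hseq,
                                     params$zmerLength)
      ch <- chainQuery(anchors, params$windowSize, params$minWindowMatch,
                       params$minChainTotal)
      if (is.null(ch)) next
      rec <- alignChainRaw(seqs[q], torseq, hf[[q]], th, ch$anchors, params)
      if (is.null(rec)) next
      if (strand == "-") {
        ts <- lens[t] - rec$tend; te <- lens[t] - rec$tstart
        rec$tstart <- ts; rec$tend <- te
      }
      rec <- cbind(data.frame(qid = q - 1L, tid = t - 1L, strand = strand,
                              stringsAsFactors = FALSE), rec)
      recs[[ci]] <- rec
    }
    recs <- recs[!vapply(recs, is.null, TRUE)]
    if (length(recs)) out[[q]] <- do.call(rbind, recs)
    if (verbose && q %% 50L == 0L)
      message("overlap: processed ", q, "/", n, " queries")
  }
  out <- out[!vapply(out, is.null, TRUE)]
  records <- if (length(out)) do.call(rbind, out) else emptyOverlapRecords()
  records <- records[, overlapColumns(), drop = FALSE]
  rownames(records) <- NULL
  new("OverlapSet", records = records, readNames = nms,
      readLengths = as.integer(lens))
}

overlapColumns <- function() {
  c("qid", "tid", "strand", "qstart", "qend", "tstart", "tend",
    "matches", "blockLen", "score", "identity", "cigar")
}

emptyOverlapRecords <- function() {
  data.frame(qid = integer(0), tid = integer(0), strand = character(0),
             qstart = integer(0), qend = integer(0), tstart = integer(0),
             tend = integer(0), matches = integer(0), blockLen = integer(0),
             score = integer(0), identity = numeric(0), cigar = character(0),
             stringsAsFactors = FALSE)
}
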