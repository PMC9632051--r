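#' Build the HPC k-mer index over a read set
#'
#' Two-pass construction: k-mers of the reads' HPC strings are counted in a
#' hash table (canonical form only, k-mers containing N skipped, and only
#' the 1/`subsampleDenominator` fraction selected by a fixed 64-bit hash
#' mix retained), then k-mers occurring more than `maxCount` times are
#' dropped and a seed array of (read, strand, HPC position) entries is
#' filled for the rest.
#'
#' @param reads a `DNAStringSet` (raw reads) or character vector.
#' @param k HPC k-mer length (default 16; must be in 8..31).
#' @param maxCount occurrence cap (default 500); k-mers present more than
#'   this many times across all reads are filtered out.
#' @param subsampleDenominator keep k-mers whose hash code is 0 modulo this
#'   (default 4, i.e. one quarter); 1 disables subsampling.
#' @return a [KmerIndex-class].
#' @export
buildKmerIndex <- function(reads, k = 16L, maxCount = 500L,
                           subsampleDenominator = 4L) {
  seqs <- as.character(reads)
  hs <- hpc_compress_cpp(seqs)
  hseqs <- vapply(hs, function(x) x$hseq, "")
  ptr <- build_index_cpp(hseqs, as.integer(k), as.integer(maxCount),
                         as.integer(subsampleDenominator))
  new("KmerIndex", ptr = ptr, k = as.integer(k),
      maxCount = as.integer(maxCount),
      subsampleDenominator = as.integer(subsampleDenominator),
      nReads = length(seqs))
}

#' Number of indexed occurrences of a k-mer
#'
#' Zero both for k-mers never seen and for k-mers removed by the occurrence
#' cap or hash subsampling.
#'
#' @param index a [KmerIndex-class].
#' @param kmer character(1) k-mer (raw, will be canonicalized).
#' @return integer count.
#' @export
kmerCount <- function(index, kmer) {
  stopifnot(is(index, "KmerIndex"))
  if (grepl("[^ACGT]", kmer)) return(0L)  # N-containing k-mers never indexed
  index_kmer_count_cpp(index@ptr, kmer)
}

#' Find candidate overlapping reads for a query
#'
#' Looks up every (subsample-selected) k-mer of the query's HPC string in
#' the index, groups seed matches by (target, strand), and computes the
#' coverage length of the putative overlap: the query extent spanned by
#' the shared seeds, in HPC coordinates (under heavy noise shared seeds
#' are sparse, so the spanned extent -- not the union of seed intervals --
#' is what measures how much of the read the overlap covers).
#' Candidates with coverage above `minCoverage` are ranked --
#' by repeat-depth-weighted coverage when `weighted = TRUE` -- and the top
#' `maxCandidates` returned. Self-hits are excluded; ties break by target
#' id ascending.
#'
#' @param index a [KmerIndex-class].
#' @param query character(1) raw sequence, or an [HPCRead-class].
#' @param queryId integer id of the query within the indexed set (used to
#'   exclude self-hits); use -1 for an external query.
#' @param minCoverage keep candidates with coverage strictly greater than
#'   this many HPC bases (default 300).
#' @param maxCandidates cap on returned candidates (default 500).
#' @param lowDepth,highDepth repeat-weighting endpoints: per-base weight is
#'   1 at depth <= `lowDepth` (default 10), 0 at depth >= `highDepth`
#'   (default 100), linear between.
#' @param weighted rank candidates by weighted coverage (default TRUE).
#' @return list with `hits` (data.frame tid, strand, coverage,
#'   weightedCoverage) and `depth` (integer per-HPC-base seed depth over
#'   the query).
#' @export
findCandidates <- function(index, query, queryId = -1L, minCoverage = 300,
                           maxCandidates = 500L, lowDepth = 10L,
                           highDepth = 100L, weighted = TRUE) {
  stopifnot(is(index, "KmerIndex"))
  qh <- if (is(query, "HPCRead")) query@hseq else
    hpc_compress_cpp(as.character(query))[[1]]$hseq
  find_candidates_cpp(index@ptr, qh, as.integer(queryId), minCoverage,
                      as.integer(maxCandidates), as.integer(lowDepth),
                      as.integer(highDepth), weighted)
}

#' Repeat-depth weights
#'
#' Per-base weight used to down-rank repetitive regions during candidate
#' selection: 1 at depth <= `lowDepth`, 0 at depth >= `highDepth`, linearly
#' interpolated in between (so depth 55 maps to 0.5 under the defaults).
#'
#' @param depth integer vector of per-base candidate seed depths.
#' @param lowDepth,highDepth interpolation endpoints (defaults 10 and 100).
#' @return numeric vector of weights in `[0, 1]`.
#' @export
depthWeights <- function(depth, lowDepth = 10, highDepth = 100) {
  stopifnot(highDepth > lowDepth)
  w <- (highDepth - depth) / (highDepth - lowDepth)
  pmin(1, pmax(0, w))
}
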