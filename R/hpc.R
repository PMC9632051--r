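#' Homopolymer-compress a sequence
#'
#' Collapses every run of identical bases to a single base and records the
#' monotone coordinate map back to the raw read. Idempotent on already
#' compressed input; an empty sequence yields an empty `HPCRead`.
#'
#' @param seq character(1), DNA over {A,C,G,T,N}.
#' @return an [HPCRead-class] object.
#' @examples
#' h <- hpcCompress("AAATTGGC")
#' h@hseq    # "ATGC"
#' h@runs    # 3 2 2 1
#' @export
hpcCompress <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nzchar(seq) && grepl("[^ACGTN]", seq))
    stop("sequence contains characters outside {A,C,G,T,N}")
  r <- hpc_compress_cpp(seq)[[1]]
  new("HPCRead", hseq = r$hseq, runs = as.integer(r$runs),
      offsets = as.integer(r$offsets), rawLength = nchar(seq))
}

#' Expand an HPC read back to its raw sequence
#'
#' @param h an [HPCRead-class].
#' @return character(1), the raw sequence.
#' @export
hpcExpand <- function(h) {
  stopifnot(is(h, "HPCRead"))
  if (nchar(h@hseq) == 0L) return("")
  paste(rep(strsplit(h@hseq, "")[[1]], h@runs), collapse = "")
}

#' Map an HPC interval to the raw-read interval it expands to
#'
#' Intervals are 0-based half-open on both sides; the mapping is monotone.
#'
#' @param h an [HPCRead-class].
#' @param interval integer(2), `c(start, end)` in HPC coordinates.
#' @return integer(2), the raw interval.
#' @examples
#' h <- hpcCompress("AAATTGGC")
#' hpcToRaw(h, c(1, 3))  # 3 7
#' @export
hpcToRaw <- function(h, interval) {
  stopifnot(is(h, "HPCRead"), length(interval) == 2L)
  s <- as.integer(interval[1]); e <- as.integer(interval[2])
  n <- nchar(h@hseq)
  if (s < 0L || e < s || e > n) stop("interval outside the HPC read")
  pos <- function(p) if (p == n) h@rawLength else h@offsets[p + 1L]
  c(pos(s), pos(e))
}

#' Canonical form of a k-mer
#'
#' The canonical k-mer is whichever of the k-mer and its reverse complement
#' has the smaller 2-bit integer encoding (A=0 < C=1 < G=2 < T=3);
#' `flipped` is TRUE iff the reverse complement was chosen. A palindromic
#' k-mer is reported unflipped.
#'
#' @param kmer character(1) over {A,C,G,T}, at most 31 bases.
#' @return list with `canonical` (character) and `flipped` (logical).
#' @examples
#' canonicalKmer("TTTT")  # canonical "AAAA", flipped TRUE
#' @export
canonicalKmer <- function(kmer) {
  stopifnot(is.character(kmer), length(kmer) == 1L)
  canonical_kmer_cpp(kmer)
}

# reverse complement of a plain character sequence (N fixed)
revcompChar <- function(s) revcomp_cpp(s)
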