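#' Homopolymer-compressed read
#'
#' A DNA sequence with every homopolymer run collapsed to a single base,
#' plus the monotone coordinate map back to the raw sequence: `runs[i]` is
#' the length of the raw run behind HPC position i and `offsets[i]` its
#' 0-based start coordinate in the raw read.
#'
#' @slot hseq character(1), the HPC string (no two adjacent equal bases).
#' @slot runs integer, per-HPC-position run length.
#' @slot offsets integer, per-HPC-position raw start coordinate (0-based).
#' @slot rawLength integer(1), length of the raw sequence.
#' @export
setClass("HPCRead",
  representation(hseq = "character", runs = "integer", offsets = "integer",
                 rawLength = "integer"))

setValidity("HPCRead", function(object) {
  h <- object@hseq
  n <- nchar(h)
  if (length(object@runs) != n || length(object@offsets) != n)
    return("runs/offsets length must equal nchar(hseq)")
  if (n > 1L) {
    b <- strsplit(h, "")[[1]]
    if (any(b[-1] == b[-n]))
      return("hseq has adjacent repeated bases")
    if (any(diff(object@offsets) != object@runs[-n]))
      return("offsets[i] + runs[i] must equal offsets[i+1]")
  }
  if (n > 0L && (object@offsets[1] != 0L ||
                 sum(object@runs) != object@rawLength))
    return("coordinate map does not span the raw read")
  TRUE
})

setMethod("show", "HPCRead", function(object) {
  cat("HPCRead of", object@rawLength, "raw bases,",
      nchar(object@hseq), "HPC bases\n")
})

#' Homopolymer-compressed k-mer index
#'
#' Canonical-k-mer hash over a read set's HPC strings with an occurrence
#' cap and hash-code subsampling, backed by a seed array of
#' (read, strand, position) entries. Built by [buildKmerIndex()].
#'
#' @slot ptr external pointer to the native index.
#' @slot k integer(1), HPC k-mer length.
#' @slot maxCount integer(1), occurrence cap; more frequent k-mers are dropped.
#' @slot subsampleDenominator integer(1), keep 1/denominator of k-mers by
#'   hash code.
#' @slot nReads integer(1).
#' @export
setClass("KmerIndex",
  representation(ptr = "externalptr", k = "integer", maxCount = "integer",
                 subsampleDenominator = "integer", nReads = "integer"))

setMethod("show", "KmerIndex", function(object) {
  info <- index_info_cpp(object@ptr)
  cat("KmerIndex: k =", object@k, ", maxCount =", object@maxCount,
      ", subsample 1/", object@subsampleDenominator, "\n", sep = "")
  cat("  ", info$nReads, " reads, ", format(info$nKmers, big.mark = ","),
      " k-mers, ", format(info$nSeeds, big.mark = ","), " seeds\n", sep = "")
})

#' Set of pairwise overlap records
#'
#' One row per overlap: read ids, relative strand, 0-based half-open
#' intervals on the forward strand of each read (PAF convention), score,
#' identity and a `=X I D` edit script relative to the oriented target.
#'
#' @slot records data.frame with columns qid, tid, strand, qstart, qend,
#'   tstart, tend, matches, blockLen, score, identity, cigar.
#' @slot readNames character, names of the read universe (index = id + 1).
#' @slot readLengths integer, raw lengths of the read universe.
#' @export
setClass("OverlapSet",
  representation(records = "data.frame", readNames = "character",
                 readLengths = "integer"))

setValidity("OverlapSet", function(object) {
  r <- object@records
  need <- c("qid", "tid", "strand", "qstart", "qend", "tstart", "tend",
            "matches", "blockLen", "score", "identity", "cigar")
  if (!all(need %in% names(r)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (length(object@readNames) != length(object@readLengths))
    return("readNames and readLengths lengths differ")
  if (nrow(r) == 0L) return(TRUE)
  n <- length(object@readNames)
  if (any(r$qid < 0L) || any(r$qid >= n) || any(r$tid < 0L) || any(r$tid >= n))
    return("read id out of range")
  ql <- object@readLengths[r$qid + 1L]
  tl <- object@readLengths[r$tid + 1L]
  if (any(r$qstart < 0L) || any(r$qstart >= r$qend) || any(r$qend > ql))
    return("query interval out of range")
  if (any(r$tstart < 0L) || any(r$tstart >= r$tend) || any(r$tend > tl))
    return("target interval out of range")
  if (!all(r$strand %in% c("+", "-"))) return("strand must be + or -")
  if (any(r$identity < 0 | r$identity > 1)) return("identity must be in [0,1]")
  TRUE
})

setMethod("show", "OverlapSet", function(object) {
  cat("OverlapSet:", nrow(object@records), "overlaps over",
      length(object@readNames), "reads\n")
  if (nrow(object@records) > 0)
    cat("  mean identity", round(mean(object@records$identity), 3),
        ", mean span", round(mean(object@records$qend - object@records$qstart)),
        "bp\n")
})

#' @describeIn OverlapSet-class the overlap record table.
#' @param x an `OverlapSet`.
#' @export
overlapRecords <- function(x) {
  stopifnot(is(x, "OverlapSet"))
  x@records
}

#' Assembly layout
#'
#' Ordered, oriented read tilings (one per unitig) defining contig
#' backbones for the consensus stage. Each tiling row gives the read, its
#' orientation on the unitig, its offset in unitig coordinates, and the
#' trimmed raw-read interval used (0-based half-open).
#'
#' @slot unitigs list; each element is `list(id, length, tiling)` with
#'   tiling a data.frame (readId, strand, offset, start, end).
#' @slot readNames character, read universe.
#' @slot readLengths integer, raw read lengths.
#' @export
setClass("Layout",
  representation(unitigs = "list", readNames = "character",
                 readLengths = "integer"))

setValidity("Layout", function(object) {
  n <- length(object@readNames)
  for (u in object@unitigs) {
    t <- u$tiling
    if (is.unsorted(t$offset)) return("offsets must be non-decreasing")
    if (any(t$readId < 0L) || any(t$readId >= n))
      return("tiling references an unknown read")
    len <- object@readLengths[t$readId + 1L]
    if (any(t$start < 0L) || any(t$start >= t$end) || any(t$end > len))
      return("tiling interval outside its read")
  }
  TRUE
})

setMethod("show", "Layout", function(object) {
  nr <- sum(vapply(object@unitigs, function(u) nrow(u$tiling), 1L))
  cat("Layout:", length(object@unitigs), "unitigs tiling", nr, "reads\n")
})

#' @describeIn Layout-class the list of unitig tilings.
#' @param x a `Layout`.
#' @export
unitigs <- function(x) {
  stopifnot(is(x, "Layout"))
  x@unitigs
}
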