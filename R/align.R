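#' Banded global alignment
#'
#' Affine-gap global alignment of two sequences restricted to a band of
#' half-width `band` around the expected diagonal. A gap of length L costs
#' `gapOpen + L * gapExtend`. The edit script uses `=` (match), `X`
#' (mismatch), `I` (base only in `a`) and `D` (base only in `b`); `N`
#' mismatches every base including `N`. With `band >= max(nchar(a),
#' nchar(b))` the result equals unbanded global DP.
#'
#' @param a,b character(1) DNA sequences.
#' @param band band half-width in bases (>= 1).
#' @param match,mismatch,gapOpen,gapExtend scoring parameters; `gapOpen`
#'   and `gapExtend` are positive penalty magnitudes (defaults 2, -4, 4, 2).
#' @return list with `score`, `cigar` (run-length edit script), `touched`
#'   (TRUE if the optimal path hit the band boundary, suggesting a retry
#'   with a wider band), `nmatch` and `ncols`.
#' @examples
#' bandedGlobalAlign("ACGT", "ACGT", 50)$cigar  # "4="
#' @export
bandedGlobalAlign <- function(a, b, band, match = 2L, mismatch = -4L,
                              gapOpen = 4L, gapExtend = 2L) {
  r <- align_banded_cpp(as.character(a), as.character(b), as.integer(band),
                        0L, as.integer(match), as.integer(mismatch),
                        as.integer(gapOpen), as.integer(gapExtend))
  r[c("score", "cigar", "touched", "nmatch", "ncols")]
}

# concatenate run-length edit scripts, merging adjacent equal ops
catCigar <- function(parts) {
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) return("")
  lens <- integer(0); ops <- character(0)
  for (p in parts) {
    m <- gregexpr("\\d+[=XID]", p)[[1]]
    if (m[1] == -1L) next
    toks <- regmatches(p, gregexpr("\\d+[=XID]", p))[[1]]
    l <- as.integer(sub("[=XID]$", "", toks))
    o <- sub("^\\d+", "", toks)
    n <- length(lens)
    if (n > 0L && length(o) > 0L && ops[n] == o[1]) {
      lens[n] <- lens[n] + l[1]
      l <- l[-1]; o <- o[-1]
    }
    lens <- c(lens, l); ops <- c(ops, o)
  }
  paste0(lens, ops, collapse = "")
}

# parse an edit script into (lengths, ops)
parseCigar <- function(cigar) {
  if (!nzchar(cigar)) return(list(lens = integer(0), ops = character(0)))
  toks <- regmatches(cigar, gregexpr("\\d+[=XID]", cigar))[[1]]
  list(lens = as.integer(sub("[=XID]$", "", toks)),
       ops = sub("^\\d+", "", toks))
}

cigarStats <- function(cigar) {
  p <- parseCigar(cigar)
  qc <- sum(p$lens[p$ops %in% c("=", "X", "I")])
  tc <- sum(p$lens[p$ops %in% c("=", "X", "D")])
  list(nmatch = sum(p$lens[p$ops == "="]), ncols = sum(p$lens),
       qspan = qc, tspan = tc)
}

# smallest band in the doubling schedule bandMin, 2*bandMin, ..., bandMax
# that accommodates a length difference `diff` (plus slack)
scheduleBand <- function(diff, bandMin = 50L, bandMax = 3200L) {
  b <- bandMin
  while (b < diff + 16L && b < bandMax) b <- b * 2L
  min(b, bandMax)
}

# align raw segments between chained anchor waypoints and extend to the
# read ends; q/t are raw oriented sequences, waypoints are (qraw, traw)
# positions, strictly increasing, each a known-corresponding pair.
# Returns NULL or list(qstart, qend, tstart, tend, score, cigar, nmatch,
# ncols) in oriented coordinates.
alignChained <- function(q, t, waypoints, params) {
  nw <- nrow(waypoints)
  if (nw < 2L) return(NULL)
  segs <- character(nw + 1L)
  score <- 0L
  # interior segments
  for (i in seq_len(nw - 1L)) {
    qs <- waypoints[i, 1]; qe <- waypoints[i + 1L, 1]
    ts <- waypoints[i, 2]; te <- waypoints[i + 1L, 2]
    la <- qe - qs; lb <- te - ts
    if (la == 0L && lb == 0L) { segs[i + 1L] <- ""; next }
    band <- scheduleBand(abs(la - lb), params$bandMin, params$bandMax)
    band <- min(band, max(la, lb, 1L))
    r <- align_banded_cpp(substr(q, qs + 1L, qe), substr(t, ts + 1L, te),
                          band, 0L, params$match, params$mismatch,
                          params$gapOpen, params$gapExtend)
    while (isTRUE(r$touched) && band < params$bandMax &&
           band < max(la, lb)) {
      band <- min(band * 2L, params$bandMax)
      r <- align_banded_cpp(substr(q, qs + 1L, qe), substr(t, ts + 1L, te),
                            band, 0L, params$match, params$mismatch,
                            params$gapOpen, params$gapExtend)
    }
    segs[i + 1L] <- r$cigar
    score <- score + r$score
  }
  q0 <- waypoints[1, 1]; t0 <- waypoints[1, 2]
  qn <- waypoints[nw, 1]; tn <- waypoints[nw, 2]
  # left extension: reversed prefixes, stop when either end is reached;
  # the longer tail is truncated to the shorter plus the band (cells beyond
  # it cannot be on an optimal path to the boundary)
  qstart <- q0; tstart <- t0
  if (q0 > 0L && t0 > 0L) {
    la <- min(q0, t0 + params$endBand); lb <- min(t0, q0 + params$endBand)
    ra <- revString(substr(q, q0 - la + 1L, q0))
    rb <- revString(substr(t, t0 - lb + 1L, t0))
    r <- align_banded_cpp(ra, rb, params$endBand, 1L, params$match,
                          params$mismatch, params$gapOpen, params$gapExtend)
    segs[1L] <- revCigar(r$cigar)
    score <- score + r$score
    qstart <- q0 - r$aend; tstart <- t0 - r$bend
  }
  # right extension: suffixes, truncated the same way
  qend <- qn; tend <- tn
  nq <- nchar(q); nt <- nchar(t)
  if (qn < nq && tn < nt) {
    la <- min(nq - qn, (nt - tn) + params$endBand)
    lb <- min(nt - tn, (nq - qn) + params$endBand)
    r <- align_banded_cpp(substr(q, qn + 1L, qn + la),
                          substr(t, tn + 1L, tn + lb),
                          params$endBand, 1L, params$match,
                          params$mismatch, params$gapOpen, params$gapExtend)
    segs[nw + 1L] <- r$cigar
    score <- score + r$score
    qend <- qn + r$aend; tend <- tn + r$bend
  }
  cigar <- catCigar(segs)
  # soft-clip terminal negative-score stretches: the forced end extension
  # runs to a read end even when the sequence past a divergence point (a
  # chimeric junction, a bad-quality tail) no longer aligns; trimming the
  # score-negative ends leaves such alignments partial, ending where the
  # agreement ends
  tr <- trimCigarEnds(cigar, params)
  if (tr$ncols == 0L) return(NULL)
  qstart <- qstart + tr$qPre
  tstart <- tstart + tr$tPre
  qend <- qend - tr$qSuf
  tend <- tend - tr$tSuf
  list(qstart = qstart, qend = qend, tstart = tstart, tend = tend,
       score = tr$score, cigar = tr$cigar, nmatch = tr$nmatch,
       ncols = tr$ncols)
}

# remove the score-minimizing prefix and suffix of an edit script
# (affine gap runs scored as open + ext * len)
trimCigarEnds <- function(cigar, params) {
  p <- parseCigar(cigar)
  n <- length(p$ops)
  if (n == 0L)
    return(list(cigar = "", ncols = 0L, nmatch = 0L, score = 0L,
                qPre = 0L, tPre = 0L, qSuf = 0L, tSuf = 0L))
  runScore <- ifelse(p$ops == "=", params$match * p$lens,
              ifelse(p$ops == "X", params$mismatch * p$lens,
                     -(params$gapOpen + params$gapExtend * p$lens)))
  # trim the score-minimizing prefix, then the score-minimizing suffix of
  # what remains (run granularity). Only clearly divergent ends are cut:
  # ordinary 10-15% noise dips a terminal segment by a few points at most
  # (positive expected score per column), while sequence past a chimeric
  # junction or into a garbage tail scores ~-2 per column, so a drop
  # threshold separates the two regimes cleanly.
  drop <- -50
  pref <- c(0, cumsum(runScore))            # pref[k+1] = score of runs 1..k
  pre <- which.min(pref) - 1L
  if (pref[pre + 1L] >= drop) pre <- 0L
  i0 <- pre + 1L
  rest <- runScore[i0:n]
  sufc <- c(0, cumsum(rev(rest)))           # sufc[k+1] = score of last k runs
  suf <- which.min(sufc) - 1L
  if (sufc[suf + 1L] >= drop) suf <- 0L
  i1 <- n - suf
  if (i1 < i0)
    return(list(cigar = "", ncols = 0L, nmatch = 0L, score = 0L,
                qPre = 0L, tPre = 0L, qSuf = 0L, tSuf = 0L))
  spans <- function(idx) {
    if (length(idx) == 0L) return(c(0L, 0L))
    c(sum(p$lens[idx][p$ops[idx] %in% c("=", "X", "I")]),
      sum(p$lens[idx][p$ops[idx] %in% c("=", "X", "D")]))
  }
  preSp <- spans(seq_len(i0 - 1L))
  sufSp <- spans(if (i1 < n) (i1 + 1L):n else integer(0))
  keep <- i0:i1
  list(cigar = paste0(p$lens[keep], p$ops[keep], collapse = ""),
       ncols = sum(p$lens[keep]),
       nmatch = sum(p$lens[keep][p$ops[keep] == "="]),
       score = as.integer(sum(runScore[keep])),
       qPre = preSp[1], tPre = preSp[2], qSuf = sufSp[1], tSuf = sufSp[2])
}

revString <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")

revCigar <- function(cigar) {
  p <- parseCigar(cigar)
  n <- length(p$lens)
  if (n == 0L) return("")
  paste0(p$lens[n:1], p$ops[n:1], collapse = "")
}

# raw coordinate of an HPC position (0-based; p may equal the HPC length)
hpcPosToRaw <- function(hpc, p) {
  n <- length(hpc$offsets)
  ifelse(p >= n, hpc$rawlen, hpc$offsets[pmin(p, n - 1L) + 1L])
}

#' Align one read pair along a chained anchor backbone
#'
#' Runs the full per-pair overlap procedure: z-mer anchor extraction
#' between the HPC strings, window chaining ([chainQuery()]), then
#' piecewise banded alignment of the raw sequences using the chained
#' anchors as waypoints (dynamic band from the doubling schedule), with
#' both ends extended at band `endBand`. Returns NULL when no chain
#' passes the filters or the stitched identity falls below
#' `minOverlapIdentity`.
#'
#' @param qseq,tseq character(1) raw read sequences (forward strand).
#' @param strand "+" or "-": orientation of the target relative to the
#'   query.
#' @param params parameter list from [pipelineConfig()].
#' @return NULL or a one-row data.frame with qstart, qend, tstart, tend
#'   (forward-strand, 0-based half-open), matches, blockLen, score,
#'   identity and cigar (relative to the oriented target).
#' @export
alignReadPair <- function(qseq, tseq, strand = "+",
                          params = pipelineConfig()) {
  qh <- hpc_compress_cpp(qseq)[[1]]
  tor <- if (strand == "+") tseq else revcompChar(tseq)
  th <- hpc_compress_cpp(tor)[[1]]
  anchors <- extract_anchors_cpp(qh$hseq, th$hseq, params$zmerLength)
  ch <- chainQuery(anchors, params$windowSize, params$minWindowMatch,
                   params$minChainTotal)
  if (is.null(ch)) return(NULL)
  qh$rawlen <- nchar(qseq); th$rawlen <- nchar(tor)
  rec <- alignChainRaw(qseq, tor, qh, th, ch$anchors, params)
  if (is.null(rec)) return(NULL)
  if (strand == "-") {
    tl <- nchar(tseq)
    ts <- tl - rec$tend; te <- tl - rec$tstart
    rec$tstart <- ts; rec$tend <- te
  }
  rec$strand <- strand
  rec
}

# shared by alignReadPair and overlapReads: oriented-space alignment from
# HPC anchors; returns NULL or a one-row data.frame in oriented coords
alignChainRaw <- function(qseq, torseq, qh, th, anchors, params) {
  # waypoints: anchor starts thinned to ~256 HPC bases apart, plus the
  # final anchor end, mapped to raw coordinates
  keep <- c(TRUE, diff(anchors[, 1]) > 0)  # safety: strictly increasing
  anchors <- anchors[keep, , drop = FALSE]
  n <- nrow(anchors)
  sel <- logical(n); last <- -1e9
  for (i in seq_len(n)) {
    if (anchors[i, 1] >= last + 256L) { sel[i] <- TRUE; last <- anchors[i, 1] }
  }
  sel[1] <- TRUE
  wq <- anchors[sel, 1]; wt <- anchors[sel, 2]
  endQ <- anchors[n, 1] + anchors[n, 3]
  endT <- anchors[n, 2] + anchors[n, 3]
  if (endQ > wq[length(wq)]) { wq <- c(wq, endQ); wt <- c(wt, endT) }
  wp <- cbind(hpcPosToRaw(qh, wq), hpcPosToRaw(th, wt))
  wp <- wp[c(TRUE, diff(wp[, 1]) > 0 | diff(wp[, 2]) > 0), , drop = FALSE]
  r <- alignChained(qseq, torseq, wp, params)
  if (is.null(r) || r$ncols == 0L) return(NULL)
  identity <- r$nmatch / r$ncols
  if (identity < params$minOverlapIdentity) return(NULL)
  data.frame(qstart = r$qstart, qend = r$qend, tstart = r$tstart,
             tend = r$tend, matches = r$nmatch, blockLen = r$ncols,
             score = r$score, identity = identity, cigar = r$cigar,
             stringsAsFactors = FALSE)
}
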