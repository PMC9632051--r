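#' Per-read overlap pileup
#'
#' Tiles the overlap intervals of one read: per-base depth plus the
#' internal alignment termini ("spurs"). A terminus is internal when it is
#' more than `endMargin` bases from both read ends.
#'
#' @param readLength raw read length.
#' @param intervals data.frame with 0-based half-open `start`, `end`
#'   columns, one row per overlap interval on this read.
#' @param endMargin internal-terminus margin in bases (default 50).
#' @return list with `depth` (integer per-base), `termini` (all internal
#'   terminus positions, with multiplicity) and `spurs` (unique positions).
#' @export
buildPileup <- function(readLength, intervals, endMargin = 50L) {
  depth <- integer(readLength)
  if (nrow(intervals) > 0L) {
    cov <- coverage(IRanges(start = intervals$start + 1L,
                            end = intervals$end), width = readLength)
    depth <- as.integer(cov)
  }
  term <- c(intervals$start, intervals$end)
  term <- term[term > endMargin & term < readLength - endMargin]
  list(depth = depth, termini = sort(term), spurs = sort(unique(term)))
}

#' Clip read ends by overlap support
#'
#' The kept interval is the longest contiguous stretch with pileup depth
#' at least `minDepth`; NULL when no base qualifies.
#'
#' @param depth integer per-base depth (from [buildPileup()]).
#' @param minDepth minimum supporting depth (default 2).
#' @return integer(2) 0-based half-open kept interval, or NULL.
#' @export
clipEnds <- function(depth, minDepth = 2L) {
  ok <- depth >= minDepth
  if (!any(ok)) return(NULL)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  i <- which(r$values)
  best <- i[which.max(r$lengths[i])]
  c(starts[best], ends[best])
}

#' Classify a spur as chimeric junction or sequencing error
#'
#' Given the depth `m` of reads crossing the spur, the count `n` of reads
#' with partial alignments terminating there, and the average depth of the
#' read's overlap-graph component, the read is chimeric iff
#' `m < avgDepth/2` or `n > avgDepth` or `n > m/2`; otherwise the spur is
#' attributed to sequencing error and the maximum region is retained.
#'
#' @param m crossing depth at the spur.
#' @param n partial-alignment (terminus) count at the spur.
#' @param avgDepth average pileup depth (> 0).
#' @return "chimeric" or "sequencing_error".
#' @export
classifySpur <- function(m, n, avgDepth) {
  stopifnot(m >= 0, n >= 0, avgDepth > 0)
  if (m < avgDepth / 2 || n > avgDepth || n > m / 2) "chimeric"
  else "sequencing_error"
}

#' Detect chimeras from overlap-graph structure
#'
#' A read is flagged when it is a cut vertex of the overlap graph whose
#' removal splits its connected component into two or more components each
#' containing at least `minComponent` reads -- i.e. it is the only bridge
#' between two substantial subgraphs and no alternative path of valid
#' overlaps bypasses it.
#'
#' @param readIds integer vector of read ids (vertices).
#' @param edges data.frame with `qid`, `tid` columns (overlap pairs).
#' @param minComponent minimum size of each side (default 3).
#' @return integer vector of flagged read ids.
#' @export
graphChimeraCheck <- function(readIds, edges, minComponent = 3L) {
  if (length(readIds) == 0L || nrow(edges) == 0L) return(integer(0))
  g <- graph_from_data_frame(
    data.frame(from = as.character(edges$qid), to = as.character(edges$tid)),
    directed = FALSE, vertices = data.frame(name = as.character(readIds)))
  arts <- igraph::as_ids(articulation_points(g))
  flagged <- integer(0)
  for (v in arts) {
    g2 <- delete_vertices(g, v)
    comp <- components(g2)
    # components that came out of v's original component: v's neighbours
    nb <- igraph::as_ids(igraph::neighbors(g, v))
    sizes <- unique(comp$membership[nb])
    big <- sum(comp$csize[sizes] >= minComponent)
    if (big >= 2L) flagged <- c(flagged, as.integer(v))
  }
  sort(flagged)
}

# long table of per-read overlap intervals (both sides of every record)
overlapIntervals <- function(ov) {
  r <- ov@records
  data.frame(read = c(r$qid, r$tid),
             start = c(r$qstart, r$tstart),
             end = c(r$qend, r$tend),
             partner = c(r$tid, r$qid),
             rec = c(seq_len(nrow(r)), seq_len(nrow(r))))
}

# termini of partial alignments: alignment ends internal on BOTH reads.
# An overlap end sitting at the partner's own extremity is a complete
# alignment of that partner and carries no junction evidence.
partialTermini <- function(ov, margin) {
  r <- ov@records
  if (nrow(r) == 0L)
    return(data.frame(read = integer(0), pos = integer(0)))
  ql <- ov@readLengths[r$qid + 1L]
  tl <- ov@readLengths[r$tid + 1L]
  plus <- r$strand == "+"
  # the four alignment termini with their mate positions on the other read
  read <- c(r$qid, r$qid, r$tid, r$tid)
  pos <- c(r$qstart, r$qend, r$tstart, r$tend)
  mate <- c(ifelse(plus, r$tstart, r$tend), ifelse(plus, r$tend, r$tstart),
            ifelse(plus, r$qstart, r$qend), ifelse(plus, r$qend, r$qstart))
  mateLen <- c(tl, tl, ql, ql)
  selfLen <- c(ql, ql, tl, tl)
  keep <- pos > margin & pos < selfLen - margin &
          mate > margin & mate < mateLen - margin
  data.frame(read = read[keep], pos = pos[keep])
}

#' Trim and chimera-filter a read set
#'
#' The full trimming stage: per-read pileups are built from the overlap
#' intervals, low-support ends clipped ([clipEnds()]), spur clusters
#' classified ([classifySpur()]) against the component's average depth,
#' and graph-level chimeras removed ([graphChimeraCheck()]). Surviving
#' overlaps are clipped to the kept intervals (the partner side mapped
#' linearly through the alignment span) and dropped when their clipped
#' span falls below `minClippedSpan` on either read.
#'
#' @param reads a `DNAStringSet` or character vector of raw reads.
#' @param overlaps an [OverlapSet-class].
#' @param params parameter list from [pipelineConfig()] (uses
#'   `clipMinDepth`, `spurMargin`, `spurMinReads`, `minClippedSpan`).
#'   A terminus cluster is only treated as a spur structure when at least
#'   `spurMinReads` alignments terminate together, since isolated termini
#'   are the normal signature of dovetail overlap ends.
#' @return list with `trim` (data.frame readId, keptStart, keptEnd,
#'   chimeric, reason) and `overlaps` (clipped [OverlapSet-class];
#'   clipped records lose their edit script).
#' @export
trimReads <- function(reads, overlaps, params = pipelineConfig()) {
  lens <- if (is(reads, "DNAStringSet")) width(reads)
          else nchar(as.character(reads))
  n <- length(lens)
  iv <- overlapIntervals(overlaps)
  margin <- params$spurMargin
  kept <- matrix(NA_integer_, nrow = n, ncol = 2)
  reason <- rep("discarded_low_support", n)
  pileups <- vector("list", n)
  meanDepth <- numeric(n)
  for (i in seq_len(n)) {
    sub <- iv[iv$read == i - 1L, , drop = FALSE]
    p <- buildPileup(lens[i], sub, margin)
    pileups[[i]] <- p
    meanDepth[i] <- mean(p$depth)
    ke <- clipEnds(p$depth, params$clipMinDepth)
    if (is.null(ke)) next
    kept[i, ] <- ke
    reason[i] <- if (ke[1] == 0L && ke[2] == lens[i]) "clean" else "clipped"
  }
  # overlap-graph components (over reads that have overlaps)
  r <- overlaps@records
  comp <- rep(NA_integer_, n)
  if (nrow(r) > 0L) {
    g <- graph_from_data_frame(
      data.frame(from = as.character(r$qid), to = as.character(r$tid)),
      directed = FALSE,
      vertices = data.frame(name = as.character(seq_len(n) - 1L)))
    comp <- components(g)$membership[as.character(seq_len(n) - 1L)]
  }
  compAvg <- tapply(meanDepth, comp, mean)
  # spur classification inside kept intervals (partial-alignment termini:
  # internal on both reads of the overlap)
  pt <- partialTermini(overlaps, margin)
  for (i in seq_len(n)) {
    if (reason[i] == "discarded_low_support") next
    # spurs are sought over the whole raw read: a junction whose flanking
    # depth dips can fall just outside the kept interval after clipping
    lo <- margin; hi <- lens[i] - margin
    term <- sort(pt$pos[pt$read == i - 1L])
    term <- term[term > lo & term < hi]
    if (length(term) == 0L) next
    avg <- compAvg[[as.character(comp[i])]]
    if (is.null(avg) || is.na(avg) || avg <= 0) next
    # cluster termini within +/- margin
    cl <- cumsum(c(1L, diff(term) > margin))
    sub <- iv[iv$read == i - 1L, , drop = FALSE]
    for (k in unique(cl)) {
      nTerm <- sum(cl == k)
      # ordinary dovetail ends leave isolated termini all along a read; a
      # chimeric junction shows as a cluster of terminating alignments
      if (nTerm < params$spurMinReads) next
      pos <- round(median(term[cl == k]))
      mCross <- sum(sub$start <= pos - margin & sub$end >= pos + margin)
      if (classifySpur(mCross, nTerm, avg) == "chimeric") {
        reason[i] <- "spur_chimera"
        kept[i, ] <- NA_integer_
        break
      }
    }
  }
  # graph chimera check over surviving reads
  alive <- which(!is.na(kept[, 1]))
  er <- r[r$qid %in% (alive - 1L) & r$tid %in% (alive - 1L), , drop = FALSE]
  flagged <- graphChimeraCheck(alive - 1L, er)
  for (f in flagged) {
    reason[f + 1L] <- "graph_chimera"
    kept[f + 1L, ] <- NA_integer_
  }
  trim <- data.frame(readId = seq_len(n) - 1L,
                     keptStart = kept[, 1], keptEnd = kept[, 2],
                     chimeric = reason %in% c("spur_chimera", "graph_chimera"),
                     reason = reason, stringsAsFactors = FALSE)
  list(trim = trim,
       overlaps = clipOverlaps(overlaps, trim, params$minClippedSpan))
}

# clip overlap records to kept intervals; partner coordinates move
# linearly with the clipped fraction of the alignment span
clipOverlaps <- function(overlaps, trim, minSpan = 300L) {
  r <- overlaps@records
  if (nrow(r) == 0L) return(overlaps)
  ks <- trim$keptStart; ke <- trim$keptEnd
  keep <- !is.na(ks[r$qid + 1L]) & !is.na(ks[r$tid + 1L])
  r <- r[keep, , drop = FALSE]
  out <- r[0, ]
  if (nrow(r) > 0L) {
    rows <- vector("list", nrow(r))
    for (i in seq_len(nrow(r))) {
      x <- r[i, ]
      qs <- x$qstart; qe <- x$qend; ts <- x$tstart; te <- x$tend
      qspan <- qe - qs; tspan <- te - ts
      ratio <- tspan / qspan
      # clip query side to its kept interval
      nqs <- max(qs, ks[x$qid + 1L]); nqe <- min(qe, ke[x$qid + 1L])
      if (nqe - nqs < minSpan) next
      dl <- nqs - qs; dr <- qe - nqe
      if (x$strand == "+") {
        nts <- ts + round(dl * ratio); nte <- te - round(dr * ratio)
      } else {
        nts <- ts + round(dr * ratio); nte <- te - round(dl * ratio)
      }
      # clip target side to its kept interval, mapping back to the query
      cts <- max(nts, ks[x$tid + 1L]); cte <- min(nte, ke[x$tid + 1L])
      if (cte - cts < minSpan) next
      dtl <- cts - nts; dtr <- nte - cte
      if (x$strand == "+") {
        nqs <- nqs + round(dtl / ratio); nqe <- nqe - round(dtr / ratio)
      } else {
        nqs <- nqs + round(dtr / ratio); nqe <- nqe - round(dtl / ratio)
      }
      if (nqe - nqs < minSpan) next
      frac <- (nqe - nqs) / qspan
      x$qstart <- nqs; x$qend <- nqe; x$tstart <- cts; x$tend <- cte
      clipped <- frac < 0.999
      if (clipped) {
        x$matches <- as.integer(round(x$matches * frac))
        x$blockLen <- as.integer(round(x$blockLen * frac))
        x$score <- as.integer(round(x$score * frac))
        x$cigar <- NA_character_
      }
      rows[[i]] <- x
    }
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows)) out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  new("OverlapSet", records = out, readNames = overlaps@readNames,
      readLengths = overlaps@readLengths)
}
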