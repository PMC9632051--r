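#' Classify an overlap for the Best-Overlap-Graph
#'
#' An overlap is a dovetail when it runs end-to-end up to at most `slack`
#' unaligned bases at the joined end of each read; a read spanned to
#' within `slack` of both its own ends is contained. Anything else is
#' internal and excluded from the graph.
#'
#' @param qstart,qend,qlen,tstart,tend,tlen 0-based half-open intervals
#'   and lengths (coordinates on the forward strand of each read).
#' @param strand "+" or "-".
#' @param slack maximum unaligned overhang at a joined end (default 100).
#' @return list with `type` ("dovetail", "contained", "containing" or
#'   "internal") and, for dovetails, `qside`/`tside` (5 or 3: which end of
#'   each read is joined).
#' @export
classifyOverlap <- function(qstart, qend, qlen, tstart, tend, tlen,
                            strand = "+", slack = 100L) {
  ql <- qstart; qr <- qlen - qend
  tl <- tstart; tr <- tlen - tend
  qFull <- ql <= slack && qr <= slack
  tFull <- tl <= slack && tr <= slack
  if (qFull && tFull)
    return(list(type = if (qlen <= tlen) "contained" else "containing",
                qside = NA_integer_, tside = NA_integer_))
  if (qFull) return(list(type = "contained", qside = NA_integer_,
                         tside = NA_integer_))
  if (tFull) return(list(type = "containing", qside = NA_integer_,
                         tside = NA_integer_))
  if (strand == "+") {
    if (qr <= slack && tl <= slack)
      return(list(type = "dovetail", qside = 3L, tside = 5L))
    if (ql <= slack && tr <= slack)
      return(list(type = "dovetail", qside = 5L, tside = 3L))
  } else {
    if (qr <= slack && tr <= slack)
      return(list(type = "dovetail", qside = 3L, tside = 3L))
    if (ql <= slack && tl <= slack)
      return(list(type = "dovetail", qside = 5L, tside = 5L))
  }
  list(type = "internal", qside = NA_integer_, tside = NA_integer_)
}

#' Select near-best mutual edges per read end
#'
#' For every read end, the candidate set is the incident dovetail edges
#' whose score is at least `ratio` times the best score at that end; the
#' selected edge is the longest overlap in the set (ties: higher score,
#' then smaller partner id). An edge survives only if it is the selection
#' of both of its endpoints (mutual best). This keeps bubbles from being
#' merged while still preferring long near-best overlaps.
#'
#' @param edges data.frame with columns qid, tid, qside, tside, score,
#'   len (one row per dovetail overlap).
#' @param ratio near-best score ratio (default 0.95).
#' @return the edge table restricted to mutual-best edges.
#' @export
buildBestOverlapGraph <- function(edges, ratio = 0.95) {
  if (nrow(edges) == 0L) return(edges)
  endKey <- function(id, side) id * 2L + as.integer(side == 3L)
  keys <- c(endKey(edges$qid, edges$qside), endKey(edges$tid, edges$tside))
  eid <- rep(seq_len(nrow(edges)), 2L)
  partner <- c(edges$tid, edges$qid)
  sel <- integer(0)
  selected <- rep(FALSE, 2L * nrow(edges))
  for (k in unique(keys)) {
    at <- which(keys == k)
    sc <- edges$score[eid[at]]
    cand <- at[sc >= ratio * max(sc)]
    o <- order(-edges$len[eid[cand]], -edges$score[eid[cand]],
               partner[cand])
    selected[cand[o[1]]] <- TRUE
  }
  n <- nrow(edges)
  mutual <- selected[seq_len(n)] & selected[n + seq_len(n)]
  edges[mutual, , drop = FALSE]
}

#' Build unitigs from a Best-Overlap-Graph
#'
#' Unitigs are the maximal simple paths of the mutual-best edge set (each
#' read end carries at most one edge, so the graph is a union of paths and
#' rare cycles, which are broken at the smallest read id). Offsets
#' accumulate along the path from the overlap coordinates; contained reads
#' are inserted afterwards at their container's position without becoming
#' path nodes.
#'
#' @param nodes integer vector of path-node read ids.
#' @param bog mutual-best edge table from [buildBestOverlapGraph()] with
#'   additional per-edge oriented interval columns (see `layoutReads`).
#' @param lens trimmed read lengths indexed by read id + 1.
#' @return list of unitigs: `list(id, length, tiling)` with tiling columns
#'   readId, strand, offset (trimmed coordinates).
#' @export
buildUnitigs <- function(nodes, bog, lens) {
  edgeAt <- new.env(parent = emptyenv())
  setEdge <- function(id, side, e) assign(paste0(id, ".", side), e,
                                          envir = edgeAt)
  getEdge <- function(id, side) {
    k <- paste0(id, ".", side)
    if (exists(k, envir = edgeAt, inherits = FALSE))
      get(k, envir = edgeAt) else NULL
  }
  if (nrow(bog) > 0L) for (i in seq_len(nrow(bog))) {
    setEdge(bog$qid[i], bog$qside[i], i)
    setEdge(bog$tid[i], bog$tside[i], i)
  }
  visited <- new.env(parent = emptyenv())
  seen <- function(id) exists(as.character(id), envir = visited,
                              inherits = FALSE)
  mark <- function(id) assign(as.character(id), TRUE, envir = visited)

  walk <- function(start, startOrient) {
    rows <- list()
    cur <- start; orient <- startOrient; offset <- 0
    repeat {
      mark(cur)
      rows[[length(rows) + 1L]] <-
        data.frame(readId = cur, strand = orient, offset = offset,
                   stringsAsFactors = FALSE)
      exitSide <- if (orient == "+") 3L else 5L
      ei <- getEdge(cur, exitSide)
      if (is.null(ei)) break
      e <- bog[ei, ]
      if (e$qid == cur) {
        nxt <- e$tid; enterSide <- e$tside
        sCur <- orientedStart(e$qstart, e$qend, lens[cur + 1L], orient)
        nOrient <- if (enterSide == 5L) "+" else "-"
        sNxt <- orientedStart(e$tstart, e$tend, lens[nxt + 1L], nOrient)
      } else {
        nxt <- e$qid; enterSide <- e$qside
        sCur <- orientedStart(e$tstart, e$tend, lens[cur + 1L], orient)
        nOrient <- if (enterSide == 5L) "+" else "-"
        sNxt <- orientedStart(e$qstart, e$qend, lens[nxt + 1L], nOrient)
      }
      if (seen(nxt)) break
      offset <- offset + sCur - sNxt
      cur <- nxt; orient <- nOrient
    }
    do.call(rbind, rows)
  }

  unitigsList <- list()
  addUnitig <- function(tiling) {
    tiling$offset <- tiling$offset - min(tiling$offset)
    tiling <- tiling[order(tiling$offset, tiling$readId), , drop = FALSE]
    len <- max(tiling$offset + lens[tiling$readId + 1L])
    unitigsList[[length(unitigsList) + 1L]] <<-
      list(id = paste0("utg", length(unitigsList) + 1L),
           length = as.integer(len), tiling = tiling)
  }
  # paths from free ends (deterministic: ascending read id)
  for (id in nodes) {
    if (seen(id)) next
    free5 <- is.null(getEdge(id, 5L)); free3 <- is.null(getEdge(id, 3L))
    if (free5 && free3) addUnitig(walk(id, "+"))
    else if (free5) addUnitig(walk(id, "+"))
    else if (free3) addUnitig(walk(id, "-"))
  }
  # cycles: whatever is left
  for (id in nodes) if (!seen(id)) addUnitig(walk(id, "+"))
  unitigsList
}

orientedStart <- function(start, end, len, orient) {
  if (orient == "+") start else len - end
}

#' Drop unitigs redundantly covered by longer ones
#'
#' Sharing between a shorter unitig A and a longer unitig B is the
#' fraction of A's length covered by the union of A-side overlap
#' intervals of records pairing an A read with a B read, projected into
#' A's unitig coordinates; A is dropped when this exceeds `maxShared`.
#' Measuring the projected overlap intervals (rather than whole reads)
#' distinguishes a redundant island -- overlapped along its entire length
#' -- from a unitig that merely abuts B at a junction, which shares only
#' the boundary strip. Unitigs are processed in descending length order.
#'
#' @param unitigsList list of unitigs (as from [buildUnitigs()]).
#' @param records overlap record table (the full clipped set, in the same
#'   coordinate space as the tiling offsets).
#' @param lens trimmed read lengths by read id + 1.
#' @param maxShared maximum tolerated shared fraction (default 0.40).
#' @return the kept unitig list (original order preserved).
#' @export
filterRedundantUnitigs <- function(unitigsList, records, maxShared = 0.40,
                                   lens = NULL) {
  if (length(unitigsList) <= 1L) return(unitigsList)
  ulen <- vapply(unitigsList, function(u) u$length, 1L)
  ord <- order(-ulen)
  keptIdx <- integer(0)
  for (i in ord) {
    A <- unitigsList[[i]]
    tA <- A$tiling
    rowOf <- match(records$qid, tA$readId)
    rowOfT <- match(records$tid, tA$readId)
    drop <- FALSE
    for (j in keptIdx) {
      B <- unitigsList[[j]]
      inB <- c(B$tiling$readId)
      # records pairing an A read with a B read, with the A-side interval
      qSide <- !is.na(rowOf) & records$tid %in% inB
      tSide <- !is.na(rowOfT) & records$qid %in% inB
      if (!any(qSide) && !any(tSide)) next
      proj <- function(sel, rows, s, e) {
        if (!any(sel)) return(NULL)
        k <- rows[sel]
        La <- if (!is.null(lens)) lens[tA$readId[k] + 1L] else
          (tA$end[k] - tA$start[k])
        plus <- tA$strand[k] == "+"
        lo <- ifelse(plus, tA$offset[k] + s[sel],
                     tA$offset[k] + La - e[sel])
        hi <- ifelse(plus, tA$offset[k] + e[sel],
                     tA$offset[k] + La - s[sel])
        cbind(lo, hi)
      }
      iv <- rbind(proj(qSide, rowOf, records$qstart, records$qend),
                  proj(tSide, rowOfT, records$tstart, records$tend))
      iv <- iv[iv[, 2] > iv[, 1], , drop = FALSE]
      if (nrow(iv) == 0L) next
      shared <- sum(width(reduce(IRanges(start = iv[, 1] + 1L,
                                         end = iv[, 2]))))
      if (shared / A$length > maxShared) { drop <- TRUE; break }
    }
    if (!drop) keptIdx <- c(keptIdx, i)
  }
  unitigsList[sort(keptIdx)]
}

#' Lay out trimmed reads into unitigs
#'
#' The layout stage: classifies the clipped overlaps ([classifyOverlap()]),
#' builds the Best-Overlap-Graph over dovetail edges
#' ([buildBestOverlapGraph()]), forms unitigs as maximal simple paths
#' ([buildUnitigs()]), re-inserts contained reads at their container's
#' position, and drops redundant unitigs
#' ([filterRedundantUnitigs()]).
#'
#' @param overlaps the clipped [OverlapSet-class] from [trimReads()].
#' @param trim the trim table from [trimReads()].
#' @param params parameter list from [pipelineConfig()] (uses `laySlack`,
#'   `layRatio`, `layRedundancy`).
#' @return a [Layout-class]; tiling `start`/`end` columns give the kept
#'   raw-read interval, offsets are unitig coordinates.
#' @export
layoutReads <- function(overlaps, trim, params = pipelineConfig()) {
  ks <- trim$keptStart; ke <- trim$keptEnd
  lens <- ke - ks  # trimmed lengths (NA for discarded reads)
  r <- overlaps@records
  # shift into trimmed coordinates
  if (nrow(r) > 0L) {
    r$qstart <- r$qstart - ks[r$qid + 1L]; r$qend <- r$qend - ks[r$qid + 1L]
    r$tstart <- r$tstart - ks[r$tid + 1L]; r$tend <- r$tend - ks[r$tid + 1L]
    r$qstart <- pmax(r$qstart, 0L); r$tstart <- pmax(r$tstart, 0L)
    r$qend <- pmin(r$qend, lens[r$qid + 1L])
    r$tend <- pmin(r$tend, lens[r$tid + 1L])
  }
  # classify
  cls <- character(nrow(r)); qside <- integer(nrow(r)); tside <- integer(nrow(r))
  for (i in seq_len(nrow(r))) {
    cl <- classifyOverlap(r$qstart[i], r$qend[i], lens[r$qid[i] + 1L],
                          r$tstart[i], r$tend[i], lens[r$tid[i] + 1L],
                          r$strand[i], params$laySlack)
    cls[i] <- cl$type; qside[i] <- cl$qside; tside[i] <- cl$tside
  }
  containedIds <- sort(unique(c(r$qid[cls == "contained"],
                                r$tid[cls == "containing"])))
  alive <- trim$readId[!is.na(ks)]
  pathNodes <- setdiff(alive, containedIds)
  dv <- which(cls == "dovetail" &
              !(r$qid %in% containedIds) & !(r$tid %in% containedIds))
  edges <- cbind(r[dv, , drop = FALSE],
                 data.frame(qside = qside[dv], tside = tside[dv],
                            len = as.integer(round(((r$qend - r$qstart) +
                                  (r$tend - r$tstart))[dv] / 2))))
  bog <- buildBestOverlapGraph(edges, params$layRatio)
  unitigsList <- buildUnitigs(pathNodes, bog, lens)
  # place contained reads into their container's unitig
  readUnitig <- rep(NA_integer_, length(trim$readId))
  readRow <- rep(NA_integer_, length(trim$readId))
  for (ui in seq_along(unitigsList)) {
    t <- unitigsList[[ui]]$tiling
    readUnitig[t$readId + 1L] <- ui
    readRow[t$readId + 1L] <- seq_len(nrow(t))
  }
  contRec <- which(cls %in% c("contained", "containing"))
  if (length(contRec)) {
    # order by score so each contained read takes its best containment;
    # iterate so that containment chains (contained in a contained read)
    # resolve once their container has been placed
    contRec <- contRec[order(-r$score[contRec])]
    placed <- logical(length(trim$readId))
    repeat {
      progressed <- FALSE
      for (i in contRec) {
        if (cls[i] == "contained") {
          cid <- r$qid[i]; pid <- r$tid[i]
          cIv <- c(r$qstart[i], r$qend[i]); pIv <- c(r$tstart[i], r$tend[i])
        } else {
          cid <- r$tid[i]; pid <- r$qid[i]
          cIv <- c(r$tstart[i], r$tend[i]); pIv <- c(r$qstart[i], r$qend[i])
        }
        if (placed[cid + 1L] || !(cid %in% containedIds)) next
        ui <- readUnitig[pid + 1L]
        if (is.na(ui)) next
        t <- unitigsList[[ui]]$tiling
        prow <- t[readRow[pid + 1L], ]
        pOrient <- prow$strand
        cOrient <- if (r$strand[i] == "+") pOrient else flipStrand(pOrient)
        sP <- orientedStart(pIv[1], pIv[2], lens[pid + 1L], pOrient)
        sC <- orientedStart(cIv[1], cIv[2], lens[cid + 1L], cOrient)
        off <- prow$offset + sP - sC  # may precede the path start
        unitigsList[[ui]]$tiling <- rbind(t,
          data.frame(readId = cid, strand = cOrient,
                     offset = as.integer(off), stringsAsFactors = FALSE))
        readUnitig[cid + 1L] <- ui
        readRow[cid + 1L] <- nrow(unitigsList[[ui]]$tiling)
        placed[cid + 1L] <- TRUE
        progressed <- TRUE
      }
      if (!progressed) break
    }
    for (ui in seq_along(unitigsList)) {
      t <- unitigsList[[ui]]$tiling
      t$offset <- t$offset - min(t$offset)
      t <- t[order(t$offset, t$readId), , drop = FALSE]
      unitigsList[[ui]]$tiling <- t
      unitigsList[[ui]]$length <-
        as.integer(max(t$offset + lens[t$readId + 1L]))
    }
  }
  # merge path-break fragments before the redundancy filter: for long
  # reads the adjacency strip of a short neighbouring unitig can exceed
  # the redundancy fraction, and a genuine island never merges because its
  # implied placement is internal
  unitigsList <- mergeLinkedUnitigs(unitigsList, r, lens)
  unitigsList <- filterRedundantUnitigs(unitigsList, r,
                                        params$layRedundancy, lens)
  # renumber and attach the kept raw intervals
  for (ui in seq_along(unitigsList)) {
    unitigsList[[ui]]$id <- paste0("utg", ui)
    t <- unitigsList[[ui]]$tiling
    t$start <- ks[t$readId + 1L]
    t$end <- ke[t$readId + 1L]
    rownames(t) <- NULL
    unitigsList[[ui]]$tiling <- t
  }
  if (isTRUE(params$extendTerminalReads))
    unitigsList <- extendTerminalReads(unitigsList,
                                       overlaps@readLengths)
  new("Layout", unitigs = unitigsList, readNames = overlaps@readNames,
      readLengths = overlaps@readLengths)
}

# Join unitigs connected by consistent overlap records. A path break (one
# missing mutual-best edge) splits a tiling into two adjacent unitigs that
# still share many overlaps across the junction; requiring >= minLinks
# link records that agree on the implied placement within `tol` bases
# makes the join robust against spurious single overlaps.
mergeLinkedUnitigs <- function(unitigsList, records, lens,
                               minLinks = 3L, tol = 300L) {
  if (length(unitigsList) <= 1L || nrow(records) == 0L) return(unitigsList)
  repeat {
    merged <- FALSE
    nU <- length(unitigsList)
    readU <- integer(0); readRow <- integer(0)
    whereU <- new.env(parent = emptyenv())
    for (ui in seq_len(nU)) {
      t <- unitigsList[[ui]]$tiling
      for (k in seq_len(nrow(t)))
        assign(as.character(t$readId[k]), c(ui, k), envir = whereU)
    }
    lookup <- function(id) {
      k <- as.character(id)
      if (exists(k, envir = whereU, inherits = FALSE))
        get(k, envir = whereU) else NULL
    }
    for (i in seq_len(nrow(records))) {
      la <- lookup(records$qid[i]); lb <- lookup(records$tid[i])
      if (is.null(la) || is.null(lb) || la[1] == lb[1]) next
      A <- unitigsList[[la[1]]]; B <- unitigsList[[lb[1]]]
      # collect all records linking these two unitigs and their implied
      # shifts of B onto A's coordinates
      sh <- linkShifts(A, B, records, lens)
      if (is.null(sh)) next
      for (flip in c(FALSE, TRUE)) {
        s <- sh$shift[sh$flip == flip]
        if (length(s) < minLinks) next
        med <- median(s)
        ok <- abs(s - med) <= tol
        if (sum(ok) < minLinks) next
        shift <- round(median(s[ok]))
        # only join when B extends A (not an internal duplicate)
        if (shift > -200L && shift + B$length < A$length + 200L) next
        tB <- B$tiling
        if (flip) {
          tB$strand <- flipStrand(tB$strand)
          tB$offset <- B$length - (tB$offset + lens[tB$readId + 1L])
        }
        tB$offset <- tB$offset + shift
        t <- rbind(A$tiling, tB)
        t$offset <- t$offset - min(t$offset)
        t <- t[order(t$offset, t$readId), , drop = FALSE]
        A$tiling <- t
        A$length <- as.integer(max(t$offset + lens[t$readId + 1L]))
        unitigsList[[la[1]]] <- A
        unitigsList[[lb[1]]] <- NULL
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) break
  }
  unitigsList
}

# implied placements of unitig B onto unitig A's coordinates, one row per
# overlap record connecting a read of A with a read of B
linkShifts <- function(A, B, records, lens) {
  rowA <- match(records$qid, A$tiling$readId)
  rowB <- match(records$tid, B$tiling$readId)
  rowA2 <- match(records$tid, A$tiling$readId)
  rowB2 <- match(records$qid, B$tiling$readId)
  sel1 <- which(!is.na(rowA) & !is.na(rowB))
  sel2 <- which(!is.na(rowA2) & !is.na(rowB2))
  one <- function(i, aRow, bRow, aIsQuery) {
    ta <- A$tiling[aRow, ]; tb <- B$tiling[bRow, ]
    if (aIsQuery) {
      aIv <- c(records$qstart[i], records$qend[i])
      bIv <- c(records$tstart[i], records$tend[i])
    } else {
      aIv <- c(records$tstart[i], records$tend[i])
      bIv <- c(records$qstart[i], records$qend[i])
    }
    la <- lens[ta$readId + 1L]; lb <- lens[tb$readId + 1L]
    # implied orientation of b's read in A coordinates
    obImpl <- if (records$strand[i] == "+") ta$strand else
      flipStrand(ta$strand)
    sA <- orientedStart(aIv[1], aIv[2], la, ta$strand)
    sB <- orientedStart(bIv[1], bIv[2], lb, obImpl)
    offImpl <- ta$offset + sA - sB  # b's implied offset in A coords
    flip <- obImpl != tb$strand
    offInB <- if (!flip) tb$offset else
      B$length - (tb$offset + lb)
    c(shift = offImpl - offInB, flip = as.integer(flip))
  }
  rows <- c(lapply(sel1, function(i) one(i, rowA[i], rowB[i], TRUE)),
            lapply(sel2, function(i) one(i, rowA2[i], rowB2[i], FALSE)))
  if (length(rows) == 0L) return(NULL)
  m <- do.call(rbind, rows)
  list(shift = m[, 1], flip = m[, 2] == 1L)
}

# extend the outermost tiling read of each unitig end to its full raw
# extent: end clipping protects junctions, but at a contig terminus the
# outer tail of the terminal read is the only observation of that part of
# the genome and standard OLC practice keeps it
extendTerminalReads <- function(unitigsList, rawLens) {
  for (ui in seq_along(unitigsList)) {
    t <- unitigsList[[ui]]$tiling
    len <- t$end - t$start
    # outward raw tail of each read, toward each unitig end
    outLeft <- ifelse(t$strand == "+", t$start,
                      rawLens[t$readId + 1L] - t$end)
    outRight <- ifelse(t$strand == "+", rawLens[t$readId + 1L] - t$end,
                       t$start)
    # the terminal read is the one whose raw extent reaches furthest out
    iFirst <- which.min(t$offset - outLeft)
    iLast <- which.max(t$offset + len + outRight)
    dFirst <- outLeft[iFirst]
    if (t$strand[iFirst] == "+") t$start[iFirst] <- 0L
    else t$end[iFirst] <- rawLens[t$readId[iFirst] + 1L]
    if (dFirst > 0L) {
      t$offset <- t$offset + dFirst
      t$offset[iFirst] <- t$offset[iFirst] - dFirst
    }
    if (t$strand[iLast] == "+") t$end[iLast] <- rawLens[t$readId[iLast] + 1L]
    else t$start[iLast] <- 0L
    t <- t[order(t$offset, t$readId), , drop = FALSE]
    rownames(t) <- NULL
    unitigsList[[ui]]$tiling <- t
    unitigsList[[ui]]$length <-
      as.integer(max(t$offset + (t$end - t$start)))
  }
  unitigsList
}

flipStrand <- function(s) ifelse(s == "+", "-", "+")
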