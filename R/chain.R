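#' Exact z-mer anchors between two HPC strings
#'
#' All maximal exact match runs of length >= `z` between the query and the
#' (already oriented) target HPC string, as a matrix of 0-based
#' (qpos, tpos, len) rows sorted by query position. For a minus-strand
#' comparison pass the reverse-complemented target HPC string.
#'
#' @param query,target character HPC strings (or [HPCRead-class] objects).
#' @param z z-mer length (default 10; must be shorter than the index k).
#' @return integer matrix with columns qpos, tpos, len.
#' @export
extractAnchors <- function(query, target, z = 10L) {
  qh <- if (is(query, "HPCRead")) query@hseq else as.character(query)
  th <- if (is(target, "HPCRead")) target@hseq else as.character(target)
  extract_anchors_cpp(qh, th, as.integer(z))
}

#' Best syntenic block of anchors within a window
#'
#' Greedy left-to-right chain over anchors sorted by query position using
#' the recurrence S[1] = L[1], S[i+1] = S[i] + L[i+1] - Distance(i, i+1),
#' where Distance = |(tpos[i+1] - tpos[i]) - (qpos[i+1] - qpos[i])| is the
#' collinearity drift between adjacent seeds: how far the candidate-side
#' spacing deviates from the query-side spacing. Indels between two noisy
#' reads make raw seed spacing highly variable, so drift -- not spacing --
#' is what is scored; off-diagonal jumps pay their full magnitude.
#' When S[i+1] would fall below L[i+1] the block is closed and the
#' score restarts at L[i+1]. The returned block is the contiguous anchor
#' run attaining the highest score (ties: earliest end, then earliest
#' start), which coincides with the best block under exhaustive enumeration
#' of all contiguous runs.
#'
#' @param anchors integer matrix (qpos, tpos, len) sorted by qpos, all one
#'   strand.
#' @return list with `start`, `end` (1-based anchor indices, inclusive;
#'   0 if no anchors) and `score`.
#' @export
chainAnchors <- function(anchors) {
  stopifnot(is.matrix(anchors), ncol(anchors) == 3L)
  chain_anchors_cpp(as.integer(anchors[, 1]), as.integer(anchors[, 2]),
                    as.integer(anchors[, 3]))
}

# best chained block among a window's anchors, restricted to near-collinear
# diagonal groups: anchors are binned by diagonal (qpos - tpos, bin width
# `diagBin`), each group of three adjacent bins is chained with the block
# recurrence, and the highest-scoring block wins. Random spurious z-mer
# matches land on scattered diagonals and would otherwise interrupt the
# greedy chain of the true (indel-jittered) diagonal run.
bestDiagonalBlock <- function(a, diagBin = 64L) {
  if (nrow(a) == 0L) return(NULL)
  diag <- a[, 1] - a[, 2]
  bin <- diag %/% diagBin
  best <- NULL; bestScore <- -Inf
  for (b in sort(unique(bin))) {
    grp <- a[bin >= b - 1L & bin <= b + 1L, , drop = FALSE]
    grp <- grp[order(grp[, 1], grp[, 2]), , drop = FALSE]
    ch <- chain_anchors_cpp(grp[, 1], grp[, 2], grp[, 3])
    if (ch$start == 0L) next
    if (ch$score > bestScore) {
      bestScore <- ch$score
      best <- grp[ch$start:ch$end, , drop = FALSE]
    }
  }
  best
}

# union length of [qpos, qpos+len) intervals (anchors within one window)
anchorQueryCoverage <- function(anchors) {
  if (nrow(anchors) == 0L) return(0L)
  o <- order(anchors[, 1])
  s <- anchors[o, 1]; e <- anchors[o, 1] + anchors[o, 3]
  cov <- 0L; cs <- s[1]; ce <- e[1]
  if (length(s) > 1L) for (i in 2:length(s)) {
    if (s[i] <= ce) ce <- max(ce, e[i])
    else { cov <- cov + (ce - cs); cs <- s[i]; ce <- e[i] }
  }
  cov + (ce - cs)
}

#' Window-chained collinear backbone between a query and a candidate
#'
#' The query's HPC coordinates are tiled into consecutive windows of
#' `windowSize` bases. Anchors falling in each window are grouped by
#' diagonal (so that scattered spurious matches cannot interrupt the
#' indel-jittered collinear run) and the best group is chained with the
#' block recurrence of [chainAnchors()]; windows whose best block covers
#' fewer than
#' `minWindowMatch` query bases are discarded. Surviving windows, each
#' summarized as a super-anchor (position = block span start, length =
#' matched bases), are chained again with the same recurrence, and the
#' result is kept only if the selected windows' matched bases total more
#' than `minChainTotal`.
#'
#' @param anchors integer matrix from [extractAnchors()] (query vs oriented
#'   target).
#' @param windowSize query window size in HPC bases (default 800).
#' @param minWindowMatch minimum matched bases for a window to survive
#'   (default 200).
#' @param minChainTotal minimum total matched bases over the selected
#'   window chain (default 300, strict).
#' @return NULL if no chain passes the filters, else a list with
#'   `anchors` (the ordered, collinearity-trimmed anchor matrix),
#'   `total` (matched query bases) and `windows` (number of windows kept).
#' @export
chainQuery <- function(anchors, windowSize = 800L, minWindowMatch = 200,
                       minChainTotal = 300) {
  if (is.null(anchors) || nrow(anchors) == 0L) return(NULL)
  r <- chain_query_cpp(anchors, as.integer(windowSize), minWindowMatch,
                       minChainTotal, 64L)
  if (!isTRUE(r$ok)) return(NULL)
  list(anchors = r$anchors, total = r$total, windows = r$windows)
}

# reference R implementation of the window-chaining pass; the exported
# chainQuery runs the equivalent native code (equivalence is property-tested)
chainQueryR <- function(anchors, windowSize = 800L, minWindowMatch = 200,
                        minChainTotal = 300) {
  if (is.null(anchors) || nrow(anchors) == 0L) return(NULL)
  win <- anchors[, 1] %/% as.integer(windowSize)
  keptBlocks <- list()
  for (w in sort(unique(win))) {
    a <- anchors[win == w, , drop = FALSE]
    blk <- bestDiagonalBlock(a)
    if (is.null(blk)) next
    matched <- anchorQueryCoverage(blk)
    if (matched < minWindowMatch) next
    keptBlocks[[length(keptBlocks) + 1L]] <-
      list(anchors = blk, matched = matched,
           qpos = min(blk[, 1]), tpos = min(blk[, 2]))
  }
  if (length(keptBlocks) == 0L) return(NULL)
  qp <- vapply(keptBlocks, function(b) b$qpos, 1)
  tp <- vapply(keptBlocks, function(b) b$tpos, 1)
  ln <- vapply(keptBlocks, function(b) b$matched, 1)
  o <- order(qp)
  sel <- chain_anchors_cpp(as.integer(qp[o]), as.integer(tp[o]),
                           as.integer(ln[o]))
  chosen <- o[sel$start:sel$end]
  total <- sum(ln[chosen])
  if (total <= minChainTotal) return(NULL)
  merged <- do.call(rbind, lapply(keptBlocks[chosen], `[[`, "anchors"))
  # enforce joint monotonicity across windows: trim or drop anchors that
  # step backwards on either read (anchors are exact matches, so trimming
  # the start of one keeps it exact)
  out <- matrix(0L, nrow = nrow(merged), ncol = 3)
  nOut <- 0L; lastQ <- -1L; lastT <- -1L
  for (i in seq_len(nrow(merged))) {
    q <- merged[i, 1]; t <- merged[i, 2]; l <- merged[i, 3]
    d <- max(lastQ - q, lastT - t, 0L)
    if (l - d <= 0L) next
    q <- q + d; t <- t + d; l <- l - d
    nOut <- nOut + 1L
    out[nOut, ] <- c(q, t, l)
    lastQ <- q + l; lastT <- t + l
  }
  if (nOut == 0L) return(NULL)
  out <- out[seq_len(nOut), , drop = FALSE]
  colnames(out) <- c("qpos", "tpos", "len")
  list(anchors = out, total = total, windows = length(chosen))
}
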