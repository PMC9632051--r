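test_that("overlap classification separates dovetail, containment, internal", {
  # perfect suffix-prefix overlap
  d <- classifyOverlap(2000, 5000, 5000, 0, 3000, 6000, "+", 100)
  expect_equal(d$type, "dovetail")
  expect_equal(c(d$qside, d$tside), c(3L, 5L))
  # 150 bases unaligned on both joined ends
  i <- classifyOverlap(2000, 4850, 5000, 150, 3000, 6000, "+", 100)
  expect_equal(i$type, "internal")
  # query spanned to within 20 bases of both its ends
  ct <- classifyOverlap(20, 4980, 5000, 500, 5480, 8000, "+", 100)
  expect_equal(ct$type, "contained")
  # minus-strand dovetail joins like ends
  m <- classifyOverlap(2000, 5000, 5000, 3000, 5950, 6000, "-", 100)
  expect_equal(m$type, "dovetail")
  expect_equal(c(m$qside, m$tside), c(3L, 3L))
})

test_that("near-best selection prefers the longest edge in the ratio set", {
  edges <- data.frame(qid = c(0L, 0L), tid = c(1L, 2L),
                      qside = c(3L, 3L), tside = c(5L, 5L),
                      score = c(100, 96), len = c(3000L, 4000L))
  kept <- buildBestOverlapGraph(edges, ratio = 0.95)
  expect_equal(kept$tid, 2L)  # longer overlap within 95% of best score
  edges2 <- data.frame(qid = c(0L, 0L), tid = c(1L, 2L),
                       qside = c(3L, 3L), tside = c(5L, 5L),
                       score = c(100, 90), len = c(3000L, 4000L))
  kept2 <- buildBestOverlapGraph(edges2, ratio = 0.95)
  expect_equal(kept2$tid, 1L)  # 90 falls out of the candidate set
})

test_that("mutual-best selection leaves at most one edge per read end", {
  set.seed(51)
  for (rep in 1:10) {
    n <- 12L
    e <- data.frame(qid = sample(0:(n - 1), 30, TRUE),
                    tid = sample(0:(n - 1), 30, TRUE),
                    qside = sample(c(5L, 3L), 30, TRUE),
                    tside = sample(c(5L, 3L), 30, TRUE),
                    score = sample(50:100, 30, TRUE),
                    len = sample(1000:4000, 30, TRUE))
    e <- e[e$qid != e$tid, ]
    kept <- buildBestOverlapGraph(e, 0.95)
    ends <- c(paste(kept$qid, kept$qside), paste(kept$tid, kept$tside))
    expect_false(any(duplicated(ends)))
  }
})

test_that("an error-free tiling reconstructs the true read order", {
  d <- smallClean()
  tr <- trimReads(d$reads, d$ov)
  lay <- layoutReads(tr$overlaps, tr$trim)
  expect_equal(length(unitigs(lay)), 1L)
  t <- unitigs(lay)[[1]]$tiling
  expect_true(all(diff(t$offset) >= 0))
  # the unitig-left end of each read is its truth start on a forward
  # tiling and its truth end on a reversed one; order must match one of
  # the two (reconstruction up to global reversal)
  tauF <- cor(t$offset, d$truth$start[t$readId + 1L], method = "kendall")
  tauR <- cor(t$offset, -d$truth$end[t$readId + 1L], method = "kendall")
  expect_gte(max(tauF, tauR), 0.98)
  # orientation consistent with truth up to global flip
  flip <- t$strand != d$truth$strand[t$readId + 1L]
  expect_true(all(flip) || all(!flip))
  # every read in at most one unitig
  ids <- unlist(lapply(unitigs(lay), function(u) u$tiling$readId))
  expect_false(any(duplicated(ids)))
})

test_that("redundant unitigs are dropped by shared-read coverage", {
  mkU <- function(id, ids, len) list(id = id, length = len,
    tiling = data.frame(readId = ids, strand = "+",
                        offset = seq(0L, by = 1000L,
                                     length.out = length(ids)),
                        start = 0L, end = 1500L))
  mkRec <- function(qid, tid) data.frame(qid = qid, tid = tid,
    strand = "+", qstart = 0L, qend = 1500L, tstart = 0L, tend = 1500L)
  lensAll <- rep(1500L, 60)
  # duplicate unitig (same reads): shorter dropped
  u1 <- mkU("a", 0:9, 10000L); u2 <- mkU("b", 0:9, 9000L)
  recs <- mkRec(0:8, 1:9)
  kept <- filterRedundantUnitigs(list(u1, u2), recs, 0.40, lensAll)
  expect_equal(vapply(kept, `[[`, "", "id"), "a")
  # disjoint regions, no cross overlaps: both kept
  u3 <- mkU("c", 10:19, 10000L)
  kept2 <- filterRedundantUnitigs(list(u1, u3), recs, 0.40, lensAll)
  expect_equal(length(kept2), 2L)
  # 5 of 10 reads fully overlapped by a 40-read unitig: 55% > 40% -> dropped
  big <- mkU("big", 20:59, 40000L)
  small <- mkU("small", 0:9, 10000L)
  cross <- mkRec(0:4, 20:24)
  kept3 <- filterRedundantUnitigs(list(big, small), cross, 0.40, lensAll)
  expect_equal(vapply(kept3, `[[`, "", "id"), "big")
})
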