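test_that("pileups count depth and record internal termini", {
  iv <- data.frame(start = rep(0L, 4), end = rep(1000L, 4))
  p <- buildPileup(1000L, iv)
  expect_true(all(p$depth == 4L))
  expect_equal(length(p$spurs), 0L)

  iv2 <- data.frame(start = c(0L, 0L), end = c(1000L, 500L))
  p2 <- buildPileup(1000L, iv2)
  expect_equal(p2$spurs, 500L)
  expect_equal(p2$depth[499:502], c(2L, 2L, 1L, 1L))

  p3 <- buildPileup(800L, iv2[0, ])
  expect_true(all(p3$depth == 0L))
})

test_that("end clipping keeps the longest supported stretch", {
  depth <- c(rep(0L, 100), rep(3L, 500), rep(0L, 100))
  expect_equal(clipEnds(depth, 2L), c(100L, 600L))
  expect_equal(clipEnds(rep(5L, 300), 2L), c(0L, 300L))
  expect_null(clipEnds(rep(1L, 300), 2L))
  # two supported stretches: longest wins
  d2 <- c(rep(3L, 50), rep(0L, 10), rep(3L, 200))
  expect_equal(clipEnds(d2, 2L), c(60L, 260L))
})

test_that("spur classification reproduces the three chimera predicates", {
  expect_equal(classifySpur(4, 0, 10), "chimeric")          # m < avg/2
  expect_equal(classifySpur(10, 12, 10), "chimeric")        # n > avg
  expect_equal(classifySpur(10, 6, 10), "chimeric")         # n > m/2
  expect_equal(classifySpur(10, 3, 10), "sequencing_error")
  for (avg in c(4, 10, 20)) {
    for (m in 0:30) for (n in 0:30) {
      want <- if (m < avg / 2 || n > avg || n > m / 2) "chimeric"
              else "sequencing_error"
      expect_identical(classifySpur(m, n, avg), want)
    }
  }
})

test_that("graph chimera check flags bridges between substantial subgraphs", {
  clusterEdges <- function(ids) {
    do.call(rbind, lapply(ids, function(i) {
      p <- ids[ids > i]
      if (length(p) == 0L) NULL else data.frame(qid = i, tid = p)
    }))
  }
  a <- 0:9; b <- 11:20; bridge <- 10L
  # the chimera overlaps two reads on each side, so no cluster member is
  # itself a bridge, but removing the chimera still severs the clusters
  edges <- rbind(clusterEdges(a), clusterEdges(b),
                 data.frame(qid = c(4L, 5L, bridge, bridge),
                            tid = c(bridge, bridge, 15L, 16L)))
  flagged <- graphChimeraCheck(0:20, edges)
  expect_equal(flagged, bridge)

  # a cycle has no cut vertex
  cyc <- data.frame(qid = 0:5, tid = c(1:5, 0L))
  expect_equal(length(graphChimeraCheck(0:5, cyc)), 0L)

  # a linear tiling at >= 2x overlap density is chordal: every interior
  # read is bypassed by the direct overlap of its two neighbours
  tilingGraph <- rbind(data.frame(qid = 0:8, tid = 1:9),
                       data.frame(qid = 0:7, tid = 2:9))
  expect_equal(length(graphChimeraCheck(0:9, tilingGraph)), 0L)
})

test_that("an empty overlap set discards every read", {
  reads <- Biostrings::DNAStringSet(c(a = randSeq(600), b = randSeq(700)))
  ov <- new("OverlapSet", records = lrasm:::emptyOverlapRecords(),
            readNames = names(reads), readLengths = Biostrings::width(reads))
  tr <- trimReads(reads, ov)
  expect_true(all(tr$trim$reason == "discarded_low_support"))
  expect_true(all(is.na(tr$trim$keptStart)))
  expect_equal(nrow(overlapRecords(tr$overlaps)), 0L)
})

test_that("clean data passes trimming essentially untouched", {
  d <- smallClean()
  tr <- trimReads(d$reads, d$ov)
  frac <- mean(tr$trim$reason %in% c("clean", "clipped"))
  expect_gte(frac, 0.95)
  expect_equal(sum(tr$trim$chimeric), 0L)
  # kept intervals never grow and reprojected overlaps stay valid
  expect_true(all(tr$trim$keptStart >= 0L, na.rm = TRUE))
  w <- Biostrings::width(d$reads)
  expect_true(all(tr$trim$keptEnd <= w[tr$trim$readId + 1L], na.rm = TRUE))
  expect_s4_class(tr$overlaps, "OverlapSet")
  validObject(tr$overlaps)
})
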