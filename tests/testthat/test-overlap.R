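test_that("an error-free dovetail pair aligns at identity 1 with exact coordinates", {
  set.seed(41)
  genome <- randSeq(6000)
  q <- substr(genome, 1, 4000)
  t <- substr(genome, 1001, 6000)  # 3 kb true overlap
  rec <- alignReadPair(q, t, "+")
  expect_false(is.null(rec))
  expect_equal(rec$identity, 1.0)
  expect_lte(abs(rec$qstart - 1000), 2)
  expect_equal(rec$qend, 4000)
  expect_equal(rec$tstart, 0)
  expect_lte(abs(rec$tend - 3000), 2)
})

test_that("minus-strand overlaps come back in forward-target coordinates", {
  set.seed(42)
  genome <- randSeq(6000)
  q <- substr(genome, 1, 4000)
  t <- lrasm:::revcompChar(substr(genome, 1001, 6000))
  rec <- alignReadPair(q, t, "-")
  expect_false(is.null(rec))
  expect_equal(rec$identity, 1.0)
  expect_lte(abs(rec$qstart - 1000), 2)
  # overlap sits at the 3' end of the forward target
  expect_lte(abs(rec$tstart - 2000), 2)
  expect_equal(rec$tend, 5000)
})

test_that("a noisy pair recovers the true overlap interval", {
  set.seed(43)
  cfg <- simConfig(seed = 43L)  # 12% error profile
  genome <- randSeq(8000)
  q <- lrasm:::mutateRead(substr(genome, 1, 5000), cfg)
  t <- lrasm:::mutateRead(substr(genome, 2001, 8000), cfg)
  rec <- alignReadPair(q, t, "+")
  expect_false(is.null(rec))
  expect_gte(rec$identity, 0.75)
  # true overlap on q: ~[2000, 5000] up to indel drift
  expect_lte(abs(rec$qstart - 2000), 100)
  expect_lte(abs(rec$qend - nchar(q)), 100)
  expect_lte(rec$tstart, 100)
})

test_that("overlap discovery reports each true adjacent pair exactly once", {
  set.seed(44)
  genome <- randSeq(9000)
  reads <- c(a = substr(genome, 1, 4000),
             b = substr(genome, 3001, 7000),
             c = substr(genome, 6001, 9000))
  ov <- overlapReads(Biostrings::DNAStringSet(reads))
  r <- overlapRecords(ov)
  pairs <- sort(paste(r$qid, r$tid))
  expect_equal(pairs, c("0 1", "1 2"))
  expect_true(all(r$qid < r$tid))
  # the forced end extension may consume a couple of leftover columns at
  # the dovetail boundary, so identity is near-exact rather than exact
  expect_true(all(r$identity >= 0.99))
  expect_true(all(abs(r$matches - 1000) <= 5))
  # single read -> no overlaps
  ov1 <- overlapReads(Biostrings::DNAStringSet(c(x = randSeq(2000))))
  expect_equal(nrow(overlapRecords(ov1)), 0L)
})

test_that("overlap roles are symmetric between query and target", {
  set.seed(45)
  genome <- randSeq(6000)
  A <- substr(genome, 1, 4000)
  B <- substr(genome, 1501, 6000)
  ab <- alignReadPair(A, B, "+")
  ba <- alignReadPair(B, A, "+")
  expect_false(is.null(ab)); expect_false(is.null(ba))
  expect_lte(abs(ab$qstart - ba$tstart), 5)
  expect_lte(abs(ab$tend - ba$qend), 5)
  expect_equal(ab$strand, ba$strand)
  expect_lte(abs(ab$matches - ba$matches) / ab$matches, 0.01)
})

test_that("raising a region's depth never raises weighted coverage", {
  set.seed(46)
  base <- randSeq(1200)
  probe <- paste0(randSeq(200), substr(base, 101, 900), randSeq(200))
  mkIdx <- function(extra) {
    tgts <- c(base, vapply(seq_len(extra), function(i)
      paste0(randSeq(50), substr(base, 101, 900), randSeq(50)), ""))
    buildKmerIndex(tgts, k = 16L, subsampleDenominator = 1L)
  }
  wcovOfBase <- function(extra) {
    res <- findCandidates(mkIdx(extra), probe, queryId = -1L,
                          minCoverage = 100)
    res$hits$weightedCoverage[res$hits$tid == 0L]
  }
  w <- vapply(c(0L, 15L, 40L, 120L), wcovOfBase, 1)
  expect_true(all(diff(w) <= 1e-9))
  expect_lt(w[4], w[1])  # deep repeat demoted
})
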