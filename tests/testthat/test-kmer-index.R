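test_that("the occurrence cap drops k-mers present more than maxCount times", {
  # reads engineered so one 12-mer occurs exactly maxCount times and
  # another maxCount + 1 times, amid distinct random padding
  set.seed(11)
  kmerA <- "ACGTACGTACGA"   # HPC-clean (no adjacent repeats)
  kmerB <- "TGCATGCATGCT"
  maxCount <- 20L
  mk <- function(core, n) vapply(seq_len(n), function(i)
    paste0(randSeq(30), core, randSeq(30)), "")
  reads <- c(mk(kmerA, maxCount), mk(kmerB, maxCount + 1L))
  idx <- buildKmerIndex(reads, k = 12L, maxCount = maxCount,
                        subsampleDenominator = 1L)
  expect_gte(kmerCount(idx, kmerA), maxCount)  # padding may add occurrences
  expect_equal(kmerCount(idx, kmerB), 0L)
})

test_that("without subsampling every canonical N-free k-mer is indexed", {
  set.seed(12)
  reads <- vapply(1:5, function(i) randSeq(120), "")
  idx <- buildKmerIndex(reads, k = 10L, maxCount = 500L,
                        subsampleDenominator = 1L)
  # brute-force count of one k-mer across HPC strings, both strands
  hseqs <- vapply(reads, function(s) hpcCompress(s)@hseq, "")
  probe <- substr(hseqs[1], 5, 14)
  rc <- lrasm:::revcompChar(probe)
  bf <- sum(vapply(hseqs, function(h) {
    n <- nchar(h)
    sum(vapply(seq_len(n - 9), function(p)
      substr(h, p, p + 9) %in% c(probe, rc), TRUE))
  }, 1))
  expect_equal(kmerCount(idx, probe), bf)
  # a k-mer containing N is never indexed
  readsN <- c("ACGTNACGTACGTACGTAGCTAGCTT")
  idxN <- buildKmerIndex(readsN, k = 10L, maxCount = 500L,
                         subsampleDenominator = 1L)
  expect_equal(kmerCount(idxN, "ACGTNACGTA"), 0L)
})

test_that("subsampling keeps roughly 1/denominator of k-mers", {
  set.seed(13)
  reads <- vapply(1:10, function(i) randSeq(2000), "")
  full <- buildKmerIndex(reads, k = 16L, subsampleDenominator = 1L)
  quarter <- buildKmerIndex(reads, k = 16L, subsampleDenominator = 4L)
  n1 <- lrasm:::index_info_cpp(full@ptr)$nKmers
  n4 <- lrasm:::index_info_cpp(quarter@ptr)$nKmers
  expect_gt(n4 / n1, 0.18)
  expect_lt(n4 / n1, 0.32)
})

test_that("candidates are found by seed coverage with deterministic ranking", {
  set.seed(14)
  shared <- randSeq(520)  # ~350+ HPC bases
  target <- paste0(randSeq(300), shared, randSeq(300))
  query <- paste0(randSeq(150), shared, randSeq(150))
  decoy <- randSeq(800)
  idx <- buildKmerIndex(c(target, decoy), k = 16L,
                        subsampleDenominator = 1L)
  res <- findCandidates(idx, query, queryId = -1L, minCoverage = 300)
  expect_equal(res$hits$tid, 0L)
  expect_equal(res$hits$strand, "+")
  sharedHpc <- nchar(hpcCompress(shared)@hseq)
  expect_gte(res$hits$coverage[1], sharedHpc - 15)
  # no shared k-mer -> empty
  res2 <- findCandidates(idx, randSeq(400), queryId = -1L)
  expect_equal(nrow(res2$hits), 0L)
})

test_that("the candidate list is truncated to the top maxCandidates", {
  set.seed(15)
  shared <- randSeq(700)
  # 6 targets share progressively shorter prefixes of the shared block
  lens <- c(700, 650, 620, 600, 580, 560)
  targets <- vapply(lens, function(l)
    paste0(randSeq(120), substr(shared, 1, l), randSeq(120)), "")
  idx <- buildKmerIndex(targets, k = 16L, subsampleDenominator = 1L)
  res <- findCandidates(idx, shared, queryId = -1L, minCoverage = 300,
                        maxCandidates = 3L, weighted = FALSE)
  expect_equal(nrow(res$hits), 3L)
  full <- findCandidates(idx, shared, queryId = -1L, minCoverage = 300,
                         maxCandidates = 500L, weighted = FALSE)
  expect_equal(res$hits$coverage,
               sort(full$hits$coverage, decreasing = TRUE)[1:3])
})

test_that("reverse-complementing the query flips strands, same coverage", {
  set.seed(16)
  reads <- vapply(1:6, function(i) randSeq(900), "")
  query <- paste0(substr(reads[2], 200, 700), substr(reads[4], 100, 500))
  idx <- buildKmerIndex(reads, k = 16L, subsampleDenominator = 1L)
  a <- findCandidates(idx, query, queryId = -1L, minCoverage = 50)
  b <- findCandidates(idx, lrasm:::revcompChar(query), queryId = -1L,
                      minCoverage = 50)
  ka <- a$hits[order(a$hits$tid, a$hits$strand), ]
  kb <- b$hits[order(b$hits$tid, b$hits$strand), ]
  expect_equal(ka$tid, kb$tid)
  expect_equal(ka$coverage, kb$coverage)
  expect_true(all(ka$strand != kb$strand))
})

test_that("depth weights hit the endpoints and interpolate linearly", {
  expect_equal(depthWeights(c(0, 5, 10)), c(1, 1, 1))
  expect_equal(depthWeights(c(100, 150)), c(0, 0))
  expect_equal(depthWeights(55), 0.5)
  d <- 0:120
  w <- depthWeights(d)
  expect_true(all(diff(w) <= 0))
  expect_true(all(w >= 0 & w <= 1))
})
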