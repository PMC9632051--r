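test_that("anchor extraction finds maximal exact runs", {
  set.seed(21)
  h <- hpcCompress(randSeq(160))@hseq
  a <- extractAnchors(h, h, z = 10L)
  expect_equal(nrow(a), 1L)
  expect_equal(unname(a[1, ]), c(0L, 0L, nchar(h)))

  # no shared z-mer
  a2 <- extractAnchors("ACGTACGTACGTACG", "TTGATTGCAAGCTTG", z = 10L)
  expect_equal(nrow(a2), 0L)

  # shared 30-HPC-base block amid random flanks
  repeat {
    blk <- hpcCompress(randSeq(50))@hseq
    if (nchar(blk) >= 30) { blk <- substr(blk, 1, 30); break }
  }
  q <- paste0(substr(hpcCompress(randSeq(20))@hseq, 1, 10), blk)
  t <- paste0(substr(hpcCompress(randSeq(90))@hseq, 1, 50), blk)
  qn <- nchar(q) - 30L; tn <- nchar(t) - 30L
  a3 <- extractAnchors(q, t, z = 10L)
  hit <- a3[a3[, 1] <= qn & a3[, 1] + a3[, 3] >= qn + 30, , drop = FALSE]
  expect_true(any(hit[, 2] <= tn & hit[, 2] + hit[, 3] >= tn + 30))
})

test_that("anchor extraction matches a brute-force z-mer matcher", {
  set.seed(22)
  z <- 6L
  for (rep in 1:10) {
    q <- hpcCompress(randSeq(60))@hseq
    t <- hpcCompress(randSeq(60))@hseq
    a <- extractAnchors(q, t, z = z)
    # expand anchors back to the per-position match set
    got <- integer(0)
    if (nrow(a)) for (i in seq_len(nrow(a))) {
      k <- a[i, 3] - z + 1L
      got <- c(got, (a[i, 1] + 0:(k - 1)) * 10000L + (a[i, 2] + 0:(k - 1)))
    }
    want <- integer(0)
    for (qp in 0:(nchar(q) - z)) for (tp in 0:(nchar(t) - z))
      if (substr(q, qp + 1, qp + z) == substr(t, tp + 1, tp + z))
        want <- c(want, qp * 10000L + tp)
    expect_setequal(got, want)
  }
})

test_that("the chain recurrence follows its worked examples", {
  # two length-20 anchors, candidate-side gap 5 beyond the query-side
  # spacing -> one block, S = 20 + 20 - 5 = 35
  a <- cbind(qpos = c(0L, 20L), tpos = c(0L, 25L), len = c(20L, 20L))
  r <- chainAnchors(a)
  expect_equal(r$score, 35)
  expect_equal(c(r$start, r$end), c(1L, 2L))
  # drift 30 -> S would drop below L, two blocks of 20; earliest returned
  a2 <- cbind(qpos = c(0L, 20L), tpos = c(0L, 50L), len = c(20L, 20L))
  r2 <- chainAnchors(a2)
  expect_equal(r2$score, 20)
  expect_equal(c(r2$start, r2$end), c(1L, 1L))
  # perfectly collinear sparse seeds chain for free
  a3 <- cbind(qpos = c(0L, 100L, 200L), tpos = c(50L, 150L, 250L),
              len = c(10L, 10L, 10L))
  expect_equal(chainAnchors(a3)$score, 30)
  # single anchor
  r4 <- chainAnchors(cbind(0L, 0L, 15L))
  expect_equal(r4$score, 15)
})

test_that("chain block equals exhaustive enumeration on random anchor sets", {
  set.seed(23)
  for (rep in 1:60) {
    n <- sample(1:12, 1)
    qp <- cumsum(sample(5:40, n, TRUE))
    tp <- qp + sample(-30:30, n, TRUE)
    ln <- sample(5:25, n, TRUE)
    a <- cbind(qpos = qp, tpos = tp, len = ln)
    a <- a[order(a[, 1]), , drop = FALSE]
    got <- chainAnchors(a)
    want <- chainOracle(a)
    expect_equal(got$score, want$score)
    expect_equal(c(got$start, got$end), c(want$start, want$end))
  }
})

test_that("window chaining applies both coverage filters", {
  set.seed(24)
  mkPair <- function(sharedLen) {
    repeat {
      s <- hpcCompress(randSeq(2 * sharedLen))@hseq
      if (nchar(s) >= sharedLen) break
    }
    s <- substr(s, 1, sharedLen)
    q <- paste0(hpcCompress(randSeq(500))@hseq, s)
    t <- paste0(hpcCompress(randSeq(900))@hseq, s)
    extractAnchors(q, t, z = 10L)
  }
  # 150 shared bases: below the 200 window minimum
  expect_null(chainQuery(mkPair(150)))
  # 250 shared bases: window passes, total 250 <= 300 -> null
  expect_null(chainQuery(mkPair(250)))
  # 400 shared bases: both filters pass
  ch <- chainQuery(mkPair(400))
  expect_false(is.null(ch))
  expect_gt(ch$total, 300)
})

test_that("a long shared suffix/prefix chains across multiple windows", {
  set.seed(25)
  shared <- randSeq(2800)  # ~2000+ HPC bases
  # light substitution noise in one copy fragments the exact anchors so
  # the chain genuinely spans several query windows
  sv <- strsplit(shared, "")[[1]]
  hit <- which(runif(length(sv)) < 0.02)
  sv[hit] <- vapply(sv[hit], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  q <- paste0(randSeq(2000), paste(sv, collapse = ""))
  t <- paste0(shared, randSeq(2000))
  qh <- hpcCompress(q); th <- hpcCompress(t)
  a <- extractAnchors(qh, th, z = 10L)
  ch <- chainQuery(a)
  expect_false(is.null(ch))
  sharedHpc <- nchar(hpcCompress(shared)@hseq)
  expect_gt(ch$total, 0.8 * sharedHpc)
  expect_gte(ch$windows, 2L)
  # anchors are jointly monotone
  expect_true(all(diff(ch$anchors[, 1]) >= 0))
  expect_true(all(diff(ch$anchors[, 2]) >= 0))
})

test_that("the native window-chain agrees with the reference implementation", {
  set.seed(26)
  for (rep in 1:40) {
    n <- sample(5:200, 1)
    qp <- sort(sample(0:4000, n, TRUE))
    tp <- pmax(0L, qp + sample(-150:150, n, TRUE))
    ln <- sample(10:40, n, TRUE)
    a <- cbind(qpos = qp, tpos = tp, len = ln)
    a <- a[order(a[, 1], a[, 2]), , drop = FALSE]
    got <- chainQuery(a)
    want <- lrasm:::chainQueryR(a)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_false(is.null(got))
      expect_equal(got$total, want$total)
      expect_equal(unname(got$anchors), unname(want$anchors))
    }
  }
})
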