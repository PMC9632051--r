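test_that("homopolymer compression collapses runs and keeps the coordinate map", {
  h <- hpcCompress("AAATTGGC")
  expect_equal(h@hseq, "ATGC")
  expect_equal(h@runs, c(3L, 2L, 2L, 1L))
  expect_equal(h@offsets, c(0L, 3L, 5L, 7L))

  fp <- hpcCompress("ACGT")
  expect_equal(fp@hseq, "ACGT")
  expect_equal(fp@runs, rep(1L, 4))

  e <- hpcCompress("")
  expect_equal(e@hseq, "")
  expect_equal(hpcExpand(e), "")
})

test_that("compression is idempotent and expansion inverts it", {
  set.seed(42)
  for (i in 1:200) {
    s <- randSeq(sample(1:300, 1))
    h <- hpcCompress(s)
    expect_identical(hpcExpand(h), s)
    h2 <- hpcCompress(h@hseq)
    expect_identical(h2@hseq, h@hseq)
    expect_true(all(h2@runs == 1L))
  }
})

test_that("hpcToRaw maps HPC intervals to their exact raw expansion", {
  h <- hpcCompress("AAATTGGC")
  expect_equal(hpcToRaw(h, c(1, 3)), c(3L, 7L))
  expect_equal(hpcToRaw(h, c(0, 4)), c(0L, 8L))
  expect_equal(hpcToRaw(h, c(2, 2)), c(5L, 5L))
  expect_error(hpcToRaw(h, c(2, 9)), "outside")
})

test_that("hpcToRaw is monotone in its argument", {
  set.seed(7)
  for (rep in 1:20) {
    s <- randSeq(200)
    h <- hpcCompress(s)
    n <- nchar(h@hseq)
    pts <- sort(sample(0:n, min(10, n + 1)))
    starts <- vapply(pts, function(p) hpcToRaw(h, c(p, p))[1], 1L)
    expect_true(all(diff(starts) >= 0))
    # the expansion of [0, p) plus [p, n) tiles the read
    for (p in pts) {
      a <- hpcToRaw(h, c(0, p)); b <- hpcToRaw(h, c(p, n))
      expect_equal(a[2], b[1])
      expect_equal(b[2], nchar(s))
    }
  }
})

test_that("canonical k-mers take the smaller 2-bit encoding, ties unflipped", {
  expect_equal(canonicalKmer("AAAC"), list(canonical = "AAAC", flipped = FALSE))
  expect_equal(canonicalKmer("TTTT"), list(canonical = "AAAA", flipped = TRUE))
  # palindrome: reverse complement equals the k-mer itself
  expect_equal(canonicalKmer("ACGT"), list(canonical = "ACGT", flipped = FALSE))
  # canonicalization is involutive over reverse complement
  set.seed(3)
  for (i in 1:50) {
    k <- randSeq(16)
    rc <- lrasm:::revcompChar(k)
    expect_equal(canonicalKmer(k)$canonical, canonicalKmer(rc)$canonical)
  }
})
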