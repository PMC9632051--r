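test_that("backbones stitch tiling reads by offset", {
  seqs <- c("ACGTACGTAA", "GTAATTGGCC")
  # single read
  t1 <- data.frame(readId = 0L, strand = "+", offset = 0L,
                   start = 0L, end = 10L)
  expect_equal(backboneOf(t1, seqs), "ACGTACGTAA")
  # two reads overlapping by 4: backbone = read1 + read2 suffix
  t2 <- rbind(t1, data.frame(readId = 1L, strand = "+", offset = 6L,
                             start = 0L, end = 10L))
  expect_equal(backboneOf(t2, seqs), "ACGTACGTAATTGGCC")
  # empty unitig errors
  expect_error(backboneOf(t1[0, ], seqs), "empty")
})

test_that("reads align to their hinted backbone region", {
  set.seed(61)
  backbone <- randSeq(3000)
  read <- substr(backbone, 1001, 2000)
  a <- alignToBackbone(read, backbone, 1000L, band = 200L)
  expect_equal(a$tstart, 1000L)
  expect_equal(a$identity, 1)
  expect_equal(a$cigar, "1000=")
  # one substitution -> exactly one mismatch column
  sub <- read
  substr(sub, 500, 500) <- setdiff(c("A", "C", "G", "T"),
                                   substr(read, 500, 500))[1]
  a2 <- alignToBackbone(sub, backbone, 1000L, band = 200L)
  p <- lrasm:::parseCigar(a2$cigar)
  expect_equal(sum(p$lens[p$ops == "X"]), 1L)
  expect_equal(sum(p$lens[p$ops == "="]), 999L)
})

test_that("the DAG consensus is the identity on a bare backbone", {
  set.seed(62)
  bb <- randSeq(500)
  r <- callConsensus(bb)
  expect_equal(r$seq, bb)
  expect_true(all(r$support == 1))
})

test_that("majority reads correct substitutions, insertions and deletions", {
  bb <- "ACGAACGT"  # erroneous A at position 4
  good <- lapply(1:4, function(i) list(seq = "ACGTACGT", tstart = 0L,
                                       cigar = "3=1X4="))
  bad <- list(list(seq = "ACGAACGT", tstart = 0L, cigar = "8="))
  r <- callConsensus(bb, c(good, bad))
  expect_equal(r$seq, "ACGTACGT")
  expect_true(all(r$support >= 4))  # the corrected column carries 4 reads

  # backbone missing a base carried by 4 of 5 reads
  ins <- lapply(1:4, function(i) list(seq = "ACGTTACG", tstart = 0L,
                                      cigar = "4=1I3="))
  r2 <- callConsensus("ACGTACG", c(ins, list(list(seq = "ACGTACG",
                                                  tstart = 0L,
                                                  cigar = "7="))))
  expect_equal(r2$seq, "ACGTTACG")

  # backbone carrying a base absent from 4 of 5 reads
  del <- lapply(1:4, function(i) list(seq = "ACGACG", tstart = 0L,
                                      cigar = "3=1D3="))
  r3 <- callConsensus("ACGTACG", c(del, list(list(seq = "ACGTACG",
                                                  tstart = 0L,
                                                  cigar = "7="))))
  expect_equal(r3$seq, "ACGACG")
})

test_that("total DAG edge weight matches the cigar-derived expectation", {
  set.seed(63)
  bb <- randSeq(300)
  alns <- list()
  expected <- nchar(bb) + 1  # backbone threading
  for (i in 1:5) {
    s <- sample(0:100, 1); e <- sample(200:300, 1)
    seq <- substr(bb, s + 1, e)
    cigar <- paste0(nchar(seq), "=")
    alns[[i]] <- list(seq = seq, tstart = s, cigar = cigar)
    emitted <- nchar(seq)
    expected <- expected + (emitted - 1) + (s == 0) + (e == nchar(bb))
  }
  r <- callConsensus(bb, alns)
  expect_equal(r$totalWeight, expected)
})

test_that("consensus of partially tiled reads still spans the backbone", {
  set.seed(64)
  bb <- randSeq(2000)
  alns <- lapply(seq(0, 1500, by = 250), function(s) {
    seq <- substr(bb, s + 1, s + 500)
    list(seq = seq, tstart = as.integer(s), cigar = "500=")
  })
  r <- callConsensus(bb, alns)
  expect_equal(r$seq, bb)
  expect_true(all(r$support >= 1))
})
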