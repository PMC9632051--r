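test_that("banded global alignment handles the basic cases", {
  r <- bandedGlobalAlign("ACGT", "ACGT", 50)
  expect_equal(r$score, 8)
  expect_equal(r$cigar, "4=")
  expect_false(r$touched)

  # one base deleted from b; score computed by the unbanded oracle
  r2 <- bandedGlobalAlign("ACGT", "ACT", 50)
  expect_equal(r2$score, oracleGlobalScore("ACGT", "ACT"))
  st <- lrasm:::cigarStats(r2$cigar)
  expect_equal(st$qspan, 4L)
  expect_equal(st$tspan, 3L)
  expect_equal(st$nmatch, 3L)

  # empty vs empty
  r3 <- bandedGlobalAlign("", "", 10)
  expect_equal(r3$score, 0)
  expect_equal(r3$cigar, "")
})

test_that("a full-width band reproduces unbanded global DP scores exactly", {
  set.seed(31)
  for (i in 1:40) {
    a <- randSeq(sample(1:120, 1))
    b <- randSeq(sample(1:120, 1))
    got <- bandedGlobalAlign(a, b, band = 150)$score
    expect_identical(got, as.integer(oracleGlobalScore(a, b)))
  }
})

test_that("edit scripts are consistent and N mismatches everything", {
  set.seed(32)
  for (i in 1:20) {
    a <- randSeq(sample(10:80, 1))
    b <- randSeq(sample(10:80, 1))
    r <- bandedGlobalAlign(a, b, band = 100)
    st <- lrasm:::cigarStats(r$cigar)
    expect_equal(st$qspan, nchar(a))
    expect_equal(st$tspan, nchar(b))
    expect_equal(st$nmatch, r$nmatch)
    expect_equal(st$ncols, r$ncols)
  }
  rn <- bandedGlobalAlign("ANA", "ANA", 10)
  expect_equal(lrasm:::cigarStats(rn$cigar)$nmatch, 2L)
})

test_that("narrow bands flag boundary contact", {
  set.seed(33)
  a <- randSeq(80)
  b <- paste0(randSeq(30), a)  # needs a 30-wide shift
  r <- bandedGlobalAlign(a, b, band = 5)
  expect_true(r$touched)
  wide <- bandedGlobalAlign(a, b, band = 120)
  expect_false(wide$touched)
  expect_gte(wide$score, r$score)
})

test_that("cigar utilities merge, parse and reverse correctly", {
  expect_equal(lrasm:::catCigar(c("3=2I", "1I4=")), "3=3I4=")
  expect_equal(lrasm:::catCigar(c("", "2=")), "2=")
  expect_equal(lrasm:::revCigar("3=1X2D"), "2D1X3=")
  p <- lrasm:::parseCigar("12=3I1X")
  expect_equal(p$lens, c(12L, 3L, 1L))
  expect_equal(p$ops, c("=", "I", "X"))
})
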