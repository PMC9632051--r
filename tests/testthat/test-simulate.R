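test_that("genome simulation is deterministic and sized as configured", {
  cfg <- simConfig(genomeLength = 5000L, seed = 5L)
  g1 <- simulateGenome(cfg)
  g2 <- simulateGenome(cfg)
  expect_identical(g1, g2)
  expect_equal(nchar(g1), 5000L)
  expect_false(grepl("[^ACGT]", g1))
  # repeats occupy about the configured fraction
  cfgR <- simConfig(genomeLength = 50000L, repeatFraction = 0.2,
                    repeatUnit = 2000L, seed = 5L)
  gR <- simulateGenome(cfgR)
  # 5 copies of the same 2 kb unit: the most common 2 kb substring recurs
  expect_equal(nchar(gR), 50000L)
})

test_that("read simulation matches the configured arithmetic and truth", {
  cfg <- simConfig(genomeLength = 10000L, coverage = 30,
                   readLengthMean = 1000L, readLengthSd = 200L, seed = 8L)
  g <- simulateGenome(cfg)
  sim <- simulateReads(g, cfg)
  expect_equal(length(sim$reads), 300L)
  expect_identical(as.character(simulateReads(g, cfg)$reads),
                   as.character(sim$reads))
  expect_true(all(sim$truth$start >= 0 & sim$truth$end <= 10000))
})

test_that("with zero error rates every read is an exact oriented substring", {
  cfg <- simConfig(genomeLength = 8000L, coverage = 5,
                   readLengthMean = 1000L, subRate = 0, insRate = 0,
                   delRate = 0, homopolymerNoise = 0, badEndLength = 0L,
                   seed = 9L)
  g <- simulateGenome(cfg)
  sim <- simulateReads(g, cfg)
  for (i in seq_along(sim$reads)) {
    tr <- sim$truth[i, ]
    frag <- substr(g, tr$start + 1, tr$end)
    if (tr$strand == "-") frag <- lrasm:::revcompChar(frag)
    expect_identical(as.character(sim$reads[[i]]), frag)
  }
})

test_that("configured error rates surface in alignment identity", {
  cfg <- simConfig(genomeLength = 30000L, coverage = 4,
                   readLengthMean = 1000L, readLengthSd = 100L,
                   subRate = 0.04, insRate = 0.04, delRate = 0.04,
                   homopolymerNoise = 0, badEndLength = 0L, seed = 10L)
  g <- simulateGenome(cfg)
  sim <- simulateReads(g, cfg)
  n <- min(100L, length(sim$reads))
  ids <- vapply(seq_len(n), function(i) {
    tr <- sim$truth[i, ]
    frag <- substr(g, tr$start + 1, tr$end)
    if (tr$strand == "-") frag <- lrasm:::revcompChar(frag)
    r <- bandedGlobalAlign(as.character(sim$reads[[i]]), frag, band = 150)
    r$nmatch / r$ncols
  }, 1)
  # matches / columns for 4% sub + 4% ins + 4% del: (1 - .08) / (1 + .04)
  expect_gt(mean(ids), 0.87)
  expect_lt(mean(ids), 0.90)
})

test_that("chimeric reads join two loci and are recorded in truth", {
  cfg <- simConfig(genomeLength = 20000L, coverage = 10,
                   readLengthMean = 1500L, chimeraRate = 0.3, seed = 12L)
  g <- simulateGenome(cfg)
  sim <- simulateReads(g, cfg)
  ch <- sim$truth[sim$truth$isChimera, ]
  expect_gt(nrow(ch), 10)
  expect_true(all(!is.na(ch$junction)))
  expect_true(all(!is.na(ch$start2)))
  expect_true(all(ch$junction > 0 &
                  ch$junction < Biostrings::width(sim$reads)[ch$readId + 1L]))
})

test_that("true overlap pairs equal the brute-force interval intersection", {
  cfg <- simConfig(genomeLength = 12000L, coverage = 8,
                   readLengthMean = 1500L, seed = 13L)
  g <- simulateGenome(cfg)
  sim <- simulateReads(g, cfg)
  got <- trueOverlaps(sim$truth, minSpan = 500L)
  t <- sim$truth[!sim$truth$isChimera, ]
  want <- list()
  for (i in seq_len(nrow(t) - 1)) for (j in (i + 1):nrow(t)) {
    span <- min(t$end[i], t$end[j]) - max(t$start[i], t$start[j])
    if (span >= 500)
      want[[length(want) + 1L]] <- data.frame(
        idA = min(t$readId[i], t$readId[j]),
        idB = max(t$readId[i], t$readId[j]), span = span)
  }
  want <- do.call(rbind, want)
  key <- function(d) sort(paste(d$idA, d$idB, d$span))
  expect_identical(key(got), key(want))
})
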