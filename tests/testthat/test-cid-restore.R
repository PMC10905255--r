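test_that("single-CID queries classify exact, corrected, ambiguous, unmatched", {
  chip <- ChipSpec("t", 8, 8, cidLength = 8)
  mask <- MaskTable(chip,
                    c("AAAAAAAA", "AAAATTTT", "CCCCCCCC", "GGGGGGGG"),
                    x = c(0L, 1L, 2L, 3L), y = c(0L, 0L, 1L, 1L))
  idx <- buildCidIndex(mask)
  r <- locateCid(idx, "AAAAAAAA")
  expect_equal(r$match_kind, "exact")
  expect_equal(unname(r$coordinate), c(0L, 0L))
  expect_null(r$mismatch_position)
  # one substitution from exactly one mask CID
  r <- locateCid(idx, "AAAAAAAT")
  expect_equal(r$match_kind, "corrected")
  expect_equal(unname(r$coordinate), c(0L, 0L))
  expect_equal(r$mismatch_position, 8L)
  # distance 1 from two mask CIDs at distinct positions -> ambiguous
  # "AAAAATTT": vs AAAAAAAA distance 3; build a dedicated pair instead
  mask2 <- MaskTable(chip, c("AAAAAAAA", "AAAAAAAT"),
                     x = c(0L, 1L), y = c(0L, 0L))
  # query sits at distance 1 from both entries (differs at position 8 from
  # the first, position 7 from the second is not possible; use middle query)
  r <- locateCid(buildCidIndex(mask2), "AAAAAAAC")
  expect_equal(r$match_kind, "ambiguous")
  expect_null(r$coordinate)
  # no neighbour at distance <= 1
  r <- locateCid(idx, "TTTTAAAA")
  expect_equal(r$match_kind, "unmatched")
  # N never matches exactly but substitutes as one error
  r <- locateCid(idx, "AAAAAAAN")
  expect_equal(r$match_kind, "corrected")
  expect_equal(r$mismatch_position, 8L)
  # two Ns can never be rescued at distance 1
  r <- locateCid(idx, "AAAAAANN")
  expect_equal(r$match_kind, "unmatched")
  expect_error(locateCid(idx, "ACGT"), "length")
})

test_that("degenerate masks behave: empty mask rejects all, singleton hits", {
  chip <- ChipSpec("t", 2, 2, cidLength = 6)
  idxEmpty <- buildCidIndex(MaskTable(chip))
  expect_equal(locateCid(idxEmpty, "ACGTAC")$match_kind, "unmatched")
  one <- buildCidIndex(MaskTable(chip, "ACGTAC", 1L, 1L))
  expect_equal(unname(locateCid(one, "ACGTAC")$coordinate), c(1L, 1L))
  expect_equal(locateCid(one, "ACGTAG")$match_kind, "corrected")
})

test_that("batch location agrees with the exhaustive Hamming-scan oracle", {
  for (seed in 1:5) {
    mask <- randomMask(1000L, L = 12L, seed = seed)
    me <- maskEntries(mask)
    set.seed(seed + 100)
    qExact <- sample(me$cid, 60)
    qVar <- vapply(sample(me$cid, 80), function(s) {
      p <- sample(12L, 1L)
      substr(s, p, p) <- sample(setdiff(BASES4, substr(s, p, p)), 1L)
      s
    }, "")
    qRand <- randomDna(60, 12L)
    qs <- c(qExact, qVar, qRand)
    idx <- buildCidIndex(mask)
    got <- stereoflow:::.locateCids(idx@mask, qs)
    want <- oracleLocate(mask, qs)
    expect_identical(got$match_kind, want$match_kind)
    expect_identical(got$x, want$x)
    expect_identical(got$y, want$y)
  }
})

test_that("restoration conserves reads, order, and counters", {
  sim <- stdSim()
  idx <- buildCidIndex(sim$mask)
  res <- restoreReads(sim$reads, idx)
  s <- res$stats
  expect_equal(s$exact_matches + s$corrected_matches + s$ambiguous +
                 s$unmatched, s$total_reads)
  expect_equal(s$total_reads, nrow(sim$reads))
  expect_equal(res$located$read_id, sim$reads$read_id)
  expect_equal(s$mapped_fraction,
               (s$exact_matches + s$corrected_matches) / s$total_reads)
  # noiseless reads restore perfectly
  sim0 <- simulateRun(simulationParams(seed = 7L, nMolecules = 100L,
                                       cidErrorRate = 0, midErrorRate = 0,
                                       cdnaErrorRate = 0))
  res0 <- restoreReads(sim0$reads, buildCidIndex(sim0$mask))
  expect_equal(res0$stats$exact_matches, nrow(sim0$reads))
  expect_equal(res0$stats$mapped_fraction, 1.0)
  # reads with exactly one substituted CID base are all corrected
  mask <- makeChip(ChipSpec("hd", 10, 10, 20L), seed = 12L, minHamming = 3L)
  me <- maskEntries(mask)
  set.seed(12)
  qs <- vapply(me$cid[1:50], function(s) {
    p <- sample(20L, 1L)
    substr(s, p, p) <- sample(setdiff(BASES4, substr(s, p, p)), 1L)
    s
  }, "")
  res1 <- restoreReads(readTable(unname(qs)), buildCidIndex(mask))
  expect_equal(res1$stats$corrected_matches, 50L)
  expect_equal(res1$located$x, me$x[1:50])
  expect_equal(res1$located$y, me$y[1:50])
})

test_that("restoration is deterministic and partition-invariant", {
  sim <- stdSim()
  idx <- buildCidIndex(sim$mask)
  a <- restoreReads(sim$reads, idx)
  b <- restoreReads(sim$reads, idx)
  expect_identical(a$located, b$located)
  for (rule in list(PartitionRule(4, "prefix"), PartitionRule(16, "prefix"),
                    PartitionRule(10, "modulo"))) {
    p <- restoreReadsPartitioned(sim$reads, sim$mask, rule)
    expect_identical(p$located, a$located)
    expect_equal(p$stats$mapped_fraction, a$stats$mapped_fraction)
  }
})
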