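test_that("mask TSV round-trips and rejects invalid input", {
  chip <- ChipSpec("toy", 4, 4, cidLength = 4)
  mask <- MaskTable(chip, c("ACGT", "TTTT", "GGCC"),
                    x = c(0L, 1L, 2L), y = c(0L, 0L, 3L))
  f <- tempfile(fileext = ".tsv")
  writeMask(mask, f)
  back <- loadMask(f)
  expect_equal(maskEntries(back)[order(maskEntries(back)$cid), ],
               maskEntries(mask)[order(maskEntries(mask)$cid), ],
               ignore_attr = TRUE)
  expect_equal(chipWidth(maskChip(back)), 4L)

  # empty mask is a valid file with zero entries
  writeMask(MaskTable(chip), f)
  expect_equal(length(loadMask(f)), 0L)

  # duplicate CID rejected, naming the CID
  writeLines(c("#chip=toy width=4 height=4 cid_length=4",
               "ACGT\t0\t0", "ACGT\t1\t1"), f)
  expect_error(loadMask(f), "ACGT")
  # wrong CID length
  writeLines(c("#chip=toy width=4 height=4 cid_length=4", "ACG\t0\t0"), f)
  expect_error(loadMask(f), "length")
  # out-of-bounds coordinate
  writeLines(c("#chip=toy width=4 height=4 cid_length=4", "ACGT\t9\t0"), f)
  expect_error(loadMask(f), "bounds")

  # large random mask round-trips entry by entry
  big <- randomMask(1000L, L = 12L, seed = 5L)
  writeMask(big, f)
  back <- loadMask(f)
  a <- maskEntries(big); a <- a[order(a$cid), ]
  b <- maskEntries(back)
  expect_equal(b$cid, a$cid)
  expect_equal(b$x, a$x)
  expect_equal(b$y, a$y)
})

test_that("partition assignment follows the fixed A=0..T=3 encoding", {
  r4 <- PartitionRule(4, "prefix")
  expect_equal(as.integer(assignPartition(paste0("A", strrep("C", 24)), r4)),
               0L)
  expect_equal(as.integer(assignPartition(paste0("T", strrep("G", 24)), r4)),
               3L)
  r16 <- PartitionRule(16, "prefix")
  # first two bases CG -> 1*4 + 2 = 6
  expect_equal(as.integer(assignPartition(paste0("CG", strrep("A", 23)),
                                          r16)), 6L)
  # modulo mode: independent big-endian encoding oracle
  enc <- function(cid) {
    v <- 0
    for (ch in strsplit(cid, "")[[1L]])
      v <- v * 4 + (match(ch, BASES4) - 1)
    v
  }
  rm10 <- PartitionRule(10, "modulo")
  set.seed(11)
  cids <- randomDna(50, 12L)
  expect_equal(as.integer(assignPartition(cids, rm10)),
               as.integer(vapply(cids, enc, 0) %% 10))
  expect_equal(as.integer(assignPartition("AAA", rm10)), 0L)
  # non-ACGT falls back to partition 0 and is counted
  got <- assignPartition(c("NAA", "CCC"), PartitionRule(4, "prefix",
                                                        prefixLen = 1L))
  expect_equal(as.integer(got), c(0L, 1L))
  expect_equal(attr(got, "fallback"), 1L)
  # prefix mode requires a power of 4
  expect_error(PartitionRule(10, "prefix"), "power of 4")
})

test_that("mask splitting is complete and disjoint", {
  mask <- randomMask(1000L, L = 10L, seed = 9L)
  for (rule in list(PartitionRule(4, "prefix"), PartitionRule(16, "prefix"),
                    PartitionRule(10, "modulo"), PartitionRule(1, "modulo"))) {
    parts <- splitMask(mask, rule)
    expect_length(parts, rule@nParts)
    expect_equal(sum(vapply(parts, length, 0L)), length(mask))
    keys <- lapply(parts, function(p) maskEntries(p)$cid)
    expect_equal(anyDuplicated(unlist(keys)), 0L)
    expect_setequal(unlist(keys), maskEntries(mask)$cid)
    for (i in seq_along(parts)) {
      if (length(parts[[i]]))
        expect_true(all(assignPartition(maskEntries(parts[[i]])$cid,
                                        rule) == i - 1L))
    }
  }
  # single-partition modulo is the identity
  one <- splitMask(mask, PartitionRule(1, "modulo"))
  expect_equal(maskEntries(one[[1L]]), maskEntries(mask))
})

test_that("read splitting routes each read to exactly one stream in order", {
  set.seed(3)
  cids <- paste0(rep(c("A", "C", "G", "T"), each = 2), randomDna(8, 9L))
  reads <- readTable(cids)
  sp <- splitReads(reads, PartitionRule(4, "prefix"), cidLength = 10L)
  expect_equal(vapply(sp$parts, nrow, 0L), rep(2L, 4))
  expect_setequal(unlist(lapply(sp$parts, function(p) p$read_id)),
                  reads$read_id)
  # within-stream order preserves input order
  for (p in sp$parts)
    expect_false(is.unsorted(match(p$read_id, reads$read_id)))
  # empty input
  sp0 <- splitReads(reads[0, ], PartitionRule(4, "prefix"), 10L)
  expect_equal(vapply(sp0$parts, nrow, 0L), rep(0L, 4))
  # short CID rejected with the read retained in rejects
  bad <- readTable(c("ACG", cids[1]))
  spb <- splitReads(bad, PartitionRule(4, "prefix"), 10L)
  expect_equal(nrow(spb$rejects), 1L)
  expect_equal(sum(vapply(spb$parts, nrow, 0L)), 1L)
})

test_that("spatial FASTQ layout round-trips through write and read", {
  set.seed(21)
  reads <- readTable(randomDna(6, 25L), randomDna(6, 10L),
                     randomDna(6, 50L))
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  writeReadFastq(reads, f1, f2)
  back <- readSpatialFastq(f1, f2)
  expect_equal(back$reads, reads, ignore_attr = TRUE)
  expect_equal(nrow(back$rejects), 0L)
  # combined single-file layout
  writeReadFastq(reads, f1)
  back1 <- readSpatialFastq(f1)
  expect_equal(back1$reads$cdna, reads$cdna)
  # a read shorter than the barcodes is rejected with a reason
  writeLines(c("@short", "ACGTACGT", "+", "IIIIIIII"), f1)
  shrt <- readSpatialFastq(f1)
  expect_equal(nrow(shrt$reads), 0L)
  expect_match(shrt$rejects$reason, "short")
})
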