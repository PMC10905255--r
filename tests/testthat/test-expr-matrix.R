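mkReads <- function(x, y, gene, mid, label = "EXONIC", antisense = FALSE) {
  data.frame(x = x, y = y, gene_id = gene, mid = mid, label = label,
             antisense = antisense, stringsAsFactors = FALSE)
}

test_that("matrix values are distinct corrected MIDs per coordinate and gene", {
  # same MID twice -> one molecule
  m <- buildExpressionMatrix(mkReads(1L, 1L, "G1", c("AAAA", "AAAA")))
  expect_equal(exprRecords(m)$count, 1L)
  # differing MIDs -> two molecules
  m <- buildExpressionMatrix(mkReads(1L, 1L, "G1", c("AAAA", "AAAT")))
  expect_equal(exprRecords(m)$count, 2L)
  # intergenic and antisense reads contribute nothing
  m <- buildExpressionMatrix(rbind(
    mkReads(1L, 1L, NA, "AAAA", label = "INTERGENIC"),
    mkReads(2L, 2L, "G1", "AAAA", antisense = TRUE)))
  expect_equal(length(m), 0L)
  # intronic sense reads do contribute
  m <- buildExpressionMatrix(mkReads(3L, 3L, "G2", "CCCC",
                                     label = "INTRONIC"))
  expect_equal(exprRecords(m)$count, 1L)
  # MID mapping merges reads before deduplication, resolving chains
  reads <- mkReads(1L, 1L, "G1", c("AAAA", "AAAT", "ATTT"))
  mapping <- data.frame(x = 1L, y = 1L, gene = "G1",
                        old_mid = c("ATTT", "AAAT"),
                        new_mid = c("AAAT", "AAAA"),
                        stringsAsFactors = FALSE)
  m <- buildExpressionMatrix(reads, mapping)
  expect_equal(exprRecords(m)$count, 1L)
})

test_that("grouping produces the nested-map counts the corrector consumes", {
  reads <- rbind(mkReads(1L, 2L, "G1", c("AAAA", "AAAA", "AAAT")),
                 mkReads(1L, 2L, "G2", "CCCC"),
                 mkReads(9L, 9L, "G1", "TTTT", antisense = TRUE))
  g <- groupMids(reads)
  expect_equal(nrow(g), 3L)
  expect_equal(g$count[g$gene == "G1" & g$mid == "AAAA"], 2L)
  expect_equal(sum(g$count), 4L)   # the antisense read is excluded
})

test_that("binning sums counts on the floor-division lattice and conserves totals", {
  m <- SpatialExpression(data.frame(
    gene = c("G", "G"), x = c(0L, 199L), y = c(0L, 199L),
    count = c(2L, 3L)))
  expect_identical(binMatrix(m, 1L), m)
  b <- binMatrix(m, 200L)
  r <- exprRecords(b)
  expect_equal(nrow(r), 1L)
  expect_equal(r$x, 0L); expect_equal(r$y, 0L); expect_equal(r$count, 5L)
  expect_equal(exprBinSize(b), 200L)
  # totals invariant for any bin size
  set.seed(8)
  df <- unique(data.frame(gene = sample(sprintf("G%d", 1:5), 500, TRUE),
                          x = sample(0:399, 500, TRUE),
                          y = sample(0:399, 500, TRUE)))
  df$count <- sample(1:9, nrow(df), TRUE)
  big <- SpatialExpression(df)
  for (bs in c(1L, 10L, 200L))
    expect_equal(exprTotal(binMatrix(big, bs)), exprTotal(big))
  expect_error(binMatrix(big, 0L), "binSize")
})

test_that("gem TSV round-trips losslessly", {
  m <- SpatialExpression(data.frame(gene = c("A", "B", "B"),
                                    x = c(1L, 2L, 3L), y = c(4L, 5L, 6L),
                                    count = c(1L, 2L, 3L)))
  f <- tempfile(fileext = ".gem")
  writeGem(m, f)
  expect_equal(exprRecords(readGem(f)), exprRecords(m))
  expect_equal(exprBinSize(readGem(f)), 1L)
  # empty matrix round-trips with a valid header
  e <- SpatialExpression(data.frame(gene = character(0), x = integer(0),
                                    y = integer(0), count = integer(0)),
                         binSize = 50L)
  writeGem(e, f)
  expect_equal(length(readGem(f)), 0L)
  expect_equal(exprBinSize(readGem(f)), 50L)
  # large generated matrix
  set.seed(13)
  n <- 100000L
  df <- unique(data.frame(gene = sample(sprintf("G%02d", 1:40), n, TRUE),
                          x = sample(0:999, n, TRUE),
                          y = sample(0:999, n, TRUE)))
  df$count <- sample(1:50, nrow(df), TRUE)
  big <- SpatialExpression(df)
  writeGem(big, f)
  expect_equal(exprRecords(readGem(f)), exprRecords(big))
  notGem <- tempfile()
  writeLines(c("geneID\tx\ty\tMIDCount", "G\t1\t1\t1"), notGem)
  expect_error(readGem(notGem), "gem")
})

test_that("duplicate coordinate-gene records are rejected by validity", {
  expect_error(SpatialExpression(data.frame(
    gene = c("A", "A"), x = c(1L, 1L), y = c(2L, 2L), count = c(1L, 2L))),
    "unique")
})

test_that("stage report computes funnel percentages against the previous stage", {
  restore <- list(total_reads = 1000L, exact_matches = 700L,
                  corrected_matches = 88L, ambiguous = 12L,
                  unmatched = 200L, mapped_fraction = 0.788)
  filter <- list(total = 788L, passed = 735L, mid_has_N = 10L,
                 mid_polyA = 20L, mid_low_quality = 13L,
                 cdna_too_short_after_polyA_trim = 10L,
                 retained_fraction = 735 / 788)
  rep <- stageReport(restore = restore, filter = filter,
                     alignment = list(unique_reads = 617L))
  expect_equal(rep$restore$pct_of_previous, 78.8)
  expect_equal(rep$filter$pct_of_previous, 100 * 735 / 788)
  expect_equal(rep$alignment$pct_of_previous, 100 * 617 / 735)
  expect_true("annotation" %in% rep$missing_stages)
  # zero reads: no division errors
  z <- stageReport(restore = list(total_reads = 0L, exact_matches = 0L,
                                  corrected_matches = 0L, ambiguous = 0L,
                                  unmatched = 0L, mapped_fraction = 0))
  expect_equal(z$restore$pct_of_previous, 0)
  # partial report flags the gaps explicitly
  p <- stageReport(filter = filter)
  expect_true("restore" %in% p$missing_stages)
})
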