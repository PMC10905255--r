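test_that("GTF coordinates convert to 0-based half-open gene models", {
  gtf <- c(
    'chr1\tsrc\tgene\t101\t200\t.\t+\t.\tgene_id "G1";',
    'chr1\tsrc\ttranscript\t101\t200\t.\t+\t.\tgene_id "G1"; transcript_id "G1.t1";',
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "G1"; transcript_id "G1.t1";')
  f <- tempfile(fileext = ".gtf")
  writeLines(gtf, f)
  models <- loadGeneModels(f)
  expect_equal(length(models), 1L)
  g <- models@genes[["G1"]]
  expect_equal(g$start, 100L)
  expect_equal(g$end, 200L)
  expect_equal(unname(g$transcripts[[1L]][1L, ]), c(100L, 200L))

  # overlapping genes on opposite strands are both returned by overlap query
  gm <- makeGeneModels(3, seed = 4L, overlapMode = TRUE)
  writeLines(gm$gtf, f)
  models <- loadGeneModels(f)
  g1 <- models@genes[[1L]]
  ov <- models@genes[["G_OVL"]]
  expect_true(ov$strand != g1$strand)
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(g1$chrom,
                           IRanges::IRanges(g1$start + 60L, g1$start + 80L)),
    models@ranges)
  hitGenes <- S4Vectors::mcols(models@ranges)$gene_id[
    S4Vectors::subjectHits(hits)]
  expect_true(all(c(g1$gene_id, "G_OVL") %in% hitGenes))
})

test_that("CIGAR parsing yields the documented block semantics", {
  r <- parseAlignBlocks("50M", 100)
  expect_equal(r$read_length, 50L)
  expect_equal(r$blocks$ref_start, 100L)
  expect_equal(r$blocks$ref_end, 150L)
  # splice gap closes the block
  r <- parseAlignBlocks("20M100N30M", 0)
  expect_equal(r$read_length, 50L)
  expect_equal(r$blocks$ref_start, c(0L, 120L))
  expect_equal(r$blocks$ref_end, c(20L, 150L))
  expect_equal(r$blocks$read_offset, c(0L, 20L))
  # soft clip consumes read only
  r <- parseAlignBlocks("10S40M", 100)
  expect_equal(r$read_length, 50L)
  expect_equal(r$blocks$ref_start, 100L)
  expect_equal(r$blocks$ref_end, 140L)
  expect_equal(r$blocks$read_offset, 10L)
  # deletion closes the block and advances the reference
  r <- parseAlignBlocks("10M2D5M", 0)
  expect_equal(r$read_length, 15L)
  expect_equal(r$blocks$ref_start, c(0L, 12L))
  expect_equal(r$blocks$ref_end, c(10L, 17L))
  # insertion consumes read but does not close the block
  r <- parseAlignBlocks("5M3I5M", 10)
  expect_equal(r$read_length, 13L)
  expect_equal(nrow(r$blocks), 1L)
  expect_equal(r$blocks$ref_end - r$blocks$ref_start, 10L)
  # hard clip consumes neither
  r <- parseAlignBlocks("5H10M", 0)
  expect_equal(r$read_length, 10L)
  expect_error(parseAlignBlocks("10Q", 0))
})

test_that("gene scoring applies the 50% exon/intron rule", {
  # gene [0, 1000), one transcript, exons [0,200) and [800,1000)
  g <- makeGeneEntry("G1", "chr1", "+", 0L, 1000L,
                     list(cbind(c(0L, 800L), c(200L, 1000L))))
  # read fully inside one exon
  b <- parseAlignBlocks("50M", 100)
  expect_equal(scoreGene(b$blocks, 50, g),
               list(exoncnt = 50L, introncnt = 0L, label = "EXONIC"))
  # 20 exonic + 30 intronic bases -> INTRONIC
  b <- parseAlignBlocks("50M", 180)
  s <- scoreGene(b$blocks, 50, g)
  expect_equal(s$exoncnt, 20L)
  expect_equal(s$introncnt, 30L)
  expect_equal(s$label, "INTRONIC")
  # 24 exonic + 24 intronic + 2 outside -> INTERGENIC
  g2 <- makeGeneEntry("G2", "chr1", "+", 0L, 48L,
                      list(cbind(0L, 24L)))
  b <- parseAlignBlocks("50M", 0)
  s <- scoreGene(b$blocks, 50, g2)
  expect_equal(s$exoncnt, 24L)
  expect_equal(s$introncnt, 24L)
  expect_equal(s$label, "INTERGENIC")
  # transcript maximization: second transcript covers the read fully
  g3 <- makeGeneEntry("G3", "chr1", "+", 0L, 1000L,
                      list(cbind(0L, 100L), cbind(0L, 1000L)))
  b <- parseAlignBlocks("100M", 500)
  expect_equal(scoreGene(b$blocks, 100, g3)$label, "EXONIC")
})

test_that("gene choice follows label priority, overlap, then position", {
  # EXONIC beats INTRONIC
  gExon <- makeGeneEntry("GE", "chr1", "+", 0L, 500L, list(cbind(0L, 500L)))
  gIntr <- makeGeneEntry("GI", "chr1", "+", 0L, 500L, list(cbind(0L, 10L)))
  models <- makeModels(list(gExon, gIntr))
  res <- annotateReads(alnRow("r1", "chr1", 100L, "50M"), models)
  expect_equal(res$gene_id, "GE")
  expect_equal(res$label, "EXONIC")
  expect_false(res$antisense)
  # larger overlap wins among equal labels
  gA <- makeGeneEntry("GA", "chr1", "+", 0L, 140L, list(cbind(0L, 140L)))
  gB <- makeGeneEntry("GB", "chr1", "+", 0L, 500L, list(cbind(0L, 500L)))
  models <- makeModels(list(gA, gB))
  res <- annotateReads(alnRow("r1", "chr1", 100L, "50M"), models)
  expect_equal(res$gene_id, "GB")   # overlap 50 vs 40
  # equal overlap: smallest (start, end) wins
  gC <- makeGeneEntry("GC", "chr1", "+", 100L, 600L, list(cbind(100L, 600L)))
  gD <- makeGeneEntry("GD", "chr1", "+", 0L, 600L, list(cbind(0L, 600L)))
  models <- makeModels(list(gC, gD))
  res <- annotateReads(alnRow("r1", "chr1", 200L, "50M"), models)
  expect_equal(res$gene_id, "GD")
  # antisense flag from strand discordance; label unaffected
  gMinus <- makeGeneEntry("GM", "chr1", "-", 0L, 500L, list(cbind(0L, 500L)))
  models <- makeModels(list(gMinus))
  res <- annotateReads(alnRow("r1", "chr1", 100L, "50M", strand = "+"),
                       models)
  expect_equal(res$label, "EXONIC")
  expect_true(res$antisense)
  # no overlapping gene -> INTERGENIC, no gene
  res <- annotateReads(alnRow("r1", "chr2", 100L, "50M"), models)
  expect_equal(res$label, "INTERGENIC")
  expect_true(is.na(res$gene_id))
  # secondary and low-MAPQ records are not annotated
  res <- annotateReads(rbind(
    alnRow("r1", "chr1", 100L, "50M", secondary = TRUE),
    alnRow("r2", "chr1", 100L, "50M", mapq = 3L)), models)
  expect_equal(nrow(res), 0L)
})

test_that("interval-arithmetic counts equal per-base labeling on random reads", {
  set.seed(77)
  gm <- makeGeneModels(6, seed = 19L)
  f <- tempfile(fileext = ".gtf")
  writeLines(gm$gtf, f)
  models <- loadGeneModels(f)
  for (rep in seq_len(200L)) {
    g <- models@genes[[sample(length(models), 1L)]]
    pos <- g$start + sample(seq(-60L, g$end - g$start), 1L)
    cigar <- sample(c("50M", "20M100N30M", "10S40M", "25M2D25M",
                      "80M", "30M1I19M"), 1L)
    b <- parseAlignBlocks(cigar, pos)
    got <- scoreGene(b$blocks, b$read_length, g)
    want <- oracleScoreGene(b$blocks, b$read_length, g)
    expect_identical(got, want)
  }
})

test_that("annotation tallies are additive and antisense is separate", {
  res <- data.frame(
    label = c("EXONIC", "EXONIC", "EXONIC", "INTRONIC", "INTRONIC"),
    antisense = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  t <- tallyAnnotation(res)
  expect_equal(t$transcriptome, 5L)
  expect_equal(t$exonic, 3L)
  expect_equal(t$antisense, 1L)
  expect_equal(t$exonic + t$intronic + t$intergenic, t$total)
  t0 <- tallyAnnotation(res[0, , drop = FALSE])
  expect_equal(t0$total, 0L)
  expect_equal(t0$transcriptome, 0L)
})

test_that("SAM records round-trip into alignment tables", {
  sim <- stdSim()
  d <- tempfile(); dir.create(d)
  writeLines(sim$sam, file.path(d, "aln.sam"))
  aln <- readAlignments(file.path(d, "aln.sam"))
  expect_equal(nrow(aln), nrow(sim$aln))
  o1 <- order(aln$read_id); o2 <- order(sim$aln$read_id)
  expect_equal(aln$cigar[o1], sim$aln$cigar[o2])
  expect_equal(aln$pos0[o1], sim$aln$pos0[o2])
  expect_equal(aln$strand[o1], sim$aln$strand[o2])
})
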