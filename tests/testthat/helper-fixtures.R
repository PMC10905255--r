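# Shared fixtures and independent oracles for the suite.

BASES4 <- c("A", "C", "G", "T")

randomDna <- function(n, len) {
  if (n == 0L) return(character(0))
  apply(matrix(sample(BASES4, n * len, replace = TRUE), nrow = n), 1L,
        paste0, collapse = "")
}

# random mask over an implicit square chip large enough to hold n entries
randomMask <- function(n, L = 25L, seed = 1L) {
  side <- ceiling(sqrt(n))
  set.seed(seed)
  cids <- unique(randomDna(2L * n, L))[seq_len(n)]
  idx <- seq_len(n) - 1L
  MaskTable(ChipSpec("rand", side, side, L), cids,
            x = idx %% side, y = idx %/% side)
}

# exhaustive Hamming-scan oracle for CID location: full query-by-mask
# distance matrix (indicator-matrix form of the all-pairs scan), then the
# same classification rules applied from raw distances
oracleLocate <- function(mask, queries) {
  L <- chipCidLength(maskChip(mask))
  me <- maskEntries(mask)
  qc <- matrix(unlist(strsplit(queries, "", fixed = TRUE)),
               ncol = L, byrow = TRUE)
  mc <- matrix(unlist(strsplit(me$cid, "", fixed = TRUE)),
               ncol = L, byrow = TRUE)
  D <- matrix(L, length(queries), nrow(me))
  for (b in BASES4) D <- D - (qc == b) %*% t(mc == b)
  kind <- character(length(queries))
  x <- rep(NA_integer_, length(queries))
  y <- rep(NA_integer_, length(queries))
  for (i in seq_along(queries)) {
    d <- D[i, ]
    if (any(d == 0L)) {
      j <- which(d == 0L)[1L]
      kind[i] <- "exact"; x[i] <- me$x[j]; y[i] <- me$y[j]
    } else {
      hits <- which(d == 1L)
      if (length(hits) == 1L) {
        kind[i] <- "corrected"; x[i] <- me$x[hits]; y[i] <- me$y[hits]
      } else if (length(hits) >= 2L) kind[i] <- "ambiguous"
      else kind[i] <- "unmatched"
    }
  }
  data.frame(match_kind = kind, x = x, y = y)
}

# per-base annotation oracle: label every aligned base individually by
# exon/intron membership, per transcript, then take the same
# (exoncnt, introncnt) maximization
oracleScoreGene <- function(blocks, readLength, gene) {
  bases <- unlist(lapply(seq_len(nrow(blocks)), function(k)
    seq(blocks$ref_start[k], blocks$ref_end[k] - 1L)))
  bestE <- -1L; bestI <- -1L
  for (tx in gene$transcripts) {
    inExon <- vapply(bases, function(p)
      any(p >= tx[, "start0"] & p < tx[, "end0"]), TRUE)
    inGene <- bases >= gene$start & bases < gene$end
    e <- sum(inExon)
    i <- sum(inGene & !inExon)
    if (e > bestE || (e == bestE && i > bestI)) { bestE <- e; bestI <- i }
  }
  label <- if (bestE >= 0.5 * readLength) "EXONIC"
           else if (bestI >= 0.5 * readLength) "INTRONIC"
           else "INTERGENIC"
  list(exoncnt = bestE, introncnt = bestI, label = label)
}

# hand-built gene entry in the internal GeneModels layout
makeGeneEntry <- function(gene_id, chrom, strand, start, end, exonsList) {
  list(gene_id = gene_id, chrom = chrom, strand = strand,
       start = start, end = end,
       transcripts = lapply(exonsList, function(e)
         cbind(start0 = e[, 1L], end0 = e[, 2L])))
}

# GeneModels object from a list of gene entries
makeModels <- function(entries) {
  names(entries) <- vapply(entries, `[[`, "", "gene_id")
  ranges <- GenomicRanges::GRanges(
    seqnames = vapply(entries, `[[`, "", "chrom"),
    ranges = IRanges::IRanges(
      start = vapply(entries, `[[`, 0L, "start") + 1L,
      end = vapply(entries, `[[`, 0L, "end")),
    gene_id = names(entries))
  new("GeneModels", genes = entries, ranges = ranges)
}

# one-row alignment table
alnRow <- function(read_id, chrom, pos0, cigar, strand = "+", mapq = 255L,
                   secondary = FALSE) {
  data.frame(read_id = read_id, chrom = chrom, pos0 = pos0, cigar = cigar,
             strand = strand, mapq = mapq, secondary = secondary,
             stringsAsFactors = FALSE)
}

# memoised standard simulation fixture (written to a per-session tempdir)
.fixtures <- new.env(parent = emptyenv())

stdSimDir <- function() {
  if (is.null(.fixtures$stdDir)) {
    d <- file.path(tempdir(), "stereoflow-stdsim")
    simulateRun(simulationParams(seed = 42L), outdir = d)
    .fixtures$stdDir <- d
  }
  .fixtures$stdDir
}

stdSim <- function() {
  if (is.null(.fixtures$stdSim))
    .fixtures$stdSim <- simulateRun(simulationParams(seed = 42L))
  .fixtures$stdSim
}

# read table built directly from sequences (constant top quality)
readTable <- function(cid, mid = strrep("C", 10L), cdna = strrep("G", 50L)) {
  n <- max(length(cid), length(mid), length(cdna))
  cid <- rep_len(cid, n); mid <- rep_len(mid, n); cdna <- rep_len(cdna, n)
  q <- function(s) vapply(nchar(s),
                          function(k) strrep("I", k), "")
  data.frame(read_id = sprintf("t%04d", seq_len(n)), cid = cid, mid = mid,
             cdna = cdna, cid_qual = q(cid), mid_qual = q(mid),
             cdna_qual = q(cdna), stringsAsFactors = FALSE)
}
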