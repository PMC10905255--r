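#' Load gene models from GTF/GFF
#'
#' Parses gene/transcript/exon features (via `rtracklayer`) into an
#' overlap-indexed [GeneModels-class]. The file's 1-based closed
#' coordinates are converted to 0-based half-open internally. Gene spans
#' may be given as `gene` features or are derived as the hull of each
#' gene's exons.
#'
#' @param path GTF or GFF3 file.
#' @return a [GeneModels-class].
#' @export
loadGeneModels <- function(path) {
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  exons <- gr[type == "exon"]
  if (!length(exons)) stop("no exon features in ", path)
  emc <- S4Vectors::mcols(exons)
  if (is.null(emc$gene_id) || anyNA(emc$gene_id))
    stop("exon feature missing gene_id attribute")
  if (is.null(emc$transcript_id) || anyNA(emc$transcript_id))
    stop("exon feature missing transcript_id attribute")
  if (any(as.character(GenomicRanges::strand(exons)) == "*"))
    stop("unknown strand on exon feature")
  geneRows <- gr[type == "gene"]
  geneSpan <- list()
  if (length(geneRows)) {
    gm <- S4Vectors::mcols(geneRows)
    for (i in seq_along(geneRows))
      geneSpan[[as.character(gm$gene_id[i])]] <-
        c(GenomicRanges::start(geneRows)[i] - 1L,
          GenomicRanges::end(geneRows)[i])
  }
  ex <- data.frame(
    gene_id = as.character(emc$gene_id),
    transcript_id = as.character(emc$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(exons)),
    strand = as.character(GenomicRanges::strand(exons)),
    start0 = GenomicRanges::start(exons) - 1L,
    end0 = GenomicRanges::end(exons),
    stringsAsFactors = FALSE)
  genes <- list()
  for (gid in unique(ex$gene_id)) {
    gx <- ex[ex$gene_id == gid, , drop = FALSE]
    chrom <- unique(gx$chrom)
    strandc <- unique(gx$strand)
    if (length(chrom) != 1L || length(strandc) != 1L)
      stop("gene ", gid, " has inconsistent chrom/strand across exons")
    span <- geneSpan[[gid]]
    if (is.null(span)) span <- c(min(gx$start0), max(gx$end0))
    if (any(gx$start0 < span[1L]) || any(gx$end0 > span[2L]))
      stop("exon outside gene span for gene ", gid)
    transcripts <- lapply(split(gx, gx$transcript_id), function(tx) {
      tx <- tx[order(tx$start0), , drop = FALSE]
      if (nrow(tx) > 1L && any(tx$start0[-1L] < tx$end0[-nrow(tx)]))
        stop("overlapping exons within a transcript of gene ", gid)
      cbind(start0 = tx$start0, end0 = tx$end0)
    })
    genes[[gid]] <- list(gene_id = gid, chrom = chrom, strand = strandc,
                         start = span[1L], end = span[2L],
                         transcripts = transcripts)
  }
  ranges <- GenomicRanges::GRanges(
    seqnames = vapply(genes, `[[`, "", "chrom"),
    ranges = IRanges::IRanges(
      start = vapply(genes, `[[`, 0L, "start") + 1L,
      end = vapply(genes, `[[`, 0L, "end")),
    gene_id = names(genes))
  new("GeneModels", genes = genes, ranges = ranges)
}

#' Parse CIGAR into reference align blocks
#'
#' M/=/X ops extend the current reference block; N (splice gap) and D
#' close it (both advance the reference); I and S consume read only; H
#' consumes neither. Read length is the sum of M/=/X/I/S lengths.
#'
#' @param cigar CIGAR string.
#' @param refPos0 0-based reference position of the first aligned base.
#' @return list with `read_length` and `blocks`, a data.frame with
#'   0-based half-open `ref_start`/`ref_end`, `read_offset` (0-based
#'   offset of the block's first base within the read) and `length`.
#' @examples
#' parseAlignBlocks("20M100N30M", 0)
#' @export
parseAlignBlocks <- function(cigar, refPos0) {
  if (!grepl("^([0-9]+[MIDNSHP=X])+$", cigar))
    stop("malformed CIGAR: ", cigar)
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1L]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]]
  ref <- as.integer(refPos0)
  readCur <- 0L
  readLen <- 0L
  bs <- integer(0); be <- integer(0); bo <- integer(0)
  curStart <- NA_integer_; curOffset <- NA_integer_
  closeBlock <- function() {
    if (!is.na(curStart) && ref > curStart) {
      bs <<- c(bs, curStart); be <<- c(be, ref); bo <<- c(bo, curOffset)
    }
    curStart <<- NA_integer_
  }
  for (k in seq_along(ops)) {
    op <- ops[k]; len <- lens[k]
    if (op %in% c("M", "=", "X")) {
      if (is.na(curStart)) { curStart <- ref; curOffset <- readCur }
      ref <- ref + len; readCur <- readCur + len; readLen <- readLen + len
    } else if (op %in% c("N", "D")) {
      closeBlock(); ref <- ref + len
    } else if (op %in% c("I", "S")) {
      readCur <- readCur + len; readLen <- readLen + len
    } # H, P: consume neither
  }
  closeBlock()
  list(read_length = readLen,
       blocks = data.frame(ref_start = bs, ref_end = be, read_offset = bo,
                           length = be - bs))
}

# overlap of one set of half-open intervals with another (total bases)
.intervalOverlap <- function(aStart, aEnd, bStart, bEnd) {
  if (!length(aStart) || !length(bStart)) return(0L)
  total <- 0L
  for (i in seq_along(aStart)) {
    o <- pmin(aEnd[i], bEnd) - pmax(aStart[i], bStart)
    total <- total + sum(pmax(0L, o))
  }
  total
}

# complement of exons within the gene span (the transcript's introns plus
# any span flanks outside its exons)
.nonExonIntervals <- function(exons, geneStart, geneEnd) {
  starts <- c(geneStart, exons[, "end0"])
  ends <- c(exons[, "start0"], geneEnd)
  keep <- ends > starts
  cbind(start0 = starts[keep], end0 = ends[keep])
}

#' Score a read's align blocks against one gene
#'
#' For each transcript, the exon count is the total overlap of the blocks
#' with that transcript's exons and the intron count the overlap with the
#' gene span minus those exons; the transcript maximizing (exoncnt, then
#' introncnt) provides the gene's counts. The label follows the 50% rule:
#' EXONIC when `exoncnt >= read_length / 2`, else INTRONIC when
#' `introncnt >= read_length / 2`, else INTERGENIC.
#'
#' @param blocks align-block data.frame from [parseAlignBlocks()].
#' @param readLength read length in bases.
#' @param gene one gene entry of a [GeneModels-class] (`models@genes[[i]]`).
#' @return list with `exoncnt`, `introncnt`, `label`.
#' @export
scoreGene <- function(blocks, readLength, gene) {
  bestE <- -1L; bestI <- -1L
  for (tx in gene$transcripts) {
    e <- .intervalOverlap(blocks$ref_start, blocks$ref_end,
                          tx[, "start0"], tx[, "end0"])
    nonExon <- .nonExonIntervals(tx, gene$start, gene$end)
    i <- .intervalOverlap(blocks$ref_start, blocks$ref_end,
                          nonExon[, "start0"], nonExon[, "end0"])
    if (e > bestE || (e == bestE && i > bestI)) { bestE <- e; bestI <- i }
  }
  label <- if (bestE >= 0.5 * readLength) "EXONIC"
           else if (bestI >= 0.5 * readLength) "INTRONIC"
           else "INTERGENIC"
  list(exoncnt = bestE, introncnt = bestI, label = label)
}

.LABEL_PRIORITY <- c(EXONIC = 3L, INTRONIC = 2L, INTERGENIC = 1L)

#' Annotate alignment records against gene models
#'
#' For every uniquely mapped record: parse the CIGAR into align blocks,
#' find all overlapping genes, score each ([scoreGene()]), keep the genes
#' with the best label (EXONIC > INTRONIC > INTERGENIC), among those the
#' gene with maximal overlap with the read, ties broken by smallest
#' (start, end, gene_id). The antisense flag compares alignment strand to
#' the chosen gene's strand; the region label itself ignores strand. Reads
#' overlapping no gene are INTERGENIC with no gene.
#'
#' @param aln alignment data.frame with columns `read_id`, `chrom`, `pos0`
#'   (0-based leftmost aligned position), `cigar`, `strand` (`"+"`/`"-"`),
#'   `mapq`, `secondary` (logical); see [readAlignments()].
#' @param models a [GeneModels-class].
#' @param minMapq minimum mapping quality regarded as unique (secondary/
#'   supplementary records are always dropped).
#' @return data.frame with `read_id`, `gene_id` (NA for intergenic),
#'   `label`, `antisense`, `exoncnt`, `introncnt`, `overlap_len`.
#' @export
annotateReads <- function(aln, models, minMapq = 20L) {
  stopifnot(is(models, "GeneModels"))
  keep <- !aln$secondary & aln$mapq >= minMapq
  aln <- aln[keep, , drop = FALSE]
  n <- nrow(aln)
  gene_id <- rep.int(NA_character_, n)
  label <- rep.int("INTERGENIC", n)
  antisense <- rep.int(FALSE, n)
  exoncnt <- integer(n); introncnt <- integer(n); overlap_len <- integer(n)
  if (n) {
    parsed <- lapply(seq_len(n),
                     function(i) parseAlignBlocks(aln$cigar[i], aln$pos0[i]))
    # candidate genes per read: any block overlapping the gene span
    qb <- do.call(rbind, lapply(seq_len(n), function(i) {
      b <- parsed[[i]]$blocks
      if (!nrow(b)) return(NULL)
      cbind(read = i, start = b$ref_start + 1L, end = b$ref_end)
    }))
    if (!is.null(qb) && nrow(qb)) {
      query <- GenomicRanges::GRanges(
        seqnames = aln$chrom[qb[, "read"]],
        ranges = IRanges::IRanges(start = qb[, "start"], end = qb[, "end"]))
      # reads on sequences without any gene are legitimately intergenic
      ov <- suppressWarnings(
        GenomicRanges::findOverlaps(query, models@ranges))
      pairs <- unique(data.frame(
        read = qb[S4Vectors::queryHits(ov), "read"],
        gene = S4Vectors::subjectHits(ov)))
      for (i in unique(pairs$read)) {
        cand <- pairs$gene[pairs$read == i]
        b <- parsed[[i]]$blocks
        rl <- parsed[[i]]$read_length
        best <- NULL
        for (gi in cand) {
          g <- models@genes[[gi]]
          sc <- scoreGene(b, rl, g)
          ov_len <- .intervalOverlap(b$ref_start, b$ref_end,
                                     g$start, g$end)
          entry <- list(gene = g, score = sc, overlap = ov_len)
          if (is.null(best)) { best <- entry; next }
          pNew <- .LABEL_PRIORITY[[sc$label]]
          pOld <- .LABEL_PRIORITY[[best$score$label]]
          better <-
            if (pNew != pOld) pNew > pOld
            else if (entry$overlap != best$overlap)
              entry$overlap > best$overlap
            else if (g$start != best$gene$start) g$start < best$gene$start
            else if (g$end != best$gene$end) g$end < best$gene$end
            else g$gene_id < best$gene$gene_id
          if (better) best <- entry
        }
        if (best$score$label != "INTERGENIC") {
          gene_id[i] <- best$gene$gene_id
          label[i] <- best$score$label
          antisense[i] <- aln$strand[i] != best$gene$strand
          exoncnt[i] <- best$score$exoncnt
          introncnt[i] <- best$score$introncnt
          overlap_len[i] <- best$overlap
        }
      }
    }
  }
  data.frame(read_id = aln$read_id, gene_id = gene_id, label = label,
             antisense = antisense, exoncnt = exoncnt,
             introncnt = introncnt, overlap_len = overlap_len,
             stringsAsFactors = FALSE)
}

#' Tally annotation results
#'
#' Region counters partition the input (exonic + intronic + intergenic =
#' total); the transcriptome row is exonic + intronic; antisense reads are
#' tallied alongside the region counts, not removed from them (they are
#' excluded later, at expression-matrix construction).
#'
#' @param results data.frame from [annotateReads()].
#' @return list of counters: total, exonic, intronic, intergenic,
#'   transcriptome, antisense.
#' @export
tallyAnnotation <- function(results) {
  ex <- sum(results$label == "EXONIC")
  intr <- sum(results$label == "INTRONIC")
  inter <- sum(results$label == "INTERGENIC")
  list(total = nrow(results), exonic = ex, intronic = intr,
       intergenic = inter, transcriptome = ex + intr,
       antisense = sum(results$antisense))
}

#' Read alignment records from SAM/BAM
#'
#' SAM input is converted with `Rsamtools::asBam` and records are read via
#' `GenomicAlignments::readGAlignments`; secondary/supplementary flags are
#' preserved in the `secondary` column.
#'
#' @param path SAM or BAM file.
#' @return alignment data.frame suitable for [annotateReads()].
#' @export
readAlignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(what = c("flag", "mapq"))
  ga <- GenomicAlignments::readGAlignments(path, use.names = TRUE,
                                           param = param)
  flag <- S4Vectors::mcols(ga)$flag
  data.frame(
    read_id = names(ga),
    chrom = as.character(GenomicRanges::seqnames(ga)),
    pos0 = GenomicAlignments::start(ga) - 1L,
    cigar = GenomicAlignments::cigar(ga),
    strand = as.character(GenomicRanges::strand(ga)),
    mapq = S4Vectors::mcols(ga)$mapq,
    secondary = bitwAnd(flag, 0x100L) > 0L | bitwAnd(flag, 0x800L) > 0L,
    stringsAsFactors = FALSE)
}
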