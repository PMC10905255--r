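#' Generate a chip mask with distinct random CIDs
#'
#' Draws one distinct uniform CID per lattice coordinate (row-major:
#' `x = i %% width`, `y = i %/% width`). For small chips the mask is
#' resampled until the minimum pairwise Hamming distance reaches
#' `minHamming`, so single-error correction is unambiguous in tests; for
#' larger chips the pairwise scan is skipped and only distinctness is
#' enforced.
#'
#' @param chip a [ChipSpec-class]; requires `4^cidLength >= width * height`.
#' @param seed RNG seed; the mask is deterministic for a seed.
#' @param minHamming minimum pairwise CID distance to enforce; default 3
#'   for chips of at most 2500 spots, else 1 (distinctness only).
#' @return a [MaskTable-class].
#' @export
makeChip <- function(chip, seed = 1L, minHamming = NULL) {
  stopifnot(is(chip, "ChipSpec"))
  n <- chip@width * chip@height
  L <- chip@cidLength
  if (4^L < n) stop("chip too large for cidLength")
  if (is.null(minHamming)) minHamming <- if (n <= 2500L) 3L else 1L
  cids <- .withSeed(seed, {
    cids <- .randomDna(n, L)
    for (iter in seq_len(200L)) {
      bad <- if (minHamming >= 2L && n > 1L)
        .minDistOffenders(cids, L, minHamming)
      else which(duplicated(cids) | duplicated(cids, fromLast = TRUE))
      if (!length(bad)) break
      cids[bad] <- .randomDna(length(bad), L)
    }
    if (length(bad <- which(duplicated(cids))))
      stop("failed to draw distinct CIDs")
    cids
  })
  idx <- seq_len(n) - 1L
  MaskTable(chip, cids, x = idx %% chip@width, y = idx %/% chip@width)
}

# rows involved in any pair closer than minHamming
.minDistOffenders <- function(cids, L, minHamming) {
  n <- length(cids)
  m <- .seqMatrix(cids, L)
  matches <- matrix(0L, n, n)
  for (b in BASES) {
    A <- (m == b) * 1L
    matches <- matches + tcrossprod(A)
  }
  d <- L - matches
  diag(d) <- L
  which(apply(d < minHamming, 1L, any))
}

#' Generate toy gene models and their GTF
#'
#' Lays out non-overlapping multi-exon genes (one transcript each, 1–3
#' exons of 100–300 bases separated by 50–200 base introns) across toy
#' chromosomes, alternating strands. With `overlapMode = TRUE` an extra
#' gene is added overlapping the first gene on the opposite strand, for
#' tie-break tests.
#'
#' @param nGenes number of genes (>= 1).
#' @param seed RNG seed.
#' @param nChroms number of toy chromosomes.
#' @param overlapMode add an opposite-strand overlapping gene pair.
#' @return list with `gtf` (character lines), `chromLengths` (named
#'   integer) and `genes` (data.frame: gene_id, chrom, strand, start0,
#'   end0 plus an `exons` list-column of 0-based half-open matrices).
#' @export
makeGeneModels <- function(nGenes, seed = 1L, nChroms = 2L,
                           overlapMode = FALSE) {
  stopifnot(nGenes >= 1L)
  .withSeed(seed, {
    cursor <- rep.int(100L, nChroms)
    rows <- vector("list", nGenes)
    for (i in seq_len(nGenes)) {
      chrom <- ((i - 1L) %% nChroms) + 1L
      nEx <- sample(1:3, 1L)
      exLen <- sample(100:300, nEx, replace = TRUE)
      inLen <- if (nEx > 1L) sample(50:200, nEx - 1L, replace = TRUE)
               else integer(0)
      start <- cursor[chrom]
      starts <- start + cumsum(c(0L, head(exLen, -1L) + inLen))
      ends <- starts + exLen
      rows[[i]] <- list(gene_id = sprintf("G%03d", i),
                        chrom = sprintf("chr%d", chrom),
                        strand = sample(c("+", "-"), 1L),
                        start0 = start, end0 = ends[nEx],
                        exons = cbind(start0 = starts, end0 = ends))
      cursor[chrom] <- ends[nEx] + sample(200:500, 1L)
    }
    if (overlapMode) {
      g1 <- rows[[1L]]
      ov <- list(gene_id = "G_OVL", chrom = g1$chrom,
                 strand = if (g1$strand == "+") "-" else "+",
                 start0 = g1$start0 + 50L, end0 = g1$end0 + 150L,
                 exons = cbind(start0 = g1$start0 + 50L,
                               end0 = g1$end0 + 150L))
      rows <- c(rows, list(ov))
    }
    chromLengths <- setNames(integer(nChroms), sprintf("chr%d",
                                                       seq_len(nChroms)))
    for (r in rows)
      chromLengths[r$chrom] <- max(chromLengths[r$chrom], r$end0 + 500L)
    gtf <- character(0)
    for (r in rows) {
      attrsG <- sprintf('gene_id "%s";', r$gene_id)
      attrsT <- sprintf('gene_id "%s"; transcript_id "%s.t1";', r$gene_id,
                        r$gene_id)
      gtf <- c(gtf,
               sprintf("%s\tstereoflow\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       r$chrom, r$start0 + 1L, r$end0, r$strand, attrsG),
               sprintf("%s\tstereoflow\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                       r$chrom, r$start0 + 1L, r$end0, r$strand, attrsT),
               sprintf("%s\tstereoflow\texon\t%d\t%d\t.\t%s\t.\t%s",
                       r$chrom, r$exons[, "start0"] + 1L, r$exons[, "end0"],
                       r$strand, attrsT))
    }
    genes <- data.frame(
      gene_id = vapply(rows, `[[`, "", "gene_id"),
      chrom = vapply(rows, `[[`, "", "chrom"),
      strand = vapply(rows, `[[`, "", "strand"),
      start0 = vapply(rows, `[[`, 0L, "start0"),
      end0 = vapply(rows, `[[`, 0L, "end0"),
      stringsAsFactors = FALSE)
    genes$exons <- lapply(rows, `[[`, "exons")
    list(gtf = gtf, chromLengths = chromLengths, genes = genes)
  })
}

#' Simulation parameters
#'
#' Defaults describe the standard desk-scale run: a 20 x 20-spot chip
#' with 25-base CIDs, 5 genes, 2000 molecules on a central disk of
#' radius one third of the chip width, light background, per-base
#' substitution error rates of 1% on the CID and cDNA and 0.5% on the
#' MID, and mean 3-fold PCR duplication (shifted Poisson).
#'
#' @param chip a [ChipSpec-class].
#' @param nGenes,nMolecules simulation size.
#' @param cidErrorRate,midErrorRate,cdnaErrorRate per-base substitution
#'   probabilities in [0, 1).
#' @param duplicationMean mean reads per molecule (>= 1); counts are
#'   1 + Poisson(duplicationMean - 1).
#' @param tissueShape `"disk"`, `"rectangle"` or `"none"` (uniform over
#'   the chip).
#' @param tissueGeometry `disk`: list(cx, cy, r); `rectangle`:
#'   list(x0, x1, y0, y1) (half-open); default: centered disk of radius
#'   width/3.
#' @param backgroundRate expected molecules per off-tissue spot.
#' @param midLength MID length in bases.
#' @param fragLength cDNA fragment length in bases (capped by transcript
#'   length).
#' @param seed RNG seed; must stay below 2^31 - 2 after internal offsets.
#' @return named list of parameters.
#' @export
simulationParams <- function(chip = ChipSpec("toy20", 20L, 20L, 25L),
                             nGenes = 5L, nMolecules = 2000L,
                             cidErrorRate = 0.01, midErrorRate = 0.005,
                             cdnaErrorRate = 0.01, duplicationMean = 3,
                             tissueShape = c("disk", "rectangle", "none"),
                             tissueGeometry = NULL, backgroundRate = 0.05,
                             midLength = 10L, fragLength = 50L, seed = 42L) {
  tissueShape <- match.arg(tissueShape)
  stopifnot(cidErrorRate >= 0, cidErrorRate < 1, midErrorRate >= 0,
            midErrorRate < 1, cdnaErrorRate >= 0, cdnaErrorRate < 1,
            duplicationMean >= 1, nGenes >= 1L, nMolecules >= 0L)
  if (is.null(tissueGeometry) && tissueShape == "disk")
    tissueGeometry <- list(cx = chip@width / 2, cy = chip@height / 2,
                           r = chip@width / 3)
  if (is.null(tissueGeometry) && tissueShape == "rectangle")
    tissueGeometry <- list(x0 = chip@width %/% 4, x1 = 3L * chip@width %/% 4,
                           y0 = chip@height %/% 4,
                           y1 = 3L * chip@height %/% 4)
  list(chip = chip, nGenes = as.integer(nGenes),
       nMolecules = as.integer(nMolecules), cidErrorRate = cidErrorRate,
       midErrorRate = midErrorRate, cdnaErrorRate = cdnaErrorRate,
       duplicationMean = duplicationMean, tissueShape = tissueShape,
       tissueGeometry = tissueGeometry, backgroundRate = backgroundRate,
       midLength = as.integer(midLength), fragLength = as.integer(fragLength),
       seed = as.integer(seed))
}

# logical: which lattice spots are inside the tissue geometry
.inTissue <- function(params, x, y) {
  g <- params$tissueGeometry
  switch(params$tissueShape,
         disk = (x - g$cx)^2 + (y - g$cy)^2 <= g$r^2,
         rectangle = x >= g$x0 & x < g$x1 & y >= g$y0 & y < g$y1,
         none = rep.int(TRUE, length(x)))
}

#' Ground-truth tissue raster at a bin size
#'
#' Binary truth for segmentation scoring: a bin is tissue when at least
#' half of its spots fall inside the simulated geometry.
#'
#' @param params see [simulationParams()].
#' @param binSize bin side in bin1 units.
#' @return logical matrix (x along rows).
#' @export
tissueTruthRaster <- function(params, binSize = 1L) {
  chip <- params$chip
  nx <- as.integer(ceiling(chip@width / binSize))
  ny <- as.integer(ceiling(chip@height / binSize))
  xs <- rep(seq_len(chip@width) - 1L, times = chip@height)
  ys <- rep(seq_len(chip@height) - 1L, each = chip@width)
  inT <- .inTissue(params, xs, ys)
  dt <- data.table::data.table(bx = xs %/% binSize, by = ys %/% binSize,
                               inT = inT)
  agg <- dt[, .(frac = mean(inT)), by = .(bx, by)]
  out <- matrix(FALSE, nx, ny)
  out[cbind(agg$bx + 1L, agg$by + 1L)] <- agg$frac >= 0.5
  out
}

# substitute bases at per-base rate; returns sequences and error positions
.injectErrors <- function(seqs, rate, len) {
  n <- length(seqs)
  if (n == 0L || rate <= 0)
    return(list(seqs = seqs, positions = vector("list", n)))
  m <- .seqMatrix(seqs, len)
  err <- matrix(runif(n * len) < rate, n, len)
  idx <- which(err, arr.ind = TRUE)
  if (nrow(idx)) {
    old <- m[idx]
    shift <- sample.int(3L, nrow(idx), replace = TRUE)
    m[idx] <- BASES[((match(old, BASES) - 1L + shift) %% 4L) + 1L]
  }
  positions <- vector("list", n)
  if (nrow(idx)) {
    sp <- split(idx[, 2L], idx[, 1L])
    positions[as.integer(names(sp))] <- lapply(sp, sort)
  }
  list(seqs = apply(m, 1L, paste0, collapse = ""), positions = positions)
}

# map a transcript-coordinate interval [fragStart, fragStart+fragLen)
# through the exon structure: returns genomic blocks and a CIGAR
.fragmentToGenome <- function(exons, fragStart, fragLen) {
  exLen <- exons[, "end0"] - exons[, "start0"]
  offs <- cumsum(c(0L, exLen))
  bs <- integer(0); be <- integer(0)
  remain <- fragLen
  pos <- fragStart
  for (k in seq_len(nrow(exons))) {
    if (remain <= 0L) break
    if (pos >= offs[k + 1L]) next
    within <- pos - offs[k]
    take <- min(remain, exLen[k] - within)
    bs <- c(bs, exons[k, "start0"] + within)
    be <- c(be, exons[k, "start0"] + within + take)
    pos <- pos + take
    remain <- remain - take
  }
  ops <- sprintf("%dM", be - bs)
  gaps <- if (length(bs) > 1L) sprintf("%dN", bs[-1L] - be[-length(be)])
          else character(0)
  cigar <- paste0(paste0(head(ops, -1L), gaps, collapse = ""),
                  ops[length(ops)])
  list(pos0 = bs[1L], cigar = cigar, blocks = cbind(start0 = bs, end0 = be))
}

#' Simulate a sequencing run with full ground truth
#'
#' Places molecules on the tissue geometry plus uniform background,
#' duplicates each (shifted Poisson), and emits reads whose CID/MID/cDNA
#' carry independent per-base substitution errors, together with
#' alignment records placed at each molecule's true exonic coordinates
#' (splice-aware CIGARs across introns). Alignments come from the truth,
#' not an aligner: genome alignment is outside this package's scope and
#' synthesizing records isolates the pipeline's own computation.
#'
#' @param params see [simulationParams()].
#' @param outdir optional directory; when given, writes `mask.tsv`,
#'   `reads_R1.fastq`, `reads_R2.fastq`, `aln.sam`, `genes.gtf`,
#'   `truth_molecules.tsv`, `truth_reads.tsv`.
#' @return list with `mask` ([MaskTable-class]), `gtf` (lines),
#'   `geneInfo` (from [makeGeneModels()]), `reads` (read table), `aln`
#'   (alignment data.frame for [annotateReads()]), `sam` (text lines),
#'   `truth` (list of `molecules` and `reads` data.frames) and `params`.
#' @export
simulateRun <- function(params = simulationParams(), outdir = NULL) {
  chip <- params$chip
  mask <- makeChip(chip, seed = params$seed)
  gm <- makeGeneModels(params$nGenes, seed = params$seed + 1L)
  sim <- .withSeed(params$seed + 2L, {
    # molecule placement
    xs <- rep(seq_len(chip@width) - 1L, times = chip@height)
    ys <- rep(seq_len(chip@height) - 1L, each = chip@width)
    inT <- .inTissue(params, xs, ys)
    tIdx <- which(inT); bIdx <- which(!inT)
    molSpots <- if (length(tIdx))
      sample(tIdx, params$nMolecules, replace = TRUE)
    else integer(0)
    nBg <- if (length(bIdx) && params$backgroundRate > 0)
      rpois(1L, params$backgroundRate * length(bIdx)) else 0L
    molSpots <- c(molSpots, if (nBg) sample(bIdx, nBg, replace = TRUE))
    nMol <- length(molSpots)
    mx <- xs[molSpots]; my <- ys[molSpots]
    geneRow <- sample.int(nrow(gm$genes), nMol, replace = TRUE)
    mids <- .randomDna(nMol, params$midLength)
    dup <- 1L + rpois(nMol, params$duplicationMean - 1)
    # fragments
    exonsOf <- gm$genes$exons
    txLen <- vapply(exonsOf, function(e) sum(e[, "end0"] - e[, "start0"]),
                    0L)
    fragLen <- pmin(params$fragLength, txLen[geneRow])
    fragStart <- vapply(seq_len(nMol), function(i) {
      room <- txLen[geneRow[i]] - fragLen[i]
      if (room > 0L) sample.int(room + 1L, 1L) - 1L else 0L
    }, 0L)
    frags <- lapply(seq_len(nMol), function(i)
      .fragmentToGenome(exonsOf[[geneRow[i]]], fragStart[i], fragLen[i]))
    # toy genome for cDNA sequence
    chromSeq <- lapply(gm$chromLengths, function(L)
      paste0(sample(BASES, L, replace = TRUE), collapse = ""))
    cdnaTrue <- vapply(seq_len(nMol), function(i) {
      b <- frags[[i]]$blocks
      paste0(substring(chromSeq[[gm$genes$chrom[geneRow[i]]]],
                       b[, "start0"] + 1L, b[, "end0"]), collapse = "")
    }, "")
    # expand to reads
    rIdx <- rep.int(seq_len(nMol), dup)
    nReads <- length(rIdx)
    readIds <- sprintf("r%07d", seq_len(nReads))
    spotKey <- mx[rIdx] + my[rIdx] * chip@width
    trueCid <- mask@cid[match(spotKey, mask@x + mask@y * chip@width)]
    cidE <- .injectErrors(trueCid, params$cidErrorRate, chip@cidLength)
    midE <- .injectErrors(mids[rIdx], params$midErrorRate, params$midLength)
    # cDNA lengths vary; inject per unique length group
    cdna <- cdnaTrue[rIdx]
    if (params$cdnaErrorRate > 0) {
      for (L in unique(nchar(cdna))) {
        sel <- which(nchar(cdna) == L)
        cdna[sel] <- .injectErrors(cdna[sel], params$cdnaErrorRate, L)$seqs
      }
    }
    q <- function(s) vapply(nchar(s), function(k)
      paste0(rep.int("I", k), collapse = ""), "")
    reads <- data.frame(
      read_id = readIds, cid = cidE$seqs, mid = midE$seqs, cdna = cdna,
      cid_qual = q(cidE$seqs), mid_qual = q(midE$seqs), cdna_qual = q(cdna),
      stringsAsFactors = FALSE)
    strandOf <- gm$genes$strand[geneRow]
    aln <- data.frame(
      read_id = readIds,
      chrom = gm$genes$chrom[geneRow[rIdx]],
      pos0 = vapply(frags, `[[`, 0L, "pos0")[rIdx],
      cigar = vapply(frags, `[[`, "", "cigar")[rIdx],
      strand = strandOf[rIdx],
      mapq = 255L, secondary = FALSE, stringsAsFactors = FALSE)
    truthMol <- data.frame(
      mol_id = seq_len(nMol), x = mx, y = my,
      gene_id = gm$genes$gene_id[geneRow], mid = mids, dup = dup,
      in_tissue = inT[molSpots], stringsAsFactors = FALSE)
    truthReads <- data.frame(
      read_id = readIds, mol_id = rIdx,
      cid_errors = vapply(cidE$positions[seq_len(nReads)], function(p)
        paste(p, collapse = ","), ""),
      mid_errors = vapply(midE$positions[seq_len(nReads)], function(p)
        paste(p, collapse = ","), ""),
      stringsAsFactors = FALSE)
    sam <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", names(gm$chromLengths),
                     gm$chromLengths),
             sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                     aln$read_id, ifelse(aln$strand == "-", 16L, 0L),
                     aln$chrom, aln$pos0 + 1L, aln$mapq, aln$cigar,
                     reads$cdna, reads$cdna_qual))
    list(reads = reads, aln = aln, sam = sam,
         truth = list(molecules = truthMol, reads = truthReads))
  })
  out <- c(list(mask = mask, gtf = gm$gtf, geneInfo = gm, params = params),
           sim)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeMask(mask, file.path(outdir, "mask.tsv"))
    writeReadFastq(sim$reads, file.path(outdir, "reads_R1.fastq"),
                   file.path(outdir, "reads_R2.fastq"))
    writeLines(sim$sam, file.path(outdir, "aln.sam"))
    writeLines(gm$gtf, file.path(outdir, "genes.gtf"))
    write.table(sim$truth$molecules,
                file.path(outdir, "truth_molecules.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(sim$truth$reads, file.path(outdir, "truth_reads.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Generate MID groups with injected errors and known truth
#'
#' Constructs per-(coordinate, gene) MID groups directly: each group holds
#' `k` distinct true MIDs, every molecule is read `1 + Poisson(duplicationMean
#' - 1)` times, and each read's MID carries independent per-base
#' substitution errors. The returned truth is the designed molecule count
#' `k`, against which corrected unique-MID counts can be scored. Group
#' coordinates/genes are synthetic labels; correction never looks across
#' groups.
#'
#' @param nGroups number of groups.
#' @param k true molecules (distinct MIDs) per group.
#' @param duplicationMean mean reads per molecule (>= 1).
#' @param midErrorRate per-base substitution probability.
#' @param midLength MID length in bases.
#' @param seed RNG seed.
#' @return list with `groups` (data.frame: x, y, gene, mid, count) and
#'   `truth` (data.frame: x, y, gene, k).
#' @export
makeMidGroups <- function(nGroups, k = 5L, duplicationMean = 5,
                          midErrorRate = 0.005, midLength = 10L,
                          seed = 1L) {
  stopifnot(k >= 1L, duplicationMean >= 1)
  .withSeed(seed, {
    out <- vector("list", nGroups)
    for (g in seq_len(nGroups)) {
      mids <- character(0)
      while (length(unique(mids)) < k)
        mids <- .randomDna(k, midLength)
      dup <- 1L + rpois(k, duplicationMean - 1)
      obs <- .injectErrors(rep(mids, dup), midErrorRate, midLength)$seqs
      cnt <- table(obs)
      out[[g]] <- data.frame(x = g, y = 0L, gene = "G",
                             mid = names(cnt), count = as.integer(cnt),
                             stringsAsFactors = FALSE)
    }
    list(groups = do.call(rbind, out),
         truth = data.frame(x = seq_len(nGroups), y = 0L, gene = "G",
                            k = k, stringsAsFactors = FALSE))
  })
}

#' Ground-truth expression matrix of a simulation
#'
#' The matrix the pipeline should recover in the noiseless limit: the
#' number of distinct true MIDs per (x, y, gene) over all simulated
#' molecules.
#'
#' @param sim result of [simulateRun()].
#' @return a [SpatialExpression-class] at bin1.
#' @export
truthMatrix <- function(sim) {
  m <- sim$truth$molecules
  dt <- data.table::data.table(gene = m$gene_id, x = m$x, y = m$y,
                               mid = m$mid)
  SpatialExpression(as.data.frame(
    dt[, .(count = data.table::uniqueN(mid)), by = .(gene, x, y)]),
    binSize = 1L)
}
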