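#' PartitionRule: CID-keyed partitioning rule
#'
#' Masks and FASTQ files can be partitioned by CID so each partition pair
#' (mask part, read part) is matched independently, bounding memory and
#' enabling parallelism. Two modes: `prefix` routes by the first
#' `prefixLen` bases (requires `nParts = 4^prefixLen`, e.g. 4 parts by the
#' first base A/C/G/T, 16 by the first two); `modulo` routes by the 2-bit
#' integer encoding of the full CID modulo `nParts`, supporting any part
#' count.
#'
#' @slot nParts number of partitions.
#' @slot mode `"prefix"` or `"modulo"`.
#' @slot prefixLen prefix length in bases (prefix mode).
#' @export
setClass("PartitionRule",
  representation(nParts = "integer", mode = "character",
                 prefixLen = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!object@mode %in% c("prefix", "modulo"))
      msg <- c(msg, "mode must be 'prefix' or 'modulo'")
    if (object@nParts < 1L) msg <- c(msg, "nParts must be >= 1")
    if (identical(object@mode, "prefix") &&
        object@nParts != 4L^object@prefixLen)
      msg <- c(msg, "prefix mode requires nParts = 4^prefixLen")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a PartitionRule
#'
#' @param nParts number of partitions (>= 1).
#' @param mode `"prefix"` (nParts must be a power of 4) or `"modulo"`.
#' @param prefixLen prefix length for prefix mode; derived from `nParts`
#'   when omitted.
#' @return a [PartitionRule-class].
#' @examples
#' PartitionRule(4, "prefix")     # split by the first CID base
#' PartitionRule(10, "modulo")    # non-power-of-4 part count
#' @export
PartitionRule <- function(nParts, mode = c("prefix", "modulo"),
                          prefixLen = NULL) {
  mode <- match.arg(mode)
  nParts <- as.integer(nParts)
  if (mode == "prefix") {
    if (is.null(prefixLen)) {
      prefixLen <- as.integer(round(log(nParts, 4)))
      if (4L^prefixLen != nParts)
        stop("prefix mode requires nParts to be a power of 4")
    }
  } else prefixLen <- 0L
  new("PartitionRule", nParts = nParts, mode = mode,
      prefixLen = as.integer(prefixLen))
}

setMethod("show", "PartitionRule", function(object) {
  if (object@mode == "prefix")
    cat(sprintf("PartitionRule: %d parts by %d-base CID prefix\n",
                object@nParts, object@prefixLen))
  else
    cat(sprintf("PartitionRule: %d parts by full-CID encoding modulo\n",
                object@nParts))
})

#' Write a mask table to TSV
#'
#' Plain-text mask format: one header line
#' `#chip=<name> width=<w> height=<h> cid_length=<L>` followed by
#' tab-separated `CID  x  y` rows sorted by CID, LF line endings. Round-trips
#' through [loadMask()].
#'
#' @param mask a [MaskTable-class].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "MaskTable"))
  validObject(mask)
  chip <- mask@chip
  con <- file(path, open = "wb")
  on.exit(close(con))
  header <- sprintf("#chip=%s width=%d height=%d cid_length=%d",
                    chip@name, chip@width, chip@height, chip@cidLength)
  ord <- order(mask@cid)
  lines <- c(header,
             if (length(ord)) sprintf("%s\t%d\t%d", mask@cid[ord],
                                      mask@x[ord], mask@y[ord]))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Load a mask table from TSV
#'
#' Reads the format written by [writeMask()]. Duplicate CIDs, wrong-length
#' or non-ACGT CIDs, and out-of-bounds coordinates are rejected.
#'
#' @param path mask TSV file.
#' @return a [MaskTable-class].
#' @export
loadMask <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "#chip="))
    stop("malformed mask file: missing '#chip=' header")
  h <- lines[1L]
  getField <- function(key) {
    m <- regmatches(h, regexpr(sprintf("%s=\\S+", key), h))
    if (!length(m)) stop("malformed mask header: missing ", key)
    sub(sprintf("%s=", key), "", m)
  }
  chip <- ChipSpec(getField("#chip"),
                   as.integer(getField("width")),
                   as.integer(getField("height")),
                   as.integer(getField("cid_length")))
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (!length(body)) return(MaskTable(chip))
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("malformed mask record at line ",
         which(lengths(parts) != 3L)[1L] + 1L)
  cid <- vapply(parts, `[[`, "", 1L)
  x <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  y <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  if (anyNA(x) || anyNA(y)) stop("malformed mask coordinates")
  mask <- MaskTable(chip, cid, x, y)
  validObject(mask)
  mask
}

#' Assign CIDs to partitions
#'
#' Deterministic total mapping of a CID to a partition index in
#' `[0, nParts)`. Prefix mode maps by the 2-bit big-endian encoding
#' (A=0, C=1, G=2, T=3) of the first `prefixLen` bases; modulo mode by the
#' 2-bit big-endian encoding of the full CID modulo `nParts`. CIDs
#' containing a non-ACGT symbol (such reads cannot match any mask entry)
#' fall back to partition 0; their number is returned in the `"fallback"`
#' attribute.
#'
#' @param cid character vector of CIDs (equal length).
#' @param rule a [PartitionRule-class].
#' @return integer vector of partition indices in `[0, nParts)`, with
#'   attribute `fallback` counting non-ACGT CIDs routed to partition 0.
#' @examples
#' rule <- PartitionRule(4, "prefix")
#' assignPartition(c("AAAA", "TGCA"), rule)
#' @export
assignPartition <- function(cid, rule) {
  stopifnot(is(rule, "PartitionRule"))
  validObject(rule)
  n <- length(cid)
  if (n == 0L)
    return(structure(integer(0), fallback = 0L))
  L <- unique(nchar(cid))
  if (length(L) != 1L) stop("CIDs must have equal length")
  m <- .seqMatrix(cid, L)
  if (rule@mode == "prefix") {
    k <- rule@prefixLen
    if (k > L) stop("prefixLen exceeds CID length")
    codes <- matrix(.baseCode(m[, seq_len(k), drop = FALSE]),
                    nrow = n, ncol = k)
    weights <- 4^((k - 1L):0)
    val <- as.vector(codes %*% weights)
  } else {
    codes <- matrix(.baseCode(m), nrow = n, ncol = L)
    weights <- 4^((L - 1L):0)
    val <- as.vector(codes %*% weights) %% rule@nParts
  }
  bad <- is.na(val)
  val[bad] <- 0
  structure(as.integer(val), fallback = sum(bad))
}

#' Split a mask into partitions
#'
#' Partitions are pairwise disjoint and their union is the input mask;
#' partition `i` (1-based list element `i`, partition index `i - 1`) holds
#' exactly the CIDs with [assignPartition()] value `i - 1`.
#'
#' @param mask a [MaskTable-class].
#' @param rule a [PartitionRule-class].
#' @return list of `nParts` [MaskTable-class] objects.
#' @export
splitMask <- function(mask, rule) {
  stopifnot(is(mask, "MaskTable"))
  idx <- assignPartition(mask@cid, rule)
  lapply(seq_len(rule@nParts) - 1L, function(p) {
    keep <- which(idx == p)
    MaskTable(mask@chip, mask@cid[keep], mask@x[keep], mask@y[keep])
  })
}

# empty read table with the canonical columns
.emptyReads <- function() {
  data.frame(read_id = character(0), cid = character(0), mid = character(0),
             cdna = character(0), cid_qual = character(0),
             mid_qual = character(0), cdna_qual = character(0),
             stringsAsFactors = FALSE)
}

#' Read spatially barcoded FASTQ into a read table
#'
#' Read 1 carries the CID at bases `[1, cidLength]` and the MID at
#' `[cidLength + 1, cidLength + midLength]`; the cDNA is read 2, or the
#' remainder of read 1 in the combined single-file layout. Records whose
#' read 1 is shorter than `cidLength + midLength` are returned separately
#' with a reason.
#'
#' @param fastq1 path to read-1 FASTQ (plain or gzipped).
#' @param fastq2 optional path to read-2 FASTQ (cDNA); when `NULL` the
#'   remainder of read 1 is used as cDNA.
#' @param cidLength,midLength barcode layout in bases.
#' @return list with `reads` (data.frame: read_id, cid, mid, cdna and the
#'   three quality strings) and `rejects` (data.frame: read_id, reason).
#' @export
readSpatialFastq <- function(fastq1, fastq2 = NULL, cidLength = 25L,
                             midLength = 10L) {
  r1 <- Biostrings::readDNAStringSet(fastq1, format = "fastq",
                                     with.qualities = TRUE)
  seq1 <- as.character(r1)
  qual1 <- as.character(S4Vectors::mcols(r1)$qualities)
  ids <- sub("\\s.*$", "", names(r1))
  need <- cidLength + midLength
  short <- nchar(seq1) < need
  rejects <- data.frame(read_id = ids[short],
                        reason = rep("read1_shorter_than_barcodes",
                                     sum(short)),
                        stringsAsFactors = FALSE)
  keep <- !short
  reads <- data.frame(
    read_id = ids[keep],
    cid = substr(seq1[keep], 1L, cidLength),
    mid = substr(seq1[keep], cidLength + 1L, need),
    cid_qual = substr(qual1[keep], 1L, cidLength),
    mid_qual = substr(qual1[keep], cidLength + 1L, need),
    stringsAsFactors = FALSE)
  if (is.null(fastq2)) {
    reads$cdna <- substr(seq1[keep], need + 1L, nchar(seq1[keep]))
    reads$cdna_qual <- substr(qual1[keep], need + 1L, nchar(qual1[keep]))
  } else {
    r2 <- Biostrings::readDNAStringSet(fastq2, format = "fastq",
                                       with.qualities = TRUE)
    ids2 <- sub("\\s.*$", "", names(r2))
    m <- match(reads$read_id, ids2)
    if (anyNA(m)) stop("read 2 missing for some read ids")
    reads$cdna <- as.character(r2)[m]
    reads$cdna_qual <- as.character(S4Vectors::mcols(r2)$qualities)[m]
  }
  reads <- reads[c("read_id", "cid", "mid", "cdna", "cid_qual", "mid_qual",
                   "cdna_qual")]
  list(reads = reads, rejects = rejects)
}

#' Split a read table by CID partition
#'
#' Each read lands in exactly one output partition (the one matching its
#' CID under `rule`), preserving input order within each partition. Reads
#' whose CID is shorter than expected go to the reject table.
#'
#' @param reads read table as returned by [readSpatialFastq()] (`$reads`).
#' @param rule a [PartitionRule-class].
#' @param cidLength expected CID length.
#' @return list with `parts` (list of read tables, one per partition) and
#'   `rejects`.
#' @export
splitReads <- function(reads, rule, cidLength = 25L) {
  ok <- nchar(reads$cid) == cidLength
  rejects <- reads[!ok, , drop = FALSE]
  reads <- reads[ok, , drop = FALSE]
  idx <- if (nrow(reads)) assignPartition(reads$cid, rule) else integer(0)
  parts <- lapply(seq_len(rule@nParts) - 1L, function(p) {
    reads[idx == p, , drop = FALSE]
  })
  list(parts = parts, rejects = rejects)
}

#' Split FASTQ file(s) by CID partition
#'
#' File-level wrapper over [splitReads()]: reads the FASTQ layout, routes
#' each record to its partition and writes one read-1 (and, when paired,
#' read-2) FASTQ per partition under `outdir`.
#'
#' @inheritParams readSpatialFastq
#' @param rule a [PartitionRule-class].
#' @param outdir output directory (created if needed).
#' @return invisible list of per-partition file paths (`fastq1`, `fastq2`).
#' @export
splitFastq <- function(fastq1, fastq2 = NULL, rule, outdir,
                       cidLength = 25L, midLength = 10L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  parsed <- readSpatialFastq(fastq1, fastq2, cidLength, midLength)
  sp <- splitReads(parsed$reads, rule, cidLength)
  paths <- lapply(seq_along(sp$parts), function(i) {
    part <- sp$parts[[i]]
    f1 <- file.path(outdir, sprintf("part%03d_R1.fastq", i - 1L))
    writeReadFastq(part, f1, if (is.null(fastq2)) NULL else
      file.path(outdir, sprintf("part%03d_R2.fastq", i - 1L)))
  })
  if (nrow(sp$rejects))
    write.table(sp$rejects, file.path(outdir, "rejects.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write a read table back to FASTQ
#'
#' Inverse of [readSpatialFastq()]: read 1 is CID + MID (+ cDNA in the
#' combined layout), read 2 the cDNA when `fastq2` is given.
#'
#' @param reads read table.
#' @param fastq1 output read-1 path.
#' @param fastq2 optional output read-2 path (paired layout).
#' @return list of written paths.
#' @export
writeReadFastq <- function(reads, fastq1, fastq2 = NULL) {
  writeFq <- function(ids, seqs, quals, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    if (length(ids))
      writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), con,
                 sep = "\n")
    else writeLines(character(0), con)
    path
  }
  if (is.null(fastq2)) {
    writeFq(reads$read_id, paste0(reads$cid, reads$mid, reads$cdna),
            paste0(reads$cid_qual, reads$mid_qual, reads$cdna_qual), fastq1)
  } else {
    writeFq(reads$read_id, paste0(reads$cid, reads$mid),
            paste0(reads$cid_qual, reads$mid_qual), fastq1)
    writeFq(reads$read_id, reads$cdna, reads$cdna_qual, fastq2)
  }
  list(fastq1 = fastq1, fastq2 = if (!is.null(fastq2)) fastq2)
}
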