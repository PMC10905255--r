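#' Build the bin1 spatial expression matrix
#'
#' From located, annotated, MID-corrected reads: (1) keep reads annotated
#' EXONIC or INTRONIC; (2) drop reads antisense to their annotated gene;
#' (3) group by (x, y, gene, MID); (4) the matrix value per (x, y, gene)
#' is the number of distinct corrected MIDs.
#'
#' @param reads data.frame with one row per read: columns `x`, `y`,
#'   `gene_id`, `label`, `antisense`, `mid`. Pass `mapping` to apply an
#'   old-to-new MID mapping (from [correctMids()]) before deduplication;
#'   if omitted, `mid` is taken as already corrected.
#' @param mapping optional data.frame (`x`, `y`, `gene`, `old_mid`,
#'   `new_mid`).
#' @return a [SpatialExpression-class] at bin1.
#' @export
buildExpressionMatrix <- function(reads, mapping = NULL) {
  keep <- reads$label %in% c("EXONIC", "INTRONIC") & !reads$antisense
  r <- reads[keep, c("x", "y", "gene_id", "mid"), drop = FALSE]
  names(r)[names(r) == "gene_id"] <- "gene"
  if (!is.null(mapping) && nrow(mapping) && nrow(r)) {
    # apply the old->new MID mapping to fixed point: merge targets can
    # themselves have been merged later in the rank traversal, and the
    # recorded mapping is single-step
    mkey <- paste(mapping$x, mapping$y, mapping$gene, mapping$old_mid,
                  sep = "\r")
    repeat {
      key <- paste(r$x, r$y, r$gene, r$mid, sep = "\r")
      hit <- match(key, mkey)
      if (all(is.na(hit))) break
      r$mid[!is.na(hit)] <- mapping$new_mid[hit[!is.na(hit)]]
    }
  }
  if (!nrow(r))
    return(SpatialExpression(
      data.frame(gene = character(0), x = integer(0), y = integer(0),
                 count = integer(0), stringsAsFactors = FALSE),
      binSize = 1L))
  dt <- data.table::as.data.table(r)
  rec <- dt[, .(count = data.table::uniqueN(mid)), by = .(gene, x, y)]
  SpatialExpression(as.data.frame(rec), binSize = 1L)
}

#' Group reads into per-(coordinate, gene) MID counts
#'
#' The nested-map preparation step for MID correction: read counts per
#' (x, y, gene, MID), restricted to the reads that will enter the matrix
#' (EXONIC/INTRONIC, sense strand).
#'
#' @param reads data.frame with `x`, `y`, `gene_id`, `label`, `antisense`,
#'   `mid` columns.
#' @return data.frame with columns `x`, `y`, `gene`, `mid`, `count`.
#' @export
groupMids <- function(reads) {
  keep <- reads$label %in% c("EXONIC", "INTRONIC") & !reads$antisense
  r <- reads[keep, , drop = FALSE]
  if (!nrow(r))
    return(data.frame(x = integer(0), y = integer(0), gene = character(0),
                      mid = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  dt <- data.table::data.table(x = r$x, y = r$y, gene = r$gene_id,
                               mid = r$mid)
  as.data.frame(dt[, .(count = .N), by = .(x, y, gene, mid)])
}

#' Aggregate an expression matrix to a coarser bin lattice
#'
#' Bin coordinates are floor(x / binSize); MID counts are summed per
#' (bin, gene), so the matrix total is invariant. `binSize = 1` is the
#' identity. `binSize` is interpreted in the units of the input lattice.
#'
#' @param matrix a [SpatialExpression-class].
#' @param binSize bin side length (>= 1).
#' @return a [SpatialExpression-class] on the bin lattice; its recorded
#'   bin size is the product of the input's and `binSize`.
#' @export
binMatrix <- function(matrix, binSize) {
  stopifnot(is(matrix, "SpatialExpression"))
  binSize <- as.integer(binSize)
  if (binSize < 1L) stop("binSize must be >= 1")
  if (binSize == 1L) return(matrix)
  r <- exprRecords(matrix)
  if (!nrow(r))
    return(SpatialExpression(r, binSize = matrix@binSize * binSize))
  dt <- data.table::as.data.table(r)
  dt[, `:=`(x = x %/% binSize, y = y %/% binSize)]
  rec <- dt[, .(count = sum(count)), by = .(gene, x, y)]
  SpatialExpression(as.data.frame(rec), binSize = matrix@binSize * binSize)
}

#' Write / read the gem TSV expression format
#'
#' Plain-text long format: metadata header lines (`#binSize=<n>`,
#' `#format=gem v1`), a column header, then
#' `geneID<TAB>x<TAB>y<TAB>MIDCount` rows. Lossless round-trip.
#'
#' @param matrix a [SpatialExpression-class].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeGem <- function(matrix, path) {
  stopifnot(is(matrix, "SpatialExpression"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  r <- exprRecords(matrix)
  writeLines(c("#format=gem v1",
               sprintf("#binSize=%d", exprBinSize(matrix)),
               "geneID\tx\ty\tMIDCount",
               if (nrow(r)) sprintf("%s\t%d\t%d\t%d", r$gene, r$x, r$y,
                                    r$count)),
             con, sep = "\n")
  invisible(path)
}

#' @rdname writeGem
#' @export
readGem <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !identical(lines[1L], "#format=gem v1"))
    stop("not a gem v1 file: ", path)
  binSize <- as.integer(sub("#binSize=", "", lines[2L], fixed = TRUE))
  if (is.na(binSize)) stop("malformed gem header (binSize)")
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  if (!length(body))
    return(SpatialExpression(data.frame(gene = character(0), x = integer(0),
                                        y = integer(0), count = integer(0)),
                             binSize = binSize))
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 4L)) stop("malformed gem record")
  SpatialExpression(data.frame(
    gene = vapply(parts, `[[`, "", 1L),
    x = as.integer(vapply(parts, `[[`, "", 2L)),
    y = as.integer(vapply(parts, `[[`, "", 3L)),
    count = as.integer(vapply(parts, `[[`, "", 4L)),
    stringsAsFactors = FALSE), binSize = binSize)
}

#' Assemble the per-stage run report
#'
#' Funnel summary across stages: counts and, for each stage, the
#' percentage relative to the previous stage's count. Missing stages are
#' reported as explicit gaps; a zero-read run yields zero counters
#' without division errors.
#'
#' @param restore restore-stage stats (from [restoreReads()]), or `NULL`.
#' @param filter filter-stage stats (from [filterReads()]), or `NULL`.
#' @param alignment list with at least `unique_reads` (uniquely mapped
#'   count), or `NULL`.
#' @param annotation tallies from [tallyAnnotation()], or `NULL`.
#' @param matrix a [SpatialExpression-class], or `NULL`.
#' @return nested list; each present stage carries `count` and
#'   `pct_of_previous` (percent, relative to the previous present stage).
#' @export
stageReport <- function(restore = NULL, filter = NULL, alignment = NULL,
                        annotation = NULL, matrix = NULL) {
  pct <- function(num, den) if (is.null(den) || !den) 0 else 100 * num / den
  report <- list()
  prev <- NULL
  if (!is.null(restore)) {
    mapped <- restore$exact_matches + restore$corrected_matches
    report$total_reads <- restore$total_reads
    report$restore <- list(count = mapped,
                           pct_of_previous = pct(mapped,
                                                 restore$total_reads),
                           stats = restore)
    prev <- mapped
  }
  if (!is.null(filter)) {
    report$filter <- list(count = filter$passed,
                          pct_of_previous = pct(filter$passed, prev),
                          stats = filter)
    prev <- filter$passed
  }
  if (!is.null(alignment)) {
    report$alignment <- list(count = alignment$unique_reads,
                             pct_of_previous = pct(alignment$unique_reads,
                                                   prev))
    prev <- alignment$unique_reads
  }
  if (!is.null(annotation)) report$annotation <- annotation
  if (!is.null(matrix) && is(matrix, "SpatialExpression")) {
    r <- exprRecords(matrix)
    report$matrix <- list(records = nrow(r),
                          genes = length(unique(r$gene)),
                          positions = nrow(unique(r[c("x", "y")])),
                          total_mid_count = sum(r$count))
  }
  missing <- setdiff(c("restore", "filter", "alignment", "annotation",
                       "matrix"), names(report))
  if (length(missing)) report$missing_stages <- missing
  report
}
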