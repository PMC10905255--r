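#' Pipeline configuration
#'
#' Bundles per-stage parameters and I/O paths for [runPipeline()]. Input
#' files: a mask TSV ([writeMask()] format), read FASTQ(s) and a SAM/BAM
#' of alignments (real or synthesized), plus a GTF of gene models.
#'
#' @param mask,fastq1,fastq2,sam,gtf input paths (`fastq2 = NULL` for the
#'   combined single-file read layout).
#' @param outdir run directory for stage outputs and the report.
#' @param nPartitions CID partition count for the restore stage (1 =
#'   unpartitioned).
#' @param partitionMode `"prefix"` or `"modulo"`.
#' @param batchSize reads per in-memory restore batch (`Inf` = single
#'   batch); outputs are independent of this.
#' @param cidLength,midLength read-1 barcode layout.
#' @param qc see [filterParams()].
#' @param correction see [correctionParams()].
#' @param minMapq unique-mapping threshold for annotation.
#' @param heatmapBin bin size of the segmentation heatmap.
#' @param tissue see [tissuecutParams()].
#' @param binSizes additional matrix bin sizes to write.
#' @param coordFrac fraction of occupied coarse bins sampled in the
#'   saturation preparation.
#' @param seed seed for the saturation stage sampling/shuffle.
#' @return named config list for [runPipeline()].
#' @export
pipelineConfig <- function(mask, fastq1, fastq2 = NULL, sam, gtf, outdir,
                           nPartitions = 1L,
                           partitionMode = c("prefix", "modulo"),
                           batchSize = Inf, cidLength = 25L, midLength = 10L,
                           qc = filterParams(),
                           correction = correctionParams(),
                           minMapq = 20L, heatmapBin = 2L,
                           tissue = tissuecutParams(),
                           binSizes = c(1L), coordFrac = 0.05, seed = 1L) {
  stopifnot(batchSize >= 1)
  list(mask = mask, fastq1 = fastq1, fastq2 = fastq2, sam = sam, gtf = gtf,
       outdir = outdir, nPartitions = as.integer(nPartitions),
       partitionMode = match.arg(partitionMode), batchSize = batchSize,
       cidLength = as.integer(cidLength), midLength = as.integer(midLength),
       qc = qc, correction = correction, minMapq = as.integer(minMapq),
       heatmapBin = as.integer(heatmapBin), tissue = tissue,
       binSizes = as.integer(binSizes), coordFrac = coordFrac,
       seed = as.integer(seed))
}

# expression matrix from corrected (x, y, gene, mid, count) groups
.matrixFromGroups <- function(groups) {
  if (!nrow(groups))
    return(SpatialExpression(
      data.frame(gene = character(0), x = integer(0), y = integer(0),
                 count = integer(0), stringsAsFactors = FALSE)))
  dt <- data.table::as.data.table(groups)
  SpatialExpression(as.data.frame(
    dt[, .(count = data.table::uniqueN(mid)), by = .(gene, x, y)]),
    binSize = 1L)
}

#' Run the full pipeline
#'
#' Stages, in order: mask load, FASTQ parse, CID restore (optionally
#' partitioned and batched), read QC, alignment intake, gene annotation,
#' MID grouping and correction, expression matrix (bin1 plus configured
#' bins), tissue segmentation and subsetting, saturation curve, run
#' report. Final outputs are independent of `nPartitions` and
#' `batchSize`. A stage failure halts with a stage-named error; outputs
#' written so far remain in `outdir`.
#'
#' @param config see [pipelineConfig()].
#' @return invisible list with the in-memory stage results (`mask`,
#'   `restore`, `filter`, `annotation`, `tally`, `correction`, `matrix`,
#'   `binned`, `tissue`, `saturation`, `report`) and `outdir`.
#' @export
runPipeline <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  mask <- stage("mask", loadMask(config$mask))
  parsed <- stage("fastq", readSpatialFastq(config$fastq1, config$fastq2,
                                            config$cidLength,
                                            config$midLength))
  reads <- parsed$reads
  restore <- stage("restore", {
    nb <- if (is.finite(config$batchSize))
      ceiling(nrow(reads) / config$batchSize) else 1L
    nb <- max(1L, nb)
    split <- if (nb == 1L) list(seq_len(nrow(reads)))
             else base::split(seq_len(nrow(reads)),
                              ceiling(seq_len(nrow(reads)) / config$batchSize))
    rule <- if (config$nPartitions > 1L)
      PartitionRule(config$nPartitions, config$partitionMode) else NULL
    index <- if (is.null(rule)) buildCidIndex(mask) else NULL
    parts <- lapply(split, function(ix) {
      if (is.null(rule)) restoreReads(reads[ix, , drop = FALSE], index)
      else restoreReadsPartitioned(reads[ix, , drop = FALSE], mask, rule)
    })
    located <- do.call(rbind, lapply(parts, `[[`, "located"))
    list(located = located, stats = .restoreStats(located$match_kind))
  })
  jsonlite::write_json(restore$stats,
                       file.path(config$outdir, "restore_stats.json"),
                       auto_unbox = TRUE)
  mapped <- restore$located[restore$located$match_kind %in%
                              c("exact", "corrected"), , drop = FALSE]
  filt <- stage("filter", filterReads(mapped, config$qc))
  jsonlite::write_json(filt$stats,
                       file.path(config$outdir, "filter_stats.json"),
                       auto_unbox = TRUE)
  anno <- stage("annotate", {
    aln <- readAlignments(config$sam)
    aln <- aln[aln$read_id %in% filt$passed$read_id, , drop = FALSE]
    models <- loadGeneModels(config$gtf)
    annotateReads(aln, models, config$minMapq)
  })
  tally <- tallyAnnotation(anno)
  jsonlite::write_json(tally,
                       file.path(config$outdir, "annotation_stats.json"),
                       auto_unbox = TRUE)
  corr <- stage("midcorrect", {
    merged <- merge(filt$passed[c("read_id", "x", "y", "mid")], anno,
                    by = "read_id")
    groups <- groupMids(merged)
    correctMids(groups, config$correction)
  })
  mat <- stage("matrix", .matrixFromGroups(corr$groups))
  writeGem(mat, file.path(config$outdir, "matrix.gem"))
  binned <- stage("binning", {
    out <- list()
    for (b in config$binSizes[config$binSizes > 1L]) {
      bm <- binMatrix(mat, b)
      writeGem(bm, file.path(config$outdir, sprintf("matrix_bin%d.gem", b)))
      out[[as.character(b)]] <- bm
    }
    out
  })
  tissue <- stage("tissuecut", {
    img <- expressionToHeatmap(mat, config$heatmapBin,
                               width = chipWidth(maskChip(mask)),
                               height = chipHeight(maskChip(mask)))
    tm <- segmentTissue(img, config$tissue)
    sub <- extractTissueRecords(mat, tm)
    writeTissueMask(tm, file.path(config$outdir, "tissue_mask.png"),
                    file.path(config$outdir, "tissue_contours.tsv"))
    writeGem(sub$matrix, file.path(config$outdir, "tissue.gem"))
    c(list(mask = tm), sub)
  })
  saturation <- stage("saturation", {
    tr <- tissue$matrix
    tuples <- merge(corr$groups,
                    unique(exprRecords(tr)[c("x", "y")]), by = c("x", "y"))
    if (nrow(tuples)) {
      coords <- sampleCoordinates(tuples, config$coordFrac, binSize = 200L,
                                  seed = config$seed)
      tuples <- merge(tuples, coords, by = c("x", "y"))
      tab <- saturationCurve(tuples, seed = config$seed)
      writeSaturation(tab, file.path(config$outdir, "saturation.tsv"))
      tab
    } else NULL
  })
  report <- stageReport(
    restore = restore$stats, filter = filt$stats,
    alignment = list(unique_reads = nrow(anno)),
    annotation = tally, matrix = mat)
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(mask = mask, restore = restore, filter = filt,
                 annotation = anno, tally = tally, correction = corr,
                 matrix = mat, binned = binned, tissue = tissue,
                 saturation = saturation, report = report,
                 outdir = config$outdir))
}
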