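#' ChipSpec: geometry of a barcoded chip
#'
#' Describes a rectangular lattice of barcoded capture spots. Each spot is
#' identified by a distinct coordinate barcode (CID) of `cidLength` bases;
#' spot coordinates are 0-based with `x` the column in `[0, width)` and `y`
#' the row in `[0, height)`, in bin1 lattice units.
#'
#' @slot name chip name.
#' @slot width,height lattice extent in bin1 units.
#' @slot cidLength CID length in bases (25 by default for this chemistry).
#' @export
setClass("ChipSpec",
  representation(name = "character", width = "integer", height = "integer",
                 cidLength = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
    if (length(object@width) != 1L || object@width < 1L)
      msg <- c(msg, "width must be a positive integer")
    if (length(object@height) != 1L || object@height < 1L)
      msg <- c(msg, "height must be a positive integer")
    if (length(object@cidLength) != 1L || object@cidLength < 1L)
      msg <- c(msg, "cidLength must be a positive integer")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a ChipSpec
#'
#' @param name chip name.
#' @param width,height lattice extent in bin1 units.
#' @param cidLength CID length in bases.
#' @return a [ChipSpec-class] object.
#' @examples
#' ChipSpec("toy", 20, 20)
#' @export
ChipSpec <- function(name, width, height, cidLength = 25L) {
  new("ChipSpec", name = as.character(name), width = as.integer(width),
      height = as.integer(height), cidLength = as.integer(cidLength))
}

#' @describeIn ChipSpec-class chip name
#' @param x a `ChipSpec`.
#' @export
chipName <- function(x) x@name
#' @describeIn ChipSpec-class lattice width (bin1 units)
#' @export
chipWidth <- function(x) x@width
#' @describeIn ChipSpec-class lattice height (bin1 units)
#' @export
chipHeight <- function(x) x@height
#' @describeIn ChipSpec-class CID length in bases
#' @export
chipCidLength <- function(x) x@cidLength

setMethod("show", "ChipSpec", function(object) {
  cat(sprintf("ChipSpec '%s': %d x %d spots, %d-base CIDs\n",
              object@name, object@width, object@height, object@cidLength))
})

#' MaskTable: CID-to-coordinate lookup for a chip
#'
#' The mask is the injective association from each chip CID to its lattice
#' coordinate; matching read CIDs against it restores reads to their spatial
#' positions.
#'
#' @slot chip the [ChipSpec-class] the mask belongs to.
#' @slot cid character vector of distinct CIDs (alphabet ACGT, length
#'   `chipCidLength(chip)`).
#' @slot x,y integer coordinates, parallel to `cid`, within chip bounds.
#' @export
setClass("MaskTable",
  representation(chip = "ChipSpec", cid = "character", x = "integer",
                 y = "integer"),
  validity = function(object) {
    msg <- NULL
    n <- length(object@cid)
    if (length(object@x) != n || length(object@y) != n)
      msg <- c(msg, "cid, x and y must have equal length")
    if (n > 0L) {
      L <- object@chip@cidLength
      if (any(nchar(object@cid) != L))
        msg <- c(msg, sprintf("all CIDs must have length %d", L))
      if (any(grepl("[^ACGT]", object@cid)))
        msg <- c(msg, "CIDs must use alphabet {A,C,G,T}")
      dup <- object@cid[duplicated(object@cid)]
      if (length(dup))
        msg <- c(msg, sprintf("duplicate CID: %s", dup[1L]))
      if (any(object@x < 0L | object@x >= object@chip@width) ||
          any(object@y < 0L | object@y >= object@chip@height))
        msg <- c(msg, "coordinates out of chip bounds")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Construct a MaskTable
#'
#' @param chip a [ChipSpec-class].
#' @param cid character vector of CIDs.
#' @param x,y integer coordinates parallel to `cid`.
#' @return a [MaskTable-class].
#' @examples
#' chip <- ChipSpec("toy", 4, 4, cidLength = 4)
#' MaskTable(chip, c("ACGT", "TTTT"), x = c(0, 1), y = c(0, 0))
#' @export
MaskTable <- function(chip, cid = character(0), x = integer(0),
                      y = integer(0)) {
  new("MaskTable", chip = chip, cid = as.character(cid), x = as.integer(x),
      y = as.integer(y))
}

#' @describeIn MaskTable-class the chip specification
#' @param x a `MaskTable`.
#' @export
maskChip <- function(x) x@chip

#' @describeIn MaskTable-class mask entries as a data.frame (cid, x, y)
#' @export
maskEntries <- function(x) {
  data.frame(cid = x@cid, x = x@x, y = x@y, stringsAsFactors = FALSE)
}

#' @describeIn MaskTable-class number of entries
#' @export
setMethod("length", "MaskTable", function(x) length(x@cid))

setMethod("show", "MaskTable", function(object) {
  cat(sprintf("MaskTable: %d CIDs on ", length(object@cid)))
  show(object@chip)
})

#' CidIndex: query structure for exact and distance-1 CID matching
#'
#' Built from a [MaskTable-class]; answers exact and single-substitution
#' queries with results identical to a naive Hamming scan of the mask.
#'
#' @slot mask the source [MaskTable-class].
#' @export
setClass("CidIndex", representation(mask = "MaskTable"))

setMethod("show", "CidIndex", function(object) {
  cat(sprintf("CidIndex over %d CIDs (exact + 1-substitution queries)\n",
              length(object@mask)))
})

#' GeneModels: indexed gene annotation
#'
#' Gene models with per-transcript exon structure, 0-based half-open
#' internal coordinates, indexed for overlap queries.
#'
#' @slot genes named list; each element holds `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open) and `transcripts`, a named list of
#'   exon [IRanges::IRanges] (1-based internally converted on access).
#' @slot ranges a [GenomicRanges::GRanges] of gene spans with a `gene_id`
#'   metadata column, used for overlap queries.
#' @export
setClass("GeneModels",
  representation(genes = "list", ranges = "GRanges"))

#' @describeIn GeneModels-class number of genes
#' @param x a `GeneModels`.
#' @export
setMethod("length", "GeneModels", function(x) length(x@genes))

#' @describeIn GeneModels-class gene identifiers
#' @export
geneIds <- function(x) names(x@genes)

setMethod("show", "GeneModels", function(object) {
  nt <- sum(vapply(object@genes, function(g) length(g$transcripts), 1L))
  cat(sprintf("GeneModels: %d genes, %d transcripts on %d sequence(s)\n",
              length(object@genes), nt,
              length(unique(as.character(
                GenomicRanges::seqnames(object@ranges))))))
})

#' SpatialExpression: spatial gene-expression matrix
#'
#' Sparse long-format expression records: one row per (gene, x, y) with the
#' number of distinct (corrected) MIDs observed there. `binSize` records the
#' lattice the coordinates live on: 1 for the native spot lattice, N when
#' aggregated to N x N-spot bins (coordinates are then bin indices).
#'
#' @slot records data.frame with columns `gene`, `x`, `y`, `count`;
#'   (gene, x, y) unique.
#' @slot binSize positive integer, bin side length in bin1 units.
#' @export
setClass("SpatialExpression",
  representation(records = "data.frame", binSize = "integer"),
  validity = function(object) {
    msg <- NULL
    need <- c("gene", "x", "y", "count")
    if (!all(need %in% names(object@records)))
      msg <- c(msg, "records must have columns gene, x, y, count")
    else {
      r <- object@records
      if (nrow(r) && anyDuplicated(r[c("gene", "x", "y")]))
        msg <- c(msg, "(gene, x, y) must be unique")
      if (nrow(r) && any(r$count < 1L))
        msg <- c(msg, "counts must be positive")
    }
    if (length(object@binSize) != 1L || object@binSize < 1L)
      msg <- c(msg, "binSize must be a positive integer")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a SpatialExpression matrix from records
#'
#' @param records data.frame with columns `gene`, `x`, `y`, `count`.
#' @param binSize bin side length in bin1 units (1 = native lattice).
#' @return a [SpatialExpression-class].
#' @export
SpatialExpression <- function(records, binSize = 1L) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records)) {
    records$gene <- as.character(records$gene)
    records$x <- as.integer(records$x)
    records$y <- as.integer(records$y)
    records$count <- as.integer(records$count)
    records <- records[order(records$gene, records$x, records$y), ,
                       drop = FALSE]
    rownames(records) <- NULL
  } else {
    records <- data.frame(gene = character(0), x = integer(0), y = integer(0),
                          count = integer(0), stringsAsFactors = FALSE)
  }
  new("SpatialExpression", records = records, binSize = as.integer(binSize))
}

#' @describeIn SpatialExpression-class expression records (long data.frame)
#' @param x a `SpatialExpression`.
#' @export
exprRecords <- function(x) x@records

#' @describeIn SpatialExpression-class bin side length in bin1 units
#' @export
exprBinSize <- function(x) x@binSize

#' @describeIn SpatialExpression-class total MID count over all records
#' @export
exprTotal <- function(x) sum(x@records$count)

#' @describeIn SpatialExpression-class number of records
#' @export
setMethod("length", "SpatialExpression", function(x) nrow(x@records))

setMethod("show", "SpatialExpression", function(object) {
  r <- object@records
  cat(sprintf(
    "SpatialExpression: %d records, %d genes, %d occupied positions (bin%d), total MID count %d\n",
    nrow(r), length(unique(r$gene)), nrow(unique(r[c("x", "y")])),
    object@binSize, sum(r$count)))
})

#' TissueMask: binary tissue-region raster with contours
#'
#' Segmentation result aligned to an expression heatmap: a binary raster on
#' the heatmap's bin lattice plus the traced contours of the retained
#' region.
#'
#' @slot mask logical matrix, `mask[i, j]` is bin (x = i-1, y = j-1).
#' @slot binSize bin side length (bin1 units) of the raster.
#' @slot contours list of two-column matrices of 0-based bin coordinates
#'   tracing each connected component's outline.
#' @export
setClass("TissueMask",
  representation(mask = "matrix", binSize = "integer", contours = "list"))

#' @describeIn TissueMask-class the binary raster (x along rows)
#' @param x a `TissueMask`.
#' @export
tissueRaster <- function(x) x@mask

#' @describeIn TissueMask-class bin size of the raster
#' @export
tissueBinSize <- function(x) x@binSize

#' @describeIn TissueMask-class traced contours (0-based bin coordinates)
#' @export
tissueContours <- function(x) x@contours

setMethod("show", "TissueMask", function(object) {
  cat(sprintf(
    "TissueMask: %d x %d bins (bin%d), %d bins in tissue, %d contour(s)\n",
    nrow(object@mask), ncol(object@mask), object@binSize,
    sum(object@mask), length(object@contours)))
})
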