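#' Rasterize an expression matrix into a heatmap image
#'
#' Pixel (i, j) holds the total MID count over all genes at bin
#' (x = i - 1, y = j - 1) of the `binSize` lattice, so the pixel sum
#' equals the matrix total. Image extent is the ceiling of the coordinate
#' extent over `binSize` (or the chip extent when `width`/`height` are
#' given).
#'
#' @param matrix a bin1 [SpatialExpression-class].
#' @param binSize heatmap bin side length in bin1 units.
#' @param width,height optional chip extent in bin1 units; defaults to the
#'   tight extent of the records.
#' @return numeric matrix (x along rows) with attribute `binSize`.
#' @export
expressionToHeatmap <- function(matrix, binSize = 1L, width = NULL,
                                height = NULL) {
  stopifnot(is(matrix, "SpatialExpression"))
  if (exprBinSize(matrix) != 1L)
    stop("expressionToHeatmap expects a bin1 matrix")
  binSize <- as.integer(binSize)
  r <- exprRecords(matrix)
  if (is.null(width)) width <- if (nrow(r)) max(r$x) + 1L else 1L
  if (is.null(height)) height <- if (nrow(r)) max(r$y) + 1L else 1L
  nx <- as.integer(ceiling(width / binSize))
  ny <- as.integer(ceiling(height / binSize))
  img <- matrix(0, nrow = nx, ncol = ny)
  if (nrow(r)) {
    bx <- r$x %/% binSize
    by <- r$y %/% binSize
    dt <- data.table::data.table(bx = bx, by = by, count = r$count)
    agg <- dt[, .(count = sum(count)), by = .(bx, by)]
    img[cbind(agg$bx + 1L, agg$by + 1L)] <- agg$count
  }
  attr(img, "binSize") <- binSize
  img
}

#' Tissue-segmentation parameters (grayscale branch)
#'
#' Concrete chain: log1p intensity transform, Gaussian smoothing, rescale
#' to [0, 1], Otsu (or fixed) threshold, morphological closing then
#' opening with disc brushes, removal of connected components below an
#' area fraction of the image, hole filling.
#'
#' @param sigma Gaussian smoothing sigma in bins (default 2).
#' @param threshold `"otsu"` or a fixed numeric threshold on the rescaled
#'   [0, 1] intensity.
#' @param closeRadius,openRadius disc radii (bins) for morphological
#'   closing/opening; 0 disables the step.
#' @param minAreaFrac minimum connected-component area as a fraction of
#'   the image area (default 0.001).
#' @return named list of parameters.
#' @export
tissuecutParams <- function(sigma = 2, threshold = "otsu", closeRadius = 3L,
                            openRadius = 2L, minAreaFrac = 0.001) {
  list(sigma = sigma, threshold = threshold,
       closeRadius = as.integer(closeRadius),
       openRadius = as.integer(openRadius), minAreaFrac = minAreaFrac)
}

#' Segment the tissue-covered region from an expression heatmap
#'
#' Grayscale pipeline on the heatmap (see [tissuecutParams()]): the tissue
#' region is where smoothed log-intensity exceeds the Otsu threshold,
#' cleaned up morphologically, small components and holes removed, and
#' its contours traced. Deterministic for fixed parameters; an all-zero
#' image yields an empty mask.
#'
#' @param image heatmap matrix from [expressionToHeatmap()].
#' @param params see [tissuecutParams()].
#' @return a [TissueMask-class] aligned to the heatmap.
#' @export
segmentTissue <- function(image, params = tissuecutParams()) {
  binSize <- attr(image, "binSize")
  if (is.null(binSize)) binSize <- 1L
  empty <- function() new("TissueMask",
                          mask = matrix(FALSE, nrow(image), ncol(image)),
                          binSize = as.integer(binSize), contours = list())
  if (all(image == 0)) return(empty())
  v <- log1p(image)
  img <- EBImage::Image(v)
  if (params$sigma > 0) {
    # gblur needs a filter window smaller than the image; shrink the
    # radius on tiny images
    rad <- min(2L * ceiling(3 * params$sigma) + 1L,
               2L * (min(dim(image)) %/% 2L) - 1L)
    if (rad >= 3L)
      img <- EBImage::gblur(img, sigma = params$sigma, radius = rad,
                            boundary = "replicate")
  }
  m <- EBImage::imageData(img)
  rng <- range(m)
  if (rng[2L] <= rng[1L]) {
    bw <- matrix(TRUE, nrow(image), ncol(image))
  } else {
    m <- (m - rng[1L]) / (rng[2L] - rng[1L])
    thr <- if (identical(params$threshold, "otsu"))
      EBImage::otsu(EBImage::Image(m), range = c(0, 1))
    else as.numeric(params$threshold)
    bw <- m > thr
  }
  bwImg <- EBImage::Image(bw * 1)
  if (params$closeRadius > 0L) {
    k <- EBImage::makeBrush(2L * params$closeRadius + 1L, shape = "disc")
    bwImg <- EBImage::closing(bwImg, k)
  }
  if (params$openRadius > 0L) {
    k <- EBImage::makeBrush(2L * params$openRadius + 1L, shape = "disc")
    bwImg <- EBImage::opening(bwImg, k)
  }
  lab <- EBImage::bwlabel(bwImg)
  sizes <- table(lab[lab > 0])
  minArea <- params$minAreaFrac * length(image)
  keepLabels <- as.integer(names(sizes)[sizes >= minArea])
  labData <- EBImage::imageData(lab)
  bw2 <- matrix(labData %in% keepLabels, nrow(image), ncol(image))
  if (!any(bw2)) return(empty())
  filled <- EBImage::fillHull(EBImage::Image(bw2 * 1))
  final <- EBImage::imageData(filled) > 0
  contours <- EBImage::ocontour(EBImage::bwlabel(EBImage::Image(final * 1)))
  contours <- lapply(contours, function(cm) {
    cm <- cm - 1L             # 0-based bin coordinates
    colnames(cm) <- c("x", "y")
    cm
  })
  new("TissueMask", mask = final, binSize = as.integer(binSize),
      contours = contours)
}

#' Subset an expression matrix to the tissue region
#'
#' Keeps records whose bin (at the mask's bin size) lies inside the
#' tissue mask; retained records are unchanged.
#'
#' @param matrix a bin1 [SpatialExpression-class].
#' @param mask a [TissueMask-class].
#' @return list with `matrix` (subset [SpatialExpression-class]) and
#'   `stats` (bins_in_tissue, records_retained, retained_count_fraction).
#' @export
extractTissueRecords <- function(matrix, mask) {
  stopifnot(is(matrix, "SpatialExpression"), is(mask, "TissueMask"))
  if (exprBinSize(matrix) != 1L)
    stop("extractTissueRecords expects a bin1 matrix")
  r <- exprRecords(matrix)
  raster <- tissueRaster(mask)
  if (nrow(r)) {
    bx <- r$x %/% tissueBinSize(mask) + 1L
    by <- r$y %/% tissueBinSize(mask) + 1L
    if (any(bx > nrow(raster)) || any(by > ncol(raster)))
      stop("matrix extent exceeds tissue mask extent (bin-size mismatch?)")
    inside <- raster[cbind(bx, by)]
  } else inside <- logical(0)
  kept <- SpatialExpression(r[inside, , drop = FALSE], binSize = 1L)
  total <- sum(r$count)
  list(matrix = kept,
       stats = list(bins_in_tissue = sum(raster),
                    records_retained = sum(inside),
                    retained_count_fraction =
                      if (total) sum(r$count[inside]) / total else 0))
}

#' Write a tissue mask as PNG plus contour TSV
#'
#' @param mask a [TissueMask-class].
#' @param pngPath binary PNG destination (white = tissue).
#' @param contourPath optional TSV of contour points
#'   (`contour_id`, `x`, `y`, 0-based bin coordinates).
#' @return `pngPath`, invisibly.
#' @export
writeTissueMask <- function(mask, pngPath, contourPath = NULL) {
  stopifnot(is(mask, "TissueMask"))
  # PNG rows are y, columns x
  png::writePNG(t(tissueRaster(mask)) * 1, pngPath)
  if (!is.null(contourPath)) {
    cs <- tissueContours(mask)
    df <- if (length(cs))
      do.call(rbind, lapply(seq_along(cs), function(i)
        data.frame(contour_id = i, x = cs[[i]][, "x"], y = cs[[i]][, "y"])))
    else data.frame(contour_id = integer(0), x = integer(0), y = integer(0))
    write.table(df, contourPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(pngPath)
}
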