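#' Sample occupied bins and return their bin1 coordinates
#'
#' Draws a uniform random fraction of the distinct occupied `binSize`
#' bins (ceiling, so a non-empty input never yields an empty sample) and
#' returns the distinct bin1 coordinates of the input that fall inside
#' the chosen bins; these coordinates then filter the read-tuple list
#' before the saturation curve is computed.
#'
#' @param tuples data.frame with bin1 `x`, `y` columns (read tuples or
#'   expression records under tissue).
#' @param frac fraction of occupied bins to sample, in (0, 1].
#' @param binSize sampling bin side length in bin1 units (default 200).
#' @param seed RNG seed for the draw.
#' @return data.frame of distinct sampled bin1 coordinates (`x`, `y`).
#' @export
sampleCoordinates <- function(tuples, frac, binSize = 200L, seed = 1L) {
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]")
  if (!nrow(tuples)) stop("empty tuple list")
  coords <- unique(data.frame(x = tuples$x, y = tuples$y))
  bin <- paste(coords$x %/% binSize, coords$y %/% binSize)
  bins <- unique(bin)
  nPick <- as.integer(ceiling(frac * length(bins)))
  picked <- .withSeed(seed, sample(bins, nPick))
  coords[bin %in% picked, , drop = FALSE]
}

#' Sequencing-saturation and median-gene curve
#'
#' The per-read list (tuples expanded by their count) is shuffled once
#' with the seed; for each sampling fraction f the first floor(f * N)
#' reads are taken, so prefixes are nested across rows. Saturation is
#' 1 - (distinct (x, y, gene, MID) tuples / total reads) in the prefix;
#' the median gene count is the median over occupied bins of the number
#' of distinct genes per bin, at bin1 and bin200. By default both
#' saturation columns use bin1-resolution deduplication keys (under which
#' the bin200 value coincides with bin1); set `bin200Keys = TRUE` to
#' deduplicate the bin200 column on (bin200, gene, MID) keys instead.
#'
#' @param tuples data.frame with `x`, `y`, `gene`, `mid`, `count`
#'   (pre-deduplication read counts).
#' @param fractions sampling fractions, ascending.
#' @param seed RNG seed for the single shuffle.
#' @param binSize coarse bin side (default 200).
#' @param bin200Keys use bin200-resolution dedup keys for the coarse
#'   saturation column.
#' @return data.frame with one row per fraction: `fraction`,
#'   `total_reads`, `saturation_bin1`, `saturation_bin200`,
#'   `median_genes_bin1`, `median_genes_bin200`.
#' @export
saturationCurve <- function(tuples,
                            fractions = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5,
                                          0.6, 0.7, 0.8, 0.9, 1.0),
                            seed = 1L, binSize = 200L, bin200Keys = FALSE) {
  if (!nrow(tuples) || sum(tuples$count) < 1L) stop("empty read list")
  idx <- rep.int(seq_len(nrow(tuples)), tuples$count)
  perm <- .withSeed(seed, sample(length(idx)))
  idx <- idx[perm]
  N <- length(idx)
  x <- tuples$x[idx]; y <- tuples$y[idx]
  gene <- tuples$gene[idx]; mid <- tuples$mid[idx]
  key1 <- paste(x, y, gene, mid, sep = "\r")
  keyB <- if (bin200Keys)
    paste(x %/% binSize, y %/% binSize, gene, mid, sep = "\r") else key1
  bin1 <- paste(x, y, sep = "\r")
  binB <- paste(x %/% binSize, y %/% binSize, sep = "\r")
  rows <- lapply(sort(fractions), function(f) {
    n <- floor(f * N)
    if (n < 1L)
      return(data.frame(fraction = f, total_reads = 0L,
                        saturation_bin1 = NA_real_,
                        saturation_bin200 = NA_real_,
                        median_genes_bin1 = NA_real_,
                        median_genes_bin200 = NA_real_))
    s <- seq_len(n)
    u1 <- length(unique(key1[s]))
    uB <- if (bin200Keys) length(unique(keyB[s])) else u1
    mg <- function(binKey) {
      dt <- data.table::data.table(bin = binKey[s], gene = gene[s])
      stats::median(dt[, .(k = data.table::uniqueN(gene)), by = bin]$k)
    }
    data.frame(fraction = f, total_reads = n,
               saturation_bin1 = 1 - u1 / n,
               saturation_bin200 = 1 - uB / n,
               median_genes_bin1 = mg(bin1),
               median_genes_bin200 = mg(binB))
  })
  do.call(rbind, rows)
}

#' Write a saturation table to TSV
#'
#' @param table data.frame from [saturationCurve()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeSaturation <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
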