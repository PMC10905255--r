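#' MID-correction parameters
#'
#' Defaults are the pipeline's standard 5/1/10: a group is only corrected
#' when it holds at least `minMidTypes` distinct MIDs, merges happen at
#' Hamming distance up to `tolerance`, and MIDs are `midLength` bases.
#'
#' @param minMidTypes minimum number of distinct MIDs for a group to be
#'   processed (default 5).
#' @param tolerance maximum Hamming distance merged (default 1).
#' @param midLength MID length in bases (default 10).
#' @return named list of parameters.
#' @export
correctionParams <- function(minMidTypes = 5L, tolerance = 1L,
                             midLength = 10L) {
  stopifnot(minMidTypes >= 0L, tolerance >= 0L, midLength >= 1L)
  list(minMidTypes = as.integer(minMidTypes),
       tolerance = as.integer(tolerance),
       midLength = as.integer(midLength))
}

#' Correct MIDs within one (coordinate, gene) group
#'
#' Count-ordered Hamming merging. If the group has fewer than
#' `minMidTypes` distinct MIDs it is returned unchanged. Otherwise MIDs
#' are sorted by descending count (ties by descending lexicographic MID,
#' which fixes a deterministic order) and traversed from the
#' smallest-count MID towards the front; each MID is compared against the
#' higher-ranked MIDs in rank order and, at the first one within
#' `tolerance`, its current count is transferred there and the old-to-new
#' mapping recorded. Ranks are fixed by the original sort — a
#' merged-away MID (count 0) stays a valid merge target at its original
#' rank — and transfers move current counts, so the total is conserved.
#'
#' @param counts named positive integer vector: MID string -> read count.
#' @param params see [correctionParams()] (`midLength` is not used for
#'   validation beyond requiring all MIDs to share one length).
#' @return list with `counts` (same keys, corrected counts; merged MIDs
#'   have count 0) and `mapping` (named character vector, old MID ->
#'   new MID).
#' @examples
#' correctGroup(c(AAA = 5, GGA = 4, AGA = 3, AAT = 2, GGG = 1, CCC = 1),
#'              correctionParams(minMidTypes = 5, tolerance = 1,
#'                               midLength = 3))
#' @export
correctGroup <- function(counts, params = correctionParams()) {
  if (!length(counts)) stop("empty MID group")
  mids <- names(counts)
  if (is.null(mids) || anyNA(mids)) stop("counts must be named by MID")
  if (length(unique(nchar(mids))) != 1L)
    stop("mixed MID lengths in group")
  counts <- as.integer(counts)
  names(counts) <- mids
  if (length(counts) < params$minMidTypes)
    return(list(counts = counts,
                mapping = setNames(character(0), character(0))))
  ord <- order(counts, mids, decreasing = c(TRUE, TRUE), method = "radix")
  sMids <- mids[ord]
  sCnt <- counts[ord]
  L <- nchar(sMids[1L])
  codes <- matrix(utf8ToInt(paste0(sMids, collapse = "")),
                  nrow = length(sMids), ncol = L, byrow = TRUE)
  mapping <- character(0)
  n <- length(sMids)
  for (i in seq.int(n, 2L)) {
    for (j in seq_len(i - 1L)) {
      if (sum(codes[i, ] != codes[j, ]) <= params$tolerance) {
        sCnt[j] <- sCnt[j] + sCnt[i]
        sCnt[i] <- 0L
        mapping[sMids[i]] <- sMids[j]
        break
      }
    }
  }
  out <- setNames(integer(length(counts)), mids)
  out[sMids] <- sCnt
  list(counts = out, mapping = mapping)
}

#' Correct MIDs across all (coordinate, gene) groups
#'
#' Applies [correctGroup()] independently per group; no group's
#' correction reads another group's data.
#'
#' @param groups data.frame with columns `x`, `y`, `gene`, `mid`, `count`.
#' @param params see [correctionParams()].
#' @return list with `groups` (corrected data.frame; merged-away MIDs with
#'   count 0 are dropped), `mapping` (data.frame: x, y, gene, old_mid,
#'   new_mid) and `stats` (groups_total, groups_corrected, mids_merged,
#'   counts_moved).
#' @export
correctMids <- function(groups, params = correctionParams()) {
  if (!nrow(groups)) {
    return(list(
      groups = groups,
      mapping = data.frame(x = integer(0), y = integer(0),
                           gene = character(0), old_mid = character(0),
                           new_mid = character(0), stringsAsFactors = FALSE),
      stats = list(groups_total = 0L, groups_corrected = 0L,
                   mids_merged = 0L, counts_moved = 0L)))
  }
  dt <- data.table::as.data.table(groups)
  keyCols <- c("x", "y", "gene")
  split_idx <- dt[, .(idx = list(.I)), by = keyCols]
  outGroups <- vector("list", nrow(split_idx))
  outMaps <- vector("list", nrow(split_idx))
  merged <- 0L; moved <- 0L; touched <- 0L
  for (k in seq_len(nrow(split_idx))) {
    rows <- split_idx$idx[[k]]
    cnt <- setNames(as.integer(dt$count[rows]), dt$mid[rows])
    res <- correctGroup(cnt, params)
    keep <- res$counts > 0L
    outGroups[[k]] <- data.frame(
      x = split_idx$x[k], y = split_idx$y[k], gene = split_idx$gene[k],
      mid = names(res$counts)[keep],
      count = unname(res$counts[keep]), stringsAsFactors = FALSE)
    if (length(res$mapping)) {
      touched <- touched + 1L
      merged <- merged + length(res$mapping)
      moved <- moved + sum(cnt[names(res$mapping)])
      outMaps[[k]] <- data.frame(
        x = split_idx$x[k], y = split_idx$y[k], gene = split_idx$gene[k],
        old_mid = names(res$mapping), new_mid = unname(res$mapping),
        stringsAsFactors = FALSE)
    }
  }
  mapping <- do.call(rbind, outMaps[!vapply(outMaps, is.null, TRUE)])
  if (is.null(mapping))
    mapping <- data.frame(x = integer(0), y = integer(0),
                          gene = character(0), old_mid = character(0),
                          new_mid = character(0), stringsAsFactors = FALSE)
  list(groups = do.call(rbind, outGroups),
       mapping = mapping,
       stats = list(groups_total = nrow(split_idx),
                    groups_corrected = touched, mids_merged = merged,
                    counts_moved = as.integer(moved)))
}
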