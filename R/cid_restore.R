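#' Build a CID query index from a mask
#'
#' The index answers exact and single-substitution (Hamming distance 1)
#' queries with results identical to a naive scan of the mask. Memory is
#' proportional to mask size: the mask itself is the store and variant
#' expansion happens on the query side (each query expands to its
#' `3 * cidLength` single-substitution variants, four per position for an
#' `N`).
#'
#' @param mask a [MaskTable-class].
#' @return a [CidIndex-class].
#' @export
buildCidIndex <- function(mask) {
  stopifnot(is(mask, "MaskTable"))
  validObject(mask)
  new("CidIndex", mask = mask)
}

# all single-substitution variants of each query:
# data.frame(q = query index, pos = substituted position, v = variant).
# At an N position all four bases are emitted (N -> base is one substitution);
# at an ACGT position the three other bases.
.variantTable <- function(cids, L) {
  n <- length(cids)
  qs <- integer(0); ps <- integer(0); vs <- character(0)
  for (p in seq_len(L)) {
    pre <- substr(cids, 1L, p - 1L)
    suf <- substr(cids, p + 1L, L)
    cur <- substr(cids, p, p)
    for (b in BASES) {
      sel <- which(cur != b)
      if (length(sel)) {
        qs <- c(qs, sel)
        ps <- c(ps, rep.int(p, length(sel)))
        vs <- c(vs, paste0(pre[sel], b, suf[sel]))
      }
    }
  }
  list(q = qs, pos = ps, v = vs)
}

# classify queries given exact-match rows and distance-1 hits.
# exact: integer vector (mask row or NA) per query; hits: list(q, row, pos).
.classifyHits <- function(mask, exact, hits, n) {
  kind <- rep.int("unmatched", n)
  x <- rep.int(NA_integer_, n)
  y <- rep.int(NA_integer_, n)
  pos <- rep.int(NA_integer_, n)
  isExact <- !is.na(exact)
  kind[isExact] <- "exact"
  x[isExact] <- mask@x[exact[isExact]]
  y[isExact] <- mask@y[exact[isExact]]
  if (length(hits$q)) {
    keep <- !isExact[hits$q]           # exact match short-circuits variants
    hq <- hits$q[keep]; hr <- hits$row[keep]; hp <- hits$pos[keep]
    if (length(hq)) {
      nh <- tabulate(hq, nbins = n)
      one <- nh == 1L
      if (any(one)) {
        sel <- one[hq]
        kind[hq[sel]] <- "corrected"
        x[hq[sel]] <- mask@x[hr[sel]]
        y[hq[sel]] <- mask@y[hr[sel]]
        pos[hq[sel]] <- hp[sel]
      }
      kind[nh >= 2L] <- "ambiguous"
    }
  }
  data.frame(match_kind = kind, x = x, y = y, mismatch_pos = pos,
             stringsAsFactors = FALSE)
}

# batch locate against the full mask
.locateCids <- function(mask, cids) {
  L <- mask@chip@cidLength
  if (any(nchar(cids) != L)) stop("query CID of wrong length")
  n <- length(cids)
  exact <- match(cids, mask@cid)
  rest <- which(is.na(exact))
  hits <- list(q = integer(0), row = integer(0), pos = integer(0))
  if (length(rest) && length(mask@cid)) {
    vt <- .variantTable(cids[rest], L)
    mi <- match(vt$v, mask@cid)
    hit <- !is.na(mi)
    hits <- list(q = rest[vt$q[hit]], row = mi[hit], pos = vt$pos[hit])
  }
  .classifyHits(mask, exact, hits, n)
}

#' Locate a single CID
#'
#' Exact hits are returned preferentially; otherwise every
#' single-substitution variant is tested against the mask: exactly one hit
#' gives a corrected match with the differing position, two or more
#' distinct hits are ambiguous (discarded downstream), zero hits
#' unmatched. A CID containing `N` can never match exactly; an `N` position
#' still participates in variant substitution.
#'
#' @param index a [CidIndex-class].
#' @param cid query string of the chip's CID length.
#' @return list with `match_kind` (`"exact"`, `"corrected"`, `"ambiguous"`
#'   or `"unmatched"`), `coordinate` (`c(x, y)` or `NULL`) and
#'   `mismatch_position` (1-based, or `NULL`).
#' @export
locateCid <- function(index, cid) {
  stopifnot(is(index, "CidIndex"))
  .stopifnot_scalar_string(cid, "cid")
  r <- .locateCids(index@mask, cid)
  list(match_kind = r$match_kind,
       coordinate = if (!is.na(r$x)) c(x = r$x, y = r$y),
       mismatch_position = if (!is.na(r$mismatch_pos)) r$mismatch_pos)
}

#' Restore reads to chip coordinates
#'
#' Matches each read's CID against the mask (exact, then single
#' substitution) and attaches the restored coordinate and match
#' provenance. One output row per input read, input order preserved; only
#' exact/corrected reads carry coordinates.
#'
#' @param reads read table (see [readSpatialFastq()]).
#' @param index a [CidIndex-class].
#' @return list with `located` (the read table plus `x`, `y`,
#'   `match_kind`, `mismatch_pos` columns) and `stats` (total_reads,
#'   exact_matches, corrected_matches, ambiguous, unmatched,
#'   mapped_fraction).
#' @export
restoreReads <- function(reads, index) {
  stopifnot(is(index, "CidIndex"))
  loc <- .locateCids(index@mask, reads$cid)
  located <- cbind(reads, loc)
  list(located = located, stats = .restoreStats(loc$match_kind))
}

.restoreStats <- function(kind) {
  total <- length(kind)
  ex <- sum(kind == "exact"); co <- sum(kind == "corrected")
  am <- sum(kind == "ambiguous"); un <- sum(kind == "unmatched")
  list(total_reads = total, exact_matches = ex, corrected_matches = co,
       ambiguous = am, unmatched = un,
       mapped_fraction = if (total) (ex + co) / total else 0)
}

#' Restore reads under CID partitioning
#'
#' Memory-bounded variant of [restoreReads()]: the mask is split by `rule`
#' and each query is matched only against the partitions that can contain
#' it — its own partition for the exact form, and for each
#' single-substitution variant the partition that variant encodes to (for
#' a prefix rule this reduces to the home partition plus the prefix-variant
#' partitions). A variant can only equal a mask CID of its own partition,
#' so results — coordinates, match kinds, ambiguity — are identical to
#' unpartitioned matching, read for read.
#'
#' @param reads read table.
#' @param mask a [MaskTable-class].
#' @param rule a [PartitionRule-class].
#' @return same shape as [restoreReads()], plus `n_parts` in `stats`.
#' @export
restoreReadsPartitioned <- function(reads, mask, rule) {
  stopifnot(is(mask, "MaskTable"), is(rule, "PartitionRule"))
  L <- mask@chip@cidLength
  cids <- reads$cid
  if (any(nchar(cids) != L)) stop("query CID of wrong length")
  n <- length(cids)
  maskParts <- splitMask(mask, rule)
  qpart <- assignPartition(cids, rule)
  # exact pass within home partitions
  exact <- rep.int(NA_integer_, n)
  rowOffset <- integer(rule@nParts)   # map part-local row -> full-mask row
  fullRowOf <- vector("list", rule@nParts)
  maskIdx <- assignPartition(mask@cid, rule)
  for (p in seq_len(rule@nParts) - 1L)
    fullRowOf[[p + 1L]] <- which(maskIdx == p)
  for (p in seq_len(rule@nParts) - 1L) {
    qs <- which(qpart == p)
    if (!length(qs)) next
    mi <- match(cids[qs], maskParts[[p + 1L]]@cid)
    hit <- !is.na(mi)
    exact[qs[hit]] <- fullRowOf[[p + 1L]][mi[hit]]
  }
  # variant pass, each variant routed to its own partition
  rest <- which(is.na(exact))
  hits <- list(q = integer(0), row = integer(0), pos = integer(0))
  if (length(rest)) {
    vt <- .variantTable(cids[rest], L)
    vpart <- assignPartition(vt$v, rule)
    for (p in seq_len(rule@nParts) - 1L) {
      sel <- which(vpart == p)
      if (!length(sel)) next
      mi <- match(vt$v[sel], maskParts[[p + 1L]]@cid)
      hit <- !is.na(mi)
      if (any(hit)) {
        hits$q <- c(hits$q, rest[vt$q[sel[hit]]])
        hits$row <- c(hits$row, fullRowOf[[p + 1L]][mi[hit]])
        hits$pos <- c(hits$pos, vt$pos[sel[hit]])
      }
    }
  }
  loc <- .classifyHits(mask, exact, hits, n)
  located <- cbind(reads, loc)
  stats <- .restoreStats(loc$match_kind)
  stats$n_parts <- rule@nParts
  list(located = located, stats = stats)
}
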