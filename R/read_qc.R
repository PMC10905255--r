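#' Pre-alignment read filter parameters
#'
#' The checks, in fixed order: (1) MID contains an `N`; (2) MID is poly-A;
#' (3) any MID base below the Phred minimum; (4) trailing cDNA poly-A run
#' of at least `polyaRunMin` bases is trimmed, and the read fails if the
#' remaining cDNA is shorter than `minCdnaLengthAfterTrim`. Poly-A tails
#' are expected biology, so the cDNA check trims rather than discards;
#' only a read left too short is dropped. The MID quality rule is a
#' per-base minimum.
#'
#' @param minMidQuality per-base Phred minimum for the MID (default 10).
#' @param polyaRunMin minimal trailing A-run length that triggers trimming
#'   (default 10).
#' @param minCdnaLengthAfterTrim minimal cDNA length after trimming
#'   (default 25).
#' @param qualityOffset ASCII offset of the quality encoding (33 =
#'   Phred+33).
#' @return a named list of parameters.
#' @export
filterParams <- function(minMidQuality = 10L, polyaRunMin = 10L,
                         minCdnaLengthAfterTrim = 25L, qualityOffset = 33L) {
  stopifnot(minMidQuality >= 0L, polyaRunMin >= 0L,
            minCdnaLengthAfterTrim >= 0L)
  list(minMidQuality = as.integer(minMidQuality),
       polyaRunMin = as.integer(polyaRunMin),
       minCdnaLengthAfterTrim = as.integer(minCdnaLengthAfterTrim),
       qualityOffset = as.integer(qualityOffset))
}

# length of the trailing A-run of each sequence
.trailingARun <- function(seqs) {
  m <- regexpr("A*$", seqs)
  attr(m, "match.length")
}

#' Filter a single located read
#'
#' @param read one-row read table (must include `mid`, `mid_qual`, `cdna`).
#' @param params see [filterParams()].
#' @return list with `passed`, `reason` (`"none"` when passed) and
#'   `trimmed_cdna`.
#' @export
filterRead <- function(read, params = filterParams()) {
  out <- .filterVec(read$mid, read$mid_qual, read$cdna, params)
  list(passed = out$passed, reason = out$reason,
       trimmed_cdna = out$trimmed_cdna)
}

.filterVec <- function(mid, mid_qual, cdna, params) {
  n <- length(mid)
  reason <- rep.int("none", n)
  # (1) N in MID
  f <- grepl("N", mid, fixed = TRUE)
  reason[f & reason == "none"] <- "mid_has_N"
  # (2) MID all A
  f <- grepl("^A*$", mid) & nchar(mid) > 0L
  reason[f & reason == "none"] <- "mid_polyA"
  # (3) per-base MID quality minimum
  if (n) {
    minq <- vapply(mid_qual, function(q) {
      if (!nchar(q)) return(Inf)
      min(utf8ToInt(q)) - params$qualityOffset
    }, 0, USE.NAMES = FALSE)
    f <- minq < params$minMidQuality
    reason[f & reason == "none"] <- "mid_low_quality"
  }
  # (4) trailing poly-A trim then length check
  run <- .trailingARun(cdna)
  doTrim <- run >= params$polyaRunMin
  trimmed <- cdna
  trimmed[doTrim] <- substr(cdna[doTrim], 1L,
                            nchar(cdna[doTrim]) - run[doTrim])
  f <- nchar(trimmed) < params$minCdnaLengthAfterTrim
  reason[f & reason == "none"] <- "cdna_too_short_after_polyA_trim"
  list(passed = reason == "none", reason = reason, trimmed_cdna = trimmed)
}

#' Filter a batch of located reads
#'
#' Applies [filterRead()] to every read; passing reads are returned with
#' their cDNA trimmed. Per-reason counters conserve the input count.
#'
#' @param reads located read table (rows with `match_kind` in
#'   exact/corrected are expected; others are not checked here).
#' @param params see [filterParams()].
#' @return list with `passed` (read table, `cdna`/`cdna_qual` trimmed) and
#'   `stats` (total, passed, one counter per failure reason,
#'   retained_fraction).
#' @export
filterReads <- function(reads, params = filterParams()) {
  out <- .filterVec(reads$mid, reads$mid_qual, reads$cdna, params)
  keep <- out$passed
  passed <- reads[keep, , drop = FALSE]
  if (nrow(passed)) {
    passed$cdna <- out$trimmed_cdna[keep]
    if ("cdna_qual" %in% names(passed))
      passed$cdna_qual <- substr(passed$cdna_qual, 1L, nchar(passed$cdna))
  }
  reasons <- c("mid_has_N", "mid_polyA", "mid_low_quality",
               "cdna_too_short_after_polyA_trim")
  counts <- vapply(reasons, function(r) sum(out$reason == r), 0L)
  stats <- c(list(total = nrow(reads), passed = sum(keep)),
             as.list(counts),
             list(retained_fraction =
                    if (nrow(reads)) sum(keep) / nrow(reads) else 0))
  list(passed = passed, stats = stats)
}
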