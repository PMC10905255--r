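#' @import methods
#' @importFrom stats median rpois runif setNames
#' @importFrom utils head write.table read.delim
NULL

BASES <- c("A", "C", "G", "T")

# allow data.table NSE ([.data.table with .N, .SD, :=) from package code
.datatable.aware <- TRUE

# 2-bit base codes, A=0 C=1 G=2 T=3; non-ACGT -> NA
.baseCode <- function(chars) {
  match(chars, BASES) - 1L
}

# split equal-length strings into a character matrix (n x L)
.seqMatrix <- function(seqs, len) {
  if (length(seqs) == 0L) {
    return(matrix(character(0), nrow = 0L, ncol = len))
  }
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), ncol = len, byrow = TRUE)
}

#' Hamming distance between equal-length strings
#'
#' Number of positions at which two strings of equal length differ
#' (substitution-only distance; the metric used for both CID error tolerance
#' and MID correction).
#'
#' @param a,b character vectors of equal-length strings; recycled pairwise.
#' @return integer vector of distances.
#' @examples
#' hammingDistance("AAA", "AGA")
#' @export
hammingDistance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  if (n == 0L) return(integer(0))
  if (any(nchar(a) != nchar(b)))
    stop("hammingDistance: strings must have equal length")
  mapply(function(x, y) {
    sum(utf8ToInt(x) != utf8ToInt(y))
  }, a, b, USE.NAMES = FALSE)
}

# run code with a temporary RNG seed, restoring prior RNG state
.withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# random DNA strings of fixed length
.randomDna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(BASES, n * len, replace = TRUE), nrow = n)
  apply(m, 1L, paste0, collapse = "")
}

.stopifnot_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single string")
}
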