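## Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

ALL_CODONS <- as.character(outer(outer(BASES, BASES, paste0), BASES, paste0))
NONSTOP_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

#' @importFrom methods new validObject is slot
#' @importFrom stats median rbinom rpois runif setNames
#' @importFrom utils head tail
NULL

randomDna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

## Split a DNA character string into codon triplets.
splitCodons <- function(x) {
  n <- nchar(x)
  stopifnot(n %% 3L == 0L)
  if (n == 0L) return(character(0))
  substring(x, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Sample `n` integer values uniformly from an inclusive range given as
## c(lo, hi) (a scalar is treated as a degenerate range).
sampleRange <- function(range, n = 1L) {
  if (length(range) == 1L) range <- c(range, range)
  stopifnot(length(range) == 2L, range[2L] >= range[1L])
  if (range[1L] == range[2L]) rep(as.integer(range[1L]), n)
  else sample(seq.int(range[1L], range[2L]), n, replace = TRUE)
}

## Count character mismatches between two equal-length raw vectors.
rawMismatches <- function(a, b) sum(a != b)

isSingleString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
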