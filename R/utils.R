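#' @importFrom stats rbinom runif sd setNames aggregate
#' @importFrom utils read.table write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Deterministic sub-seed derivation; keeps every derived seed inside the
## 32-bit signed range so set.seed() never overflows.
derive_seed <- function(seed, n) {
  as.integer(((as.double(seed) %% 2147483647) * 48271 + 1009 * as.double(n)) %% 2147483629) + 1L
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## Vectorised single-character extraction from one long string.
str_chars <- function(x) {
  strsplit(x, "", fixed = TRUE)[[1]]
}

substr0 <- function(seq, start0, end0) {
  ## 0-based half-open slice of a 1-based R string
  substr(seq, start0 + 1L, end0)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
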