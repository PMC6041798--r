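#' @useDynLib hapquant, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import data.table
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement nucleotide strings
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @keywords internal
rev_comp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Canonical unordered-pair label, e.g. "A/B" with sorted members.
pair_label <- function(h1, h2) {
  a <- pmin(h1, h2); b <- pmax(h1, h2)
  paste(a, b, sep = "/")
}

pair_members <- function(label) strsplit(label, "/", fixed = TRUE)

## Draw a random DNA sequence of length n (uses the current RNG stream).
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
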