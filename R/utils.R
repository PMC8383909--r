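#' @useDynLib mamut, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA sequences (ACGT, case-insensitive).
#' @return character vector of reverse complements, uppercase.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCATGCA", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# stop() with a consistent invalid-argument prefix
bad_arg <- function(...) stop("invalid argument: ", ..., call. = FALSE)

# integer base codes 1..4 for A,C,G,T; NA otherwise
base_codes <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], BASES)
}

# derive a child seed from a base seed and a label, staying inside 32-bit range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}
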