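# internal helpers shared across modules

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorized reverse complement over character DNA sequences (IUPAC codes
#' allowed).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
reverse_complement <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# TRUE where the string consists only of A/C/G/T
is_acgt <- function(x) {
  !grepl("[^ACGT]", x)
}

# split a single sequence into a character vector of bases
seq_chars <- function(x) {
  strsplit(x, "", fixed = TRUE)[[1L]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
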