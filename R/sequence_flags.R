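# Non-model per-guide sequence features: GC content, homopolymer runs, and
# 4-nt self-complementarity against the guide itself and the sgRNA backbone.

#' Default sgRNA backbone sequences
#'
#' Returns the backbone sequences used by [self_complementarity()] when none
#' are supplied: the hairpin-prone tracrRNA-proximal region of the standard
#' SpCas9 sgRNA scaffold. This is a configuration default, shipped as a plain
#' text file (one sequence per line) that users can replace for non-standard
#' scaffolds.
#'
#' @return character vector of uppercase DNA sequences.
#' @export
default_backbones <- function() {
  path <- system.file("extdata", "backbone.txt", package = "guidecraft")
  toupper(readLines(path, warn = FALSE))
}

#' GC content of a protospacer
#'
#' G+C count and percentage over the 20-mer target sequence only; the PAM is
#' excluded because its composition does not contribute to guide binding.
#'
#' @param protospacer 20-mer DNA string (A/C/G/T).
#' @return list with `gc_count` (0--20) and `gc_percent` (0--100).
#' @export
gc_content <- function(protospacer) {
  if (nchar(protospacer) != 20L || !is_acgt(protospacer)) {
    stop("protospacer must be a 20-mer over A/C/G/T")
  }
  n <- sum(seq_chars(protospacer) %in% c("G", "C"))
  list(gc_count = n, gc_percent = 100 * n / 20)
}

#' Find homopolymer runs in a protospacer
#'
#' Maximal runs of four or more identical bases. Runs of T are additionally
#' flagged: four consecutive T's terminate transcription prematurely in
#' RNA polymerase III expression systems.
#'
#' @param protospacer 20-mer DNA string.
#' @return data frame with columns `base`, `start` (1-based offset in the
#'   20-mer), `length`, and `pol3_terminator` (TRUE for T runs).
#' @export
find_homopolymers <- function(protospacer) {
  if (nchar(protospacer) != 20L) stop("protospacer must be 20 bp")
  r <- rle(seq_chars(protospacer))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= 4L
  data.frame(base = r$values[keep], start = starts[keep],
             length = r$lengths[keep],
             pol3_terminator = r$values[keep] == "T",
             stringsAsFactors = FALSE)
}

#' Count self-complementary 4-mers
#'
#' Counts 4-nt windows of the protospacer whose reverse complement occurs
#' either elsewhere in the protospacer (at a different offset, so a
#' palindromic window does not pair with itself) or anywhere in a backbone
#' sequence. Guide-internal and backbone matches carry equal weight; each
#' window is counted at most once. Such windows can fold the guide into
#' hairpins with itself or with the scaffold, reducing activity.
#'
#' @param protospacer 20-mer DNA string.
#' @param backbones character vector of backbone sequences; defaults to
#'   [default_backbones()].
#' @return non-negative integer count of matching windows.
#' @export
self_complementarity <- function(protospacer, backbones = default_backbones()) {
  if (nchar(protospacer) != 20L || !is_acgt(protospacer)) {
    stop("protospacer must be a 20-mer over A/C/G/T")
  }
  backbones <- toupper(backbones[nzchar(backbones)])
  offs <- 1:17
  windows <- substring(protospacer, offs, offs + 3L)
  rc <- reverse_complement(windows)
  hits <- vapply(offs, function(i) {
    other <- windows[-i]
    rc[i] %in% other ||
      any(vapply(backbones, function(b) grepl(rc[i], b, fixed = TRUE), logical(1)))
  }, logical(1))
  sum(hits)
}
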