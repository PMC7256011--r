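#!/usr/bin/env Rscript

# Optional, download-gated validation against published example inputs.
# Counts guides in user-supplied example sequences and off-targets in a
# user-supplied genome; nothing here runs without those files.
#
#   Rscript scripts/external_validation.R --seq DAK1short.fa \
#       [--genome sacCer.fa] [--gtf sacCer.gtf]

suppressPackageStartupMessages(library(guidecraft))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) && i < length(args)) args[i + 1] else default
}
seqfile <- get_arg("--seq")
genomefile <- get_arg("--genome")
gtffile <- get_arg("--gtf")
if (is.null(seqfile)) stop("--seq is required (example query FASTA)")

res <- sgrna_design(seqfile, genome = genomefile, gtf = gtffile)
cat("guides:", nrow(res$guides), "\n")
if (!is.null(genomefile)) cat("off-target rows:", nrow(res$offtargets), "\n")
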