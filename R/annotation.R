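# Cross-referencing off-target loci with GTF records.

#' Annotate off-target hits against GTF records
#'
#' Joins each hit interval against the annotation by strand-agnostic overlap
#' (any shared base counts: a double-strand break within one base of a
#' feature affects it). A hit overlapping an exon record reports that exon's
#' gene and exon number with `sequence_type = "exon"`; with no exon, an
#' overlapping CDS is reported, then any other non-gene feature; a hit inside
#' a gene (or transcript) body only is an `"intron"`; no overlap at all is
#' `"intergenic"`. When several records of the chosen type overlap, the one
#' with the smallest start (then lexicographically smallest gene_id) wins, so
#' the join is deterministic under record permutation.
#'
#' @param hits data frame from [find_offtargets()] (needs `chromosome`,
#'   `start`, `end`).
#' @param records annotation data frame from [read_gtf()].
#' @return `hits` with columns `gene_id`, `gene_name`, `sequence_type`,
#'   `exon_number` appended; one output row per input hit.
#' @export
annotate_hits <- function(hits, records) {
  n <- nrow(hits)
  ann <- data.frame(gene_id = character(n), gene_name = character(n),
                    sequence_type = rep("intergenic", n),
                    exon_number = character(n), stringsAsFactors = FALSE)
  if (n == 0L) return(cbind(hits, ann))
  if (is.null(records) || nrow(records) == 0L) return(cbind(hits, ann))
  hit_gr <- GenomicRanges::GRanges(hits$chromosome,
                                   IRanges::IRanges(hits$start, hits$end))
  rec_gr <- GenomicRanges::GRanges(records$seqname,
                                   IRanges::IRanges(records$start, records$end))
  # disjoint seqlevels (hit chromosome absent from the GTF) is a legitimate
  # intergenic case, not a warning-worthy condition
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(hit_gr, rec_gr, ignore.strand = TRUE))
  ov_by_hit <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))
  gene_like <- c("gene", "transcript", "mRNA")
  for (h in names(ov_by_hit)) {
    i <- as.integer(h)
    recs <- records[ov_by_hit[[h]], , drop = FALSE]
    pick_from <- function(sub) {
      sub[order(sub$start, sub$gene_id), , drop = FALSE][1L, , drop = FALSE]
    }
    exons <- recs[recs$feature == "exon", , drop = FALSE]
    cds <- recs[recs$feature == "CDS", , drop = FALSE]
    other <- recs[!(recs$feature %in% c("exon", "CDS", gene_like)), , drop = FALSE]
    genes <- recs[recs$feature %in% gene_like, , drop = FALSE]
    chosen <- if (nrow(exons)) pick_from(exons)
              else if (nrow(cds)) pick_from(cds)
              else if (nrow(other)) pick_from(other)
              else NULL
    if (!is.null(chosen)) {
      ann$sequence_type[i] <- chosen$feature
      ann$gene_id[i] <- chosen$gene_id
      ann$gene_name[i] <- chosen$gene_name
      ann$exon_number[i] <- chosen$exon_number
    } else if (nrow(genes)) {
      g <- pick_from(genes)
      ann$sequence_type[i] <- "intron"
      ann$gene_id[i] <- g$gene_id
      ann$gene_name[i] <- g$gene_name
    }
  }
  cbind(hits, ann)
}
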