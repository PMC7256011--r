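# Synthetic fixture generation: a random genome with planted off-target loci
# at chosen Hamming distances and PAM variants, a query carrying exactly one
# guide, a GTF covering a stated subset of the plants, and a manifest listing
# every planted truth. The construction itself is the oracle for scanner and
# pipeline tests.

#' Generate a synthetic design fixture with planted ground truth
#'
#' Builds a random genome into which copies of a single guide are planted at
#' the requested Hamming distances (0 = the on-target locus), each followed
#' by the requested PAM variant, alternating strands. The query sequence is a
#' 30-bp region containing exactly one NGG guide: its 5'/3' padding uses an
#' A/T alternation and the guide itself is generated without `GG`/`CC`
#' dinucleotides, so no secondary PAM can arise on either strand. A GTF
#' places the second plant inside an exon and the third inside a gene but
#' outside its exons (an intron); remaining plants are intergenic. The
#' manifest records every planted locus with its expected coordinates,
#' strand, distance, PAM and annotation.
#'
#' @param seed integer seed; fixes every random choice (genome bytes
#'   included).
#' @param genome_size genome length in bp (default 10000).
#' @param distances integer vector of planted Hamming distances, each <= 4
#'   (default `0:4`).
#' @param pams PAM variant planted at each locus (default `"TGG"` for all).
#' @param dir optional directory; when given, `genome.fa`, `query.fa`,
#'   `annotation.gtf` and `manifest.csv` are written there and their paths
#'   returned.
#' @return list with `genome` (named character vector), `query` (string),
#'   `guide` (the planted 20-mer), `gtf` (annotation data frame), `manifest`
#'   (data frame: `label`, `chromosome`, `start`, `end`, `strand`,
#'   `distance`, `pam`, `planted_protospacer`, `sequence_type`, `gene_id`,
#'   `gene_name`, `exon_number`), and `paths` when `dir` is given.
#' @export
generate_fixture <- function(seed, genome_size = 10000L, distances = 0:4,
                             pams = rep("TGG", length(distances)),
                             dir = NULL) {
  if (any(distances > 4L | distances < 0L)) {
    stop("planted mismatch distances must be between 0 and 4")
  }
  if (length(pams) != length(distances)) {
    stop("pams must have one PAM variant per planted distance")
  }
  np <- length(distances)
  if (genome_size < (np + 2L) * 60L) {
    stop("genome too small for ", np, " planted loci; need at least ",
         (np + 2L) * 60L, " bp")
  }
  set.seed(seed)

  # guide without GG/CC so the query contains exactly one PAM site
  g <- character(20)
  g[1] <- sample(DNA_BASES, 1)
  for (k in 2:20) {
    excl <- if (g[k - 1] %in% c("G", "C")) g[k - 1] else character(0)
    g[k] <- sample(setdiff(DNA_BASES, excl), 1)
  }
  guide <- paste(g, collapse = "")
  query <- paste0("ATAT", guide, "TGG", "TAT")

  genome <- paste(sample(DNA_BASES, genome_size, replace = TRUE), collapse = "")
  strands <- rep(c("+", "-"), length.out = np)
  spacing <- genome_size %/% (np + 1L)
  manifest <- vector("list", np)
  for (i in seq_len(np)) {
    d <- distances[i]
    mut <- g
    if (d > 0L) {
      pos <- sample(1:20, d)
      for (p in pos) mut[p] <- sample(setdiff(DNA_BASES, g[p]), 1)
    }
    insert <- paste0(paste(mut, collapse = ""), pams[i])
    if (strands[i] == "-") insert <- reverse_complement(insert)
    q <- i * spacing
    substr(genome, q, q + nchar(insert) - 1L) <- insert
    if (strands[i] == "+") {
      start <- q; end <- q + 19L
    } else {
      start <- q + nchar(pams[i]); end <- start + 19L
    }
    manifest[[i]] <- data.frame(
      label = sprintf("plant_d%d_%s", d, strands[i]),
      chromosome = "chr1", start = start, end = end, strand = strands[i],
      distance = d, pam = pams[i],
      planted_protospacer = paste(mut, collapse = ""),
      sequence_type = "intergenic", gene_id = "", gene_name = "",
      exon_number = "", stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, manifest)

  # annotation: plant 2 exonic, plant 3 intronic, the rest intergenic
  gtf <- empty_annotation()
  if (np >= 2L) {
    s <- manifest$start[2L]; e <- manifest$end[2L]
    gtf <- rbind(gtf, data.frame(
      seqname = "chr1", start = c(s - 50L, s - 5L), end = c(e + 50L, e + 5L),
      strand = "+", feature = c("gene", "exon"), gene_id = "g1",
      gene_name = "GENE1", exon_number = c("", "2"), stringsAsFactors = FALSE))
    manifest[2L, c("sequence_type", "gene_id", "gene_name", "exon_number")] <-
      list("exon", "g1", "GENE1", "2")
  }
  if (np >= 3L) {
    s <- manifest$start[3L]; e <- manifest$end[3L]
    gtf <- rbind(gtf, data.frame(
      seqname = "chr1", start = c(s - 50L, e + 30L), end = c(e + 50L, e + 45L),
      strand = "+", feature = c("gene", "exon"), gene_id = "g2",
      gene_name = "GENE2", exon_number = c("", "1"), stringsAsFactors = FALSE))
    manifest[3L, c("sequence_type", "gene_id", "gene_name")] <-
      list("intron", "g2", "GENE2")
  }

  out <- list(genome = stats::setNames(genome, "chr1"), query = query,
              guide = guide, gtf = gtf, manifest = manifest)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(genome = file.path(dir, "genome.fa"),
                  query = file.path(dir, "query.fa"),
                  gtf = file.path(dir, "annotation.gtf"),
                  manifest = file.path(dir, "manifest.csv"))
    write_fasta(out$genome, paths$genome)
    write_fasta(stats::setNames(query, "query"), paths$query)
    write_gtf_records(gtf, paths$gtf)
    utils::write.csv(manifest, paths$manifest, row.names = FALSE)
    out$paths <- paths
  }
  out
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width (default 70).
#' @return invisibly, the path.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# serialize annotation records back to GTF (fixture output)
write_gtf_records <- function(records, path) {
  attrs <- sprintf('gene_id "%s";', records$gene_id)
  nz <- nzchar(records$gene_name)
  attrs[nz] <- paste0(attrs[nz], sprintf(' gene_name "%s";', records$gene_name[nz]))
  nz <- nzchar(records$exon_number)
  attrs[nz] <- paste0(attrs[nz], sprintf(' exon_number "%s";', records$exon_number[nz]))
  lines <- sprintf("%s\tguidecraft\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   records$seqname, records$feature, records$start,
                   records$end, records$strand, attrs)
  writeLines(lines, path)
  invisible(path)
}
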