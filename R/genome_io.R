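# Reading genomes/queries (FASTA or bare text), GTF annotations, and writing
# the two output tables.

#' Read a genome or query sequence
#'
#' Reads a multi-record FASTA file into a named character vector of uppercase
#' DNA sequences. A file without a `>` header is treated as a bare sequence
#' (whitespace stripped) and returned as a single record named `"query"`.
#' IUPAC ambiguity codes (including `N`) are accepted; anything else is an
#' error naming the offending character and line.
#'
#' @param path path to a FASTA or plain-text sequence file.
#' @return named character vector (sequence name -> uppercase DNA string).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    stop("empty sequence file: ", path)
  }
  first <- trimws(lines[nzchar(trimws(lines))][1L])
  iupac <- paste0(names(Biostrings::IUPAC_CODE_MAP), collapse = "")
  check_alphabet <- function(ln, i) {
    bad <- regmatches(ln, regexpr(sprintf("[^%s%s]", iupac, tolower(iupac)), ln))
    if (length(bad) && nzchar(bad)) {
      stop(sprintf("invalid sequence character '%s' on line %d of %s",
                   bad, i, path))
    }
  }
  if (!startsWith(first, ">")) {
    for (i in seq_along(lines)) check_alphabet(gsub("\\s", "", lines[i]), i)
    seqs <- toupper(paste(gsub("\\s", "", lines), collapse = ""))
    names(seqs) <- "query"
    return(seqs)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, ">")) next
    check_alphabet(ln, i)
  }
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  seqs <- toupper(as.character(set))
  # keep only the record identifier, drop description
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(names(seqs))) {
    stop("duplicate record names in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  if (any(!nzchar(names(seqs)))) stop("empty record name in ", path)
  if (any(!nzchar(seqs))) stop("empty sequence record in ", path)
  seqs
}

#' Read a GTF annotation file
#'
#' Parses a (optionally gzip-compressed) GTF into a data frame of annotation
#' records with the attributes used for off-target annotation. Comment lines
#' are skipped; missing optional attributes become empty strings.
#'
#' @param path path to a `.gtf` or `.gtf.gz` file.
#' @return data frame with columns `seqname`, `start`, `end`, `strand`
#'   (`+`/`-`/`.`), `feature`, `gene_id`, `gene_name`, `exon_number`.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)  # file() transparently decompresses gz
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  body <- lines[keep]
  if (length(body) == 0L) return(empty_annotation())
  nfield <- lengths(strsplit(body, "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    bad <- which(keep)[which(nfield != 9L)[1L]]
    stop(sprintf("malformed GTF line %d in %s: expected 9 tab-separated columns, found %d",
                 bad, path, nfield[nfield != 9L][1L]))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  att <- function(nm) {
    v <- S4Vectors::mcols(gr)[[nm]]
    if (is.null(v)) rep("", length(gr)) else ifelse(is.na(v), "", as.character(v))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  out <- data.frame(
    seqname = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = strand,
    feature = as.character(S4Vectors::mcols(gr)$type),
    gene_id = att("gene_id"),
    gene_name = att("gene_name"),
    exon_number = att("exon_number"),
    stringsAsFactors = FALSE
  )
  if (any(out$start > out$end)) stop("malformed GTF interval (start > end) in ", path)
  out
}

empty_annotation <- function() {
  data.frame(seqname = character(), start = integer(), end = integer(),
             strand = character(), feature = character(), gene_id = character(),
             gene_name = character(), exon_number = character(),
             stringsAsFactors = FALSE)
}

GUIDE_TABLE_COLS <- c("sgRNA_sequence", "PAM", "direction", "start", "end",
                      "GC_content", "homopolymer", "self_complementarity",
                      "efficiency_score", "MM0", "MM1", "MM2", "MM3", "MM4",
                      "notes")

OFFTARGET_TABLE_COLS <- c("sgRNA_sequence", "chromosome", "start", "end",
                          "mismatches", "strand", "CFD_score",
                          "matched_sequence", "mismatch_positions", "gene_id",
                          "gene_name", "sequence_type", "exon_number")

coerce_table <- function(rows, cols) {
  if (is.null(rows) || nrow(as.data.frame(rows)) == 0L) {
    rows <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                          stringsAsFactors = FALSE)
  }
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  missing <- setdiff(cols, names(rows))
  if (length(missing)) stop("missing table columns: ", paste(missing, collapse = ", "))
  rows[, cols, drop = FALSE]
}

#' Write the per-guide output table
#'
#' Writes guide rows produced by [sgrna_design()] as CSV with a fixed column
#' order. Empty input yields a header-only file.
#'
#' @param rows data frame of guide rows.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_guide_table <- function(rows, path) {
  utils::write.csv(coerce_table(rows, GUIDE_TABLE_COLS), path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' Write the off-target output table
#'
#' @param rows data frame of annotated off-target rows.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_offtarget_table <- function(rows, path) {
  utils::write.csv(coerce_table(rows, OFFTARGET_TABLE_COLS), path,
                   row.names = FALSE, na = "")
  invisible(path)
}
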