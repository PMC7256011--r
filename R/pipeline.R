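# Full design run: guide discovery -> sequence flags -> efficiency scoring ->
# off-target scan -> annotation, assembled into the two output tables.

#' Design sgRNAs for a query sequence
#'
#' The single-call entry point. Enumerates candidate guides in the query,
#' computes per-guide sequence features and efficiency scores, optionally
#' scans a genome for off-target loci (CFD-scored) and annotates them against
#' a GTF. Off-target calling defaults to on exactly when a genome is
#' supplied, and annotation to on exactly when both are; requesting either
#' explicitly without its input is an error.
#'
#' @param userseq query DNA: a raw sequence string or a path to a FASTA/plain
#'   text file (first record used; a warning is issued for multi-record
#'   files).
#' @param genome optional genome: path to a multi-record FASTA or a named
#'   character vector as returned by [read_fasta()].
#' @param gtf optional annotation: path to a GTF (optionally gzipped) or a
#'   data frame from [read_gtf()].
#' @param pam PAM pattern (IUPAC, <= 6 bp); default `"NGG"`.
#' @param call_offtargets search the genome for off-targets (default: TRUE
#'   iff `genome` is supplied).
#' @param annotate_offtargets annotate hits with the GTF (default: TRUE iff
#'   off-targets are called and `gtf` is supplied).
#' @param model an `efficiency_model` or path to one saved with
#'   [save_model()]; defaults to the synthetic [demo_model()].
#' @param cfd_tables a `cfd_table` or `c(mismatch_path, pam_path)`; defaults
#'   to [toy_cfd_table()].
#' @param backbones backbone sequences for [self_complementarity()], or a
#'   path to a one-sequence-per-line file; default [default_backbones()].
#' @param max_mismatches off-target mismatch cap (at most 4).
#' @return list with `guides` and `offtargets` data frames in the output
#'   column orders used by [write_guide_table()] and
#'   [write_offtarget_table()].
#' @export
sgrna_design <- function(userseq, genome = NULL, gtf = NULL, pam = "NGG",
                         call_offtargets = !is.null(genome),
                         annotate_offtargets = call_offtargets && !is.null(gtf),
                         model = NULL, cfd_tables = NULL, backbones = NULL,
                         max_mismatches = 4L) {
  if (annotate_offtargets && !call_offtargets) {
    stop("annotate_offtargets requires call_offtargets")
  }
  if (call_offtargets && is.null(genome)) {
    stop("off-target calling requires a genome")
  }
  if (annotate_offtargets && is.null(gtf)) {
    stop("off-target annotation requires a GTF annotation file")
  }
  query <- resolve_query(userseq)
  if (nchar(query) > 250 && call_offtargets) {
    warning("query exceeds 250 bp; off-target search time grows with query ",
            "length and genome size — consider a shorter target region")
  }
  pam <- as_pam_spec(pam)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  if (is.character(gtf) && length(gtf) == 1L) gtf <- read_gtf(gtf)
  if (is.null(model)) {
    model <- demo_model()
  } else if (is.character(model)) {
    model <- load_model(model)
  }
  if (is.null(cfd_tables)) {
    cfd_tables <- toy_cfd_table()
  } else if (is.character(cfd_tables)) {
    cfd_tables <- load_cfd_tables(cfd_tables[[1L]], cfd_tables[[2L]])
  }
  if (is.null(backbones)) {
    backbones <- default_backbones()
  } else if (length(backbones) == 1L && file.exists(backbones)) {
    backbones <- toupper(readLines(backbones, warn = FALSE))
  }

  guides <- find_guides(query, pam)
  n <- nrow(guides)
  empty_off <- coerce_table(NULL, OFFTARGET_TABLE_COLS)
  if (n == 0L) {
    return(list(guides = coerce_table(NULL, GUIDE_TABLE_COLS),
                offtargets = empty_off))
  }

  scores <- predict_efficiency(model, guides$context30)
  flags <- lapply(guides$protospacer, function(p) {
    hp <- find_homopolymers(p)
    list(gc = gc_content(p), hp = hp,
         sc = self_complementarity(p, backbones))
  })

  mm_counts <- matrix(NA_integer_, nrow = n, ncol = 5,
                      dimnames = list(NULL, paste0("MM", 0:4)))
  all_hits <- empty_off[0, ]
  if (call_offtargets) {
    hit_list <- lapply(seq_len(n), function(i) {
      find_offtargets(guides$protospacer[i], genome, pam, cfd_tables,
                      max_mm = max_mismatches)
    })
    for (i in seq_len(n)) mm_counts[i, ] <- summarize_mismatches(hit_list[[i]])
    hits <- do.call(rbind, hit_list)
    if (annotate_offtargets) {
      hits <- annotate_hits(hits, gtf)
    } else if (nrow(hits)) {
      hits$gene_id <- ""
      hits$gene_name <- ""
      hits$sequence_type <- ""
      hits$exon_number <- ""
    }
    if (nrow(hits)) all_hits <- coerce_table(hits, OFFTARGET_TABLE_COLS)
  }

  notes <- vapply(seq_len(n), function(i) {
    fl <- flags[[i]]
    msgs <- character(0)
    if (nrow(fl$hp)) {
      msgs <- c(msgs, paste0("homopolymer (",
                             paste0(strrep(fl$hp$base, fl$hp$length), collapse = ", "), ")"))
      if (any(fl$hp$pol3_terminator)) {
        msgs <- c(msgs, "TTTT terminates RNA Pol III transcription")
      }
    }
    if (fl$sc > 0) {
      msgs <- c(msgs, paste0("self-complementary 4-mers: ", fl$sc))
    }
    if (call_offtargets && !is.na(mm_counts[i, "MM0"]) && mm_counts[i, "MM0"] > 1) {
      msgs <- c(msgs, "multiple perfect genomic matches")
    }
    if (!pam$canonical) {
      msgs <- c(msgs, "custom PAM: efficiency score is low-confidence")
    }
    paste(msgs, collapse = "; ")
  }, character(1))

  guide_rows <- data.frame(
    sgRNA_sequence = guides$protospacer,
    PAM = guides$pam,
    direction = guides$direction,
    start = guides$start,
    end = guides$end,
    GC_content = vapply(flags, function(f) f$gc$gc_percent, numeric(1)),
    homopolymer = vapply(flags, function(f) {
      if (nrow(f$hp) == 0L) "" else
        paste(sprintf("%s:%d-%d", f$hp$base, f$hp$start,
                      f$hp$start + f$hp$length - 1L), collapse = ";")
    }, character(1)),
    self_complementarity = vapply(flags, function(f) f$sc, numeric(1)),
    efficiency_score = scores,
    MM0 = mm_counts[, 1], MM1 = mm_counts[, 2], MM2 = mm_counts[, 3],
    MM3 = mm_counts[, 4], MM4 = mm_counts[, 5],
    notes = notes,
    stringsAsFactors = FALSE
  )
  rownames(guide_rows) <- NULL
  list(guides = guide_rows, offtargets = all_hits)
}

resolve_query <- function(userseq) {
  if (length(userseq) != 1L || !is.character(userseq)) {
    stop("userseq must be a single string (sequence or file path)")
  }
  if (file.exists(userseq)) {
    recs <- read_fasta(userseq)
    if (length(recs) > 1L) {
      warning("query file has ", length(recs), " records; using the first ('",
              names(recs)[1L], "')")
    }
    return(recs[[1L]])
  }
  q <- toupper(gsub("\\s", "", userseq))
  if (!nzchar(q)) stop("empty query sequence")
  bad <- regmatches(q, regexpr("[^ACGTNRYSWKMBDHV]", q))
  if (length(bad) && nzchar(bad)) {
    stop("query is neither an existing file nor a DNA sequence ",
         "(invalid character '", bad, "')")
  }
  q
}
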