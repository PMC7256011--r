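# Mismatch-tolerant off-target search with CFD scoring. The scanner is a
# rolling, un-indexed comparison over every window of the genome on both
# strands; no pre-indexing is required.

#' Load CFD penalty tables
#'
#' Reads the two tab-separated penalty tables of the CFD (cutting frequency
#' determinant) scheme: per-mismatch penalties keyed by guide position
#' (1--20, PAM-distal = 1), guide base and off-target base; and PAM-variant
#' penalties keyed by the observed PAM string. Guide bases given as RNA (U)
#' are converted to DNA (T). All penalties must lie in \[0, 1\].
#'
#' @param mismatch_path TSV with header `position`, `guide_base`,
#'   `offtarget_base`, `penalty`.
#' @param pam_path TSV with header `pam`, `penalty`.
#' @return object of class `cfd_table`: list with `mm` (named numeric,
#'   keys `"pos_guide_off"`) and `pam` (named numeric keyed by PAM string).
#' @export
load_cfd_tables <- function(mismatch_path, pam_path) {
  mm <- utils::read.delim(mismatch_path, stringsAsFactors = FALSE)
  need <- c("position", "guide_base", "offtarget_base", "penalty")
  if (!all(need %in% names(mm))) {
    stop("mismatch table must have columns: ", paste(need, collapse = ", "))
  }
  mm$guide_base <- chartr("Uu", "Tt", toupper(mm$guide_base))
  mm$offtarget_base <- toupper(mm$offtarget_base)
  if (any(mm$penalty < 0 | mm$penalty > 1)) stop("mismatch penalties must be in [0, 1]")
  if (any(mm$position < 1 | mm$position > 20)) stop("mismatch positions must be 1-20")
  if (any(mm$guide_base == mm$offtarget_base)) {
    stop("mismatch table must not contain identical-base entries")
  }
  mmv <- stats::setNames(mm$penalty,
                         paste(mm$position, mm$guide_base, mm$offtarget_base, sep = "_"))
  pam <- utils::read.delim(pam_path, stringsAsFactors = FALSE)
  if (!all(c("pam", "penalty") %in% names(pam))) {
    stop("PAM table must have columns: pam, penalty")
  }
  if (any(pam$penalty < 0 | pam$penalty > 1)) stop("PAM penalties must be in [0, 1]")
  pamv <- stats::setNames(pam$penalty, toupper(pam$pam))
  structure(list(mm = mmv, pam = pamv), class = "cfd_table")
}

toy_cfd_cache <- new.env(parent = emptyenv())

#' Toy CFD table shipped with the package
#'
#' A complete-coverage penalty table with round synthetic values (every
#' (position, guide base, off-target base) key present; canonical NGG PAMs at
#' penalty 1.0 plus NAG/NGA-style variants). It exercises the CFD algebra and
#' the scanner's PAM-compatibility rules; the values are NOT the published
#' empirical CFD penalties, which users should load from the original
#' supplementary tables with [load_cfd_tables()].
#'
#' @return a `cfd_table`.
#' @export
toy_cfd_table <- function() {
  if (is.null(toy_cfd_cache$tbl)) {
    toy_cfd_cache$tbl <- load_cfd_tables(
      system.file("extdata", "cfd_toy_mismatch.tsv", package = "guidecraft"),
      system.file("extdata", "cfd_toy_pam.tsv", package = "guidecraft"))
  }
  toy_cfd_cache$tbl
}

#' CFD score of an off-target sequence
#'
#' Product over mismatched protospacer positions of the per-mismatch penalty,
#' multiplied by the PAM-variant penalty; 1 means cutting as likely as at a
#' perfect canonical site, 0 means unlikely. Positions are 1--20 with
#' position 1 PAM-distal.
#'
#' @param guide20 the guide protospacer (20-mer).
#' @param offtarget20 the genomic 20-mer at the candidate locus.
#' @param observed_pam the PAM found at the locus.
#' @param table a `cfd_table`.
#' @param pam_spec optional `pam_spec`; a PAM matching this pattern but
#'   absent from the table takes penalty 1.0 (custom-PAM runs).
#' @return numeric score in \[0, 1\].
#' @export
cfd_score <- function(guide20, offtarget20, observed_pam, table,
                      pam_spec = NULL) {
  stopifnot(nchar(guide20) == 20L, nchar(offtarget20) == 20L)
  g <- seq_chars(guide20)
  o <- seq_chars(offtarget20)
  pos <- which(g != o)
  score <- 1
  if (length(pos)) {
    keys <- paste(pos, g[pos], o[pos], sep = "_")
    vals <- table$mm[keys]
    if (anyNA(vals)) {
      stop("mismatch penalty missing for key '", keys[which(is.na(vals))[1L]],
           "' (position_guidebase_offtargetbase)")
    }
    score <- prod(vals)
  }
  observed_pam <- toupper(observed_pam)
  if (observed_pam %in% names(table$pam)) {
    score <- score * table$pam[[observed_pam]]
  } else if (!is.null(pam_spec) && pam_matches(as_pam_spec(pam_spec), observed_pam)) {
    score <- score * 1
  } else {
    stop("PAM '", observed_pam, "' not present in the PAM penalty table")
  }
  unname(score)
}

# scan the forward strand of one sequence for windows within max_mm of guide
scan_strand <- function(seq, guide20, pam_spec, table, max_mm) {
  L <- nchar(seq)
  pamlen <- pam_spec$length
  nstart <- L - 19L - pamlen
  if (nstart < 1L) return(NULL)
  ch <- seq_chars(seq)
  g <- seq_chars(guide20)
  mm <- integer(nstart)
  for (k in 1:20) {
    mm <- mm + (ch[k:(k + nstart - 1L)] != g[k])
  }
  # windows containing non-ACGT bases (protospacer or PAM) are skipped
  bad <- cumsum(!(ch %in% DNA_BASES))
  wlen <- 19L + pamlen
  nbad <- bad[seq_len(nstart) + wlen] - c(0L, bad)[seq_len(nstart)]
  s <- which(mm <= max_mm & nbad == 0L)
  if (!length(s)) return(NULL)
  pams <- substring(seq, s + 20L, s + 19L + pamlen)
  direct <- pam_matches(pam_spec, pams)
  in_table <- pams %in% names(table$pam)
  # 4-mismatch loci must match the PAM pattern directly to be reported
  keep <- (direct | in_table) & !(mm[s] == 4L & !direct)
  s <- s[keep]
  if (!length(s)) return(NULL)
  data.frame(s = s, pam = pams[keep], mm = mm[s],
             window = substring(seq, s, s + 19L), stringsAsFactors = FALSE)
}

#' Scan a genome for off-target loci of a guide
#'
#' Finds every locus on both strands of every genome record whose 20-mer is
#' within `max_mm` Hamming mismatches of the guide and whose adjacent PAM
#' either matches the PAM pattern or appears in the PAM-variant penalty
#' table. Loci with exactly 4 mismatches whose PAM does not directly match
#' the pattern are dropped (they are highly unlikely to be active). Perfect
#' matches — including the on-target site — are reported so the target locus
#' can be verified. Mismatches are counted over the 20-mer only; PAM
#' positions never contribute to the mismatch count. Indels are not
#' considered.
#'
#' @param guide a 20-mer string or a row of [find_guides()] output.
#' @param genome named character vector of chromosome sequences
#'   (see [read_fasta()]).
#' @param pam a `pam_spec` or pattern string (default `"NGG"`).
#' @param table a `cfd_table` (default [toy_cfd_table()]).
#' @param max_mm maximum mismatches, at most 4 (default 4).
#' @return data frame with one row per hit: `sgRNA_sequence`, `chromosome`,
#'   `start`, `end` (1-based inclusive protospacer coordinates on the
#'   forward strand), `strand`, `mismatches`, `mismatch_positions`
#'   (comma-separated, 1--20 PAM-distal = 1), `CFD_score`,
#'   `matched_sequence` (20-mer + PAM in guide orientation).
#' @export
find_offtargets <- function(guide, genome, pam = compile_pam("NGG"),
                            table = toy_cfd_table(), max_mm = 4L) {
  if (is.list(guide) || is.data.frame(guide)) guide <- guide$protospacer[1L]
  stopifnot(nchar(guide) == 20L)
  if (max_mm > 4L) stop("max_mm is capped at 4 mismatches")
  if (length(genome) == 0L || all(!nzchar(genome))) stop("empty genome")
  if (is.null(names(genome))) stop("genome records must be named")
  pam <- as_pam_spec(pam)
  out <- list()
  for (chrom in names(genome)) {
    seq <- genome[[chrom]]
    Lc <- nchar(seq)
    fwd <- scan_strand(seq, guide, pam, table, max_mm)
    if (!is.null(fwd)) {
      fwd$chromosome <- chrom
      fwd$strand <- "+"
      fwd$start <- fwd$s
      fwd$end <- fwd$s + 19L
      out[[length(out) + 1L]] <- fwd
    }
    rev <- scan_strand(reverse_complement(seq), guide, pam, table, max_mm)
    if (!is.null(rev)) {
      rev$chromosome <- chrom
      rev$strand <- "-"
      rev$start <- Lc - rev$s - 18L
      rev$end <- Lc - rev$s + 1L
      out[[length(out) + 1L]] <- rev
    }
  }
  if (!length(out)) {
    return(data.frame(sgRNA_sequence = character(), chromosome = character(),
                      start = integer(), end = integer(), strand = character(),
                      mismatches = integer(), mismatch_positions = character(),
                      CFD_score = numeric(), matched_sequence = character(),
                      stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, out)
  g <- seq_chars(guide)
  hits$mismatch_positions <- vapply(hits$window, function(w) {
    paste(which(seq_chars(w) != g), collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  hits$CFD_score <- mapply(function(w, p) cfd_score(guide, w, p, table, pam),
                           hits$window, hits$pam, USE.NAMES = FALSE)
  hits$sgRNA_sequence <- guide
  hits$matched_sequence <- paste0(hits$window, hits$pam)
  hits$mismatches <- hits$mm
  hits <- hits[order(hits$chromosome, hits$start, hits$strand), ]
  rownames(hits) <- NULL
  hits[, c("sgRNA_sequence", "chromosome", "start", "end", "strand",
           "mismatches", "mismatch_positions", "CFD_score", "matched_sequence")]
}

#' Tally hits by mismatch count
#'
#' @param hits data frame of hits for one guide from [find_offtargets()].
#' @return named integer vector `MM0`..`MM4` (MM0 includes the on-target
#'   locus).
#' @export
summarize_mismatches <- function(hits) {
  counts <- integer(5)
  names(counts) <- paste0("MM", 0:4)
  if (!is.null(hits) && nrow(hits)) {
    t <- table(factor(hits$mismatches, levels = 0:4))
    counts[] <- as.integer(t)
  }
  counts
}
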