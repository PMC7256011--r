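# Candidate guide enumeration: every 20-mer immediately 5' of a PAM match on
# either strand, together with its 30-mer scoring context.

#' Compile a PAM pattern
#'
#' Validates an IUPAC PAM pattern (at most 6 bp) and precompiles the matching
#' machinery. An empty or missing pattern defaults to the canonical SpCas9
#' `"NGG"`.
#'
#' @param pattern IUPAC DNA string, length 1--6, or `""`/`NULL` for the
#'   default `"NGG"`.
#' @return an object of class `pam_spec` with elements `pattern`, `length`,
#'   `regex` and `canonical` (TRUE for the default NGG).
#' @export
compile_pam <- function(pattern = "") {
  if (is.null(pattern) || !nzchar(pattern)) pattern <- "NGG"
  pattern <- toupper(pattern)
  if (nchar(pattern) > 6L) {
    stop("PAM patterns are limited to 6 bp or fewer; got ", nchar(pattern),
         " bp ('", pattern, "')")
  }
  codes <- Biostrings::IUPAC_CODE_MAP
  chars <- seq_chars(pattern)
  bad <- setdiff(chars, names(codes))
  if (length(bad)) stop("invalid IUPAC code in PAM pattern: ", bad[1L])
  regex <- paste0(vapply(chars, function(ch) {
    opts <- codes[[ch]]
    if (nchar(opts) == 1L) opts else paste0("[", opts, "]")
  }, character(1)), collapse = "")
  structure(list(pattern = pattern, length = nchar(pattern), regex = regex,
                 canonical = identical(pattern, "NGG")),
            class = "pam_spec")
}

as_pam_spec <- function(pam) {
  if (inherits(pam, "pam_spec")) pam else compile_pam(pam)
}

# TRUE for each string fully matching the PAM pattern
pam_matches <- function(pam_spec, x) {
  grepl(paste0("^", pam_spec$regex, "$"), x)
}

# 1-based start positions of (possibly overlapping) PAM matches in seq
pam_positions <- function(pam_spec, seq) {
  m <- gregexpr(paste0("(?=", pam_spec$regex, ")"), seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

#' Enumerate candidate guides in a query sequence
#'
#' Finds every position on both strands of `query` where a PAM match is
#' immediately preceded by a 20-mer protospacer, and extracts the 30-mer
#' scoring context (4 nt 5' flank + protospacer + 6 nt 3' flank, in guide
#' orientation). Candidates whose 30-mer window runs off the end of the
#' query, or whose window contains a non-ACGT base, are dropped.
#'
#' @param query DNA string (uppercase; IUPAC codes tolerated but windows
#'   containing them are skipped).
#' @param pam a `pam_spec` from [compile_pam()], or a pattern string.
#' @return data frame with one row per candidate: `protospacer`, `pam`,
#'   `context30`, `start`, `end` (1-based inclusive protospacer coordinates on
#'   the forward strand), `direction` (`+`/`-`), ordered by `start` then
#'   direction (`+` first).
#' @export
find_guides <- function(query, pam = compile_pam("NGG")) {
  pam <- as_pam_spec(pam)
  query <- toupper(query)
  L <- nchar(query)
  if (L < 20L + pam$length) {
    stop("query (", L, " bp) is shorter than a protospacer plus PAM (",
         20L + pam$length, " bp)")
  }
  scan_one <- function(seq, dir) {
    pos <- pam_positions(pam, seq)           # PAM start positions
    s <- pos - 20L                           # protospacer start
    s <- s[s >= 5L & (s + 25L) <= nchar(seq) & (s + 19L + pam$length) <= nchar(seq)]
    if (!length(s)) return(NULL)
    ctx <- substring(seq, s - 4L, s + 25L)
    keep <- is_acgt(ctx)
    s <- s[keep]; ctx <- ctx[keep]
    if (!length(s)) return(NULL)
    data.frame(
      protospacer = substring(seq, s, s + 19L),
      pam = substring(seq, s + 20L, s + 19L + pam$length),
      context30 = ctx,
      s = s,
      direction = dir,
      stringsAsFactors = FALSE
    )
  }
  fwd <- scan_one(query, "+")
  rev <- scan_one(reverse_complement(query), "-")
  if (!is.null(fwd)) {
    fwd$start <- fwd$s
    fwd$end <- fwd$s + 19L
  }
  if (!is.null(rev)) {
    rev$start <- L - rev$s - 18L
    rev$end <- L - rev$s + 1L
  }
  out <- rbind(fwd, rev)
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(protospacer = character(), pam = character(),
                      context30 = character(), start = integer(),
                      end = integer(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  out$s <- NULL
  out <- out[order(out$start, out$direction != "+"), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("protospacer", "pam", "context30", "start", "end", "direction")]
}
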