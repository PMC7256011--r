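# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: guide enumeration by explicit per-window looping,
# off-target search via Biostrings::matchPattern, CFD products straight from
# the raw penalty TSVs.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# does `base` satisfy the IUPAC code `code`?
iupac_ok <- function(code, base) {
  grepl(base, Biostrings::IUPAC_CODE_MAP[[code]], fixed = TRUE)
}

oracle_pam_match <- function(pattern, pam) {
  pc <- strsplit(pattern, "")[[1]]
  bc <- strsplit(pam, "")[[1]]
  length(pc) == length(bc) &&
    all(mapply(iupac_ok, pc, bc)) && !grepl("[^ACGT]", pam)
}

# brute-force guide enumeration: test every 20+|PAM| window on both strands
oracle_find_guides <- function(query, pattern = "NGG") {
  L <- nchar(query)
  plen <- nchar(pattern)
  rows <- list()
  scan <- function(seq, dir) {
    for (s in seq_len(nchar(seq))) {
      if (s + 19 + plen > nchar(seq)) break
      pam <- substr(seq, s + 20, s + 19 + plen)
      if (!oracle_pam_match(pattern, pam)) next
      if (s - 4 < 1 || s + 25 > nchar(seq)) next
      ctx <- substr(seq, s - 4, s + 25)
      if (grepl("[^ACGT]", ctx)) next
      if (dir == "+") {
        start <- s; end <- s + 19
      } else {
        start <- L - s - 18; end <- L - s + 1
      }
      rows[[length(rows) + 1]] <<- data.frame(
        protospacer = substr(seq, s, s + 19), pam = pam, context30 = ctx,
        start = start, end = end, direction = dir, stringsAsFactors = FALSE)
    }
  }
  scan(query, "+")
  scan(oracle_revcomp(query), "-")
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$direction != "+"), ]
  rownames(out) <- NULL
  out
}

# off-target oracle built on Biostrings::matchPattern (the genome-scanning
# routine the CFD literature's reference tools use), plus the PAM rules
oracle_offtargets <- function(guide, genome, pattern = "NGG",
                              table = guidecraft::toy_cfd_table(),
                              max_mm = 4) {
  plen <- nchar(pattern)
  rows <- list()
  consider <- function(seq, st, chrom, Lc, strand) {
    if (st < 1 || st + 19 + plen > nchar(seq)) return()
    window <- substr(seq, st, st + 19)
    pam <- substr(seq, st + 20, st + 19 + plen)
    if (grepl("[^ACGT]", paste0(window, pam))) return()
    mm <- sum(strsplit(window, "")[[1]] != strsplit(guide, "")[[1]])
    if (mm > max_mm) return()
    direct <- oracle_pam_match(pattern, pam)
    if (!direct && !(pam %in% names(table$pam))) return()
    if (mm == 4 && !direct) return()
    if (strand == "+") {
      start <- st; end <- st + 19
    } else {
      start <- Lc - st - 18; end <- Lc - st + 1
    }
    rows[[length(rows) + 1]] <<- data.frame(
      chromosome = chrom, start = start, end = end, strand = strand,
      mismatches = mm, stringsAsFactors = FALSE)
  }
  for (chrom in names(genome)) {
    seq <- genome[[chrom]]
    Lc <- nchar(seq)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq else oracle_revcomp(seq)
      m <- Biostrings::matchPattern(guide, Biostrings::DNAString(s),
                                    max.mismatch = max_mm)
      for (st in BiocGenerics::start(m)) consider(s, st, chrom, Lc, strand)
    }
  }
  if (!length(rows)) {
    return(data.frame(chromosome = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$chromosome, out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

# raw-TSV CFD product, independent of the cfd_table lookup structure
raw_cfd_tables <- function() {
  list(
    mm = read.delim(system.file("extdata", "cfd_toy_mismatch.tsv",
                                package = "guidecraft")),
    pam = read.delim(system.file("extdata", "cfd_toy_pam.tsv",
                                 package = "guidecraft"))
  )
}

oracle_cfd <- function(guide, off, pam, raw) {
  g <- strsplit(guide, "")[[1]]
  o <- strsplit(off, "")[[1]]
  score <- 1
  for (p in which(g != o)) {
    row <- raw$mm[raw$mm$position == p & raw$mm$guide_base == g[p] &
                    raw$mm$offtarget_base == o[p], ]
    stopifnot(nrow(row) == 1)
    score <- score * row$penalty
  }
  prow <- raw$pam[raw$pam$pam == pam, ]
  stopifnot(nrow(prow) == 1)
  score * prow$penalty
}

# comparable subset of scanner output for oracle equivalence checks
hit_key <- function(hits) {
  if (nrow(hits) == 0) return(character(0))
  sort(sprintf("%s:%d-%d:%s:%d", hits$chromosome, hits$start, hits$end,
               hits$strand, hits$mismatches))
}
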