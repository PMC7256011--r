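test_that("CFD score is the product of looked-up penalties", {
  tbl <- toy_cfd_table()
  raw <- raw_cfd_tables()
  g <- "ACGTACGTACGTACGTACGT"
  expect_equal(cfd_score(g, g, "AGG", tbl), 1.0)

  # single mismatch: score equals that key's penalty alone
  off <- g
  substr(off, 7, 7) <- "C"
  want <- raw$mm$penalty[raw$mm$position == 7 & raw$mm$guide_base == "G" &
                           raw$mm$offtarget_base == "C"]
  expect_equal(cfd_score(g, off, "TGG", tbl), want)

  # two mismatches and a PAM variant: hand multiplication from the raw table
  off2 <- off
  substr(off2, 15, 15) <- "A"
  expect_equal(cfd_score(g, off2, "AAG", tbl), oracle_cfd(g, off2, "AAG", raw))

  expect_error(cfd_score(g, off, "NOPE", tbl), "PAM")
})

test_that("CFD is non-increasing as mismatches accumulate", {
  set.seed(19)
  tbl <- toy_cfd_table()
  for (rep in 1:10) {
    g <- random_dna(20)
    off <- g
    prev <- 1
    for (p in sample(1:20, 4)) {
      substr(off, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(g, p, p)), 1)
      cur <- cfd_score(g, off, "AGG", tbl)
      expect_lte(cur, prev)
      prev <- cur
    }
  }
})

test_that("a planted on-target site is recovered exactly", {
  fx <- generate_fixture(33, distances = 0)
  hits <- find_offtargets(fx$guide, fx$genome)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$mismatches, 0L)
  expect_equal(hits$CFD_score, 1.0)
  expect_equal(hits$start, fx$manifest$start)
  expect_equal(hits$end, fx$manifest$end)
  expect_equal(hits$strand, fx$manifest$strand)
})

test_that("4-mismatch loci with a non-matching PAM are excluded", {
  fx <- generate_fixture(34, distances = c(0, 1, 2, 3, 4, 4),
                         pams = c("TGG", "TGG", "TGG", "TGG", "TGG", "TAG"))
  hits <- find_offtargets(fx$guide, fx$genome)
  expect_equal(summarize_mismatches(hits),
               c(MM0 = 1L, MM1 = 1L, MM2 = 1L, MM3 = 1L, MM4 = 1L))
  # the 4-mismatch NAG-variant plant is absent even though TAG is penalized
  four <- hits[hits$mismatches == 4, ]
  expect_equal(four$start, fx$manifest$start[5])
  # but a 3-mismatch hit at a PAM variant IS reported, counting only the 20-mer
  fx2 <- generate_fixture(35, distances = c(0, 3), pams = c("TGG", "TAG"))
  hits2 <- find_offtargets(fx2$guide, fx2$genome)
  v <- hits2[hits2$start == fx2$manifest$start[2], ]
  expect_equal(v$mismatches, 3L)
})

test_that("mismatch tallies partition the hit list", {
  expect_equal(unname(summarize_mismatches(NULL)), rep(0L, 5))
  fx <- generate_fixture(36)
  hits <- find_offtargets(fx$guide, fx$genome)
  expect_equal(sum(summarize_mismatches(hits)), nrow(hits))
})

test_that("the scanner agrees with the matchPattern oracle on random fixtures", {
  for (seed in 1:4) {
    fx <- generate_fixture(seed + 400, genome_size = 5000)
    set.seed(seed)
    guides <- c(fx$guide, replicate(5, random_dna(20)))
    for (g in guides) {
      got <- find_offtargets(g, fx$genome)
      want <- oracle_offtargets(g, fx$genome)
      expect_identical(hit_key(got), hit_key(want))
    }
  }
})

test_that("reverse-complementing the genome flips strands and mirrors coordinates", {
  fx <- generate_fixture(61, genome_size = 4000)
  L <- nchar(fx$genome[["chr1"]])
  fwd <- find_offtargets(fx$guide, fx$genome)
  rcg <- stats::setNames(reverse_complement(fx$genome[["chr1"]]), "chr1")
  rev <- find_offtargets(fx$guide, rcg)
  expect_equal(
    sort(sprintf("%d-%d:%s:%d", fwd$start, fwd$end, fwd$strand, fwd$mismatches)),
    sort(sprintf("%d-%d:%s:%d", L - rev$end + 1, L - rev$start + 1,
                 ifelse(rev$strand == "+", "-", "+"), rev$mismatches)))
})

test_that("scanner input contracts are enforced", {
  fx <- generate_fixture(71)
  expect_error(find_offtargets(fx$guide, character(0)), "empty genome")
  expect_error(find_offtargets(fx$guide, fx$genome, max_mm = 5), "capped")
  expect_error(find_offtargets("ACGT", fx$genome))
})

test_that("penalty-table loading validates ranges and converts RNA bases", {
  mmf <- withr::local_tempfile(fileext = ".tsv")
  pamf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("position\tguide_base\tofftarget_base\tpenalty", "3\tU\tG\t0.5"), mmf)
  writeLines(c("pam\tpenalty", "AGG\t1.0"), pamf)
  tbl <- load_cfd_tables(mmf, pamf)
  expect_equal(unname(tbl$mm["3_T_G"]), 0.5)
  writeLines(c("position\tguide_base\tofftarget_base\tpenalty", "3\tA\tG\t1.5"), mmf)
  expect_error(load_cfd_tables(mmf, pamf), "\\[0, 1\\]")
  # missing key in a sparse table is reported by name
  writeLines(c("position\tguide_base\tofftarget_base\tpenalty", "3\tA\tG\t0.5"), mmf)
  tbl <- load_cfd_tables(mmf, pamf)
  g <- strrep("A", 20)
  off <- paste0(strrep("A", 9), "C", strrep("A", 10))
  expect_error(cfd_score(g, off, "AGG", tbl), "10_A_C")
})
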