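test_that("uniform sequences force every feature group", {
  v <- featurize(strrep("A", 30))
  expect_length(v, 627L)
  expect_equal(unname(v[c("pos01_A", "pos01_C", "pos01_G", "pos01_T")]),
               c(1, 0, 0, 0))
  expect_equal(unname(v["count_A"]), 30)
  expect_equal(unname(v["dicount_AA"]), 29)
  expect_equal(unname(v["gc_count"]), 0)
  expect_equal(unname(v["gc_below_10"]), 1)
  expect_equal(unname(v["gc_above_10"]), 0)
  expect_equal(unname(v["bookend_AA"]), 1)

  v <- featurize(strrep("T", 30))
  di <- v[startsWith(names(v), "dicount_")]
  expect_equal(unname(di["dicount_TT"]), 29)
  expect_equal(sum(di), 29)
})

test_that("feature layout arithmetic holds for random 30-mers", {
  set.seed(9)
  reg <- feature_registry()
  expect_length(reg, 627L)
  for (rep in 1:20) {
    v <- featurize(random_dna(30))
    expect_identical(names(v), reg)
    for (k in 1:30) {
      expect_equal(sum(v[sprintf("pos%02d_%s", k, c("A", "C", "G", "T"))]), 1)
    }
    expect_equal(sum(v[paste0("count_", c("A", "C", "G", "T"))]), 30)
    expect_equal(sum(v[startsWith(reg, "dicount_")]), 29)
    expect_equal(sum(v[startsWith(reg, "bookend_")]), 1)
    gc <- v[["gc_count"]]
    expect_false(v[["gc_above_10"]] == 1 && v[["gc_below_10"]] == 1)
    expect_equal(v[["gc_above_10"]] == 0 && v[["gc_below_10"]] == 0, gc == 10)
  }
  expect_error(featurize("ACGT"), "30 bp")
  expect_error(featurize(paste0(strrep("A", 29), "N")), "A/C/G/T")
})

test_that("featurize is pure and batch rows equal single calls", {
  set.seed(14)
  ctx <- vapply(1:5, function(i) random_dna(30), character(1))
  M <- featurize(ctx)
  expect_equal(dim(M), c(5L, 627L))
  for (i in 1:5) expect_equal(M[i, ], featurize(ctx[i]))
  expect_identical(featurize(ctx[1]), featurize(ctx[1]))
})

test_that("melting temperatures match an independent nearest-neighbor oracle", {
  # frozen values from an independently coded Allawi & SantaLucia NN sum
  # (50 nM strands, C/4 duplex term, 16.6*log10([Na+]) salt correction)
  oracle <- c(GCGTATGC = 4.922669, AAAAAAAAAA = -2.771175,
              GGGGGGGGGG = 30.347920, ATGCATGCATGCATGCATGC = 48.763812,
              ACGTACGTACGTACGTACGTACGTACGGTA = 55.630275)
  for (s in names(oracle)) {
    expect_equal(melting_temperature(s), unname(oracle[s]), tolerance = 1e-5)
  }
  expect_gt(melting_temperature(strrep("G", 10)),
            melting_temperature(strrep("A", 10)))
  expect_error(melting_temperature("A"), "2 bases")
  expect_error(melting_temperature("ACGN"), "A/C/G/T")
})

test_that("Tm is symmetric under reverse complement (duplex symmetry)", {
  set.seed(31)
  for (rep in 1:10) {
    s <- random_dna(sample(5:30, 1))
    expect_equal(melting_temperature(s), melting_temperature(oracle_revcomp(s)),
                 tolerance = 1e-12)
  }
})

test_that("Tm features slice positions 20-24, 12-19 and 7-11 exactly", {
  set.seed(6)
  ctx <- random_dna(30)
  tm <- tm_features(ctx)
  expect_equal(unname(tm[1, "tm_30mer"]), melting_temperature(ctx))
  expect_equal(unname(tm[1, "tm_5mer_prox"]),
               melting_temperature(substr(ctx, 20, 24)))
  expect_equal(unname(tm[1, "tm_8mer"]),
               melting_temperature(substr(ctx, 12, 19)))
  expect_equal(unname(tm[1, "tm_5mer_distal"]),
               melting_temperature(substr(ctx, 7, 11)))
  # identical substrings give identical Tm
  u <- tm_features(strrep("G", 30))
  expect_equal(u[1, "tm_5mer_prox"], u[1, "tm_5mer_distal"])
})
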