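test_that("zero-variance pruning matches a direct variance scan", {
  set.seed(4)
  ctx <- vapply(1:40, function(i) {
    paste0(random_dna(21), "TGG", random_dna(6))  # NGG-like fixed GG
  }, character(1))
  ctx <- vapply(ctx, function(x) {
    paste0(substr(x, 1, 25), "GG", substr(x, 28, 30))
  }, character(1), USE.NAMES = FALSE)
  M <- featurize(ctx)
  pr <- prune_features(M)
  want <- colnames(M)[apply(M, 2, function(col) stats::var(col) > 0)]
  expect_identical(pr$retained, want)
  # positions 26-27 are forced to G by the PAM: their one-hots must be gone
  expect_false(any(c("pos26_G", "pos27_G", "pos26_A") %in% pr$retained))
  expect_true("pos01_A" %in% pr$retained ||
                any(startsWith(pr$retained, "pos01_")))
  M2 <- M[rep(1, 5), ]
  expect_error(prune_features(M2), "no informative features")
  expect_error(prune_features(M[1, , drop = FALSE]), "2 rows")
})

test_that("a separable two-context set is fit to its labels", {
  set.seed(2)
  a <- random_dna(30); b <- random_dna(30)
  data <- data.frame(context30 = rep(c(a, b), each = 100),
                     score = rep(c(0.1, 0.9), each = 100))
  fit <- train_efficiency_model(data, seed = 5)
  expect_lt(abs(predict_efficiency(fit, a) - 0.1), 0.05)
  expect_lt(abs(predict_efficiency(fit, b) - 0.9), 0.05)
})

test_that("training validates scores and is deterministic", {
  bad <- data.frame(context30 = replicate(60, random_dna(30)), score = 1.5)
  expect_error(train_efficiency_model(bad), "\\[0, 1\\]")
  d <- synthetic_training_set(120, seed = 3)
  expect_warning(train_efficiency_model(d[1:40, ], seed = 1,
                                        params = list(nrounds = 5)), "50")
  f1 <- train_efficiency_model(d, seed = 9, params = list(nrounds = 40))
  f2 <- train_efficiency_model(d, seed = 9, params = list(nrounds = 40))
  probe <- replicate(20, random_dna(30))
  expect_identical(predict_efficiency(f1, probe), predict_efficiency(f2, probe))
})

test_that("predictions are clamped to [0, 1] and batch equals single", {
  d <- synthetic_training_set(150, seed = 7)
  fit <- train_efficiency_model(d, seed = 7, params = list(nrounds = 40))
  probe <- replicate(25, random_dna(30))
  p <- predict_efficiency(fit, probe)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(p, vapply(probe, function(x) predict_efficiency(fit, x),
                         numeric(1), USE.NAMES = FALSE))
  expect_error(predict_efficiency(list(), probe), "not a trained")
})

test_that("training is invariant to row order up to numerical noise", {
  d <- synthetic_training_set(200, seed = 13)
  f1 <- train_efficiency_model(d, seed = 4, params = list(nrounds = 60))
  set.seed(99)
  f2 <- train_efficiency_model(d[sample(nrow(d)), ], seed = 4,
                               params = list(nrounds = 60))
  probe <- replicate(30, random_dna(30))
  expect_equal(predict_efficiency(f1, probe), predict_efficiency(f2, probe),
               tolerance = 1e-6)
})

test_that("importance mass concentrates on the generative features", {
  d <- synthetic_training_set(800, seed = 17)
  fit <- train_efficiency_model(d, seed = 17, params = list(nrounds = 150))
  top5 <- feature_importance(fit)$feature[1:5]
  gc_related <- c("gc_count", "gc_above_10", "gc_below_10")
  expect_true(any(top5 %in% gc_related))
  expect_true(any(grepl("(pos24_|dipos23_|dipos24_)", top5)))
})

test_that("save/load round-trips predictions and guards the registry", {
  d <- synthetic_training_set(150, seed = 23)
  fit <- train_efficiency_model(d, seed = 23, params = list(nrounds = 40))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fit, path)
  back <- load_model(path)
  probe <- replicate(100, random_dna(30))
  expect_equal(predict_efficiency(back, probe), predict_efficiency(fit, probe))

  # truncated file
  raw <- readBin(path, "raw", file.size(path))
  writeBin(raw[1:50], path)
  expect_error(load_model(path), "cannot read|not a serialized")

  # registry drift
  bundle <- fit
  bundle$booster <- xgboost::xgb.save.raw(fit$booster)
  bundle$registry <- c(bundle$registry[-1], "made_up_feature")
  saveRDS(bundle, path)
  expect_error(load_model(path), "registry mismatch")
})

test_that("the demo model is cached, labeled synthetic and usable", {
  m1 <- demo_model()
  m2 <- demo_model()
  expect_identical(m1, m2)
  p <- predict_efficiency(m1, replicate(5, random_dna(30)))
  expect_true(all(p >= 0 & p <= 1))
})
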