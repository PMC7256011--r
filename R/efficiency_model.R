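# Trainable gradient-boosted regression model mapping Rule Set 2 feature
# vectors to activity scores in [0, 1].

#' Remove zero-variance feature columns
#'
#' Position-dependent features can carry no variation at all (e.g. a
#' restrictive PAM forces the same base at the PAM-slot positions of every
#' training 30-mer); such columns are removed before training and the
#' retained names recorded so prediction-time matrices can be aligned.
#'
#' @param mat numeric feature matrix (rows = sequences, named columns).
#' @return list with `matrix` (reduced) and `retained` (column names kept).
#' @export
prune_features <- function(mat) {
  if (is.null(dim(mat)) || nrow(mat) < 2L) stop("need at least 2 rows to prune features")
  keep <- apply(mat, 2L, function(col) any(col != col[1L]))
  if (!any(keep)) stop("no informative features: every column has zero variance")
  list(matrix = mat[, keep, drop = FALSE], retained = colnames(mat)[keep])
}

default_hyperparameters <- function() {
  list(nrounds = 300L, max_depth = 3L, eta = 0.08, min_child_weight = 2,
       subsample = 1, colsample_bytree = 1)
}

#' Train the guide efficiency model
#'
#' Fits gradient-boosted regression trees (xgboost, squared-error objective)
#' on 30-mer contexts with activity scores normalized to \[0, 1\]
#' (rank-normalized read-count data in the original training scheme).
#' Zero-variance features are pruned before fitting; the retained feature
#' list and the full feature registry are stored for prediction-time
#' alignment and serialization checks. Training is deterministic for a fixed
#' seed (single-threaded, exact tree construction).
#'
#' @param data data frame with columns `context30` (30-mer strings) and
#'   `score` (numeric in \[0, 1\]).
#' @param params hyperparameter list (see `default_hyperparameters`
#'   internals): `nrounds`, `max_depth`, `eta`, `min_child_weight`,
#'   `subsample`, `colsample_bytree`. Partial lists override defaults.
#' @param seed integer seed.
#' @return object of class `efficiency_model` with the fitted booster,
#'   retained feature names, hyperparameters, and in-sample Spearman rank
#'   correlation (`train_cor`).
#' @export
train_efficiency_model <- function(data, params = list(), seed = 1L) {
  stopifnot(is.data.frame(data), all(c("context30", "score") %in% names(data)))
  if (any(data$score < 0 | data$score > 1 | is.na(data$score))) {
    stop("activity scores must lie within [0, 1]")
  }
  check_context30(data$context30)
  if (nrow(data) < 50L) {
    warning("fewer than 50 training rows; the fitted model is unlikely to be meaningful")
  }
  hp <- utils::modifyList(default_hyperparameters(), params)
  X <- featurize(data$context30)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L, dimnames = list(NULL, names(X)))
  pruned <- prune_features(X)
  set.seed(seed)
  booster <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", max_depth = hp$max_depth,
                  eta = hp$eta, min_child_weight = hp$min_child_weight,
                  subsample = hp$subsample, colsample_bytree = hp$colsample_bytree,
                  tree_method = "exact", nthread = 1L, seed = seed),
    data = xgboost::xgb.DMatrix(pruned$matrix, label = data$score, nthread = 1L),
    nrounds = hp$nrounds, verbose = 0
  )
  fit <- structure(list(booster = booster, retained = pruned$retained,
                        registry = feature_registry(), params = hp,
                        seed = as.integer(seed)),
                   class = "efficiency_model")
  fit$train_cor <- stats::cor(predict_efficiency(fit, data$context30),
                              data$score, method = "spearman")
  fit
}

#' Predict guide efficiency
#'
#' Scores 30-mer contexts with a trained model; the raw ensemble output is
#' clamped to \[0, 1\], with 0 indicating less and 1 greater expected
#' activity.
#'
#' @param model an `efficiency_model`.
#' @param ctx character vector of 30-mers.
#' @return numeric vector of scores in \[0, 1\].
#' @export
predict_efficiency <- function(model, ctx) {
  if (!inherits(model, "efficiency_model") || is.null(model$booster)) {
    stop("model is not a trained efficiency model")
  }
  X <- featurize(ctx)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L, dimnames = list(NULL, names(X)))
  X <- X[, model$retained, drop = FALSE]
  p <- stats::predict(model$booster, xgboost::xgb.DMatrix(X, nthread = 1L))
  pmin(1, pmax(0, p))
}

#' Feature importances of a trained model
#'
#' @param model an `efficiency_model`.
#' @return data frame with columns `feature` and `gain`, sorted decreasing.
#' @export
feature_importance <- function(model) {
  imp <- xgboost::xgb.importance(model = model$booster)
  data.frame(feature = imp$Feature, gain = imp$Gain, stringsAsFactors = FALSE)
}

#' Save / load an efficiency model
#'
#' The serialized bundle embeds the feature registry in force at training
#' time; loading into a package version whose registry differs is an error.
#'
#' @param model an `efficiency_model`.
#' @param path file path.
#' @return `save_model` returns the path invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "efficiency_model"))
  bundle <- model
  bundle$booster <- xgboost::xgb.save.raw(model$booster)
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  bundle <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read model file ", path, ": ", conditionMessage(e))
  })
  if (!is.list(bundle) || is.null(bundle$booster) || is.null(bundle$registry)) {
    stop("file ", path, " is not a serialized efficiency model")
  }
  current <- feature_registry()
  if (!identical(bundle$registry, current)) {
    stop(sprintf(paste0("feature registry mismatch: model was trained with %d",
                        " features, this package defines %d (first difference: '%s')"),
         length(bundle$registry), length(current),
         c(setdiff(bundle$registry, current), setdiff(current, bundle$registry), "?")[1L]))
  }
  bundle$booster <- xgboost::xgb.load.raw(bundle$booster)
  class(bundle) <- "efficiency_model"
  bundle
}

#' Generate a synthetic efficiency training set
#'
#' Random 30-mers whose latent activity is a known function of protospacer GC
#' count and the base at protospacer position 20 (position 24 of the 30-mer):
#' `clamp01(gc_count/20 + 0.2 * [base24 == G]) + Gaussian noise`, re-clamped
#' to \[0, 1\]. Used for signal-recovery validation and the bundled demo
#' model; it emulates rank-normalized activity data, not any real screen.
#'
#' @param n number of rows.
#' @param noise_sd Gaussian noise standard deviation (default 0.05).
#' @param seed integer seed.
#' @return data frame with `context30` and `score`.
#' @export
synthetic_training_set <- function(n, noise_sd = 0.05, seed = 1L) {
  set.seed(seed)
  ctx <- vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, 30, replace = TRUE), collapse = "")
  }, character(1))
  ch <- matrix(unlist(strsplit(ctx, "")), ncol = 30, byrow = TRUE)
  gc <- rowSums(ch[, 5:24] == "G" | ch[, 5:24] == "C")
  latent <- pmin(1, pmax(0, gc / 20 + 0.2 * (ch[, 24] == "G")))
  score <- pmin(1, pmax(0, latent + stats::rnorm(n, 0, noise_sd)))
  data.frame(context30 = ctx, score = score, stringsAsFactors = FALSE)
}

demo_model_cache <- new.env(parent = emptyenv())

#' Bundled demo efficiency model (synthetic)
#'
#' A small model trained on [synthetic_training_set()] data, built on first
#' use and cached for the session. It demonstrates the scoring pipeline and
#' keeps the package self-contained; its scores reflect the synthetic
#' generative model only and must not be read as experimentally calibrated
#' efficiencies. Train on real 30-mer/activity tables with
#' [train_efficiency_model()] for production use.
#'
#' @param seed integer seed for the synthetic data and fit.
#' @return an `efficiency_model`.
#' @export
demo_model <- function(seed = 20L) {
  key <- paste0("m", seed)
  if (is.null(demo_model_cache[[key]])) {
    demo_model_cache[[key]] <- train_efficiency_model(
      synthetic_training_set(600L, seed = seed),
      params = list(nrounds = 120L), seed = seed)
  }
  demo_model_cache[[key]]
}
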