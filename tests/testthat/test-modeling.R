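test_that("evaluation metrics follow the confusion-matrix formulas", {
  truth <- c(rep(1, 5), rep(0, 5))
  expect_identical(evaluate_predictions(truth, truth)$acc, 1)
  # TP=3, TN=4, FP=1, FN=2 -> Acc 0.7, SE 0.6, SP 0.8
  pred <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1)
  ev <- evaluate_predictions(pred, truth)
  expect_identical(ev$acc, 0.7)
  expect_identical(ev$se, 0.6)
  expect_identical(ev$sp, 0.8)
  expect_true(is.na(ev$auc))
  # constant scores -> AUC 0.5 (all ties)
  ev2 <- evaluate_predictions(pred, truth, scores = rep(0.3, 10))
  expect_identical(ev2$auc, 0.5)
  expect_error(evaluate_predictions(pred, rep(1, 10)), "both classes")
})

test_that("AUC is the pair-ranking probability and is monotone-invariant", {
  set.seed(3)
  labels <- rbinom(60, 1, 0.4)
  labels[1] <- 1; labels[2] <- 0
  scores <- rnorm(60) + labels
  base <- auc_score(scores, labels)
  # brute-force pair counting oracle
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  expect_equal(base, mean(pairs), tolerance = 1e-12)
  # strictly monotone transforms leave AUC unchanged
  expect_equal(auc_score(exp(scores), labels), base, tolerance = 1e-12)
  expect_equal(auc_score(rank(scores), labels), base, tolerance = 1e-12)
  if (requireNamespace("pROC", quietly = TRUE)) {
    expect_equal(base,
                 as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                quiet = TRUE))),
                 tolerance = 1e-9)
  }
})

test_that("majority vote matches brute-force counting for 2-5 members", {
  for (m in 2:5) {
    patterns <- as.matrix(expand.grid(rep(list(0:1), m)))
    # lay all 2^m vote patterns out over compounds (chunks of <= 8)
    for (start in seq(1, nrow(patterns), by = 8)) {
      idx <- seq(start, min(start + 7, nrow(patterns)))
      members <- lapply(seq_len(m), function(j) patterns[idx, j])
      expect_identical(majority_vote(members), vote_oracle(members))
    }
  }
  expect_identical(majority_vote(list(c(1, 0), c(0, 0))), c(1L, 0L))  # tie -> 1
  expect_error(majority_vote(list(c(1, 0))), "at least two")
  expect_error(majority_vote(list(c(1, 0), c(1, 0, 1))), "length")
})

test_that("stratified shuffle splits preserve class ratio and reproduce exactly", {
  y <- c(rep(1, 30), rep(0, 70))
  splits <- stratified_shuffle_splits(y, n_splits = 10, val_fraction = 0.1,
                                      seed = 123)
  expect_identical(length(splits), 10L)
  for (s in splits) {
    expect_identical(length(s), 10L)
    expect_identical(sum(y[s] == 1), 3L)
  }
  splits2 <- stratified_shuffle_splits(y, 10, 0.1, seed = 123)
  expect_identical(splits, splits2)
  expect_false(identical(splits,
                         stratified_shuffle_splits(y, 10, 0.1, seed = 124)))
  expect_error(stratified_shuffle_splits(c(1, 0, 0), 2, 0.5, seed = 1),
               "infeasible")
})

test_that("all three learners recover a label-equal feature in cross-validation", {
  set.seed(21)
  n <- 300
  labels <- rbinom(n, 1, 0.5)
  X <- cbind(signal = labels,
             matrix(rnorm(n * 20), n, 20,
                    dimnames = list(NULL, sprintf("noise%02d", 1:20))))
  for (model in c("rf", "svm", "xgb")) {
    cfg <- pipeline_config(model, outer_folds = 4, seed = 21,
                           params = list(num_trees = 100, nrounds = 40))
    rep <- stratified_cv(X, labels, cfg)
    expect_gte(rep$means[["auc"]], 0.95)
    expect_true(all(rep$folds$acc >= 0 & rep$folds$acc <= 1))
  }
})

test_that("cross-validation is reproducible and balancing runs inside folds", {
  ds <- planted_feature_data(n = 200, seed = 55)
  X <- unclass(ds$features)
  cfg <- pipeline_config("rf", balancing = list(method = "smote"),
                         outer_folds = 3, seed = 31,
                         params = list(num_trees = 100))
  r1 <- stratified_cv(X, ds$labels, cfg)
  r2 <- stratified_cv(X, ds$labels, cfg)
  expect_identical(r1$folds, r2$folds)
  expect_identical(r1$splits, r2$splits)
  # the fold's SMOTE input is the training portion only: synthetic rows are
  # convex combinations of training-minority rows, never validation rows
  val_idx <- r1$splits[[1]]
  Xtr <- X[-val_idx, , drop = FALSE]; ytr <- ds$labels[-val_idx]
  bal <- mnqsar:::apply_balancing(Xtr, ytr, list(method = "smote"),
                                  seed = cfg$seed + 1)
  synth <- bal$X[seq(nrow(Xtr) + 1, nrow(bal$X)), , drop = FALSE]
  tr_min <- Xtr[ytr == mnqsar:::minority_class(ytr), , drop = FALSE]
  for (r in seq_len(min(5, nrow(synth)))) {
    p <- synth[r, ]
    dists <- apply(tr_min, 1, function(a) sqrt(sum((a - p)^2)))
    # each synthetic point interpolates two minority rows, so it is within
    # the minority set's diameter of its nearest original
    expect_lt(min(dists), max(dist(tr_min)))
  }
})

test_that("grid search picks the stronger setting and honors tie order", {
  ds <- planted_feature_data(n = 200, seed = 66)
  X <- unclass(ds$features)
  cfg <- pipeline_config("rf", grid = list(num_trees = c(1, 100)),
                         inner_folds = 3, seed = 12)
  gs <- grid_search_fit(cfg, X, ds$labels, seed = 12)
  expect_identical(gs$best_params$num_trees, 100)
  # singleton grid -> that combination
  cfg1 <- pipeline_config("rf", grid = list(num_trees = 50),
                          inner_folds = 3, seed = 12)
  expect_identical(grid_search_fit(cfg1, X, ds$labels)$best_params$num_trees,
                   50)
  # same seed -> same choice
  gs2 <- grid_search_fit(cfg, X, ds$labels, seed = 12)
  expect_identical(gs$best_params, gs2$best_params)
  expect_error(grid_search_fit(pipeline_config("rf"), X, ds$labels), "grid")
})

test_that("Butina split keeps structural families on one side", {
  # duplicates cluster together and never straddle the split
  fam <- matrix(0L, 10, 8)
  fam[1:8, 1:4] <- 1L   # family A: 8 identical fingerprints
  fam[9:10, 5:8] <- 1L  # family B: 2 identical, disjoint from A
  fm <- feature_matrix(fam, kind = "ecfp",
                       compound_ids = sprintf("m%02d", 1:10))
  out <- butina_split(fm, val_fraction = 0.2, distance_cutoff = 0.4)
  expect_setequal(out$val_ids, c("m09", "m10"))
  expect_identical(out$clusters[1:8], rep(1L, 8))
  expect_identical(out$clusters[9:10], rep(2L, 10 - 8))
  # cutoff 0: only identical structures merge
  three <- feature_matrix(rbind(c(1, 0), c(1, 0), c(0, 1)), kind = "ecfp")
  out0 <- butina_split(three, val_fraction = 0.34, distance_cutoff = 0)
  expect_identical(max(out0$clusters), 2L)
  # everything in one cluster is an error
  one <- feature_matrix(matrix(rep(c(1, 0), 5), 5, 2, byrow = TRUE),
                        kind = "ecfp")
  expect_error(butina_split(one, distance_cutoff = 1), "single cluster")
})

test_that("Butina split works from structures end to end", {
  smis <- c(rep("c1ccccc1O", 3), rep("CCCCCCCC", 3), rep("ClC(Cl)(Cl)Cl", 2))
  out <- butina_split(smis, val_fraction = 0.25, distance_cutoff = 0.4)
  cl <- out$clusters
  expect_identical(cl[1], cl[2])
  expect_identical(cl[4], cl[5])
  expect_false(cl[1] == cl[4])
  expect_identical(length(out$val_ids), 2L)
})

test_that("ensemble training and prediction combine members by vote", {
  ds <- planted_feature_data(n = 200, seed = 91)
  X <- unclass(ds$features)
  members <- list(
    list(block = "feat", model = "rf", params = list(num_trees = 100),
         balancing = list(method = "smote")),
    list(block = "feat", model = "xgb", params = list(nrounds = 40)),
    list(block = "feat", model = "svm",
         balancing = list(method = "class_weight")))
  ens <- train_ensemble(list(feat = X), ds$labels, members, seed = 4)
  expect_s3_class(ens, "mn_ensemble")
  pred <- predict(ens, list(feat = X))
  expect_true(all(pred %in% c(0L, 1L)))
  expect_gte(balanced_accuracy(pred, ds$labels), 0.8)
  expect_error(train_ensemble(list(feat = X), ds$labels, members[1]),
               "at least two")
})
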