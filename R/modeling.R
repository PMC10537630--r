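# Model training and evaluation: RF / SVM / XGB wrappers, stratified
# shuffle-split cross-validation with in-fold balancing, inner grid search,
# Butina cluster splits, and majority-vote ensembling.

#' Fit a base classifier
#'
#' Uniform wrapper over the three supported learners:
#' * `"rf"` — random forest (`ranger`), params `num_trees` (default 300),
#'   `max_depth` (0 = unlimited);
#' * `"svm"` — RBF-kernel SVM (`e1071`), params `cost` (default 1), `gamma`
#'   (numeric, or `"scale"` for 1 / (p * var(X)));
#' * `"xgb"` — gradient boosting (`xgboost`), params `nrounds` (default
#'   100), `max_depth` (default 6), `eta` (default 0.3).
#'
#' Class weights (from [class_weights()]) are applied as per-sample weights
#' (`rf`, `xgb`) or class weights (`svm`).
#'
#' @param model `"rf"`, `"svm"` or `"xgb"`.
#' @param X numeric matrix of features.
#' @param y 0/1 labels.
#' @param params named list of hyperparameters (see above).
#' @param weights optional named class-weight vector `c("0"=, "1"=)`.
#' @param seed integer seed controlling learner randomness.
#' @return Object of class `mnqsar_model`; [predict.mnqsar_model()] returns
#'   positive-class probability scores.
#' @export
fit_classifier <- function(model = c("rf", "svm", "xgb"), X, y,
                           params = list(), weights = NULL, seed = 1) {
  model <- match.arg(model)
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X and y differ in length")
  if (length(unique(y)) < 2) stop("training needs both classes present")
  w <- if (is.null(weights)) NULL else unname(weights[as.character(y)])

  fit <- switch(model,
    rf = {
      num_trees <- params$num_trees %||% 300
      max_depth <- params$max_depth %||% 0
      ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                     num.trees = num_trees, max.depth = max_depth,
                     probability = TRUE, seed = seed,
                     case.weights = w, num.threads = 1)
    },
    svm = {
      cost <- params$cost %||% 1
      gamma <- params$gamma %||% "scale"
      if (identical(gamma, "scale"))
        gamma <- 1 / (ncol(X) * max(stats::var(as.vector(X)), 1e-12))
      cw <- if (is.null(weights)) NULL else weights
      set.seed(seed)
      e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                 kernel = "radial", cost = cost, gamma = gamma,
                 class.weights = cw, probability = TRUE, scale = FALSE)
    },
    xgb = {
      nrounds <- params$nrounds %||% 100
      max_depth <- params$max_depth %||% 6
      eta <- params$eta %||% 0.3
      dtrain <- xgboost::xgb.DMatrix(X, label = y,
                                     weight = if (is.null(w)) rep(1, length(y)) else w)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = max_depth,
                      eta = eta, nthread = 1, seed = seed),
        data = dtrain, nrounds = nrounds, verbose = 0)
    })
  structure(list(model = model, fit = fit, params = params,
                 feature_names = colnames(X), seed = seed),
            class = "mnqsar_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict positive-class scores
#'
#' @param object an `mnqsar_model` from [fit_classifier()].
#' @param newdata numeric matrix with the training feature columns.
#' @param ... unused.
#' @return Numeric vector of positive-class probabilities.
#' @export
predict.mnqsar_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(newdata)))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  switch(object$model,
    rf = predict(object$fit, newdata, num.threads = 1)$predictions[, "1"],
    svm = {
      pr <- predict(object$fit, newdata, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    xgb = predict(object$fit, xgboost::xgb.DMatrix(newdata)))
}

#' Pipeline configuration
#'
#' Bundles the choices defining one modeling pipeline: learner, balancing,
#' hyperparameter grid and cross-validation layout.
#'
#' @param model `"rf"`, `"svm"` or `"xgb"`.
#' @param balancing list: `method` (`"none"`, `"class_weight"` or
#'   `"smote"`), and for SMOTE `k` (default 5) and `target_ratio`
#'   (default 1).
#' @param grid named list of hyperparameter value vectors for
#'   [grid_search_fit()]; `NULL` skips the search and uses `params`.
#' @param params fixed hyperparameters used when `grid` is `NULL`.
#' @param outer_folds number of outer shuffle splits (default 10).
#' @param val_fraction validation fraction per split (default 0.1).
#' @param inner_folds folds of the inner grid-search CV (default 10).
#' @param seed integer seed (default 1).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(model = c("rf", "svm", "xgb"),
                            balancing = list(method = "none"),
                            grid = NULL, params = list(),
                            outer_folds = 10, val_fraction = 0.1,
                            inner_folds = 10, seed = 1) {
  model <- match.arg(model)
  stopifnot(val_fraction > 0, val_fraction < 1, outer_folds >= 2,
            inner_folds >= 2)
  balancing$method <- match.arg(balancing$method %||% "none",
                                c("none", "class_weight", "smote"))
  structure(list(model = model, balancing = balancing, grid = grid,
                 params = params, outer_folds = outer_folds,
                 val_fraction = val_fraction, inner_folds = inner_folds,
                 seed = seed),
            class = "pipeline_config")
}

#' Default hyperparameter grids
#'
#' @param model `"rf"`, `"svm"` or `"xgb"`.
#' @return Named list of value vectors.
#' @export
default_grid <- function(model = c("rf", "svm", "xgb")) {
  switch(match.arg(model),
    rf = list(num_trees = c(100, 300, 500), max_depth = c(0, 10, 20)),
    svm = list(cost = c(0.1, 1, 10), gamma = list("scale", 0.01)),
    xgb = list(nrounds = c(100, 300), max_depth = c(3, 6),
               eta = c(0.1, 0.3)))
}

#' Stratified shuffle splits
#'
#' Generates `n_splits` independent random 90/10-style splits preserving the
#' class ratio: per class, `round(val_fraction * n_class)` compounds (at
#' least 1) go to validation. Reproducible for a fixed seed.
#'
#' @param y 0/1 labels.
#' @param n_splits number of splits.
#' @param val_fraction validation fraction.
#' @param seed integer seed.
#' @return List of integer vectors (validation indices per split).
#' @export
stratified_shuffle_splits <- function(y, n_splits = 10, val_fraction = 0.1,
                                      seed = 1) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  classes <- sort(unique(y))
  lapply(seq_len(n_splits), function(s) {
    val <- integer(0)
    for (cl in classes) {
      idx <- which(y == cl)
      n_val <- max(1L, round(val_fraction * length(idx)))
      if (n_val >= length(idx))
        stop("stratification infeasible: class ", cl, " too small")
      val <- c(val, sample(idx, n_val))
    }
    sort(val)
  })
}

# Balance a training portion according to a balancing config; returns
# possibly augmented data plus class weights (NULL unless class_weight).
apply_balancing <- function(X, y, balancing, seed) {
  method <- balancing$method %||% "none"
  if (method == "class_weight")
    return(list(X = X, y = y, weights = class_weights(y)))
  if (method == "smote") {
    res <- smote_resample(X, y, k = balancing$k %||% 5,
                          target_ratio = balancing$target_ratio %||% 1,
                          round_bits = isTRUE(balancing$round_bits),
                          seed = seed)
    return(list(X = res$X, y = res$y, weights = NULL))
  }
  list(X = X, y = y, weights = NULL)
}

#' Stratified shuffle-split cross-validation of one pipeline
#'
#' Runs `cfg$outer_folds` independent stratified splits. In each fold the
#' training portion alone is balanced (class weights or SMOTE), the model is
#' fitted — with an inner grid search when `cfg$grid` is given — and
#' accuracy, sensitivity, specificity and AUC are computed on the held-out
#' validation portion (threshold 0.5 on the probability scores).
#'
#' @param X numeric feature matrix (a [feature_matrix()] or plain matrix).
#' @param y 0/1 labels.
#' @param cfg a [pipeline_config()].
#' @return Object of class `evaluation_report`: list with `folds`
#'   (data.frame of per-fold metrics), `means` (named numeric vector),
#'   `confusions` (per-fold contingency counts), `splits`.
#' @export
stratified_cv <- function(X, y, cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  X <- as.matrix(X)
  splits <- stratified_shuffle_splits(y, cfg$outer_folds, cfg$val_fraction,
                                      cfg$seed)
  rows <- list(); confusions <- list()
  for (f in seq_along(splits)) {
    val_idx <- splits[[f]]
    fold_seed <- cfg$seed + f
    Xtr <- X[-val_idx, , drop = FALSE]; ytr <- y[-val_idx]
    bal <- apply_balancing(Xtr, ytr, cfg$balancing, seed = fold_seed)
    fit <- if (!is.null(cfg$grid)) {
      grid_search_fit(cfg, bal$X, bal$y, weights = bal$weights,
                      seed = fold_seed)$fit
    } else {
      fit_classifier(cfg$model, bal$X, bal$y, params = cfg$params,
                     weights = bal$weights, seed = fold_seed)
    }
    sc <- predict(fit, X[val_idx, , drop = FALSE])
    pred <- as.integer(sc >= 0.5)
    ev <- evaluate_predictions(pred, y[val_idx], scores = sc)
    rows[[f]] <- data.frame(fold = f, acc = ev$acc, se = ev$se, sp = ev$sp,
                            auc = ev$auc)
    confusions[[f]] <- ev$confusion
  }
  folds <- do.call(rbind, rows)
  means <- colMeans(folds[, c("acc", "se", "sp", "auc")])
  structure(list(folds = folds, means = means, confusions = confusions,
                 splits = splits),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> %d folds | Acc %.3f  SE %.3f  SP %.3f  AUC %s\n",
    nrow(x$folds), x$means["acc"], x$means["se"], x$means["sp"],
    if (is.na(x$means["auc"])) "-" else sprintf("%.3f", x$means["auc"])))
  invisible(x)
}

#' Exhaustive inner grid search
#'
#' Evaluates every combination of `cfg$grid` by mean AUC over an inner
#' stratified `cfg$inner_folds`-fold partition of the training data, picks
#' the best (ties broken by grid order: earlier rows of
#' `expand.grid(cfg$grid)` win), and refits it on the full training portion.
#'
#' @param cfg a [pipeline_config()] with a non-empty `grid`.
#' @param X training feature matrix.
#' @param y training 0/1 labels.
#' @param weights optional class weights passed to the learner.
#' @param seed integer seed.
#' @return List: `fit` (an `mnqsar_model`), `best_params` (named list),
#'   `inner_auc` (numeric vector over combinations).
#' @export
grid_search_fit <- function(cfg, X, y, weights = NULL, seed = 1) {
  if (is.null(cfg$grid) || length(cfg$grid) == 0)
    stop("empty hyperparameter grid")
  X <- as.matrix(X)
  combos <- expand.grid(cfg$grid, stringsAsFactors = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  folds <- make_stratified_folds(y, min(cfg$inner_folds, min(table(y))))
  scores <- vapply(seq_len(nrow(combos)), function(i) {
    params <- lapply(combos[i, , drop = FALSE], function(v)
      if (is.list(v)) v[[1]] else v)
    aucs <- vapply(folds, function(test_idx) {
      ytr <- y[-test_idx]
      if (length(unique(ytr)) < 2 || length(unique(y[test_idx])) < 2)
        return(NA_real_)
      fit <- fit_classifier(cfg$model, X[-test_idx, , drop = FALSE], ytr,
                            params = params, weights = weights, seed = seed)
      auc_score(predict(fit, X[test_idx, , drop = FALSE]), y[test_idx])
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(scores)  # first max wins: ties broken by grid order
  best_params <- lapply(combos[best, , drop = FALSE], function(v)
    if (is.list(v)) v[[1]] else v)
  list(fit = fit_classifier(cfg$model, X, y, params = best_params,
                            weights = weights, seed = seed),
       best_params = best_params, inner_auc = scores)
}

#' Butina cluster split
#'
#' Clusters compounds with the Butina leader algorithm on Tanimoto distance
#' of circular fingerprints, then assigns whole clusters to the validation
#' side until it holds approximately `val_fraction` of the compounds
#' (clusters visited by decreasing size; a cluster goes to validation iff it
#' still fits). No cluster straddles the split, so near-duplicate structures
#' never leak across it.
#'
#' @param records data.frame with `smiles` (or character vector), or a
#'   binary [feature_matrix()] of precomputed fingerprints.
#' @param val_fraction target validation share (default 0.1).
#' @param distance_cutoff Tanimoto distance radius of a cluster
#'   (default 0.4).
#' @param radius,nbits fingerprint parameters when `records` are structures.
#' @return List: `train_ids`, `val_ids` (compound ids), `clusters` (integer
#'   cluster label per compound, in input order).
#' @export
butina_split <- function(records, val_fraction = 0.1, distance_cutoff = 0.4,
                         radius = 2, nbits = 2048) {
  fm <- if (inherits(records, "feature_matrix")) records
        else compute_fingerprints(records, "ecfp", radius = radius,
                                  nbits = nbits)
  n <- nrow(fm)
  if (n < 2) stop("Butina split needs at least 2 compounds")
  ids <- attr(fm, "compound_ids")
  d <- 1 - tanimoto_matrix(unclass(fm))
  clusters <- butina_cluster(d, distance_cutoff)
  if (max(clusters) == 1)
    stop("a single cluster contains every compound; ",
         "use a smaller distance_cutoff")
  sizes <- table(clusters)
  target <- round(val_fraction * n)
  val_clusters <- integer(0); val_n <- 0
  for (cl in as.integer(names(sort(sizes, decreasing = TRUE)))) {
    if (val_n + sizes[as.character(cl)] <= target) {
      val_clusters <- c(val_clusters, cl)
      val_n <- val_n + sizes[as.character(cl)]
    }
  }
  in_val <- clusters %in% val_clusters
  list(train_ids = ids[!in_val], val_ids = ids[in_val], clusters = clusters)
}

# Pairwise Tanimoto similarity of binary row vectors; two all-zero vectors
# count as identical.
tanimoto_matrix <- function(B) {
  B <- as.matrix(B)
  common <- B %*% t(B)
  rs <- rowSums(B)
  union <- outer(rs, rs, "+") - common
  sim <- ifelse(union == 0, 1, common / union)
  sim
}

# Butina leader clustering on a distance matrix: repeatedly promote the
# unassigned compound with the most unassigned neighbors (within cutoff) to
# centroid; its neighbors join its cluster. Deterministic (index tie-break).
butina_cluster <- function(d, cutoff) {
  n <- nrow(d)
  neighbor <- d <= cutoff
  diag(neighbor) <- FALSE
  assigned <- rep(FALSE, n)
  clusters <- integer(n)
  cl <- 0L
  while (!all(assigned)) {
    counts <- vapply(seq_len(n), function(i)
      if (assigned[i]) -1L else sum(neighbor[i, ] & !assigned), integer(1))
    centroid <- which.max(counts)
    cl <- cl + 1L
    members <- c(centroid, which(neighbor[centroid, ] & !assigned))
    clusters[members] <- cl
    assigned[members] <- TRUE
  }
  clusters
}

#' Majority vote over ensemble member predictions
#'
#' Per compound, the label receiving more votes wins; exact ties go to
#' positive (precautionary choice for a hazard endpoint).
#'
#' @param member_predictions list of at least two aligned 0/1 vectors.
#' @return 0/1 vector of consensus labels.
#' @export
majority_vote <- function(member_predictions) {
  if (!is.list(member_predictions) || length(member_predictions) < 2)
    stop("majority vote needs at least two member prediction vectors")
  lens <- lengths(member_predictions)
  if (length(unique(lens)) != 1)
    stop("member prediction vectors differ in length")
  votes <- Reduce(`+`, member_predictions)
  m <- length(member_predictions)
  as.integer(2 * votes >= m)
}

#' Train a majority-vote ensemble
#'
#' Fits each member pipeline (its own feature block, balancing and
#' hyperparameters) on the full training data; predictions are combined by
#' [majority_vote()].
#'
#' @param blocks named list of feature matrices, one entry per feature
#'   block, all row-aligned.
#' @param y 0/1 labels.
#' @param members list of member specs: each a list with `block` (name into
#'   `blocks`), `model`, optional `params`, optional `balancing` list.
#' @param seed integer seed.
#' @return Object of class `mn_ensemble`.
#' @export
train_ensemble <- function(blocks, y, members, seed = 1) {
  if (length(members) < 2) stop("an ensemble needs at least two members")
  fits <- lapply(seq_along(members), function(i) {
    m <- members[[i]]
    X <- as.matrix(blocks[[m$block]])
    bal <- apply_balancing(X, y, m$balancing %||% list(method = "none"),
                           seed = seed + i)
    fit_classifier(m$model, bal$X, bal$y, params = m$params %||% list(),
                   weights = bal$weights, seed = seed + i)
  })
  structure(list(members = members, fits = fits, vote = "majority",
                 tie_rule = "positive"),
            class = "mn_ensemble")
}

#' Predict with a majority-vote ensemble
#'
#' @param object an `mn_ensemble`.
#' @param blocks named list of feature matrices matching the training
#'   blocks.
#' @param ... unused.
#' @return 0/1 consensus labels.
#' @export
predict.mn_ensemble <- function(object, blocks, ...) {
  preds <- lapply(seq_along(object$fits), function(i) {
    X <- as.matrix(blocks[[object$members[[i]]$block]])
    as.integer(predict(object$fits[[i]], X) >= 0.5)
  })
  majority_vote(preds)
}

#' Cross-validate an ensemble and its members
#'
#' Runs the same stratified shuffle splits for every member and the
#' majority-vote ensemble: members are trained per fold on the balanced
#' training portion; the ensemble's fold prediction is the majority vote of
#' the members' fold predictions. Members are scored with AUC; the
#' vote-based ensemble yields labels only, so its AUC is `NA`.
#'
#' @param blocks named list of row-aligned feature matrices.
#' @param y 0/1 labels.
#' @param members member specs, see [train_ensemble()].
#' @param n_splits,val_fraction,seed split parameters, see
#'   [stratified_shuffle_splits()].
#' @return List: `members` (named list of `evaluation_report`-like
#'   summaries), `ensemble` (per-fold and mean Acc/SE/SP).
#' @export
ensemble_cv <- function(blocks, y, members, n_splits = 10,
                        val_fraction = 0.1, seed = 1) {
  splits <- stratified_shuffle_splits(y, n_splits, val_fraction, seed)
  member_rows <- lapply(members, function(m) list())
  ens_rows <- list()
  for (f in seq_along(splits)) {
    val_idx <- splits[[f]]
    fold_seed <- seed + f
    member_preds <- list()
    for (i in seq_along(members)) {
      m <- members[[i]]
      X <- as.matrix(blocks[[m$block]])
      bal <- apply_balancing(X[-val_idx, , drop = FALSE], y[-val_idx],
                             m$balancing %||% list(method = "none"),
                             seed = fold_seed + i)
      fit <- fit_classifier(m$model, bal$X, bal$y,
                            params = m$params %||% list(),
                            weights = bal$weights, seed = fold_seed + i)
      sc <- predict(fit, X[val_idx, , drop = FALSE])
      ev <- evaluate_predictions(as.integer(sc >= 0.5), y[val_idx],
                                 scores = sc)
      member_rows[[i]][[f]] <- data.frame(fold = f, acc = ev$acc,
                                          se = ev$se, sp = ev$sp,
                                          auc = ev$auc)
      member_preds[[i]] <- as.integer(sc >= 0.5)
    }
    vote <- majority_vote(member_preds)
    ev <- evaluate_predictions(vote, y[val_idx])
    ens_rows[[f]] <- data.frame(fold = f, acc = ev$acc, se = ev$se,
                                sp = ev$sp)
  }
  member_summaries <- lapply(seq_along(members), function(i) {
    folds <- do.call(rbind, member_rows[[i]])
    list(folds = folds,
         means = colMeans(folds[, c("acc", "se", "sp", "auc")]))
  })
  names(member_summaries) <- vapply(members, function(m)
    paste(m$model, m$block, sep = "_"), "")
  ens_folds <- do.call(rbind, ens_rows)
  list(members = member_summaries,
       ensemble = list(folds = ens_folds,
                       means = colMeans(ens_folds[, c("acc", "se", "sp")])))
}
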