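# Genetic-algorithm descriptor subset selection.

#' Genetic algorithm configuration
#'
#' Conventional settings for a tournament-selection GA over fixed-size
#' feature subsets. Fitness is the mean AUC of an inner stratified
#' cross-validation of a random forest restricted to the candidate subset.
#'
#' @param population_size individuals per generation (default 50).
#' @param generations number of generations (default 30).
#' @param subset_size_target number of features per individual (required).
#' @param crossover_rate probability of recombining two parents
#'   (default 0.7).
#' @param mutation_rate per-gene probability of replacement by an unused
#'   feature (default 0.05).
#' @param tournament_size tournament size for parent selection (default 3).
#' @param elitism number of best individuals copied unchanged (default 1).
#' @param inner_folds folds of the fitness cross-validation (default 5).
#' @param num_trees forest size of the fitness learner (default 100).
#' @param seed integer seed; the whole search is reproducible given the
#'   seed.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(subset_size_target, population_size = 50,
                      generations = 30, crossover_rate = 0.7,
                      mutation_rate = 0.05, tournament_size = 3,
                      elitism = 1, inner_folds = 5, num_trees = 100,
                      seed = 1) {
  stopifnot(subset_size_target >= 1, population_size >= 2, generations >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            tournament_size >= 1, inner_folds >= 2)
  structure(as.list(environment()), class = "ga_config")
}

#' Select a descriptor subset by genetic algorithm
#'
#' Searches for the feature subset (of size `cfg$subset_size_target`)
#' maximizing the mean inner-cross-validation AUC of a random forest. The
#' search is a conventional generational GA: tournament selection, uniform
#' set-based crossover, per-gene mutation to an unused feature, elitism.
#' Fixed seed gives a reproducible subset. When `subset_size_target` covers
#' all features, every feature name is returned without searching.
#'
#' @param fm a (prefiltered) [feature_matrix()].
#' @param labels 0/1 labels aligned to rows; both classes required.
#' @param cfg a [ga_config()].
#' @return Character vector of selected feature names (sorted by original
#'   column order), with attribute `fitness` (the subset's inner-CV AUC).
#' @export
ga_select_features <- function(fm, labels, cfg) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(cfg, "ga_config"))
  if (nrow(fm) != length(labels))
    stop("labels must align with feature matrix rows")
  if (length(unique(labels)) < 2)
    stop("feature selection needs both classes in the labels")
  vals <- unclass(fm)
  p <- ncol(vals)
  size <- min(cfg$subset_size_target, p)
  if (size >= p) {
    out <- colnames(vals)
    attr(out, "fitness") <- NA_real_
    return(out)
  }

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)

  folds <- make_stratified_folds(labels, cfg$inner_folds)
  cache <- new.env(parent = emptyenv())
  fitness <- function(idx) {
    key <- paste(sort(idx), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- subset_cv_auc(vals[, sort(idx), drop = FALSE], labels, folds,
                         num_trees = cfg$num_trees, seed = cfg$seed)
    cache[[key]] <- val
    val
  }

  pop <- replicate(cfg$population_size, sample.int(p, size),
                   simplify = FALSE)
  fit <- vapply(pop, fitness, numeric(1))

  for (gen in seq_len(cfg$generations)) {
    ord <- order(-fit)
    new_pop <- pop[ord[seq_len(min(cfg$elitism, length(pop)))]]
    while (length(new_pop) < cfg$population_size) {
      p1 <- pop[[tournament(fit, cfg$tournament_size)]]
      p2 <- pop[[tournament(fit, cfg$tournament_size)]]
      child <- if (runif(1) < cfg$crossover_rate) {
        pool <- unique(c(p1, p2))
        sample(pool, min(size, length(pool)))
      } else p1
      # per-gene mutation: swap a selected feature for an unused one
      mut <- which(runif(length(child)) < cfg$mutation_rate)
      if (length(mut) > 0) {
        unused <- setdiff(seq_len(p), child)
        repl <- sample(unused, min(length(mut), length(unused)))
        child[mut[seq_along(repl)]] <- repl
      }
      # top up if crossover pool was too small
      if (length(child) < size) {
        extra <- sample(setdiff(seq_len(p), child), size - length(child))
        child <- c(child, extra)
      }
      new_pop[[length(new_pop) + 1]] <- child
    }
    pop <- new_pop
    fit <- vapply(pop, fitness, numeric(1))
  }
  best <- pop[[which.max(fit)]]
  out <- colnames(vals)[sort(best)]
  attr(out, "fitness") <- max(fit)
  out
}

tournament <- function(fit, size) {
  cand <- sample.int(length(fit), min(size, length(fit)))
  cand[which.max(fit[cand])]
}

# Mean out-of-fold AUC of a random forest on a feature subset.
subset_cv_auc <- function(X, y, folds, num_trees, seed) {
  aucs <- vapply(folds, function(test_idx) {
    ytr <- y[-test_idx]
    if (length(unique(ytr)) < 2 || length(unique(y[test_idx])) < 2)
      return(NA_real_)
    fit <- ranger::ranger(
      x = X[-test_idx, , drop = FALSE],
      y = factor(ytr, levels = c(0, 1)),
      num.trees = num_trees, probability = TRUE,
      seed = seed, num.threads = 1)
    sc <- predict(fit, X[test_idx, , drop = FALSE],
                  num.threads = 1)$predictions[, "1"]
    auc_score(sc, y[test_idx])
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

# Disjoint stratified fold assignment (per-class round robin on a shuffled
# order); used for inner fitness evaluation and disjoint-partition CV.
make_stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f) which(fold == f))
}
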