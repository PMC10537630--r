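# Classification metrics used across enrichment and modeling.

#' Contingency counts for a binary feature vs binary labels
#'
#' `tp` counts compounds with bit 1 and label 1, `fp` bit 1 / label 0,
#' `fn` bit 0 / label 1, `tn` bit 0 / label 0.
#'
#' @param feature_bits 0/1 vector (chemotype presence, or predicted labels).
#' @param labels 0/1 vector of the same length.
#' @return Object of class `contingency_counts`: named list `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
contingency_for_feature <- function(feature_bits, labels) {
  if (length(feature_bits) != length(labels))
    stop("feature and label vectors differ in length")
  if (!all(feature_bits %in% c(0, 1)) || !all(labels %in% c(0, 1)))
    stop("feature bits and labels must be 0/1")
  out <- list(tp = sum(feature_bits == 1 & labels == 1),
              fp = sum(feature_bits == 1 & labels == 0),
              fn = sum(feature_bits == 0 & labels == 1),
              tn = sum(feature_bits == 0 & labels == 0))
  class(out) <- "contingency_counts"
  out
}

#' Association odds ratio of a 2x2 table
#'
#' Computed as `tp * tn / (fn * fp)`. When the denominator is zero and the
#' numerator positive the result is `Inf`; when both products are zero the
#' ratio is undefined and `NaN` is returned (treated as not enriched
#' downstream). With `haldane = TRUE`, 0.5 is added to every cell first
#' (Haldane-Anscombe correction); the default applies no correction.
#'
#' @param counts a [contingency_for_feature()] result (or any list with
#'   `tp`, `fp`, `fn`, `tn`).
#' @param haldane apply the +0.5 continuity correction (default `FALSE`).
#' @return A single numeric ratio (possibly `Inf` or `NaN`).
#' @export
odds_ratio <- function(counts, haldane = FALSE) {
  a <- counts$tp; b <- counts$fp; c <- counts$fn; d <- counts$tn
  if (haldane) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  num <- a * d
  den <- c * b
  if (den == 0 && num == 0) return(NaN)
  if (den == 0) return(Inf)
  num / den
}

#' One-sided Fisher exact p-value (enrichment direction)
#'
#' Exact probability, under the hypergeometric null with both table margins
#' fixed, of observing at least the given number of true positives. This is
#' the upper-tail exact test for over-representation of the feature among
#' positive compounds; no approximation is involved.
#'
#' @inheritParams odds_ratio
#' @return p-value in `[0, 1]`.
#' @export
fisher_exact_one_sided <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  n_pos <- tp + fn          # positive compounds
  n_neg <- fp + tn          # negative compounds
  k <- tp + fp              # feature-bearing compounds (fixed margin)
  if (k == 0) return(1)
  # P(X >= tp), X ~ Hypergeometric(n_pos, n_neg, k)
  phyper(tp - 1, n_pos, n_neg, k, lower.tail = FALSE)
}

#' Positive predictive value of a chemotype
#'
#' Fraction of chemotype-bearing compounds that are active:
#' `tp / (tp + fp)`. `NaN` when no compound carries the chemotype.
#'
#' @inheritParams odds_ratio
#' @return Value in `[0, 1]`, or `NaN` if undefined.
#' @export
positive_predictive_value <- function(counts) {
  den <- counts$tp + counts$fp
  if (den == 0) return(NaN)
  counts$tp / den
}

#' Balanced accuracy of binary predictions
#'
#' Arithmetic mean of sensitivity and specificity, `(SE + SP) / 2`.
#'
#' @param pred 0/1 predicted labels.
#' @param labels 0/1 true labels; both classes must be present.
#' @return Value in `[0, 1]`.
#' @export
balanced_accuracy <- function(pred, labels) {
  if (length(unique(labels)) < 2)
    stop("balanced accuracy needs both classes in the labels")
  cc <- contingency_for_feature(pred, labels)
  se <- cc$tp / (cc$tp + cc$fn)
  sp <- cc$tn / (cc$tn + cc$fp)
  (se + sp) / 2
}

#' Area under the ROC curve (rank / Wilcoxon form)
#'
#' The probability that a uniformly chosen positive compound receives a
#' higher score than a uniformly chosen negative one, counting ties as 1/2.
#' Invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 true labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length")
  if (length(unique(labels)) < 2)
    stop("AUC needs both classes in the labels")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate binary predictions against true labels
#'
#' Computes accuracy `(TP+TN)/n`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)` and, when continuous `scores` are supplied, the rank AUC
#' ([auc_score()]). Label-only predictors (e.g. a majority-vote ensemble)
#' yield no AUC: the field is `NA`.
#'
#' @param pred 0/1 predicted labels.
#' @param labels 0/1 true labels (both classes required).
#' @param scores optional numeric scores behind `pred`.
#' @return A list: `acc`, `se`, `sp`, `auc` (NA without scores), and
#'   `confusion` (a [contingency_for_feature()] object).
#' @export
evaluate_predictions <- function(pred, labels, scores = NULL) {
  if (length(unique(labels)) < 2)
    stop("evaluation needs both classes in the labels")
  cc <- contingency_for_feature(pred, labels)
  n <- cc$tp + cc$tn + cc$fp + cc$fn
  list(acc = (cc$tp + cc$tn) / n,
       se = cc$tp / (cc$tp + cc$fn),
       sp = cc$tn / (cc$tn + cc$fp),
       auc = if (is.null(scores)) NA_real_ else auc_score(scores, labels),
       confusion = cc)
}
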