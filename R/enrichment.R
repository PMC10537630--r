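# Chemotype enrichment workflow: per-chemotype 2x2 statistics, significance
# filtering, rule-based set-level prediction, cross-endpoint relevance.

#' Enrichment thresholds
#'
#' A chemotype is flagged enriched when its odds ratio is at least
#' `odds_min` and its one-sided Fisher exact p-value is below `p_max`.
#' The default significance cut is 0.05; any other value (e.g. 0.5) can be
#' supplied.
#'
#' @param odds_min minimum odds ratio (default 3).
#' @param p_max exclusive p-value ceiling (default 0.05).
#' @return A list with class `enrichment_thresholds`.
#' @export
enrichment_thresholds <- function(odds_min = 3, p_max = 0.05) {
  if (odds_min <= 0) stop("odds_min must be positive")
  if (!(p_max > 0 && p_max <= 1)) stop("p_max must be in (0, 1]")
  structure(list(odds_min = odds_min, p_max = p_max),
            class = "enrichment_thresholds")
}

#' Per-chemotype enrichment analysis
#'
#' For every column of a binary feature matrix, builds the 2x2 contingency
#' table against the activity labels and computes the odds ratio, one-sided
#' Fisher exact p-value, balanced accuracy and positive predictive value of
#' the single-chemotype classifier "predict positive iff the chemotype is
#' present". Chemotypes passing both thresholds are flagged enriched. The
#' enriched flag is a pure function of (odds, p, thresholds).
#'
#' @param fm binary [feature_matrix()] (chemotype fingerprints).
#' @param labels 0/1 activity labels aligned to the rows of `fm`; both
#'   classes must be present.
#' @param thresholds an [enrichment_thresholds()] object.
#' @param haldane apply the +0.5 odds-ratio correction (default `FALSE`).
#' @return A data.frame of class `enrichment_table`, one row per chemotype,
#'   columns `ct_name`, `tp`, `fp`, `fn`, `tn`, `odds`, `p_value`, `ba`,
#'   `ppv`, `enriched`, sorted by descending odds then ascending p.
#' @export
run_enrichment <- function(fm, labels, thresholds = enrichment_thresholds(),
                           haldane = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!fm_binary(fm)) stop("enrichment requires a binary feature matrix")
  if (nrow(fm) != length(labels))
    stop("labels must align with feature matrix rows")
  if (length(unique(labels)) < 2)
    stop("enrichment needs both classes in the labels")
  vals <- unclass(fm)
  rows <- lapply(seq_len(ncol(vals)), function(j) {
    cc <- contingency_for_feature(vals[, j], labels)
    odds <- odds_ratio(cc, haldane = haldane)
    p <- fisher_exact_one_sided(cc)
    se <- if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else NaN
    sp <- if (cc$tn + cc$fp > 0) cc$tn / (cc$tn + cc$fp) else NaN
    data.frame(ct_name = colnames(vals)[j],
               tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn,
               odds = odds, p_value = p,
               ba = (se + sp) / 2,
               ppv = positive_predictive_value(cc),
               enriched = is_enriched(odds, p, thresholds),
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(ct_name = character(0), tp = integer(0), fp = integer(0),
               fn = integer(0), tn = integer(0), odds = numeric(0),
               p_value = numeric(0), ba = numeric(0), ppv = numeric(0),
               enriched = logical(0), stringsAsFactors = FALSE)
  ord <- order(-ifelse(is.nan(tab$odds), -Inf, tab$odds), tab$p_value)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("enrichment_table", "data.frame")
  tab
}

# Enriched iff odds >= odds_min and p < p_max; undefined odds (NaN) never
# qualifies.
is_enriched <- function(odds, p, thresholds) {
  !is.nan(odds) && odds >= thresholds$odds_min && p < thresholds$p_max
}

#' Rule-based set-level classifier
#'
#' Predicts a compound positive iff it carries at least `min_hits` distinct
#' enriched chemotypes. This is the set-level reading of an enriched
#' chemotype list: with `min_hits = 1` a single structural alert suffices,
#' with `min_hits = 2` two independent alerts are required.
#'
#' @param fm binary [feature_matrix()] of chemotype fingerprints.
#' @param enriched_cts character vector of enriched chemotype names
#'   (columns of `fm`); typically `subset(tab, enriched)$ct_name`.
#' @param min_hits minimum number of distinct enriched chemotypes
#'   (default 1).
#' @return 0/1 predicted labels, one per row of `fm`.
#' @export
rule_based_classifier <- function(fm, enriched_cts, min_hits = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (min_hits < 1) stop("min_hits must be at least 1")
  if (length(enriched_cts) == 0) {
    warning("empty enriched chemotype set: predicting all-negative")
    return(rep(0L, nrow(fm)))
  }
  missing_cts <- setdiff(enriched_cts, colnames(fm))
  if (length(missing_cts) > 0)
    stop("chemotypes not in matrix: ", paste(missing_cts, collapse = ", "))
  hits <- rowSums(unclass(fm)[, enriched_cts, drop = FALSE])
  as.integer(hits >= min_hits)
}

#' Coverage of compounds by enriched chemotypes
#'
#' Fraction of compounds (overall and per class) carrying at least
#' `min_hits` enriched chemotypes — the set-level coverage statistic used to
#' summarize how much of an endpoint's positive space a chemotype list
#' explains.
#'
#' @inheritParams rule_based_classifier
#' @param labels 0/1 activity labels.
#' @return A list: `overall`, `positives`, `negatives` coverage fractions
#'   plus the set-level `ba` of the rule-based classifier.
#' @export
enriched_set_coverage <- function(fm, enriched_cts, labels, min_hits = 1) {
  pred <- suppressWarnings(rule_based_classifier(fm, enriched_cts, min_hits))
  list(overall = mean(pred == 1),
       positives = mean(pred[labels == 1] == 1),
       negatives = mean(pred[labels == 0] == 1),
       ba = balanced_accuracy(pred, labels))
}

#' Relevance tier from a PPV value
#'
#' `high` for PPV >= 0.70, `moderate` for 0.50 < PPV < 0.70, `poor` for
#' PPV <= 0.50 (the boundary 0.50 falls in `poor` since the moderate band
#' is open), `not_evaluable` for undefined PPV.
#'
#' @param ppv positive predictive value (possibly `NaN`).
#' @param cut_high,cut_mod tier cut points (defaults 0.70 and 0.50).
#' @return One of `"high"`, `"moderate"`, `"poor"`, `"not_evaluable"`.
#' @export
relevance_tier <- function(ppv, cut_high = 0.70, cut_mod = 0.50) {
  if (is.nan(ppv) || is.na(ppv)) return("not_evaluable")
  if (ppv >= cut_high) return("high")
  if (ppv > cut_mod) return("moderate")
  "poor"
}

#' Cross-endpoint relevance of a chemotype
#'
#' Assesses how well a chemotype enriched in one endpoint (e.g. in vitro)
#' carries over to another (e.g. in vivo) by computing its PPV on the second
#' endpoint's data and assigning a relevance tier.
#'
#' @param ct_name chemotype name; must be a column of `fm_b`.
#' @param fm_b binary [feature_matrix()] of the second endpoint.
#' @param labels_b 0/1 labels of the second endpoint.
#' @param cut_high,cut_mod tier cut points, see [relevance_tier()].
#' @return A list: `ct_name`, `ppv`, `tier`, `n_carriers`.
#' @export
cross_endpoint_relevance <- function(ct_name, fm_b, labels_b,
                                     cut_high = 0.70, cut_mod = 0.50) {
  stopifnot(inherits(fm_b, "feature_matrix"))
  if (!ct_name %in% colnames(fm_b))
    stop("chemotype not present in endpoint-B matrix: ", ct_name)
  bits <- unclass(fm_b)[, ct_name]
  cc <- contingency_for_feature(bits, labels_b)
  ppv <- positive_predictive_value(cc)
  list(ct_name = ct_name, ppv = ppv,
       tier = relevance_tier(ppv, cut_high, cut_mod),
       n_carriers = cc$tp + cc$fp)
}

#' Write an enrichment table to CSV
#'
#' @param tab an `enrichment_table` from [run_enrichment()].
#' @param path output path.
#' @return Invisibly, `tab`.
#' @export
write_enrichment_table <- function(tab, path) {
  write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(tab)
}
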