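test_that("contingency counting matches direct enumeration", {
  out <- contingency_for_feature(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_identical(out[c("tp", "fp", "fn", "tn")],
                   list(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  expect_identical(contingency_for_feature(rep(0, 5), c(1, 1, 0, 0, 1))$tp, 0L)
  ident <- contingency_for_feature(c(1, 0, 1), c(1, 0, 1))
  expect_identical(ident$fp + ident$fn, 0L)
  expect_error(contingency_for_feature(c(1, 0), c(1, 0, 1)), "length")
})

test_that("odds ratio follows the TP*TN/(FN*FP) formula with degenerate conventions", {
  expect_identical(odds_ratio(cc(1, 1, 1, 1)), 1)
  expect_identical(odds_ratio(cc(10, 2, 5, 20)), 20)
  expect_identical(odds_ratio(cc(5, 0, 2, 5)), Inf)
  expect_true(is.nan(odds_ratio(cc(0, 0, 3, 0))))
  # Haldane correction keeps zero-cell tables finite
  expect_equal(odds_ratio(cc(5, 0, 2, 5), haldane = TRUE),
               (5.5 * 5.5) / (2.5 * 0.5))
})

test_that("one-sided Fisher p matches the combinatorial oracle on small tables", {
  expect_equal(fisher_exact_one_sided(cc(3, 0, 0, 3)), 0.05, tolerance = 1e-12)
  expect_identical(fisher_exact_one_sided(cc(0, 0, 4, 7)), 1)
  cases <- list(c(2, 1, 3, 4), c(5, 0, 1, 2), c(0, 3, 2, 1), c(4, 4, 2, 2))
  for (x in cases) {
    expect_equal(fisher_exact_one_sided(cc(x[1], x[2], x[3], x[4])),
                 fisher_oracle(x[1], x[2], x[3], x[4]), tolerance = 1e-12)
    # and agrees with the reference exact test
    m <- matrix(c(x[1], x[2], x[3], x[4]), 2, byrow = TRUE)
    expect_equal(fisher_exact_one_sided(cc(x[1], x[2], x[3], x[4])),
                 fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("adding a concordant compound never weakens enrichment", {
  for (seed in 1:20) {
    set.seed(seed)
    x <- sample(0:6, 4, replace = TRUE)
    base <- cc(x[1] + 1, x[2], x[3], x[4])  # ensure tp >= 1
    more <- cc(base$tp + 1, base$fp, base$fn, base$tn)
    o1 <- odds_ratio(base); o2 <- odds_ratio(more)
    if (!is.nan(o1) && !is.nan(o2)) expect_gte(o2, o1)
    expect_lte(fisher_exact_one_sided(more), fisher_exact_one_sided(base))
  }
})

test_that("PPV is the positive fraction among carriers", {
  expect_identical(positive_predictive_value(cc(7, 3, 5, 5)), 0.7)
  expect_identical(positive_predictive_value(cc(4, 0, 1, 5)), 1)
  expect_identical(positive_predictive_value(cc(1, 3, 2, 2)), 0.25)
  expect_true(is.nan(positive_predictive_value(cc(0, 0, 3, 3))))
})

test_that("balanced accuracy averages sensitivity and specificity", {
  labels <- c(1, 1, 1, 0, 0)
  expect_identical(balanced_accuracy(labels, labels), 1)
  expect_identical(balanced_accuracy(rep(1, 5), labels), 0.5)
  # SE = 0.7, SP = 0.6 constructed: 7/10 positives hit, 6/10 negatives hit
  pred <- c(rep(1, 7), rep(0, 3), rep(0, 6), rep(1, 4))
  truth <- c(rep(1, 10), rep(0, 10))
  expect_equal(balanced_accuracy(pred, truth), 0.65)
  expect_error(balanced_accuracy(rep(1, 3), rep(1, 3)), "both classes")
})

test_that("enrichment table flags a perfect association and not an independent one", {
  labels <- c(rep(1, 30), rep(0, 70))
  vals <- cbind(perfect = labels,
                flat = rep(c(1, 0), 50))  # independent of labels by design
  fm <- feature_matrix(vals, kind = "chemotype")
  tab <- run_enrichment(fm, labels)
  expect_s3_class(tab, "enrichment_table")
  perfect <- tab[tab$ct_name == "perfect", ]
  expect_true(perfect$enriched)
  expect_identical(perfect$odds, Inf)
  expect_lt(perfect$p_value, 1 / choose(100, 30) * 1.01)
  expect_false(tab[tab$ct_name == "flat", "enriched"])
  # sorted by descending odds then ascending p
  expect_identical(tab$ct_name[1], "perfect")
  # empty matrix -> empty table
  fm0 <- feature_matrix(matrix(integer(0), 100, 0), kind = "chemotype")
  expect_identical(nrow(run_enrichment(fm0, labels)), 0L)
  expect_error(run_enrichment(fm, rep(1, 100)), "both classes")
})

test_that("enriched flag is a pure function of odds, p and thresholds", {
  expect_true(mnqsar:::is_enriched(3, 0.049, enrichment_thresholds()))
  expect_false(mnqsar:::is_enriched(2.99, 1e-10, enrichment_thresholds()))
  expect_false(mnqsar:::is_enriched(100, 0.05, enrichment_thresholds()))
  expect_true(mnqsar:::is_enriched(3, 0.4, enrichment_thresholds(p_max = 0.5)))
  expect_false(mnqsar:::is_enriched(NaN, 0.001, enrichment_thresholds()))
})

test_that("rule-based classifier thresholds on distinct enriched chemotypes", {
  vals <- rbind(c(1, 1, 0), c(1, 0, 0), c(0, 0, 1), c(0, 0, 0))
  fm <- feature_matrix(vals, kind = "chemotype",
                       compound_ids = paste0("c", 1:4))
  colnames(vals) <- colnames(unclass(fm))
  enriched <- colnames(unclass(fm))[1:2]
  expect_identical(rule_based_classifier(fm, enriched, min_hits = 1),
                   c(1L, 1L, 0L, 0L))
  expect_identical(rule_based_classifier(fm, enriched, min_hits = 2),
                   c(1L, 0L, 0L, 0L))
  expect_warning(pred <- rule_based_classifier(fm, character(0)), "empty")
  expect_identical(pred, rep(0L, 4))
})

test_that("relevance tiers follow the PPV cut points", {
  expect_identical(relevance_tier(0.75), "high")
  expect_identical(relevance_tier(0.70), "high")
  expect_identical(relevance_tier(0.60), "moderate")
  expect_identical(relevance_tier(0.50), "poor")   # boundary goes to poor
  expect_identical(relevance_tier(0.40), "poor")
  expect_identical(relevance_tier(NaN), "not_evaluable")
})

test_that("cross-endpoint relevance computes PPV on the second endpoint", {
  vals <- cbind(ct_x = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0))
  fm_b <- feature_matrix(vals, kind = "chemotype")
  labels_b <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  out <- cross_endpoint_relevance("ct_x", fm_b, labels_b)
  expect_identical(out$ppv, 0.75)
  expect_identical(out$tier, "high")
  expect_identical(out$n_carriers, 4L)
  # chemotype absent from every compound -> not evaluable
  vals0 <- cbind(ct_0 = rep(0, 10))
  out0 <- cross_endpoint_relevance("ct_0",
                                   feature_matrix(vals0, kind = "chemotype"),
                                   labels_b)
  expect_identical(out0$tier, "not_evaluable")
  expect_error(cross_endpoint_relevance("nope", fm_b, labels_b), "not present")
})

test_that("set coverage reports the fraction of compounds carrying alerts", {
  labels <- c(1, 1, 1, 0, 0)
  vals <- cbind(a = c(1, 1, 0, 1, 0), b = c(0, 1, 0, 0, 0))
  fm <- feature_matrix(vals, kind = "chemotype")
  cov <- enriched_set_coverage(fm, c("a", "b"), labels, min_hits = 1)
  expect_identical(cov$overall, 3 / 5)
  expect_identical(cov$positives, 2 / 3)
  expect_identical(cov$negatives, 1 / 2)
})
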