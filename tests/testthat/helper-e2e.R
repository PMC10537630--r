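# End-to-end pipeline run on a synthetic molecule dataset with planted
# carbamate/nitroso structure-activity signal: curate -> featurize (MACCS +
# descriptors) -> SMOTE -> RF + XGB -> majority-vote ensemble, evaluated by
# stratified shuffle-split cross-validation. Also evaluates the same members
# on permuted labels as a negative control.
run_e2e_pipeline <- function(seed, n = 800, n_splits = 10) {
  spec <- synthetic_spec(
    n, 0.7,
    planted = list(
      list(name = "carbamate", prev_pos = 0.55, prev_neg = 0.03),
      list(name = "nitroso", prev_pos = 0.55, prev_neg = 0.03)),
    seed = seed)
  mols <- generate_molecule_dataset(spec)
  cur <- curate_records(mols)$curated
  y <- cur$label

  desc <- compute_descriptors(cur)
  stopifnot(nrow(desc) == nrow(cur))
  maccs <- compute_fingerprints(cur, "maccs")
  blocks <- list(desc = unclass(desc), maccs = unclass(maccs))
  members <- list(
    list(block = "desc", model = "rf", params = list(num_trees = 300),
         balancing = list(method = "smote")),
    list(block = "maccs", model = "xgb",
         params = list(nrounds = 100, max_depth = 6),
         balancing = list(method = "smote")))

  cv <- ensemble_cv(blocks, y, members, n_splits = n_splits,
                    val_fraction = 0.1, seed = seed)
  set.seed(seed + 999)
  y_shuffled <- sample(y)
  cv_shuffled <- ensemble_cv(blocks, y_shuffled, members,
                             n_splits = n_splits, val_fraction = 0.1,
                             seed = seed)
  list(n_curated = nrow(cur),
       member_aucs = vapply(cv$members, function(m) m$means[["auc"]],
                            numeric(1)),
       shuffled_aucs = vapply(cv_shuffled$members,
                              function(m) m$means[["auc"]], numeric(1)),
       ensemble = cv$ensemble$means)
}
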