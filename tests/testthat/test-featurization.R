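test_that("descriptor battery includes molecular weight and logP and is deterministic", {
  fm <- compute_descriptors(c("CCO", "CCO", "c1ccccc1"))
  expect_s3_class(fm, "feature_matrix")
  expect_false(attr(fm, "binary"))
  expect_equal(unname(fm[1, "mw"]), 46.07, tolerance = 1e-3)
  expect_true("logp" %in% colnames(fm))
  expect_gt(ncol(fm), 80)
  # same molecule twice -> identical rows
  expect_identical(unname(fm[1, ]), unname(fm[2, ]))
  # benzene: six aromatic atoms, no rotatable bonds
  expect_equal(unname(fm[3, "n_aromatic_atoms"]), 6)
  expect_equal(unname(fm[3, "n_rotatable_bonds"]), 0)
})

test_that("descriptors on an empty record set give a 0-row matrix with full columns", {
  fm0 <- compute_descriptors(character(0))
  fm1 <- compute_descriptors("CCO")
  expect_identical(nrow(fm0), 0L)
  expect_identical(colnames(fm0), colnames(fm1))
})

test_that("failing molecules are excluded with a log entry", {
  fm <- compute_descriptors(data.frame(record_id = c("ok", "bad"),
                                       smiles = c("CCO", "xx$oops"),
                                       stringsAsFactors = FALSE))
  expect_identical(nrow(fm), 1L)
  excluded <- attr(fm, "excluded")
  expect_identical(excluded$record_id, "bad")
})

test_that("prefilter removes constant, low-variance and correlated columns", {
  set.seed(5)
  base <- rnorm(40, sd = 3)
  vals <- cbind(a = base,
                b = base * 2 + 1e-8 * rnorm(40),  # R^2 ~ 1 with a
                c = rep(5, 40),                   # constant
                d = rnorm(40, sd = 0.1),          # sd < 0.5
                e = rnorm(40, sd = 3))
  fm <- feature_matrix(vals, kind = "descriptor", binary = FALSE)
  out <- prefilter_descriptors(fm)
  expect_identical(colnames(out), c("a", "e"))
  removed <- attr(out, "removed")
  expect_setequal(removed$feature, c("b", "c", "d"))
  # survivors keep original order and contain no pair above the ceiling
  cm <- cor(unclass(out))^2
  expect_true(all(cm[upper.tri(cm)] <= 0.9))
})

test_that("prefilter keeps exactly one of two identical columns", {
  vals <- cbind(x = c(1, 5, 9, 2, 8), y = c(1, 5, 9, 2, 8),
                z = c(0, 3, 1, 7, 2))
  fm <- feature_matrix(vals, kind = "descriptor", binary = FALSE)
  out <- prefilter_descriptors(fm)
  expect_identical(colnames(out), c("x", "z"))
  expect_error(prefilter_descriptors(fm[1:2, ]), "3 compounds")
})

test_that("fingerprints have the stated lengths and are deterministic", {
  expect_identical(length(compute_fingerprint("CCO", "maccs")), 166L)
  expect_identical(length(compute_fingerprint("CCO", "path_fp")), 1024L)
  expect_identical(length(compute_fingerprint("CCO", "ecfp", radius = 2,
                                              nbits = 1024)), 1024L)
  for (kind in c("maccs", "path_fp", "ecfp", "fcfp")) {
    a <- compute_fingerprint("CCOC(N)=O", kind)
    b <- compute_fingerprint("CCOC(N)=O", kind)
    expect_identical(a, b)
    expect_true(all(a %in% c(0L, 1L)))
  }
  expect_error(compute_fingerprint("CCO", "ecfp", radius = 5), "radius")
})

test_that("circular fingerprint of methane sets one or two bits at radius 1", {
  pc <- sum(compute_fingerprint("C", "ecfp", radius = 1, nbits = 1024))
  expect_gte(pc, 1)
  expect_lte(pc, 2)
})

test_that("larger radius never loses environments", {
  for (smi in c("CCO", "c1ccccc1CCl", "CC(=O)Oc1ccccc1C(=O)O")) {
    p1 <- sum(compute_fingerprint(smi, "ecfp", radius = 1, nbits = 2048))
    p3 <- sum(compute_fingerprint(smi, "ecfp", radius = 3, nbits = 2048))
    expect_gte(p3, p1)
  }
})

test_that("chemotype fingerprints flag substructure presence", {
  cts <- chemotype_set(c("carbamate", "nitroso"),
                       c("[NX3][CX3](=O)[OX2]", "[NX2]=[OX1]"))
  # urethane carries the carbamate chemotype
  bits <- compute_chemotype_fingerprint("CCOC(N)=O", cts)
  expect_identical(unname(bits), c(1L, 0L))
  # benzene carries neither
  expect_identical(unname(compute_chemotype_fingerprint("c1ccccc1", cts)),
                   c(0L, 0L))
  # empty set -> empty vector
  empty <- chemotype_set(character(0), character(0))
  expect_identical(length(compute_chemotype_fingerprint("CCO", empty)), 0L)
})

test_that("chemotype matrix aligns with per-molecule fingerprints", {
  cts <- generator_chemotypes()
  smis <- c("CCOC(N)=O", "CCN=O", "c1ccccc1")
  fm <- compute_chemotype_matrix(smis, cts)
  expect_identical(dim(unclass(fm)), c(3L, 6L))
  for (i in 1:3)
    expect_identical(unname(unclass(fm)[i, ]),
                     unname(compute_chemotype_fingerprint(smis[i], cts)))
})

test_that("chemotype files reject bad SMARTS and duplicate names", {
  expect_error(chemotype_set(c("a", "a"), c("[CX4]", "[OX2]")), "unique")
  expect_error(chemotype_set("bad", "[[["), "compile")
  cts <- default_chemotypes()
  expect_gt(nrow(cts), 25)
  expect_false(anyDuplicated(cts$name) > 0)
})

test_that("feature matrix CSV round trip preserves values and metadata", {
  fm <- compute_fingerprints(c("CCO", "CCN=O"), "maccs")
  tmp <- tempfile(fileext = ".csv")
  write_feature_matrix(fm, tmp)
  back <- read_feature_matrix(tmp)
  expect_identical(unclass(back), unclass(fm))
  expect_identical(fm_kind(back), "maccs")
  unlink(tmp)
})

test_that("GA selection finds a planted informative descriptor", {
  set.seed(77)
  n <- 200
  labels <- rep(c(1, 0), each = n / 2)
  vals <- cbind(signal = labels + rnorm(n, sd = 0.05),
                matrix(rnorm(n * 11), n, 11,
                       dimnames = list(NULL, sprintf("noise%02d", 1:11))))
  fm <- feature_matrix(vals, kind = "descriptor", binary = FALSE)
  cfg <- ga_config(subset_size_target = 3, population_size = 10,
                   generations = 5, inner_folds = 3, num_trees = 50,
                   seed = 42)
  sel <- ga_select_features(fm, labels, cfg)
  expect_true("signal" %in% sel)
  expect_lte(length(sel), 3)
  # determinism
  sel2 <- ga_select_features(fm, labels, cfg)
  expect_identical(sel, sel2)
  # selection pressure off: target covering all features returns everything
  cfg_all <- ga_config(subset_size_target = ncol(vals), population_size = 10,
                       generations = 2, seed = 1)
  expect_identical(as.character(ga_select_features(fm, labels, cfg_all)),
                   colnames(vals))
  expect_error(ga_select_features(fm, rep(1, n), cfg), "both classes")
})

test_that("GA subset beats random subsets of equal size on planted signal", {
  set.seed(88)
  n <- 150
  labels <- rep(c(1, 0), each = n / 2)
  vals <- cbind(signal = labels + rnorm(n, sd = 0.1),
                matrix(rnorm(n * 9), n, 9,
                       dimnames = list(NULL, sprintf("noise%02d", 1:9))))
  fm <- feature_matrix(vals, kind = "descriptor", binary = FALSE)
  cfg <- ga_config(subset_size_target = 2, population_size = 8,
                   generations = 4, inner_folds = 3, num_trees = 50,
                   seed = 9)
  sel <- ga_select_features(fm, labels, cfg)
  sel_fit <- attr(sel, "fitness")
  set.seed(9)
  folds <- mnqsar:::make_stratified_folds(labels, 3)
  rand_fits <- replicate(20, {
    idx <- sample(ncol(vals), 2)
    mnqsar:::subset_cv_auc(vals[, idx, drop = FALSE], labels, folds,
                           num_trees = 50, seed = 9)
  })
  expect_gte(sel_fit, max(rand_fits) - 0.02)
  expect_gt(sel_fit, mean(rand_fits))
})
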