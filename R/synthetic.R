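# Synthetic datasets with planted structure-activity signal: feature-level
# generators (binary chemotype tables), molecule-level generators (template
# grammar producing valid SMILES), and paired endpoints with controlled
# cross-endpoint PPV.

#' Specification of a synthetic dataset
#'
#' Describes the statistical structure of a generated dataset: class
#' imbalance, planted chemotypes with class-conditional prevalences, noise
#' features and optional label noise.
#'
#' @param n_compounds number of compounds (at least 10).
#' @param positive_fraction fraction of positive labels (e.g. 0.70 for an
#'   in-vitro-like endpoint, 0.32 for an in-vivo-like one).
#' @param planted list of planted chemotypes, each a list with `name`,
#'   `prev_pos` (prevalence among positives) and `prev_neg` (prevalence
#'   among negatives).
#' @param n_noise_features number of label-independent noise features.
#' @param noise_prevalence prevalence of each noise feature in both classes
#'   (default 0.1).
#' @param label_noise_rate probability of flipping each label after
#'   planting (default 0).
#' @param exclusive draw planted chemotypes mutually exclusively (each
#'   compound carries at most one planted chemotype; the class-conditional
#'   prevalences must then sum to at most 1 per class). Default `FALSE`:
#'   independent draws per chemotype.
#' @param seed integer seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds, positive_fraction, planted = list(),
                           n_noise_features = 0, noise_prevalence = 0.1,
                           label_noise_rate = 0, exclusive = FALSE,
                           seed = 1) {
  if (n_compounds < 10) stop("n_compounds must be at least 10")
  check_frac <- function(x, what) {
    if (any(x < 0 | x > 1)) stop(what, " must lie in [0, 1]")
  }
  check_frac(positive_fraction, "positive_fraction")
  check_frac(noise_prevalence, "noise_prevalence")
  check_frac(label_noise_rate, "label_noise_rate")
  for (p in planted) {
    if (is.null(p$name)) stop("each planted chemotype needs a name")
    check_frac(c(p$prev_pos, p$prev_neg), paste0("prevalence of ", p$name))
  }
  if (exclusive && length(planted) > 0) {
    if (sum(vapply(planted, `[[`, 0, "prev_pos")) > 1 ||
        sum(vapply(planted, `[[`, 0, "prev_neg")) > 1)
      stop("exclusive planting requires prevalences summing to at most 1")
  }
  n_pos <- round(n_compounds * positive_fraction)
  if (n_pos == 0 && any(vapply(planted, function(p) p$prev_pos > 0, TRUE)))
    stop("no positive compounds but a planted positive prevalence > 0")
  if (n_pos == n_compounds &&
      any(vapply(planted, function(p) p$prev_neg > 0, TRUE)))
    stop("no negative compounds but a planted negative prevalence > 0")
  structure(list(n_compounds = n_compounds,
                 positive_fraction = positive_fraction, planted = planted,
                 n_noise_features = n_noise_features,
                 noise_prevalence = noise_prevalence,
                 label_noise_rate = label_noise_rate,
                 exclusive = exclusive, seed = seed),
            class = "synthetic_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a binary feature dataset with planted enrichment
#'
#' Labels match `positive_fraction` exactly (after rounding); each planted
#' feature bit is drawn independently per compound at its class-conditional
#' prevalence; noise features have equal prevalence in both classes. The
#' generating odds ratio of a planted feature is
#' `(prev_pos * (1 - prev_neg)) / ((1 - prev_pos) * prev_neg)`.
#'
#' @param spec a [synthetic_spec()].
#' @return List: `features` (binary [feature_matrix()] of kind
#'   `"chemotype"`), `labels` (0/1 vector).
#' @export
generate_feature_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_compounds
    n_pos <- round(n * spec$positive_fraction)
    labels <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
    cols <- list()
    if (isTRUE(spec$exclusive) && length(spec$planted) > 0) {
      nms <- vapply(spec$planted, `[[`, "", "name")
      pp <- vapply(spec$planted, `[[`, 0, "prev_pos")
      pn <- vapply(spec$planted, `[[`, 0, "prev_neg")
      draw <- integer(n)  # 0 = none, i = planted chemotype i
      pos <- labels == 1
      draw[pos] <- sample.int(length(nms) + 1, sum(pos), replace = TRUE,
                              prob = c(pp, 1 - sum(pp))) %% (length(nms) + 1)
      draw[!pos] <- sample.int(length(nms) + 1, sum(!pos), replace = TRUE,
                               prob = c(pn, 1 - sum(pn))) %% (length(nms) + 1)
      for (i in seq_along(nms)) cols[[nms[i]]] <- as.integer(draw == i)
    } else {
      for (p in spec$planted) {
        bits <- integer(n)
        bits[labels == 1] <- rbinom(sum(labels == 1), 1, p$prev_pos)
        bits[labels == 0] <- rbinom(sum(labels == 0), 1, p$prev_neg)
        cols[[p$name]] <- bits
      }
    }
    if (spec$n_noise_features > 0) {
      for (j in seq_len(spec$n_noise_features)) {
        cols[[sprintf("noise_%03d", j)]] <-
          rbinom(n, 1, spec$noise_prevalence)
      }
    }
    mat <- if (length(cols) > 0) do.call(cbind, cols) else
      matrix(integer(0), nrow = n, ncol = 0)
    if (spec$label_noise_rate > 0) {
      flip <- runif(n) < spec$label_noise_rate
      labels[flip] <- 1L - labels[flip]
    }
    list(features = feature_matrix(mat, kind = "chemotype",
                                   compound_ids = sprintf("syn%05d",
                                                          seq_len(n))),
         labels = labels)
  })
}

## ---- molecule-level generator -------------------------------------------

# Template grammar: backbone alkyl carbons carrying branch fragments, with
# an optional terminal ring scaffold. All emitted SMILES are valid, single
# fragment, metal-free, and survive standardization unchanged in identity.
.FRAGMENT_GRAMMAR <- list(
  carbamate      = "OC(N)=O",
  nitroso        = "N=O",
  sulfonic_ester = "OS(C)(=O)=O",
  aziridine      = "N1CC1",
  quinone        = "C1=CC(=O)C=CC1=O",
  alkyl_halide   = "CCl"
)
.INERT_FRAGMENTS <- c("C", "CC", "O", "OC", "N", "CCC", "CCO", "C(C)C",
                      "OCC", "CN")
.SCAFFOLDS <- c("c1ccccc1", "C1CCCCC1", "c1ccncc1", "C1CCOC1", "")

#' SMARTS patterns recognizing the generator's planted fragments
#'
#' A [chemotype_set()] whose entries match exactly the fragments the
#' molecule generator can plant; use it to featurize generated datasets.
#' @return A [chemotype_set()].
#' @export
generator_chemotypes <- function() {
  chemotype_set(
    c("carbamate", "nitroso", "sulfonic_ester", "aziridine", "quinone",
      "alkyl_halide"),
    c("[NX3][CX3](=O)[OX2]", "[NX2]=[OX1]",
      "[OX2;$(O[CX4])][SX4](=[OX1])(=[OX1])", "[NX3]1[CX4][CX4]1",
      "O=C1C=CC(=O)C=C1", "[CX4][Cl,Br,I]"))
}

#' Generate a molecule dataset with planted substructure signal
#'
#' Assembles valid SMILES from a template grammar (alkyl backbone, optional
#' benzene / cyclohexane scaffold, inert decorations) and plants functional
#' group fragments (carbamate, nitroso, sulfonic ester, aziridine, quinone,
#' alkyl halide) at the class-conditional prevalences of the spec. Labels
#' are assigned exactly as in [generate_feature_dataset()]. Every emitted
#' SMILES parses and passes [standardize_structure()]; `n_noise_features`
#' is expressed as label-independent inert decorations.
#'
#' @param spec a [synthetic_spec()]; planted names must be among the
#'   grammar's fragments (see [generator_chemotypes()]).
#' @param endpoint endpoint tag for the records (default `"mn_in_vitro"`).
#' @return data.frame of records (`record_id`, `smiles`, `label`,
#'   `endpoint`, `source`) ready for [curate_records()].
#' @export
generate_molecule_dataset <- function(spec, endpoint = "mn_in_vitro") {
  stopifnot(inherits(spec, "synthetic_spec"))
  unknown <- setdiff(vapply(spec$planted, `[[`, "", "name"),
                     names(.FRAGMENT_GRAMMAR))
  if (length(unknown) > 0)
    stop("grammar cannot realize fragment(s): ",
         paste(unknown, collapse = ", "))
  with_seed(spec$seed, {
    n <- spec$n_compounds
    n_pos <- round(n * spec$positive_fraction)
    labels <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
    smiles <- character(n)
    for (i in seq_len(n)) {
      frags <- character(0)
      for (p in spec$planted) {
        prev <- if (labels[i] == 1) p$prev_pos else p$prev_neg
        if (runif(1) < prev)
          frags <- c(frags, .FRAGMENT_GRAMMAR[[p$name]])
      }
      n_inert <- sample(0:2, 1)
      if (n_inert > 0)
        frags <- c(frags, sample(.INERT_FRAGMENTS, n_inert, replace = TRUE))
      scaffold <- sample(.SCAFFOLDS, 1)
      smiles[i] <- assemble_smiles(frags, scaffold)
    }
    if (spec$label_noise_rate > 0) {
      flip <- runif(n) < spec$label_noise_rate
      labels[flip] <- 1L - labels[flip]
    }
    data.frame(record_id = sprintf("syn%05d", seq_len(n)),
               smiles = smiles, label = labels, endpoint = endpoint,
               source = "synthetic_grammar", stringsAsFactors = FALSE)
  })
}

# One backbone carbon per branch fragment (backbone length 2-5), optional
# terminal scaffold: C(frag1)C(frag2)...C[scaffold]
assemble_smiles <- function(frags, scaffold) {
  n_backbone <- max(sample(2:5, 1), length(frags))
  parts <- character(n_backbone)
  for (j in seq_len(n_backbone)) {
    parts[j] <- if (j <= length(frags))
      paste0("C(", frags[j], ")") else "C"
  }
  paste0(paste(parts, collapse = ""), scaffold)
}

#' Specification of paired endpoints
#'
#' One shared compound set with two label vectors: endpoint A follows
#' `spec_a`; endpoint B has its own class balance, and for each planted
#' chemotype the labels of its carriers are drawn so that the expected PPV
#' in B equals the `cross_map` target.
#'
#' @param spec_a a [synthetic_spec()] for endpoint A.
#' @param positive_fraction_b positive fraction of endpoint B.
#' @param cross_map named numeric vector: target PPV in endpoint B per
#'   planted chemotype name (values in `[0, 1]`).
#' @return A list of class `paired_spec`.
#' @export
paired_spec <- function(spec_a, positive_fraction_b, cross_map) {
  stopifnot(inherits(spec_a, "synthetic_spec"))
  if (any(cross_map < 0 | cross_map > 1))
    stop("cross_map PPVs must lie in [0, 1]")
  planted_names <- vapply(spec_a$planted, `[[`, "", "name")
  unknown <- setdiff(names(cross_map), planted_names)
  if (length(unknown) > 0)
    stop("cross_map names not planted in endpoint A: ",
         paste(unknown, collapse = ", "))
  structure(list(spec_a = spec_a,
                 positive_fraction_b = positive_fraction_b,
                 cross_map = cross_map),
            class = "paired_spec")
}

#' Generate paired endpoints with controlled cross-endpoint PPV
#'
#' Generates the shared compound set and endpoint-A labels from
#' `pspec$spec_a`, then draws endpoint-B labels: carriers of a mapped
#' chemotype are positive with probability equal to the target PPV (for
#' compounds carrying several mapped chemotypes, the first in planted order
#' takes precedence); non-carrier labels are then filled so that endpoint
#' B's total positive count matches `positive_fraction_b`. An error is
#' raised when the targets are unattainable at that class balance.
#'
#' @param pspec a [paired_spec()].
#' @return List: `features` (shared binary [feature_matrix()]), `labels_a`,
#'   `labels_b`.
#' @export
generate_paired_endpoints <- function(pspec) {
  stopifnot(inherits(pspec, "paired_spec"))
  ds <- generate_feature_dataset(pspec$spec_a)
  with_seed(pspec$spec_a$seed + 1L, {
    vals <- unclass(ds$features)
    n <- nrow(vals)
    labels_b <- rep(NA_integer_, n)
    mapped <- names(pspec$cross_map)
    # first mapped chemotype carried by each compound, in planted order
    for (ct in mapped) {
      idx <- which(vals[, ct] == 1 & is.na(labels_b))
      if (length(idx) > 0)
        labels_b[idx] <- rbinom(length(idx), 1, pspec$cross_map[[ct]])
    }
    n_pos_b <- round(n * pspec$positive_fraction_b)
    open <- which(is.na(labels_b))
    remaining <- n_pos_b - sum(labels_b, na.rm = TRUE)
    if (remaining < 0 || remaining > length(open))
      stop("cross_map PPV targets unattainable at endpoint B's class balance")
    labels_b[open] <- 0L
    if (remaining > 0)
      labels_b[sample(open, remaining)] <- 1L
    list(features = ds$features, labels_a = ds$labels, labels_b = labels_b)
  })
}
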