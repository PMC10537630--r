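# 1D/2D molecular descriptor battery and descriptor preprocessing.

# Count-type structural descriptors evaluated as unique-SMARTS-match counts.
.COUNT_SMARTS <- c(
  n_atoms_heavy     = "[!#1]",
  n_bonds           = "*~*",
  n_carbon          = "[#6]",
  n_nitrogen        = "[#7]",
  n_oxygen          = "[#8]",
  n_sulfur          = "[#16]",
  n_phosphorus      = "[#15]",
  n_fluorine        = "[F]",
  n_chlorine        = "[Cl]",
  n_bromine         = "[Br]",
  n_iodine          = "[I]",
  n_boron           = "[B]",
  n_silicon         = "[Si]",
  n_halogen         = "[F,Cl,Br,I]",
  n_heteroatom      = "[!#6;!#1]",
  n_aromatic_atoms  = "[a]",
  n_ring_atoms      = "[R]",
  n_ring_bonds      = "[R]~[R]",
  n_sp3_carbon      = "[CX4]",
  n_sp2_carbon      = "[CX3]",
  n_sp_carbon       = "[CX2]",
  n_rotatable_bonds = "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]",
  n_amide           = "[NX3][CX3](=[OX1])",
  n_ester           = "[CX3](=[OX1])[OX2][#6]",
  n_ketone          = "[#6][CX3](=[OX1])[#6]",
  n_nitrile         = "[NX1]#[CX2]",
  n_sulfone         = "[SX4](=[OX1])(=[OX1])",
  n_urea            = "[NX3][CX3](=[OX1])[NX3]",
  n_phenol          = "[c][OX2H]",
  n_aniline_n       = "[c][NX3]",
  n_methyl          = "[CH3]",
  n_quaternary_c    = "[CX4H0]"
)

#' Compute the 1D/2D molecular descriptor battery
#'
#' One row per compound. The battery combines OpenBabel physicochemical
#' properties (molecular weight, exact mass, logP, molar refractivity,
#' topological polar surface area, hydrogen-bond donor/acceptor counts),
#' element / hybridization / ring counts, functional-group counts, the full
#' bundled chemotype counts, and substructure fractions (each group count
#' normalized by heavy-atom count) — roughly one hundred real-valued,
#' deterministic 1D/2D descriptors in the spirit of the standard
#' physicochemical-plus-substructure-fraction batteries used in QSAR work.
#'
#' Molecules for which any descriptor fails to evaluate are excluded from the
#' matrix and listed in the `excluded` attribute (record id + reason).
#'
#' @param records data.frame with `smiles` (standardized) and optional
#'   `record_id`, or a character vector of SMILES.
#' @return A real-valued [feature_matrix()] of kind `"descriptor"`, with
#'   attribute `excluded` (data.frame: `record_id`, `reason`).
#' @examples
#' fm <- compute_descriptors("CCO")
#' fm[, "mw"]  # about 46.07
#' @export
compute_descriptors <- function(records) {
  rec <- as_record_frame(records)
  cts <- default_chemotypes()
  ct_smarts <- setNames(cts$smarts, paste0("ct_", cts$name))
  count_smarts <- c(.COUNT_SMARTS, ct_smarts)

  prop_names <- c("mw", "exact_mass", "logp", "mr", "tpsa",
                  "hba_strict", "hba_loose", "hbd")
  frac_base <- c("n_halogen", "n_heteroatom", "n_aromatic_atoms",
                 "n_ring_atoms", "n_sp3_carbon", "n_rotatable_bonds",
                 names(ct_smarts))
  col_names <- c(prop_names, names(count_smarts),
                 paste0("frac_", sub("^n_", "", frac_base)))

  rows <- vector("list", nrow(rec))
  excluded <- list()
  for (i in seq_len(nrow(rec))) {
    res <- tryCatch(
      descriptor_row(rec$smiles[i], count_smarts, prop_names, frac_base),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      excluded[[length(excluded) + 1]] <-
        data.frame(record_id = rec$record_id[i], reason = res,
                   stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- res
    }
  }
  ok <- !vapply(rows, is.null, logical(1))
  mat <- do.call(rbind, rows[ok])
  if (is.null(mat)) mat <- matrix(numeric(0), nrow = 0, ncol = length(col_names))
  colnames(mat) <- col_names
  fm <- feature_matrix(mat, kind = "descriptor",
                       compound_ids = rec$record_id[ok], binary = FALSE)
  attr(fm, "excluded") <- if (length(excluded) > 0)
    do.call(rbind, excluded) else
      data.frame(record_id = character(0), reason = character(0))
  fm
}

descriptor_row <- function(smiles, count_smarts, prop_names, frac_base) {
  mol <- ob_parse_smiles(smiles)
  if (is.null(mol)) stop("SMILES does not parse: ", smiles)
  p <- ChemmineOB::prop_OB(mol)
  props <- c(mw = as.numeric(p$MW),
             exact_mass = as.numeric(ChemmineOB::exactMass_OB(mol)),
             logp = as.numeric(p$logP),
             mr = as.numeric(p$MR),
             tpsa = as.numeric(p$TPSA),
             hba_strict = as.numeric(p$HBA1),
             hba_loose = as.numeric(p$HBA2),
             hbd = as.numeric(p$HBD))
  if (anyNA(props)) stop("property calculation failed for: ", smiles)
  counts <- vapply(count_smarts, function(sm) ob_smarts_count(mol, sm),
                   numeric(1))
  heavy <- max(counts[["n_atoms_heavy"]], 1)
  fracs <- counts[frac_base] / heavy
  names(fracs) <- paste0("frac_", sub("^n_", "", frac_base))
  c(props[prop_names], counts, fracs)
}

#' Prefilter a descriptor matrix
#'
#' Removes (in this order) constant columns, columns with standard deviation
#' below `std_min`, and, for every pair of remaining columns whose squared
#' Pearson correlation exceeds `r2_max`, the pair member with the larger
#' original column index. Surviving columns keep their original order.
#'
#' @param fm a [feature_matrix()] of kind `"descriptor"`.
#' @param r2_max squared-correlation ceiling (default 0.9).
#' @param std_min standard-deviation floor (default 0.5).
#' @return The filtered [feature_matrix()], with attribute `removed`
#'   (data.frame: `feature`, `reason`).
#' @export
prefilter_descriptors <- function(fm, r2_max = 0.9, std_min = 0.5) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (fm_kind(fm) != "descriptor")
    stop("prefiltering applies to descriptor matrices")
  if (!(r2_max > 0 && r2_max <= 1)) stop("r2_max must be in (0, 1]")
  if (std_min < 0) stop("std_min must be >= 0")
  if (nrow(fm) < 3)
    stop("need at least 3 compounds for correlation prefiltering")
  vals <- unclass(fm)
  sds <- apply(vals, 2, sd)
  drop <- sds == 0
  low <- !drop & sds < std_min
  removed <- data.frame(
    feature = c(colnames(vals)[drop], colnames(vals)[low]),
    reason = c(rep("constant", sum(drop)), rep("low_variance", sum(low))),
    stringsAsFactors = FALSE)
  keep_idx <- which(!(drop | low))

  if (length(keep_idx) >= 2) {
    cm <- suppressWarnings(cor(vals[, keep_idx, drop = FALSE]))
    cm[is.na(cm)] <- 0
    r2 <- cm^2
    alive <- rep(TRUE, length(keep_idx))
    for (i in seq_along(keep_idx)) {
      if (!alive[i]) next
      for (j in seq_along(keep_idx)) {
        if (j <= i || !alive[j]) next
        if (r2[i, j] > r2_max) {
          alive[j] <- FALSE
          removed <- rbind(removed, data.frame(
            feature = colnames(vals)[keep_idx[j]],
            reason = paste0("correlated_with:",
                            colnames(vals)[keep_idx[i]])))
        }
      }
    }
    keep_idx <- keep_idx[alive]
  }
  out <- fm_select(fm, keep_idx)
  attr(out, "removed") <- removed
  out
}
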