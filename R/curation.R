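# Chemical-record curation: structure standardization, rejection of
# non-modelable species, and InChIKey-based deduplication.

# Elements admitted in the organic QSAR subset; anything else counts as a
# metal/metalloid and triggers rejection of the parent structure.
.ORGANIC_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S",
                       "Cl", "Se", "Br", "I")

#' Endpoint tags understood by the pipeline
#' @return Character vector of valid endpoint names.
#' @export
mn_endpoints <- function() c("mn_in_vitro", "mn_in_vivo_mouse", "mn_in_vivo_rat")

#' Standardize a single structure
#'
#' Applies the cleaning rules used to curate micronucleus datasets: the input
#' SMILES is parsed, counter-ion fragments without carbon are stripped (salt
#' stripping), the remaining parent is charge-neutralized where chemically
#' valid, and its canonical SMILES plus full 27-character InChIKey are
#' returned. Structures that cannot enter a QSAR dataset are rejected with a
#' coded reason:
#'
#' * `unparseable` — the SMILES does not parse;
#' * `polymer` — the SMILES contains wildcard/attachment atoms (`*`);
#' * `mixture` — two or more carbon-containing fragments remain after salt
#'   stripping;
#' * `organometallic` — a metal atom (any element outside H, B, C, N, O, F,
#'   Si, P, S, Cl, Se, Br, I) is present in the parent structure;
#' * `inorganic` — no carbon atom is present.
#'
#' Salt stripping keeps the single largest carbon-containing fragment
#' (heavy-atom count, ties by molecular weight, then by lexicographic
#' canonical SMILES). The procedure is deterministic.
#'
#' @param smiles a single non-empty SMILES string.
#' @return A list with `accepted` (logical); on acceptance
#'   `canonical_smiles` and `inchikey`; on rejection `code` (one of
#'   `"mixture"`, `"polymer"`, `"inorganic"`, `"organometallic"`,
#'   `"unparseable"`) and a human-readable `detail`.
#' @examples
#' standardize_structure("CC(=O)[O-].[Na+]")$canonical_smiles  # "CC(=O)O"
#' standardize_structure("CCO.OCC")$code                        # "mixture"
#' @export
standardize_structure <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) ||
      !nzchar(trimws(smiles)))
    stop("'smiles' must be a single non-empty string")
  smiles <- trimws(smiles)

  reject <- function(code, detail)
    list(accepted = FALSE, code = code, detail = detail)

  if (grepl("*", smiles, fixed = TRUE))
    return(reject("polymer", "wildcard atom '*' (repeat unit / attachment point)"))

  can <- ob_canonical_smiles(smiles)
  if (!nzchar(can))
    return(reject("unparseable", paste0("SMILES does not parse: ", smiles)))

  frags <- strsplit(can, ".", fixed = TRUE)[[1]]
  elem_list <- lapply(frags, smiles_elements)
  has_c <- vapply(elem_list, function(e) "C" %in% e, logical(1))
  organic <- frags[has_c]

  if (length(organic) == 0) {
    all_elems <- unique(unlist(elem_list))
    metals <- setdiff(all_elems, .ORGANIC_ELEMENTS)
    if (length(metals) > 0)
      return(reject("organometallic",
                    paste0("metal atom(s) without organic parent: ",
                           paste(metals, collapse = ","))))
    return(reject("inorganic", "no carbon atom present"))
  }
  if (length(organic) >= 2)
    return(reject("mixture",
                  paste0(length(organic), " organic fragments after salt stripping")))

  parent <- organic[1]
  metals <- setdiff(smiles_elements(parent), .ORGANIC_ELEMENTS)
  if (length(metals) > 0)
    return(reject("organometallic",
                  paste0("metal atom(s) in parent: ", paste(metals, collapse = ","))))

  neut <- ob_canonical_smiles(parent, neutralize = TRUE)
  if (!nzchar(neut))
    return(reject("unparseable", paste0("parent fragment does not re-parse: ", parent)))
  key <- ob_inchikey(neut)
  if (nchar(key) != 27)
    return(reject("unparseable", paste0("no InChIKey for: ", neut)))

  list(accepted = TRUE, canonical_smiles = neut, inchikey = key)
}

# Deterministic choice of the parent among several organic fragments would go
# here; with the mixture rule above at most one organic fragment survives, but
# fragment ranking is kept for reuse by callers that relax the mixture rule.
rank_fragments <- function(frags) {
  heavy <- vapply(frags, smiles_heavy_atoms, integer(1))
  mw <- vapply(frags, function(f) {
    m <- ob_parse_smiles(f)
    if (is.null(m)) return(0)
    as.numeric(ChemmineOB::prop_OB(m)$MW)
  }, numeric(1))
  frags[order(-heavy, -mw, frags)]
}

#' Standardize a vector of structures
#'
#' Vectorized wrapper around [standardize_structure()].
#'
#' @param smiles character vector of SMILES.
#' @return A data.frame with one row per input: `smiles`, `accepted`,
#'   `canonical_smiles`, `inchikey`, `code`, `detail` (the last four `NA`
#'   where not applicable).
#' @export
standardize_structures <- function(smiles) {
  rows <- lapply(smiles, function(s) {
    r <- standardize_structure(s)
    data.frame(smiles = s,
               accepted = r$accepted,
               canonical_smiles = if (r$accepted) r$canonical_smiles else NA_character_,
               inchikey = if (r$accepted) r$inchikey else NA_character_,
               code = if (r$accepted) NA_character_ else r$code,
               detail = if (r$accepted) NA_character_ else r$detail,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Deduplicate standardized records by InChIKey
#'
#' One record is retained per (InChIKey, endpoint) pair. Duplicates with the
#' same activity label are merged to a single record. Duplicates with
#' conflicting labels are resolved by `policy`:
#'
#' * `"exclude_conflicts"` — the compound is dropped from the dataset and
#'   logged in the conflict report;
#' * `"prefer_compliant"` — if exactly one of the conflicting records is
#'   marked `guideline_compliant`, that record is kept; otherwise the
#'   compound is dropped and logged.
#'
#' @param records data.frame of standardized records; must contain columns
#'   `record_id`, `inchikey`, `label`, `endpoint` (plus any others, carried
#'   through). A missing/NA `inchikey` is an error: records must be
#'   standardized first.
#' @param policy `"exclude_conflicts"` (default) or `"prefer_compliant"`.
#' @return A list with `curated` (data.frame sorted by InChIKey then
#'   endpoint) and `conflicts` (data.frame: `inchikey`, `endpoint`,
#'   `record_ids`, `labels`, `resolution`).
#' @export
deduplicate_records <- function(records,
                                policy = c("exclude_conflicts", "prefer_compliant")) {
  policy <- match.arg(policy)
  needed <- c("record_id", "inchikey", "label", "endpoint")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0)
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(records) > 0 &&
      (any(is.na(records$inchikey)) || any(!nzchar(records$inchikey))))
    stop("records without InChIKey: standardize structures before deduplication")
  if (nrow(records) > 0 && !all(records$label %in% c(0, 1)))
    stop("labels must be 0 or 1")

  if (nrow(records) == 0)
    return(list(curated = records, conflicts = empty_conflicts()))

  key <- paste(records$inchikey, records$endpoint, sep = "\r")
  keep <- logical(nrow(records))
  conf <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    labs <- unique(records$label[idx])
    if (length(labs) == 1) {
      keep[idx[order(records$record_id[idx])][1]] <- TRUE
    } else {
      resolution <- "excluded"
      if (policy == "prefer_compliant") {
        gc <- records$guideline_compliant[idx]
        if (!is.null(gc)) {
          compliant <- which(!is.na(gc) & gc)
          if (length(compliant) == 1) {
            keep[idx[compliant]] <- TRUE
            resolution <- "kept_compliant"
          }
        }
      }
      conf[[length(conf) + 1]] <- data.frame(
        inchikey = records$inchikey[idx[1]],
        endpoint = records$endpoint[idx[1]],
        record_ids = paste(records$record_id[idx], collapse = ";"),
        labels = paste(records$label[idx], collapse = ";"),
        resolution = resolution,
        stringsAsFactors = FALSE)
    }
  }
  curated <- records[keep, , drop = FALSE]
  curated <- curated[order(curated$inchikey, curated$endpoint), , drop = FALSE]
  rownames(curated) <- NULL
  conflicts <- if (length(conf) > 0) do.call(rbind, conf) else empty_conflicts()
  list(curated = curated, conflicts = conflicts)
}

empty_conflicts <- function() {
  data.frame(inchikey = character(0), endpoint = character(0),
             record_ids = character(0), labels = character(0),
             resolution = character(0), stringsAsFactors = FALSE)
}

#' Curate a raw record table end to end
#'
#' Standardizes every structure ([standardize_structure()]), collects
#' rejections, then deduplicates the accepted records
#' ([deduplicate_records()]). Every input record ends up in exactly one of:
#' the curated set, the rejection report, or the conflict report (records
#' merged as identical duplicates are accounted for by the surviving record).
#' Curation is idempotent: running it on its own output changes nothing.
#'
#' @param records data.frame with at least `smiles`, `label`, `endpoint`;
#'   optional `record_id` (generated when absent), `cas`, `name`, `source`,
#'   `guideline_compliant`.
#' @param policy conflict policy, see [deduplicate_records()].
#' @return A list with `curated` (standardized, deduplicated records with
#'   `canonical_smiles` and `inchikey` columns), `rejections` (data.frame:
#'   `record_id`, `smiles`, `code`, `detail`), `conflicts` (see
#'   [deduplicate_records()]), and `n_merged` (count of identical-label
#'   duplicate records absorbed into a kept record).
#' @export
curate_records <- function(records,
                           policy = c("exclude_conflicts", "prefer_compliant")) {
  policy <- match.arg(policy)
  needed <- c("smiles", "label", "endpoint")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0)
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(records$record_id))
    records$record_id <- sprintf("rec%05d", seq_len(nrow(records)))
  if (anyDuplicated(records$record_id))
    stop("record_id values must be unique")
  bad_ep <- setdiff(unique(records$endpoint), mn_endpoints())
  if (length(bad_ep) > 0)
    stop("unknown endpoint(s): ", paste(bad_ep, collapse = ", "))

  std <- standardize_structures(records$smiles)
  acc <- std$accepted
  rejections <- data.frame(record_id = records$record_id[!acc],
                           smiles = records$smiles[!acc],
                           code = std$code[!acc],
                           detail = std$detail[!acc],
                           stringsAsFactors = FALSE)
  kept <- records[acc, , drop = FALSE]
  kept$canonical_smiles <- std$canonical_smiles[acc]
  kept$smiles <- kept$canonical_smiles
  kept$inchikey <- std$inchikey[acc]

  dd <- deduplicate_records(kept, policy = policy)
  n_conflict_records <- if (nrow(dd$conflicts) > 0)
    sum(lengths(strsplit(dd$conflicts$record_ids, ";", fixed = TRUE)) -
          (dd$conflicts$resolution == "kept_compliant")) else 0L
  n_merged <- nrow(kept) - nrow(dd$curated) - n_conflict_records

  list(curated = dd$curated, rejections = rejections,
       conflicts = dd$conflicts, n_merged = as.integer(n_merged))
}

#' Read a chemical record table from CSV
#'
#' @param path CSV file path.
#' @param col_map named character vector mapping the standard column names
#'   (`smiles`, `label`, `endpoint`, `cas`, `name`, `source`,
#'   `guideline_compliant`) to the file's column names; only non-default
#'   mappings need to be given.
#' @param sep field delimiter (default `","`).
#' @return data.frame ready for [curate_records()].
#' @export
read_molecule_csv <- function(path, col_map = character(0), sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  for (std in names(col_map)) {
    from <- col_map[[std]]
    if (!from %in% names(df)) stop("column not in file: ", from)
    names(df)[names(df) == from] <- std
  }
  needed <- c("smiles", "label", "endpoint")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0)
    stop("CSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  if ("guideline_compliant" %in% names(df))
    df$guideline_compliant <- as.logical(df$guideline_compliant)
  df
}

#' Read chemical records from an SDF file
#'
#' Structures are taken from the connection table; the activity label,
#' endpoint and optional identifiers are read from data-block properties.
#'
#' @param path SDF file path.
#' @param label_prop,endpoint_prop data-block property names holding the
#'   binary label and the endpoint tag.
#' @return data.frame ready for [curate_records()].
#' @export
read_molecule_sdf <- function(path, label_prop = "label",
                              endpoint_prop = "endpoint") {
  sdfs <- ChemmineR::read.SDFset(path)
  smiles <- as.character(ChemmineR::sdf2smiles(sdfs))
  n <- length(sdfs)
  get_prop <- function(i, prop) {
    db <- ChemmineR::datablock(sdfs[[i]])
    if (prop %in% names(db)) db[[prop]] else NA_character_
  }
  data.frame(
    smiles = smiles,
    label = as.numeric(vapply(seq_len(n), get_prop, "", prop = label_prop)),
    endpoint = vapply(seq_len(n), get_prop, "", prop = endpoint_prop),
    stringsAsFactors = FALSE)
}

#' Write curation outputs to CSV
#'
#' @param curation result of [curate_records()].
#' @param curated_path,rejections_path,conflicts_path output file paths;
#'   `NULL` skips that file.
#' @return Invisibly, `curation`.
#' @export
write_curation <- function(curation, curated_path,
                           rejections_path = NULL, conflicts_path = NULL) {
  write.csv(curation$curated, curated_path, row.names = FALSE)
  if (!is.null(rejections_path))
    write.csv(curation$rejections, rejections_path, row.names = FALSE)
  if (!is.null(conflicts_path))
    write.csv(curation$conflicts, conflicts_path, row.names = FALSE)
  invisible(curation)
}
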