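# Thin wrappers around ChemmineOB / OpenBabel used across modules.
# All structure handling (parsing, canonicalization, InChIKey generation,
# neutralization, SMARTS matching, keyed fingerprints) is delegated to
# OpenBabel; these helpers only normalize its calling conventions.

ob_no_options <- function() data.frame(names = character(0), args = character(0))

# Parse one SMILES into an in-memory OpenBabel molecule; NULL on failure.
ob_parse_smiles <- function(smiles) {
  tryCatch(
    suppressWarnings(ChemmineOB::forEachMol("SMILES", smiles, identity)),
    error = function(e) NULL
  )
}

# SMILES -> canonical SMILES ("" if unparseable). `neutralize` applies
# OpenBabel's charge neutralization model (protonate anions / deprotonate
# cations where chemically valid; fixed charges such as quaternary N stay).
ob_canonical_smiles <- function(smiles, neutralize = FALSE) {
  opts <- if (neutralize)
    data.frame(names = "neutralize", args = "") else ob_no_options()
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", smiles, options = opts),
    error = function(e) ""
  )
  sub("[\t\n ]+$", "", out)
}

# SMILES -> 27-character InChIKey ("" if unavailable).
ob_inchikey <- function(smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "INCHIKEY", smiles,
                              options = ob_no_options()),
    error = function(e) ""
  )
  sub("[\t\n ]+$", "", out)
}

# Count of unique SMARTS matches in a parsed molecule.
ob_smarts_count <- function(mol, smarts) {
  as.numeric(ChemmineOB::smartsSearch_OB(mol, smarts, uniqueMatches = TRUE))
}

# Element symbols occurring in one SMILES fragment (as written by OpenBabel's
# canonical writer). Handles bracket atoms, two-letter organic-subset symbols
# and aromatic lowercase symbols.
smiles_elements <- function(frag) {
  elems <- character(0)
  # bracket atoms: [13CH3+], [Na+], [nH], [Pt] ...
  brackets <- regmatches(frag, gregexpr("\\[[^]]*\\]", frag))[[1]]
  for (b in brackets) {
    inner <- sub("^\\[", "", sub("\\]$", "", b))
    inner <- sub("^[0-9]+", "", inner)            # isotope
    sym <- regmatches(inner, regexpr("^[A-Z][a-z]?|^[a-z]", inner))
    if (length(sym) == 1) {
      if (sym %in% c("b", "c", "n", "o", "p", "s", "se", "as"))
        sym <- paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
      elems <- c(elems, sym)
    }
  }
  rest <- gsub("\\[[^]]*\\]", "", frag)
  m <- gregexpr("Cl|Br|B|C|N|O|P|S|F|I|b|c|n|o|p|s", rest)[[1]]
  if (m[1] != -1) {
    toks <- regmatches(rest, list(m))[[1]]
    toks <- ifelse(toks %in% c("b", "c", "n", "o", "p", "s"),
                   toupper(toks), toks)
    elems <- c(elems, toks)
  }
  unique(elems)
}

# Heavy-atom count of a SMILES fragment (all non-H atom tokens).
smiles_heavy_atoms <- function(frag) {
  n <- 0L
  brackets <- regmatches(frag, gregexpr("\\[[^]]*\\]", frag))[[1]]
  for (b in brackets) {
    sym <- regmatches(sub("^\\[[0-9]*", "", b),
                      regexpr("^[A-Z][a-z]?|^[a-z]", sub("^\\[[0-9]*", "", b)))
    if (length(sym) == 1 && !identical(sym, "H")) n <- n + 1L
  }
  rest <- gsub("\\[[^]]*\\]", "", frag)
  m <- gregexpr("Cl|Br|B|C|N|O|P|S|F|I|b|c|n|o|p|s", rest)[[1]]
  if (m[1] != -1) n <- n + length(regmatches(rest, list(m))[[1]])
  n
}
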