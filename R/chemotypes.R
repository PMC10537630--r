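#' Chemotype sets
#'
#' A chemotype set is an ordered collection of named SMARTS substructure
#' patterns used as binary structural features, playing the role that large
#' curated chemotype libraries (e.g. ToxPrint) play in structural-alert
#' analysis. The order of entries is fixed and defines the bit order of
#' chemotype fingerprints.
#'
#' @param names character vector of unique chemotype names.
#' @param smarts character vector of SMARTS patterns, same length as `names`.
#' @return An object of class `chemotype_set`: a data.frame with columns
#'   `name` and `smarts`, in input order.
#' @examples
#' cts <- chemotype_set(c("nitroso", "carbamate"),
#'                      c("[NX2]=[OX1]", "[NX3][CX3](=O)[OX2]"))
#' length(cts$name)
#' @export
chemotype_set <- function(names, smarts) {
  if (length(names) != length(smarts))
    stop("'names' and 'smarts' must have equal length")
  names <- as.character(names)
  smarts <- as.character(smarts)
  if (anyDuplicated(names))
    stop("chemotype names must be unique")
  if (length(smarts) > 0) {
    probe <- ob_parse_smiles("CCO")
    for (i in seq_along(smarts)) {
      ok <- tryCatch({
        ChemmineOB::smartsSearch_OB(probe, smarts[i], uniqueMatches = TRUE)
        TRUE
      }, error = function(e) FALSE)
      if (!ok) stop("SMARTS does not compile: ", names[i], " = ", smarts[i])
    }
  }
  out <- data.frame(name = names, smarts = smarts, stringsAsFactors = FALSE)
  class(out) <- c("chemotype_set", "data.frame")
  out
}

#' Read a chemotype definition file
#'
#' The file format is two tab-separated columns, `name<TAB>SMARTS`, one
#' chemotype per line. Lines starting with `#` and blank lines are ignored.
#'
#' @param path path to the definition file.
#' @return A [chemotype_set()].
#' @export
read_chemotypes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2
  if (any(bad))
    stop("malformed chemotype line(s): ", paste(lines[bad], collapse = "; "))
  chemotype_set(vapply(parts, `[[`, "", 1L),
                vapply(parts, `[[`, "", 2L))
}

#' Bundled genotoxicity-oriented chemotype set
#'
#' Loads the chemotype definitions shipped with the package: ~30 SMARTS
#' patterns for substructures with established genotoxicity relevance
#' (nitroso and nitro groups, carbamates, sulfonic and sulfate esters,
#' epoxides, aziridines, quinones, PAH cores, alkyl halides, Michael
#' acceptors, hydrazines, azo compounds, and common inert scaffolds used as
#' negative controls). This is a generic stand-in for proprietary chemotype
#' libraries; any user-supplied file in the same format can be used instead
#' via [read_chemotypes()].
#'
#' @return A [chemotype_set()].
#' @export
default_chemotypes <- function() {
  read_chemotypes(system.file("extdata", "chemotypes_genotox.tsv",
                              package = "mnqsar", mustWork = TRUE))
}
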