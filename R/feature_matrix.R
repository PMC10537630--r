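#' Feature matrix container
#'
#' A thin wrapper around a numeric matrix (compounds in rows, features in
#' columns) carrying the feature kind and provenance. Binary kinds (all
#' fingerprints) are constrained to 0/1 entries.
#'
#' @param values numeric matrix, one row per compound.
#' @param kind one of `"descriptor"`, `"maccs"`, `"path_fp"`, `"ecfp"`,
#'   `"fcfp"`, `"chemotype"`.
#' @param compound_ids character vector of row identities (defaults to
#'   rownames or generated ids).
#' @param binary logical; defaults to `TRUE` for all fingerprint kinds.
#' @return An object of class `feature_matrix` (a numeric matrix with
#'   attributes `kind`, `binary`, `compound_ids`).
#' @export
feature_matrix <- function(values,
                           kind = c("descriptor", "maccs", "path_fp",
                                    "ecfp", "fcfp", "chemotype"),
                           compound_ids = NULL,
                           binary = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("feature values must be numeric")
  if (anyNA(values)) stop("feature matrix contains missing values")
  if (is.null(binary)) binary <- kind != "descriptor"
  if (binary && nrow(values) > 0 && !all(values %in% c(0, 1)))
    stop("binary feature matrix has entries outside {0,1}")
  if (is.null(compound_ids)) {
    compound_ids <- rownames(values)
    if (is.null(compound_ids))
      compound_ids <- sprintf("cmp%05d", seq_len(nrow(values)))
  }
  if (length(compound_ids) != nrow(values))
    stop("compound_ids length must equal row count")
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("%s_%04d", kind, seq_len(ncol(values)))
  rownames(values) <- compound_ids
  structure(values, kind = kind, binary = binary,
            compound_ids = compound_ids,
            class = c("feature_matrix", "matrix", "array"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> kind=%s  %d compounds x %d features  (%s)\n",
              attr(x, "kind"), nrow(x), ncol(x),
              if (attr(x, "binary")) "binary" else "real-valued"))
  invisible(x)
}

#' Subset a feature matrix
#'
#' Matrix subsetting that keeps the `feature_matrix` class and metadata when
#' the result is still a matrix; single rows/columns drop to plain vectors
#' as with ordinary matrices.
#'
#' @param x a [feature_matrix()].
#' @param i,j row/column indices.
#' @param ... passed to the matrix method.
#' @param drop drop dimensions of single-row/column results (default
#'   `TRUE`).
#' @return A [feature_matrix()] or a plain vector.
#' @export
`[.feature_matrix` <- function(x, i, j, ..., drop = TRUE) {
  m <- unclass(x)
  out <- m[i, j, ..., drop = drop]
  if (!is.matrix(out)) return(out)
  feature_matrix(out, kind = attr(x, "kind"), compound_ids = rownames(out),
                 binary = attr(x, "binary"))
}

fm_kind <- function(fm) attr(fm, "kind")
fm_binary <- function(fm) isTRUE(attr(fm, "binary"))

# Subset columns, keeping class/attributes.
fm_select <- function(fm, cols) {
  feature_matrix(unclass(fm)[, cols, drop = FALSE], kind = fm_kind(fm),
                 compound_ids = attr(fm, "compound_ids"),
                 binary = fm_binary(fm))
}

#' Write / read a feature matrix as CSV
#'
#' The first column holds compound ids; the feature kind is stored in a
#' header comment line.
#' @param fm a [feature_matrix()].
#' @param path file path.
#' @return `write_feature_matrix` returns `fm` invisibly;
#'   `read_feature_matrix` returns a [feature_matrix()].
#' @export
write_feature_matrix <- function(fm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s binary=%s", fm_kind(fm),
                     tolower(fm_binary(fm))), con)
  df <- data.frame(compound_id = attr(fm, "compound_ids"),
                   unclass(fm), check.names = FALSE)
  write.csv(df, con, row.names = FALSE)
  invisible(fm)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  header <- readLines(path, n = 1)
  kind <- sub(".*kind=(\\S+).*", "\\1", header)
  binary <- grepl("binary=true", header)
  df <- read.csv(path, skip = 1, check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  feature_matrix(vals, kind = kind, compound_ids = df[[1]], binary = binary)
}
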