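# Molecular fingerprints: MACCS keys and Daylight-style path fingerprints
# via OpenBabel; hashed circular (ECFP/FCFP-style) fingerprints computed
# natively on the connection table; chemotype fingerprints via SMARTS.

#' Compute a single molecular fingerprint
#'
#' Supported kinds:
#' * `"maccs"` — the 166 public MACCS keys (OpenBabel's RDKit-derived SMARTS
#'   definitions); `radius`/`nbits` are ignored.
#' * `"path_fp"` — Daylight-style hashed linear-path fingerprint (paths up
#'   to 7 atoms, OpenBabel FP2), native length 1024; `nbits` may fold it
#'   down to a power-of-two fraction.
#' * `"ecfp"` — hashed circular fingerprint over atom-environment
#'   identifiers (element, heavy degree, bond-order sum, implicit H count,
#'   ring membership), radius 1-3. The common naming maps diameter to
#'   radius: ECFP2 is radius 1, ECFP4 radius 2, ECFP6 radius 3.
#' * `"fcfp"` — as `"ecfp"` but with pharmacophoric atom roles (donor,
#'   acceptor, aromatic, halogen, formal charge sign) as initial invariants.
#'
#' All fingerprints are deterministic: same input, same bits.
#'
#' @param smiles a single SMILES string (standardized input recommended).
#' @param kind fingerprint family.
#' @param radius circular-neighborhood radius for `ecfp`/`fcfp` (1, 2 or 3).
#' @param nbits hashed fingerprint length for `ecfp`/`fcfp` (default 2048)
#'   and fold target for `path_fp` (default 1024).
#' @return Integer 0/1 vector of the stated length.
#' @examples
#' length(compute_fingerprint("CCO", "maccs"))  # 166
#' @export
compute_fingerprint <- function(smiles,
                                kind = c("maccs", "path_fp", "ecfp", "fcfp"),
                                radius = 2, nbits = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("ecfp", "fcfp")) {
    if (!radius %in% 1:3) stop("radius must be 1, 2 or 3 for ", kind)
    if (is.null(nbits)) nbits <- 2048
    return(morgan_fingerprint(smiles, radius = radius, nbits = nbits,
                              functional = kind == "fcfp"))
  }
  mol <- ob_parse_smiles(smiles)
  if (is.null(mol)) stop("SMILES does not parse: ", smiles)
  if (kind == "maccs") {
    fp <- ChemmineOB::fingerprint_OB(mol, "MACCS")
    return(as.integer(fp[1:166]))
  }
  # path_fp
  fp <- as.integer(ChemmineOB::fingerprint_OB(mol, "FP2"))
  if (is.null(nbits)) nbits <- length(fp)
  fold_bits(fp, nbits)
}

# OR-fold a bit vector down to nbits (nbits must divide its length).
fold_bits <- function(bits, nbits) {
  n <- length(bits)
  if (nbits == n) return(bits)
  if (nbits > n || n %% nbits != 0)
    stop("nbits must be a divisor of the native length ", n)
  folded <- matrix(bits, nrow = nbits)
  as.integer(rowSums(folded) > 0)
}

#' Compute fingerprints for a set of records
#'
#' @param records data.frame with a `smiles` column (and optional
#'   `record_id`), or a character vector of SMILES.
#' @inheritParams compute_fingerprint
#' @return A binary [feature_matrix()] with one row per compound.
#' @export
compute_fingerprints <- function(records, kind = c("maccs", "path_fp",
                                                   "ecfp", "fcfp"),
                                 radius = 2, nbits = NULL) {
  kind <- match.arg(kind)
  rec <- as_record_frame(records)
  rows <- lapply(rec$smiles, compute_fingerprint, kind = kind,
                 radius = radius, nbits = nbits)
  mat <- do.call(rbind, rows)
  if (is.null(mat)) {
    len <- switch(kind, maccs = 166,
                  path_fp = if (is.null(nbits)) 1024 else nbits,
                  if (is.null(nbits)) 2048 else nbits)
    mat <- matrix(integer(0), nrow = 0, ncol = len)
  }
  colnames(mat) <- sprintf("%s_%04d", kind, seq_len(ncol(mat)))
  feature_matrix(mat, kind = kind, compound_ids = rec$record_id)
}

#' Chemotype fingerprint of one molecule
#'
#' Bit *i* is 1 iff chemotype *i* of the set has at least one substructure
#' match in the molecule; the bit order is the set's entry order.
#'
#' @param smiles a single SMILES string.
#' @param cts a [chemotype_set()].
#' @return Integer 0/1 vector of length `nrow(cts)`, named by chemotype.
#' @export
compute_chemotype_fingerprint <- function(smiles, cts) {
  stopifnot(inherits(cts, "chemotype_set"))
  if (nrow(cts) == 0) return(setNames(integer(0), character(0)))
  mol <- ob_parse_smiles(smiles)
  if (is.null(mol)) stop("SMILES does not parse: ", smiles)
  bits <- vapply(cts$smarts,
                 function(sm) as.integer(ob_smarts_count(mol, sm) > 0),
                 integer(1))
  setNames(bits, cts$name)
}

#' Chemotype fingerprint matrix for a set of records
#'
#' @param records data.frame with `smiles` (and optional `record_id`), or a
#'   character vector of SMILES.
#' @param cts a [chemotype_set()]; defaults to the bundled set.
#' @return A binary [feature_matrix()] of kind `"chemotype"` with one column
#'   per chemotype, named by chemotype.
#' @export
compute_chemotype_matrix <- function(records, cts = default_chemotypes()) {
  rec <- as_record_frame(records)
  mat <- matrix(0L, nrow = nrow(rec), ncol = nrow(cts),
                dimnames = list(rec$record_id, cts$name))
  for (i in seq_len(nrow(rec))) {
    mol <- ob_parse_smiles(rec$smiles[i])
    if (is.null(mol)) stop("SMILES does not parse: ", rec$smiles[i])
    for (j in seq_len(nrow(cts)))
      mat[i, j] <- as.integer(ob_smarts_count(mol, cts$smarts[j]) > 0)
  }
  feature_matrix(mat, kind = "chemotype", compound_ids = rec$record_id)
}

# Normalize records input (data.frame or character vector) to a data.frame
# with smiles + record_id.
as_record_frame <- function(records) {
  if (is.character(records)) {
    data.frame(record_id = sprintf("cmp%05d", seq_along(records)),
               smiles = records, stringsAsFactors = FALSE)
  } else {
    if (!"smiles" %in% names(records)) stop("records need a 'smiles' column")
    if (is.null(records$record_id))
      records$record_id <- sprintf("cmp%05d", seq_len(nrow(records)))
    records
  }
}

## ---- native circular (Morgan-style) fingerprint -------------------------

# Standard valences used to infer implicit hydrogen counts from the
# connection table (neutral organic subset).
.STD_VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3,
                  S = 2, Cl = 1, Se = 2, Br = 1, I = 1)

# Parse a SMILES into a simple connection table: elements, bonds (i, j,
# order), ring-membership flags (edges not being bridges are cycle edges).
connection_table <- function(smiles) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  sdf <- if (inherits(sdf, "SDFset")) sdf[[1]] else sdf
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  n <- length(elements)
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0 || ncol(bb) < 3) {
    matrix(numeric(0), ncol = 3)
  } else {
    b <- cbind(as.numeric(bb[, 1]), as.numeric(bb[, 2]), as.numeric(bb[, 3]))
    b[b[, 1] > 0 & b[, 2] > 0, , drop = FALSE]  # drop placeholder rows
  }
  ring_edge <- ring_edges(n, bonds)
  in_ring <- rep(FALSE, n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      if (ring_edge[k]) in_ring[bonds[k, 1:2]] <- TRUE
    }
  }
  list(elements = elements, bonds = bonds, in_ring = in_ring)
}

# Identify cycle edges = edges that are not bridges (iterative DFS).
ring_edges <- function(n, bonds) {
  m <- nrow(bonds)
  if (m == 0) return(logical(0))
  adj <- vector("list", n)
  for (k in seq_len(m)) {
    a <- bonds[k, 1]; b <- bonds[k, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, k))
    adj[[b]] <- rbind(adj[[b]], c(a, k))
  }
  disc <- rep(0L, n); low <- rep(0L, n)
  bridge <- rep(FALSE, m)
  timer <- 0L
  for (root in seq_len(n)) {
    if (disc[root] != 0L) next
    stack <- list(c(root, 0L, 0L))  # vertex, parent-edge, next-neighbor idx
    while (length(stack) > 0) {
      top <- stack[[length(stack)]]
      v <- top[1]; pe <- top[2]; it <- top[3]
      if (it == 0L) {
        timer <- timer + 1L
        disc[v] <- low[v] <- timer
      }
      nb <- adj[[v]]
      advanced <- FALSE
      while (it < NROW(nb)) {
        it <- it + 1L
        w <- nb[it, 1]; ek <- nb[it, 2]
        if (ek == pe) next
        if (disc[w] == 0L) {
          stack[[length(stack)]] <- c(v, pe, it)
          stack[[length(stack) + 1L]] <- c(w, ek, 0L)
          advanced <- TRUE
          break
        } else {
          low[v] <- min(low[v], disc[w])
        }
      }
      if (!advanced) {
        stack[[length(stack)]] <- NULL
        if (pe != 0L) {
          u <- if (bonds[pe, 1] == v) bonds[pe, 2] else bonds[pe, 1]
          low[u] <- min(low[u], low[v])
          if (low[v] > disc[u]) bridge[pe] <- TRUE
        }
      }
    }
  }
  !bridge
}

# Deterministic integer hash of an integer vector (values < 2^31 throughout,
# exact in double arithmetic).
hash_ints <- function(v) {
  x <- 17
  for (val in v) x <- (x * 31 + (val %% 2147483647) + 7) %% 2147483647
  x
}

morgan_fingerprint <- function(smiles, radius, nbits, functional = FALSE) {
  ct <- connection_table(smiles)
  n <- length(ct$elements)
  if (n == 0) stop("empty molecule: ", smiles)
  bonds <- ct$bonds
  deg <- rep(0L, n); bosum <- rep(0, n)
  nbrs <- vector("list", n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      a <- bonds[k, 1]; b <- bonds[k, 2]; o <- bonds[k, 3]
      deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
      bosum[a] <- bosum[a] + o; bosum[b] <- bosum[b] + o
      nbrs[[a]] <- rbind(nbrs[[a]], c(b, o))
      nbrs[[b]] <- rbind(nbrs[[b]], c(a, o))
    }
  }
  valence <- .STD_VALENCE[ct$elements]
  valence[is.na(valence)] <- bosum[is.na(valence)]
  hcount <- pmax(0, valence - bosum)

  ids <- numeric(n)
  for (a in seq_len(n)) {
    el <- ct$elements[a]
    inv <- if (functional) {
      is_n_o <- el %in% c("N", "O")
      has_double <- !is.null(nbrs[[a]]) && any(nbrs[[a]][, 2] >= 2)
      c(as.integer(is_n_o && hcount[a] >= 1),          # donor
        as.integer(is_n_o),                            # acceptor
        as.integer(ct$in_ring[a] && has_double),       # aromatic-like
        as.integer(el %in% c("F", "Cl", "Br", "I")),   # halogen
        0L, 0L)                                        # charge signs
    } else {
      c(match(el, names(.STD_VALENCE), nomatch = 99L), deg[a],
        round(bosum[a]), round(hcount[a]), as.integer(ct$in_ring[a]))
    }
    ids[a] <- hash_ints(inv)
  }

  all_ids <- ids
  for (r in seq_len(radius)) {
    new_ids <- numeric(n)
    for (a in seq_len(n)) {
      nb <- nbrs[[a]]
      payload <- c(r, ids[a])
      if (!is.null(nb) && NROW(nb) > 0) {
        pairs <- cbind(nb[, 2], ids[nb[, 1]])
        ord <- order(pairs[, 1], pairs[, 2])
        payload <- c(payload, t(pairs[ord, , drop = FALSE]))
      }
      new_ids[a] <- hash_ints(round(payload))
    }
    ids <- new_ids
    all_ids <- c(all_ids, ids)
  }
  bits <- integer(nbits)
  bits[unique(all_ids %% nbits) + 1] <- 1L
  bits
}
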