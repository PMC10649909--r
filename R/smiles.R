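# SMILES ingestion and hashed circular (Morgan-type) fingerprints.
#
# SMILES parsing and canonicalization are delegated to Open Babel via
# ChemmineR/ChemmineOB; the circular-environment hashing itself is implemented
# here (deterministic polynomial hashing of iteratively refined atom
# invariants, folded to nbits). Stereochemistry is ignored by construction:
# atom invariants carry element, degree, bond-order sum and ring membership
# only, so "[C@H]" and "/C=C/" flags do not change the bit set.

.element_z <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
  Cl = 17, Se = 34, Br = 35, I = 53
)

atomic_number <- function(sym) {
  z <- .element_z[sym]
  bad <- is.na(z)
  # unknown elements: stable fallback hash of the symbol characters
  if (any(bad)) z[bad] <- vapply(sym[bad],
                                 function(s) 200 + poly_hash(utf8ToInt(s)) %% 800,
                                 numeric(1))
  unname(z)
}

#' Parse a SMILES string into an atom/bond graph (internal)
#'
#' Converts through Open Babel to a V2000 molfile and reads the atom and bond
#' blocks from the counts line (robust to zero-bond molecules).
#'
#' @param smiles a single SMILES string.
#' @return list with `atoms` (element symbols) and `bonds`
#'   (data.frame a, b, order), or an error for unparseable input.
#' @noRd
mol_graph <- function(smiles) {
  sdf <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", smiles),
    error = function(e) stopf("unparseable SMILES '%s'", smiles)
  )
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) stopf("unparseable SMILES '%s'", smiles)
  counts <- lines[grep("V2000", lines)[1]]
  if (is.na(counts)) stopf("unparseable SMILES '%s'", smiles)
  nA <- as.integer(substr(counts, 1, 3))
  nB <- as.integer(substr(counts, 4, 6))
  if (is.na(nA) || nA < 1L) stopf("unparseable SMILES '%s'", smiles)
  off <- grep("V2000", lines)[1]
  atom_lines <- lines[off + seq_len(nA)]
  atoms <- trimws(substr(atom_lines, 32, 34))
  if (nB > 0L) {
    bond_lines <- lines[off + nA + seq_len(nB)]
    bonds <- data.frame(
      a = as.integer(substr(bond_lines, 1, 3)),
      b = as.integer(substr(bond_lines, 4, 6)),
      order = as.integer(substr(bond_lines, 7, 9)))
  } else {
    bonds <- data.frame(a = integer(0), b = integer(0), order = integer(0))
  }
  list(atoms = atoms, bonds = bonds)
}

#' Canonical SMILES via Open Babel (used for deduplication)
#' @noRd
canonical_smiles <- function(smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", smiles),
    error = function(e) stopf("cannot canonicalize SMILES '%s'", smiles)
  )
  out <- trimws(strsplit(out, "\n", fixed = TRUE)[[1]][1])
  if (is.na(out) || !nzchar(out)) stopf("cannot canonicalize SMILES '%s'", smiles)
  out
}

#' Parse a compound table with name and SMILES columns
#'
#' Accepts a path or literal text of a tab-separated table. Column headers are
#' matched case-insensitively ("Molecule Name"/"name"/"compound" and "Smiles");
#' a two-column headerless table is read as (name, smiles). Rows whose SMILES
#' fail to parse are skipped and collected in the `errors` attribute; rows
#' duplicating an earlier canonical SMILES are dropped with a warning.
#'
#' @param x file path, or a character vector of table text lines.
#' @return data.frame with columns `id`, `name`, `smiles`, `canonical_smiles`
#'   and attribute `errors` (data.frame of skipped rows).
#' @export
parse_smiles_table <- function(x) {
  if (length(x) == 1L && file.exists(x)) {
    lines <- readLines(x, encoding = "UTF-8", warn = FALSE)
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE))
  }
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(id = character(0), name = character(0),
                      smiles = character(0), canonical_smiles = character(0),
                      stringsAsFactors = FALSE)
  attr(empty, "errors") <- data.frame(row = integer(0), name = character(0),
                                      message = character(0))
  if (length(lines) == 0L) return(empty)

  df <- utils::read.delim(text = lines, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  lc <- tolower(trimws(names(df)))
  name_col <- which(lc %in% c("molecule name", "name", "molecule", "compound"))[1]
  smi_col <- which(lc %in% c("smiles", "smile", "canonical_smiles"))[1]
  if (is.na(name_col) || is.na(smi_col)) {
    if (ncol(df) >= 2L) {
      # headerless two-column table: re-read without header
      df <- utils::read.delim(text = lines, sep = "\t", header = FALSE,
                              stringsAsFactors = FALSE)
      name_col <- 1L; smi_col <- 2L
    } else {
      stopf("cannot identify name and SMILES columns")
    }
  }
  nm <- trimws(as.character(df[[name_col]]))
  smi <- trimws(as.character(df[[smi_col]]))

  keep <- logical(length(nm))
  canon <- character(length(nm))
  errs <- list()
  for (i in seq_along(nm)) {
    res <- tryCatch({
      mol_graph(smi[i])              # validates parseability
      canonical_smiles(smi[i])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs[[length(errs) + 1L]] <- data.frame(
        row = i, name = nm[i], message = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      keep[i] <- TRUE
      canon[i] <- res
    }
  }
  out <- data.frame(id = make.unique(nm[keep]), name = nm[keep],
                    smiles = smi[keep], canonical_smiles = canon[keep],
                    stringsAsFactors = FALSE)
  dup <- duplicated(out$canonical_smiles)
  if (any(dup)) {
    warnf("dropping %d duplicate compound(s) (same canonical SMILES): %s",
          sum(dup), paste(out$name[dup], collapse = ", "))
    out <- out[!dup, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "errors") <- if (length(errs)) do.call(rbind, errs) else
    data.frame(row = integer(0), name = character(0), message = character(0))
  out
}

#' Hashed circular (Morgan-type) fingerprint of a molecule
#'
#' Implements the ECFP-style construction: an initial per-atom invariant
#' (atomic number, heavy-atom degree, bond-order sum, ring membership) is
#' iteratively refined for `radius` rounds by hashing each atom's invariant
#' together with its sorted (bond order, neighbour invariant) pairs. Each
#' (atom, radius) environment whose bond set grew relative to the previous
#' radius emits an identifier; identifiers are folded modulo `nbits`.
#' Stereochemistry is ignored. Bond orders are as kekulized by Open Babel.
#'
#' @param x a SMILES string, or a row-compatible list/data.frame with a
#'   `smiles` element.
#' @param radius maximum environment radius in bonds (default 2).
#' @param nbits folded bit-vector length (default 2048; use 1024 for the
#'   embedding variant).
#' @return a `csn_fingerprint`.
#' @export
morgan_fingerprint <- function(x, radius = 2L, nbits = 2048L) {
  smiles <- if (is.character(x) && length(x) == 1L) x else x$smiles
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 0L) stopf("radius must be >= 0")
  if (as.integer(nbits) < 64L) stopf("nbits must be >= 64")
  g <- mol_graph(smiles)
  nA <- length(g$atoms)
  nB <- nrow(g$bonds)

  # adjacency with bond ids
  nbr <- vector("list", nA); bord <- vector("list", nA); bid <- vector("list", nA)
  for (i in seq_len(nA)) { nbr[[i]] <- integer(0); bord[[i]] <- integer(0); bid[[i]] <- integer(0) }
  if (nB > 0L) for (e in seq_len(nB)) {
    a <- g$bonds$a[e]; b <- g$bonds$b[e]; o <- g$bonds$order[e]
    nbr[[a]] <- c(nbr[[a]], b); bord[[a]] <- c(bord[[a]], o); bid[[a]] <- c(bid[[a]], e)
    nbr[[b]] <- c(nbr[[b]], a); bord[[b]] <- c(bord[[b]], o); bid[[b]] <- c(bid[[b]], e)
  }

  # ring membership: a bond is in a ring iff it is not a bridge
  in_ring_atom <- rep(FALSE, nA)
  if (nB > 0L) {
    ig <- igraph::graph_from_edgelist(cbind(g$bonds$a, g$bonds$b), directed = FALSE)
    if (igraph::vcount(ig) < nA) ig <- igraph::add_vertices(ig, nA - igraph::vcount(ig))
    br <- igraph::bridges(ig)
    ring_bond <- setdiff(seq_len(nB), as.integer(br))
    in_ring_atom[unique(c(g$bonds$a[ring_bond], g$bonds$b[ring_bond]))] <- TRUE
  }

  z <- atomic_number(g$atoms)
  deg <- lengths(nbr)
  bsum <- vapply(bord, sum, numeric(1))
  inv <- vapply(seq_len(nA), function(i)
    poly_hash(c(z[i], deg[i], bsum[i], as.integer(in_ring_atom[i]))), numeric(1))

  ids <- inv                               # radius-0 identifiers
  bondset <- lapply(seq_len(nA), function(i) integer(0))
  if (radius > 0L && nB > 0L) {
    for (k in seq_len(radius)) {
      new_inv <- numeric(nA)
      new_bondset <- vector("list", nA)
      for (i in seq_len(nA)) {
        if (deg[i] == 0L) { new_inv[i] <- inv[i]; new_bondset[[i]] <- integer(0); next }
        ord <- order(bord[[i]], inv[nbr[[i]]])
        pairs <- as.numeric(rbind(bord[[i]][ord], inv[nbr[[i]]][ord]))
        new_inv[i] <- poly_hash(c(k, inv[i], pairs))
        new_bondset[[i]] <- sort(unique(c(bondset[[i]], bid[[i]],
                                          unlist(bondset[nbr[[i]]]))))
      }
      grew <- vapply(seq_len(nA), function(i)
        length(new_bondset[[i]]) > length(bondset[[i]]), logical(1))
      ids <- c(ids, new_inv[grew])
      inv <- new_inv
      bondset <- new_bondset
    }
  }
  fingerprint(unique(ids %% as.integer(nbits)), nbits)
}

#' Fingerprints for every compound in a parsed SMILES table
#'
#' @param compounds data.frame from [parse_smiles_table()].
#' @inheritParams morgan_fingerprint
#' @return named list of `csn_fingerprint`s (names = compound ids).
#' @export
library_fingerprints <- function(compounds, radius = 2L, nbits = 2048L) {
  fps <- lapply(compounds$smiles, morgan_fingerprint, radius = radius, nbits = nbits)
  names(fps) <- compounds$id
  fps
}
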