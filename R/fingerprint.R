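#' Construct a binary substructure fingerprint
#'
#' A fingerprint is the set of on-bit indices of a hashed binary vector of
#' length `nbits`. Bit indices are 0-based, as is conventional for hashed
#' circular fingerprints.
#'
#' @param on_bits integer vector of 0-based bit indices (duplicates collapsed).
#' @param nbits total bit-vector length (>= 64).
#' @return an object of class `csn_fingerprint`.
#' @export
fingerprint <- function(on_bits, nbits) {
  nbits <- as.integer(nbits)
  if (is.na(nbits) || nbits < 64L) stopf("nbits must be an integer >= 64")
  on_bits <- sort(unique(as.integer(on_bits)))
  if (length(on_bits) && (min(on_bits) < 0L || max(on_bits) >= nbits)) {
    stopf("on_bits must lie in [0, nbits)")
  }
  structure(list(on_bits = on_bits, nbits = nbits), class = "csn_fingerprint")
}

#' @export
print.csn_fingerprint <- function(x, ...) {
  cat(sprintf("<csn_fingerprint: %d/%d bits on>\n", length(x$on_bits), x$nbits))
  invisible(x)
}

#' Dice similarity of two fingerprints
#'
#' Dice(a, b) = 2|a n b| / (|a| + |b|), computed exactly on the on-bit sets.
#' Two empty fingerprints are an error (0/0 is undefined).
#'
#' @param a,b `csn_fingerprint` objects with equal `nbits`.
#' @return a numeric value in \[0, 1\].
#' @export
dice_similarity <- function(a, b) {
  if (!inherits(a, "csn_fingerprint") || !inherits(b, "csn_fingerprint")) {
    stopf("dice_similarity expects csn_fingerprint inputs")
  }
  if (a$nbits != b$nbits) stopf("fingerprints have mismatched nbits (%d vs %d)",
                                a$nbits, b$nbits)
  na <- length(a$on_bits); nb <- length(b$on_bits)
  if (na + nb == 0L) stopf("Dice similarity of two empty fingerprints is undefined")
  2 * length(intersect(a$on_bits, b$on_bits)) / (na + nb)
}

#' Pairwise Dice similarity matrix
#'
#' @param fps a (preferably named) list of `csn_fingerprint`s sharing `nbits`.
#' @return a symmetric n x n matrix with unit diagonal; dimnames taken from
#'   `names(fps)` when present.
#' @export
similarity_matrix <- function(fps) {
  n <- length(fps)
  if (n < 1L) stopf("similarity_matrix needs at least one fingerprint")
  nbits <- vapply(fps, function(f) f$nbits, integer(1))
  if (length(unique(nbits)) != 1L) stopf("all fingerprints must share nbits")
  sizes <- vapply(fps, function(f) length(f$on_bits), integer(1))
  if (any(sizes == 0L)) stopf("empty fingerprint(s) at position(s): %s",
                              paste(which(sizes == 0L), collapse = ", "))
  B <- nbits[1]
  A <- matrix(0, n, B)
  for (i in seq_len(n)) A[i, fps[[i]]$on_bits + 1L] <- 1
  inter <- tcrossprod(A)
  S <- 2 * inter / outer(sizes, sizes, `+`)
  diag(S) <- 1
  ids <- names(fps) %||% as.character(seq_len(n))
  dimnames(S) <- list(ids, ids)
  S
}

# --- hex serialization (bit 0 = least-significant bit of the first byte) ----

#' Serialize fingerprints to a TSV of hex-encoded bit strings
#'
#' Columns: `id`, `nbits`, `hex`. Requires `nbits` divisible by 8.
#' @param fps named list of `csn_fingerprint`s.
#' @param path output file.
#' @export
write_fingerprints <- function(fps, path) {
  ids <- names(fps)
  if (is.null(ids)) stopf("fingerprint list must be named")
  hex <- vapply(fps, fp_to_hex, character(1))
  nb <- vapply(fps, function(f) f$nbits, integer(1))
  write_tsv(data.frame(id = ids, nbits = nb, hex = hex,
                       stringsAsFactors = FALSE), path)
}

#' Read fingerprints from a hex TSV written by [write_fingerprints()]
#' @param path input file.
#' @return named list of `csn_fingerprint`s.
#' @export
read_fingerprints <- function(path) {
  df <- read_tsv(path)
  if (!all(c("id", "nbits", "hex") %in% names(df))) {
    stopf("fingerprint table must have columns id, nbits, hex")
  }
  fps <- Map(hex_to_fp, df$hex, df$nbits)
  names(fps) <- df$id
  fps
}

fp_to_hex <- function(fp) {
  if (fp$nbits %% 8L != 0L) stopf("hex serialization requires nbits divisible by 8")
  bits <- integer(fp$nbits)
  bits[fp$on_bits + 1L] <- 1L
  paste(format(packBits(as.raw(bits), type = "raw")), collapse = "")
}

hex_to_fp <- function(hex, nbits) {
  bytes <- as.raw(strtoi(substring(hex, seq(1, nchar(hex), 2),
                                   seq(2, nchar(hex), 2)), 16L))
  bits <- as.integer(rawToBits(bytes))
  fingerprint(which(bits[seq_len(nbits)] == 1L) - 1L, nbits)
}

#' Write a similarity matrix as TSV (row ids in the first column)
#' @param s similarity matrix from [similarity_matrix()].
#' @param path output file.
#' @export
write_similarity_matrix <- function(s, path) {
  df <- data.frame(id = rownames(s), as.data.frame(s, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}
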