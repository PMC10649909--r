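# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Dice on two logical bit vectors, straight from the set formula.
dice_oracle <- function(bits_a, bits_b) {
  2 * sum(bits_a & bits_b) / (sum(bits_a) + sum(bits_b))
}

fp_to_logical <- function(fp) {
  v <- logical(fp$nbits)
  v[fp$on_bits + 1L] <- TRUE
  v
}

random_fp <- function(nbits = 256L, density = 0.1) {
  repeat {
    on <- which(stats::runif(nbits) < density) - 1L
    if (length(on)) return(fingerprint(on, nbits))
  }
}

# MWGS by direct substitution: per member, sum its similarities to every
# cluster member (self included), subtract 1, divide by cluster size.
mwgs_oracle <- function(members, s) {
  vapply(members, function(i) {
    total <- 0
    for (j in members) total <- total + s[i, j]
    (total - 1) / length(members)
  }, numeric(1))
}

# Exhaustive maximal-clique enumeration and MCC over all vertex subsets of a
# small graph given as an adjacency matrix (n <= 16). Uses bitmask arithmetic.
mcc_oracle <- function(adj) {
  n <- nrow(adj)
  stopifnot(n <= 16)
  nodes <- rownames(adj) %||% as.character(seq_len(n))
  nbr_mask <- vapply(seq_len(n), function(v)
    sum(bitwShiftL(1L, which(adj[v, ] != 0) - 1L)), numeric(1))
  is_clique <- function(mask) {
    vs <- which(bitwAnd(bitwShiftL(1L, seq_len(n) - 1L), mask) != 0L)
    for (v in vs) {
      need <- bitwAnd(mask, bitwNot(bitwShiftL(1L, v - 1L)))
      if (bitwAnd(nbr_mask[v], need) != need) return(FALSE)
    }
    TRUE
  }
  cliques <- list()
  for (mask in seq_len(2^n - 1)) {
    if (!is_clique(mask)) next
    # maximal iff no outside vertex is adjacent to every member
    maximal <- TRUE
    for (w in seq_len(n)) {
      wbit <- bitwShiftL(1L, w - 1L)
      if (bitwAnd(mask, wbit) != 0L) next
      if (bitwAnd(nbr_mask[w], mask) == mask) { maximal <- FALSE; break }
    }
    if (maximal) cliques[[length(cliques) + 1L]] <- mask
  }
  scores <- stats::setNames(numeric(n), nodes)
  clique_sets <- list()
  for (mask in cliques) {
    vs <- which(bitwAnd(bitwShiftL(1L, seq_len(n) - 1L), mask) != 0L)
    clique_sets[[length(clique_sets) + 1L]] <- sort(nodes[vs])
    if (length(vs) >= 2L) {
      scores[vs] <- scores[vs] + factorial(length(vs) - 1L)
    }
  }
  list(scores = scores, cliques = clique_sets)
}

random_adj <- function(n, p) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
  }
  rownames(adj) <- colnames(adj) <- sprintf("V%02d", seq_len(n))
  adj
}

adj_to_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# Hypergeometric upper tail by exhaustive enumeration of all draws: the
# universe is 1..N with 1..K annotated; enumerate every n-subset.
hypergeom_oracle <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# BH step-up with explicit cummin, independent of stats::p.adjust.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / rev(seq_len(m))))[ro]
}

# Partition ARI without mclust (used where Suggests should not be required);
# mclust::adjustedRandIndex is the cross-check where available.
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  stot <- ch2(sum(tab))
  expected <- si * sj / stot
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)
  (sij - expected) / denom
}

# Shared fixtures -------------------------------------------------------------

licorice_table_path <- function() {
  system.file("extdata", "licorice_compounds.tsv", package = "csnpharm",
              mustWork = TRUE)
}

# Recovered planted-compound partition for one simulation seed.
planted_partition <- function(seed, flip_rate, ...) {
  cfg <- sim_config(seed = seed, flip_rate = flip_rate, ...)
  lib <- gen_compound_library(cfg)
  s <- similarity_matrix(lib$fingerprints)
  emb <- embed_2d(lib$fingerprints, seed = seed)
  cl <- cluster_csn(build_csn(emb, s), s)
  memb <- stats::setNames(cl$report$cluster, cl$report$id)
  planted <- names(lib$labels)[lib$labels > 0]
  list(found = memb[planted], truth = lib$labels[planted])
}
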