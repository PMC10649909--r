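# Exact t-SNE on a precomputed distance matrix.
#
# O(n^2) implementation suitable for compound libraries of up to a few
# hundred molecules: per-point perplexity calibration by bisection on the
# Gaussian bandwidth, early exaggeration, momentum gradient descent on the
# Student-t low-dimensional affinities. Deterministic given the seed.

#' @noRd
tsne_precomputed <- function(D, perplexity, seed, dims = 2L, max_iter = 500L,
                             eta = NULL, exaggeration = 12, exag_iter = 250L,
                             Y0 = NULL) {
  n <- nrow(D)
  if (n < 3L) stopf("t-SNE needs at least 3 points")
  if (perplexity >= n) stopf("perplexity must be < number of points")
  if (perplexity < 1) perplexity <- 1
  # moderate fixed rate: large rates intermittently blow the layout up for
  # libraries with many exact-duplicate rows
  if (is.null(eta)) eta <- 20
  D2 <- D^2
  logU <- log(perplexity)

  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1; betamin <- -Inf; betamax <- Inf
    for (it in seq_len(64L)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { H <- 0; p <- rep(1 / length(di), length(di)) }
      else {
        p <- w / sw
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      diff <- H - logU
      if (abs(diff) < 1e-5) break
      if (diff > 0) {                   # entropy too high -> sharpen
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  Y <- Y0 %||% with_seed(seed, matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims))
  G <- matrix(0, n, dims)               # momentum buffer
  gains <- matrix(1, n, dims)
  Pe <- P * exaggeration
  for (iter in seq_len(max_iter)) {
    Pit <- if (iter <= exag_iter) Pe else P
    mom <- if (iter <= exag_iter) 0.5 else 0.8
    sq <- rowSums(Y^2)
    num <- 1 / (1 + outer(sq, sq, `+`) - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Pit - Q) * num
    grad <- 4 * (diag(rowSums(W)) %*% Y - W %*% Y)
    gains <- pmax(0.01, ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8))
    G <- mom * G - eta * gains * grad
    stepn <- sqrt(rowSums(G^2))          # guardrail against runaway steps
    G <- G * pmin(1, 5 / pmax(stepn, 1e-300))
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' Embed a fingerprint library in two dimensions by t-SNE
#'
#' Distances are 1 - Dice on the supplied fingerprints (conventionally the
#' 1024-bit embedding variant), or a caller-provided distance matrix.
#' Identical seeds give identical coordinates. The layout is initialized from
#' a per-compound hash of (seed, id), so the result is invariant to the row
#' order of the input, not just to the seed.
#'
#' @param fps named list of `csn_fingerprint`s (ignored when `dist` is given,
#'   except for ids).
#' @param seed integer RNG seed for the layout initialization (required).
#' @param perplexity t-SNE perplexity; default `min(30, (n - 1) / 3)`.
#' @param dist optional precomputed symmetric distance matrix with dimnames
#'   (e.g. 1 - Dice on 2048-bit fingerprints).
#' @param max_iter gradient-descent iterations (default 500: 250
#'   exaggerated + 250 plain, ample for library-scale inputs).
#' @return object of class `csn_embedding`: list with `coords` (n x 2 matrix,
#'   rownames = compound ids), `seed`, `perplexity`.
#' @export
embed_2d <- function(fps = NULL, seed, perplexity = NULL, dist = NULL,
                     max_iter = 500L) {
  if (missing(seed) || is.null(seed)) stopf("embed_2d requires an explicit seed")
  if (is.null(dist)) {
    if (is.null(fps)) stopf("supply fingerprints or a distance matrix")
    S <- similarity_matrix(fps)
    dist <- 1 - S
  }
  n <- nrow(dist)
  if (n < 3L) stopf("embedding needs at least 3 compounds")
  ids <- rownames(dist) %||% as.character(seq_len(n))
  if (is.null(perplexity)) perplexity <- min(30, (n - 1) / 3)
  if (perplexity >= n) stopf("perplexity (%.1f) must be < n (%d)", perplexity, n)
  # canonical id order: the layout is bit-identical for any input row order
  ord <- order(ids)
  ids <- ids[ord]
  dist <- dist[ord, ord, drop = FALSE]
  Y0 <- hash_init(ids, seed)
  Y <- tsne_precomputed(as.matrix(dist), perplexity, seed, max_iter = max_iter,
                        Y0 = Y0)
  rownames(Y) <- ids
  colnames(Y) <- c("x", "y")
  structure(list(coords = Y, seed = as.integer(seed), perplexity = perplexity),
            class = "csn_embedding")
}

#' @export
print.csn_embedding <- function(x, ...) {
  cat(sprintf("<csn_embedding: %d compounds, perplexity %.1f, seed %d>\n",
              nrow(x$coords), x$perplexity, x$seed))
  invisible(x)
}

# Deterministic, permutation-equivariant layout init: each compound's start
# position depends only on (seed, id).
hash_init <- function(ids, seed, sd = 1e-4) {
  m <- 2147483647
  u <- vapply(ids, function(id) {
    h1 <- poly_hash(c(seed, 1, utf8ToInt(id)))
    h2 <- poly_hash(c(seed, 2, utf8ToInt(id)))
    c((h1 + 0.5) / m, (h2 + 0.5) / m)
  }, numeric(2))
  matrix(stats::qnorm(t(u)) * sd, ncol = 2)
}

#' Write an embedding as TSV (id, x, y, seed)
#' @param e a `csn_embedding`.
#' @param path output file.
#' @export
write_embedding <- function(e, path) {
  write_tsv(data.frame(id = rownames(e$coords), x = e$coords[, 1],
                       y = e$coords[, 2], seed = e$seed,
                       stringsAsFactors = FALSE), path)
}
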