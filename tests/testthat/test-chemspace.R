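# Embedding, chemical-space network, clustering and member scoring.

fake_embedding <- function(coords) {
  ids <- rownames(coords)
  structure(list(coords = coords, seed = 0L, perplexity = 1), class = "csn_embedding")
}

ones_simmat <- function(ids) {
  s <- matrix(1, length(ids), length(ids), dimnames = list(ids, ids))
  s
}

test_that("embedding is sized, seeded and row-order invariant", {
  cfg <- sim_config(seed = 2, n_clusters = 2, members_per_cluster = 5,
                    n_background = 2)
  lib <- gen_compound_library(cfg)
  e1 <- embed_2d(lib$fingerprints, seed = 42)
  expect_equal(nrow(e1$coords), 12L)
  expect_true(all(is.finite(e1$coords)))
  e2 <- embed_2d(lib$fingerprints, seed = 42)
  expect_identical(e1$coords, e2$coords)
  e3 <- embed_2d(lib$fingerprints, seed = 43)
  expect_false(identical(e1$coords, e3$coords))
  # permuting the input changes nothing once rows are matched by id
  perm <- rev(seq_along(lib$fingerprints))
  e4 <- embed_2d(lib$fingerprints[perm], seed = 42)
  expect_identical(e1$coords[order(rownames(e1$coords)), ],
                   e4$coords[order(rownames(e4$coords)), ])
  expect_error(embed_2d(lib$fingerprints[1:2], seed = 1), "at least 3")
  expect_error(embed_2d(lib$fingerprints, seed = 1, perplexity = 50),
               "perplexity")
  expect_error(embed_2d(lib$fingerprints), "seed")
})

test_that("duplicated compounds embed closer than the bulk", {
  # two Dice-identical compounds among 20 land in the closest pair tail
  hits <- 0
  for (seed in 1:20) {
    cfg <- sim_config(seed = seed, n_clusters = 1, members_per_cluster = 2,
                      n_background = 18, flip_rate = 0)
    lib <- gen_compound_library(cfg)
    e <- embed_2d(lib$fingerprints, seed = seed)
    D <- as.matrix(dist(e$coords))
    dups <- names(lib$labels)[lib$labels == 1]
    ddup <- D[dups[1], dups[2]]
    q05 <- stats::quantile(D[upper.tri(D)], 0.05)
    hits <- hits + (ddup <= q05)
  }
  expect_gte(hits / 20, 0.95)
})

test_that("the network applies the strict D_max/24 edge rule", {
  # two points exactly 24 apart: theta = 1 and 24 >= 1, so no edge
  co <- matrix(c(0, 0, 24, 0), 2, 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("x", "y")))
  net <- build_csn(fake_embedding(co), ones_simmat(c("a", "b")))
  expect_equal(net$theta, 1)
  expect_equal(nrow(net$edges), 0L)
  # unit square: D_max = sqrt(2), theta = sqrt(2)/24 < 1 <= all distances
  sq <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), 4, 2, byrow = TRUE,
               dimnames = list(letters[1:4], c("x", "y")))
  net2 <- build_csn(fake_embedding(sq), ones_simmat(letters[1:4]))
  expect_equal(net2$theta, sqrt(2) / 24)
  expect_equal(nrow(net2$edges), 0L)
  expect_error(build_csn(fake_embedding(co[1, , drop = FALSE]),
                         ones_simmat("a")), "at least 2")
})

test_that("edges match a brute-force all-pairs threshold check", {
  set.seed(31)
  for (rep in 1:3) {
    n <- 50
    ids <- sprintf("m%02d", 1:n)
    co <- matrix(stats::rnorm(2 * n, sd = 3), n, 2,
                 dimnames = list(ids, c("x", "y")))
    s <- ones_simmat(ids) * 0.5; diag(s) <- 1
    net <- build_csn(fake_embedding(co), s)
    D <- as.matrix(dist(co))
    want <- data.frame()
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (D[i, j] < max(D) / 24) {
        want <- rbind(want, data.frame(from = ids[i], to = ids[j]))
      }
    }
    got <- net$edges[order(net$edges$from, net$edges$to), c("from", "to")]
    if (nrow(want)) {
      want <- want[order(want$from, want$to), ]
      expect_equal(got, want, ignore_attr = TRUE)
    } else {
      expect_equal(nrow(got), 0L)
    }
    # every edge carries the matching Dice weight
    if (nrow(net$edges)) {
      expect_true(all(net$edges$dice ==
                        s[cbind(net$edges$from, net$edges$to)]))
    }
  }
})

test_that("clusters are connected components, deterministically ordered", {
  ids <- letters[1:5]
  co <- matrix(c(0, 0, 100, 0, 200, 0, 300, 0, 400, 0), 5, 2, byrow = TRUE,
               dimnames = list(ids, c("x", "y")))
  net <- build_csn(fake_embedding(co), ones_simmat(ids))
  cl <- cluster_components(net)
  expect_length(cl, 5L)
  expect_true(all(vapply(cl, `[[`, integer(1), "n") == 1L))
  # path a-b, b-c plus far d: transitive closure joins {a, b, c}
  co2 <- matrix(c(0, 0, 1, 0, 2, 0, 200, 0), 4, 2, byrow = TRUE,
                dimnames = list(letters[1:4], c("x", "y")))
  net2 <- build_csn(fake_embedding(co2), ones_simmat(letters[1:4]))
  cl2 <- cluster_components(net2)
  expect_equal(cl2[[1]]$members, c("a", "b", "c"))
  expect_equal(cl2[[2]]$members, "d")
})

test_that("MWGS matches hand substitution and its bounds", {
  ids <- c("p", "q", "r")
  s <- ones_simmat(ids)
  s["p", "q"] <- s["q", "p"] <- 0.9
  s["p", "r"] <- s["r", "p"] <- 0.8
  s["q", "r"] <- s["r", "q"] <- 0.7
  cl <- list(members = ids)
  got <- mwgs_scores(cl, s)
  expect_equal(got[["p"]], (1 + 0.9 + 0.8 - 1) / 3)
  expect_equal(got[["q"]], (1 + 0.9 + 0.7 - 1) / 3)
  expect_equal(got[["r"]], (1 + 0.8 + 0.7 - 1) / 3)
  expect_equal(unname(got), unname(mwgs_oracle(ids, s)), tolerance = 1e-12)
  # singleton scores zero; a Dice-0.8 pair scores 0.4 each
  expect_equal(unname(mwgs_scores(list(members = "p"), s)), 0)
  s2 <- matrix(c(1, .8, .8, 1), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(unname(mwgs_scores(list(members = c("x", "y")), s2)), c(.4, .4))
  # perfect cluster attains the (n-1)/n ceiling, never 1
  expect_equal(unname(mwgs_scores(cl, ones_simmat(ids))), rep(2 / 3, 3))
  expect_error(mwgs_scores(list(members = c("p", "zz")), s), "missing")
})

test_that("closeness uses Wasserman-Faust scaling across components", {
  # P3 plus an isolated node
  g <- igraph::make_graph(~ a - b, b - c) + igraph::vertices("iso")
  fake_net <- list(graph = g)
  got <- closeness_scores(fake_net)
  n <- 4 # total nodes
  k <- 3 # component size
  expect_equal(got[["b"]], ((k - 1) / (n - 1)) * ((k - 1) / 2))
  expect_equal(got[["a"]], ((k - 1) / (n - 1)) * ((k - 1) / 3))
  expect_equal(got[["iso"]], 0)
  # star K1,4 alone: centre 1, leaves 4/7
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("ctr", paste0("l", 1:4))
  got2 <- closeness_scores(list(graph = star))
  expect_equal(got2[["ctr"]], 1)
  expect_equal(unname(got2[paste0("l", 1:4)]), rep(4 / 7, 4))
  expect_true(all(got2 >= 0 & got2 <= 1))
})

test_that("representative selection follows closeness, MWGS, then id", {
  cl <- list(members = c("a", "b", "c"), n = 3L, cluster = 1L)
  clo <- c(a = 0.5, b = 0.9, c = 0.7)
  mw <- c(a = 0.1, b = 0.2, c = 0.3)
  expect_equal(select_representative(cl, clo, mw)$representative, "b")
  # closeness tie broken by MWGS
  clo2 <- c(a = 0.9, b = 0.9, c = 0.1)
  mw2 <- c(a = 0.4, b = 0.5, c = 0.9)
  sel <- select_representative(cl, clo2, mw2)
  expect_equal(sel$representative, "b")
  expect_equal(sel$representative_mwgs, "c")
  # full tie falls back to the lexicographically smallest id
  expect_equal(select_representative(cl, c(a = 1, b = 1, c = 1),
                                     c(a = 1, b = 1, c = 1))$representative, "a")
  singleton <- list(members = "z", n = 1L, cluster = 2L)
  expect_equal(select_representative(singleton, c(z = 0), c(z = 0))$representative,
               "z")
})

test_that("planted families are recovered and degrade monotonically with noise", {
  p0 <- planted_partition(seed = 1, flip_rate = 0)
  expect_equal(ari_oracle(p0$found, p0$truth), 1.0)
  # the hand-rolled ARI agrees with the reference implementation
  expect_equal(ari_oracle(p0$found, p0$truth),
               mclust::adjustedRandIndex(p0$found, p0$truth))
  set.seed(99)
  x <- sample(3, 40, replace = TRUE); y <- sample(4, 40, replace = TRUE)
  expect_equal(ari_oracle(x, y), mclust::adjustedRandIndex(x, y))
  # heavier flipping never helps on average (3 seeds per rate here; the
  # acceptance suite runs the full Monte Carlo)
  mean_ari <- function(eps) {
    mean(vapply(1:3, function(s) {
      p <- planted_partition(seed = s, flip_rate = eps)
      ari_oracle(p$found, p$truth)
    }, numeric(1)))
  }
  a <- vapply(c(0, 0.1, 0.5), mean_ari, numeric(1))
  expect_true(all(diff(a) <= 1e-9))
  expect_equal(a[[1]], 1.0)
})

test_that("network exports are written and re-readable", {
  cfg <- sim_config(seed = 2, n_clusters = 2, members_per_cluster = 5,
                    n_background = 0)
  lib <- gen_compound_library(cfg)
  s <- similarity_matrix(lib$fingerprints)
  net <- build_csn(embed_2d(lib$fingerprints, seed = 2), s)
  gml <- tempfile(fileext = ".graphml")
  etsv <- tempfile(fileext = ".tsv")
  write_csn(net, gml, etsv)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 10)
  edges <- utils::read.delim(etsv)
  expect_equal(nrow(edges), nrow(net$edges))
  unlink(c(gml, etsv))
})
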