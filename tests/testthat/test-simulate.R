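# Synthetic-data generators: shapes, planted structure, determinism.

test_that("configuration invariants are enforced", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(flip_rate = 1.2), "flip_rate")
  expect_error(sim_config(bit_density = -0.1), "bit_density")
  expect_error(sim_config(planted_correlation = 1.5), "planted_correlation")
  expect_error(sim_config(core_size = 30, target_set_size = 20), "core_size")
  expect_error(sim_config(clique_size = 1), "clique_size")
  expect_error(sim_config(clique_size = 500, n_ppi_nodes = 100), "exceeds")
  expect_error(sim_config(n_samples = 3), "n_samples")
  expect_error(sim_config(nbits = 32), "nbits")
  expect_error(sim_config(bit_density = 1e-5), "rho")
})

test_that("compound library has the configured shape and labels", {
  cfg <- sim_config(seed = 2, n_clusters = 3, members_per_cluster = 5,
                    n_background = 0)
  lib <- gen_compound_library(cfg)
  expect_length(lib$fingerprints, 15L)
  expect_equal(unname(table(lib$labels)), rep(5L, 3), ignore_attr = TRUE)
  # with background: 0-labelled extras, density-matched prototypes
  cfg2 <- sim_config(seed = 2, n_clusters = 2, members_per_cluster = 4,
                     n_background = 3)
  lib2 <- gen_compound_library(cfg2)
  expect_length(lib2$fingerprints, 11L)
  expect_equal(sum(lib2$labels == 0), 3L)
})

test_that("zero flip rate gives identical copies within each cluster", {
  cfg <- sim_config(seed = 4, flip_rate = 0, n_clusters = 3,
                    members_per_cluster = 4, n_background = 0)
  lib <- gen_compound_library(cfg)
  s <- similarity_matrix(lib$fingerprints)
  for (k in 1:3) {
    members <- names(lib$labels)[lib$labels == k]
    expect_equal(unname(s[members, members]),
                 matrix(1, 4, 4), ignore_attr = TRUE)
  }
})

test_that("mean intra-cluster Dice matches the closed-form expectation", {
  # Under independent per-bit flips, a prototype bit (prob rho) stays on in a
  # member with prob (1-eps) and an off bit turns on with prob eps, so
  #   E|X ^ Y| = B(rho(1-eps)^2 + (1-rho)eps^2),  E|X| = B(rho(1-eps)+(1-rho)eps)
  # and mean Dice ~ 2 E|X^Y| / (E|X| + E|Y|) to first order.
  B <- 2048; rho <- 0.02; eps <- 0.01
  e_inter <- B * (rho * (1 - eps)^2 + (1 - rho) * eps^2)
  e_size <- B * (rho * (1 - eps) + (1 - rho) * eps)
  expected <- 2 * e_inter / (2 * e_size)
  dices <- c()
  for (seed in 1:10) {
    cfg <- sim_config(seed = seed, nbits = B, bit_density = rho,
                      flip_rate = eps, n_clusters = 3,
                      members_per_cluster = 8, n_background = 0)
    lib <- gen_compound_library(cfg)
    s <- similarity_matrix(lib$fingerprints)
    for (k in 1:3) {
      m <- names(lib$labels)[lib$labels == k]
      sub <- s[m, m]
      dices <- c(dices, sub[upper.tri(sub)])
    }
  }
  expect_equal(mean(dices), expected, tolerance = 0.02)
})

test_that("target tables share exactly the planted core", {
  cfg <- sim_config(seed = 3)
  tt <- gen_target_tables(cfg)
  expect_length(tt$core, 17L)
  expect_identical(Reduce(intersect, tt$target_sets), tt$core)
  expect_true(all(lengths(tt$target_sets) == 25L))
  # a zero core empties the all-compound intersection
  tt0 <- gen_target_tables(sim_config(seed = 3, core_size = 0))
  expect_length(Reduce(intersect, tt0$target_sets), 0L)
})

test_that("disease and DE tables recover the planted genes through filtering", {
  cfg <- sim_config(seed = 5)
  tt <- gen_target_tables(cfg)
  surv <- filter_disease_genes(tt$disease_table)
  expect_setequal(surv, toupper(tt$disease_genes))
  cons <- consensus_deg(tt$deg_table, k = 3)
  expect_setequal(union(cons$up, cons$down), toupper(tt$disease_genes))
})

test_that("PPI generator plants an exact clique and no self-loops", {
  cfg <- sim_config(seed = 1, noise_edge_prob = 0, clique_size = 4,
                    n_ppi_nodes = 10)
  ppi <- gen_ppi_graph(cfg)
  expect_equal(nrow(ppi$edges), choose(4, 2))
  expect_true(all(ppi$edges$geneA != ppi$edges$geneB))
  g <- load_ppi(ppi$edges, min_confidence = 0)
  scores <- mcc_scores(g)$scores
  expect_equal(unname(scores[ppi$clique]), rep(factorial(3), 4))
  # minimal clique: a single edge scores 1 at both endpoints
  ppi2 <- gen_ppi_graph(sim_config(seed = 1, noise_edge_prob = 0,
                                   clique_size = 2, n_ppi_nodes = 5))
  s2 <- mcc_scores(load_ppi(ppi2$edges, min_confidence = 0))$scores
  expect_equal(unname(s2[ppi2$clique]), c(1, 1))
})

test_that("expression generator plants exact and noisy correlation", {
  cfg <- sim_config(seed = 6, planted_correlation = 1)
  ex <- gen_expression_matrix(cfg)
  for (g in ex$planted) {
    expect_equal(stats::cor(ex$expr[, ex$query], ex$expr[, g]), 1.0)
  }
  # shape: S x (genes + query)
  cfg2 <- sim_config(seed = 6, n_samples = 4, n_genes_expr = 3,
                     n_planted_corr = 2)
  ex2 <- gen_expression_matrix(cfg2)
  expect_equal(dim(ex2$expr), c(4L, 4L))
  # null: mean |r| over non-planted genes close to E|r| for S samples
  cfg3 <- sim_config(seed = 7, n_samples = 200, n_genes_expr = 400,
                     n_planted_corr = 0, planted_correlation = 0)
  ex3 <- gen_expression_matrix(cfg3)
  r <- as.numeric(stats::cor(ex3$expr[, ex3$query], ex3$expr[, -1]))
  # E|r| under the null ~ sqrt(2 / (pi S))
  expect_equal(mean(abs(r)), sqrt(2 / (pi * 200)), tolerance = 0.1)
})

test_that("generators are deterministic and stream-isolated", {
  cfg <- sim_config(seed = 9)
  expect_identical(gen_compound_library(cfg), gen_compound_library(cfg))
  expect_identical(gen_target_tables(cfg), gen_target_tables(cfg))
  expect_identical(gen_ppi_graph(cfg), gen_ppi_graph(cfg))
  expect_identical(gen_expression_matrix(cfg), gen_expression_matrix(cfg))
  # changing the expression stream's parameters never perturbs the compounds
  cfg2 <- sim_config(seed = 9, n_samples = 90)
  expect_identical(gen_compound_library(cfg)$fingerprints,
                   gen_compound_library(cfg2)$fingerprints)
})

test_that("a written bundle is byte-identical across runs", {
  cfg <- sim_config(seed = 11, n_clusters = 2, members_per_cluster = 4,
                    n_background = 2, gene_universe = 200,
                    target_set_size = 10, core_size = 5, n_ppi_nodes = 30,
                    n_samples = 10, n_genes_expr = 20, n_terms = 10,
                    term_size = 20)
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  unlink(c(d1, d2), recursive = TRUE)
  write_synthetic_bundle(cfg, d1)
  write_synthetic_bundle(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})
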