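# Synthetic-data generators with planted ground truth.
#
# Every input class the pipeline consumes can be generated offline: a
# fingerprint library with planted cluster structure, per-compound target sets
# sharing a planted core, scored disease-gene tables, three-method DE call
# tables, a PPI graph with a planted clique, annotation tables with a planted
# enriched term, and an expression matrix with a planted correlated gene set.
# One global seed expands into fixed per-stream child seeds (compounds, genes,
# graph, expression, annotation), so adding a stream never perturbs another.

#' Simulation configuration
#'
#' Defaults describe the study conditions the generators emulate: a
#' library-scale natural-product retrieval (6 structural families of 10
#' compounds at 2048 bits, bit density 0.02, flip rate 0.01, plus 10
#' unrelated background compounds -- the scale at which a global
#' distance-threshold rule on a 2-D embedding resolves families),
#' 7 query compounds whose
#' liver-disease target sets of 25 genes share a 17-gene core inside a
#' 2000-gene universe, a PPI graph of 100 proteins with a planted 6-clique and
#' 1% noise edges, and a 50-sample expression matrix with 10 genes correlated
#' at 0.6 with the query gene.
#'
#' @param seed global integer seed, recorded in every output artifact.
#' @param n_clusters,members_per_cluster,n_background compound library shape.
#' @param nbits,bit_density,flip_rate fingerprint length B, prototype on-bit
#'   probability rho, and per-bit member flip probability epsilon.
#' @param gene_universe,n_compound_sets,target_set_size,core_size target-table
#'   shape; the all-compound intersection is exactly `core_size` genes.
#' @param n_ppi_nodes,clique_size,noise_edge_prob PPI graph shape.
#' @param n_samples,n_genes_expr,n_planted_corr,planted_correlation expression
#'   matrix shape; planted genes have population correlation
#'   `planted_correlation` with the query gene.
#' @param n_terms,term_size,enrichment_fold annotation table shape for the
#'   planted enriched term.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_clusters = 6L, members_per_cluster = 10L,
                       n_background = 10L,
                       nbits = 2048L, bit_density = 0.02, flip_rate = 0.01,
                       gene_universe = 2000L, n_compound_sets = 7L,
                       target_set_size = 25L, core_size = 17L,
                       n_ppi_nodes = 100L, clique_size = 6L,
                       noise_edge_prob = 0.01,
                       n_samples = 50L, n_genes_expr = 200L,
                       n_planted_corr = 10L, planted_correlation = 0.6,
                       n_terms = 50L, term_size = 80L, enrichment_fold = 5) {
  cfg <- list(seed = as.integer(seed),
              n_clusters = as.integer(n_clusters),
              members_per_cluster = as.integer(members_per_cluster),
              n_background = as.integer(n_background),
              nbits = as.integer(nbits), bit_density = bit_density,
              flip_rate = flip_rate,
              gene_universe = as.integer(gene_universe),
              n_compound_sets = as.integer(n_compound_sets),
              target_set_size = as.integer(target_set_size),
              core_size = as.integer(core_size),
              n_ppi_nodes = as.integer(n_ppi_nodes),
              clique_size = as.integer(clique_size),
              noise_edge_prob = noise_edge_prob,
              n_samples = as.integer(n_samples),
              n_genes_expr = as.integer(n_genes_expr),
              n_planted_corr = as.integer(n_planted_corr),
              planted_correlation = planted_correlation,
              n_terms = as.integer(n_terms), term_size = as.integer(term_size),
              enrichment_fold = enrichment_fold)
  for (p in c("bit_density", "flip_rate", "noise_edge_prob")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stopf("%s must be in [0, 1]", p)
  }
  if (abs(cfg$planted_correlation) > 1) stopf("planted_correlation must be in [-1, 1]")
  counts <- c("n_clusters", "members_per_cluster", "nbits", "gene_universe",
              "n_compound_sets", "target_set_size", "n_ppi_nodes",
              "clique_size", "n_samples", "n_genes_expr", "n_terms", "term_size")
  for (p in counts) if (cfg[[p]] < 1L) stopf("%s must be >= 1", p)
  if (cfg$n_background < 0L) stopf("n_background must be >= 0")
  if (cfg$core_size < 0L) stopf("core_size must be >= 0")
  if (cfg$nbits < 64L) stopf("nbits must be >= 64")
  if (cfg$bit_density * cfg$nbits < 1) stopf("expected on-bits (rho * B) must be >= 1")
  if (cfg$core_size > cfg$target_set_size) stopf("core_size exceeds target_set_size")
  if (cfg$target_set_size > cfg$gene_universe) stopf("target_set_size exceeds gene universe")
  if (cfg$clique_size < 2L) stopf("clique_size must be >= 2")
  if (cfg$clique_size > cfg$n_ppi_nodes) stopf("clique_size exceeds n_ppi_nodes")
  if (cfg$n_samples < 4L) stopf("n_samples must be >= 4")
  structure(cfg, class = "sim_config")
}

sample_nonempty_bits <- function(B, p) {
  repeat {
    bits <- which(stats::runif(B) < p)
    if (length(bits)) return(bits)
  }
}

#' Generate a fingerprint library with planted cluster structure
#'
#' Each of K clusters is built from a prototype bit set (every bit on with
#' probability rho); each member copies the prototype and flips every bit
#' independently with probability epsilon. Background compounds are fresh
#' independent prototypes (density-matched, so they are not trivially
#' separable). Empty fingerprints are redrawn.
#'
#' @param config a [sim_config()].
#' @return list with `fingerprints` (named list of `csn_fingerprint`s),
#'   `labels` (named integer vector; 0 = background), `seed`.
#' @export
gen_compound_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  B <- config$nbits; rho <- config$bit_density; eps <- config$flip_rate
  with_seed(child_seed(config$seed, "compounds"), {
    fps <- list(); labels <- integer(0)
    for (k in seq_len(config$n_clusters)) {
      proto <- logical(B)
      proto[sample_nonempty_bits(B, rho)] <- TRUE
      for (m in seq_len(config$members_per_cluster)) {
        repeat {
          flip <- stats::runif(B) < eps
          bits <- xor(proto, flip)
          if (any(bits)) break
        }
        id <- sprintf("CPD_K%02d_M%02d", k, m)
        fps[[id]] <- fingerprint(which(bits) - 1L, B)
        labels[id] <- k
      }
    }
    for (b in seq_len(config$n_background)) {
      id <- sprintf("CPD_BG_%03d", b)
      fps[[id]] <- fingerprint(sample_nonempty_bits(B, rho) - 1L, B)
      labels[id] <- 0L
    }
    list(fingerprints = fps, labels = labels, seed = config$seed)
  })
}

gene_names <- function(n) sprintf("G%05d", seq_len(n))

#' Generate per-compound target sets, disease score tables and a DE table
#'
#' The `n_compound_sets` per-compound target sets share exactly `core_size`
#' planted genes (any non-core gene falling into every set by chance is
#' resampled). All target genes are planted as disease genes (scored above the
#' source thresholds: > 0.1 in disgenet, > 5 in genecards, all kept in
#' pharmgkb) and as consistently-called DE genes in all three methods; decoy
#' genes score below the thresholds or are called by fewer methods.
#'
#' @param config a [sim_config()].
#' @return list with `universe`, `core`, `target_sets` (named list),
#'   `disease_genes`, `disease_table` (gene, score, source), `deg_table`
#'   (gene, log2fc, pvalue, direction, method), `deg_direction`, `seed`.
#' @export
gen_target_tables <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, "genes"), {
    universe <- gene_names(config$gene_universe)
    core <- sort(sample(universe, config$core_size))
    n_extra <- config$target_set_size - config$core_size
    pool <- setdiff(universe, core)
    sets <- lapply(seq_len(config$n_compound_sets), function(i)
      sort(c(core, sample(pool, n_extra))))
    names(sets) <- sprintf("LC%s", LETTERS[seq_len(config$n_compound_sets)])
    # enforce: all-set intersection is exactly the planted core
    if (config$n_compound_sets >= 2L && n_extra > 0L) {
      repeat {
        inter <- Reduce(intersect, sets)
        stray <- setdiff(inter, core)
        if (!length(stray)) break
        for (g in stray) {
          avoid <- unique(c(unlist(sets), core))
          sets[[1]] <- sort(c(setdiff(sets[[1]], g),
                              sample(setdiff(pool, avoid), 1L)))
        }
      }
    }

    disease_genes <- sort(unique(unlist(sets)))
    n_decoy <- max(2L * length(disease_genes), 50L)
    decoys <- sample(setdiff(universe, disease_genes),
                     min(n_decoy, config$gene_universe - length(disease_genes)))
    src <- c("disgenet", "genecards", "pharmgkb")
    rows <- list()
    for (g in disease_genes) {
      for (s in sample(src, sample(1:3, 1))) {
        score <- switch(s,
          disgenet = stats::runif(1, 0.15, 0.95),
          genecards = stats::runif(1, 6, 60),
          pharmgkb = stats::runif(1, 0, 1))
        rows[[length(rows) + 1L]] <- data.frame(gene = g, score = score,
                                                source = s)
      }
    }
    for (g in decoys) {
      s <- sample(c("disgenet", "genecards"), 1)  # below-threshold decoys
      score <- switch(s, disgenet = stats::runif(1, 0, 0.1),
                      genecards = stats::runif(1, 0, 5))
      rows[[length(rows) + 1L]] <- data.frame(gene = g, score = score,
                                              source = s)
    }
    disease_table <- do.call(rbind, rows)

    # DE calls: every disease gene consistently in all 3 methods; decoys in 1-2
    methods <- c("edger", "deseq2", "limma")
    direction <- stats::setNames(sample(c("up", "down"), length(disease_genes),
                                        replace = TRUE), disease_genes)
    deg <- list()
    for (g in disease_genes) {
      lfc <- stats::runif(1, 1, 4) * if (direction[g] == "up") 1 else -1
      for (m in methods) {
        deg[[length(deg) + 1L]] <- data.frame(
          gene = g, log2fc = lfc + stats::rnorm(1, 0, 0.1),
          pvalue = stats::runif(1, 0, 0.01), direction = direction[[g]],
          method = m)
      }
    }
    for (g in decoys) {
      d <- sample(c("up", "down"), 1)
      lfc <- stats::runif(1, 1, 3) * if (d == "up") 1 else -1
      for (m in sample(methods, sample(1:2, 1))) {
        deg[[length(deg) + 1L]] <- data.frame(
          gene = g, log2fc = lfc, pvalue = stats::runif(1, 0, 0.05),
          direction = d, method = m)
      }
    }
    deg_table <- do.call(rbind, deg)
    # fix direction signs to match log2fc where noise crossed zero
    deg_table$direction <- ifelse(deg_table$log2fc >= 0, "up", "down")

    list(universe = universe, core = core, target_sets = sets,
         disease_genes = disease_genes, disease_table = disease_table,
         deg_table = deg_table,
         deg_direction = ifelse(
           vapply(split(deg_table$log2fc, deg_table$gene), mean, 0) >= 0,
           "up", "down"),
         seed = config$seed)
  })
}

#' Generate a PPI graph with a planted clique plus noise edges
#'
#' A clique on `clique_size` named proteins, plus Erdos-Renyi noise edges with
#' probability `noise_edge_prob` over all remaining pairs. No self-loops.
#' Clique edges carry confidence 0.9; noise edges uniform in \[0.4, 0.9\].
#'
#' @param config a [sim_config()].
#' @return list with `edges` (data.frame geneA, geneB, combined_score),
#'   `clique` (planted member names), `nodes`, `seed`.
#' @export
gen_ppi_graph <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, "graph"), {
    n <- config$n_ppi_nodes; c <- config$clique_size
    nodes <- sprintf("PROT%03d", seq_len(n))
    clique <- nodes[seq_len(c)]
    pairs <- utils::combn(n, 2)
    in_clique <- pairs[1, ] <= c & pairs[2, ] <= c
    noise <- !in_clique & stats::runif(ncol(pairs)) < config$noise_edge_prob
    keep <- in_clique | noise
    edges <- data.frame(
      geneA = nodes[pairs[1, keep]], geneB = nodes[pairs[2, keep]],
      combined_score = ifelse(in_clique[keep], 0.9,
                              round(stats::runif(sum(keep), 0.4, 0.9), 3)),
      stringsAsFactors = FALSE)
    list(edges = edges, clique = clique, nodes = nodes, seed = config$seed)
  })
}

#' Generate an expression matrix with a planted correlated gene set
#'
#' The query gene is standard normal across samples; each planted gene is
#' `rho_g * query + sqrt(1 - rho_g^2) * noise` (bivariate-normal construction,
#' population correlation exactly `planted_correlation`); all other genes are
#' independent standard normals.
#'
#' @param config a [sim_config()].
#' @param query name of the query gene column (default "NOS2").
#' @return list with `expr` (samples x genes matrix, query included as first
#'   column), `query`, `planted` (names of correlated genes), `seed`.
#' @export
gen_expression_matrix <- function(config, query = "NOS2") {
  stopifnot(inherits(config, "sim_config"))
  rho <- config$planted_correlation
  with_seed(child_seed(config$seed, "expression"), {
    S <- config$n_samples; G <- config$n_genes_expr
    np <- min(config$n_planted_corr, G)
    q <- stats::rnorm(S)
    planted <- sprintf("CORR%03d", seq_len(np))
    others <- sprintf("RAND%03d", seq_len(G - np))
    M <- matrix(stats::rnorm(S * G), S, G)
    colnames(M) <- c(planted, others)
    if (np > 0) {
      M[, planted] <- rho * q + sqrt(1 - rho^2) * M[, planted, drop = FALSE]
    }
    expr <- cbind(matrix(q, S, 1, dimnames = list(NULL, query)), M)
    rownames(expr) <- sprintf("S%03d", seq_len(S))
    list(expr = expr, query = query, planted = planted, seed = config$seed)
  })
}

#' Generate a term-annotation table with one planted enriched term
#'
#' Terms are random gene sets of size `term_size` from the universe; the
#' planted term instead contains `enrichment_fold` times the null-expected
#' number of study genes (capped at the study and term sizes).
#'
#' @param config a [sim_config()].
#' @param universe character vector of universe genes.
#' @param study character vector of study genes (subset of universe).
#' @return list with `annotation` (named list term -> genes), `planted_term`,
#'   `seed`.
#' @export
gen_annotation <- function(config, universe, study) {
  stopifnot(inherits(config, "sim_config"))
  study <- intersect(study, universe)
  with_seed(child_seed(config$seed, "annotation"), {
    K <- min(config$term_size, length(universe))
    terms <- lapply(seq_len(config$n_terms), function(i) sort(sample(universe, K)))
    names(terms) <- sprintf("TERM%03d", seq_len(config$n_terms))
    expected <- length(study) * K / length(universe)
    k_plant <- min(length(study), K, max(1L, round(config$enrichment_fold * expected)))
    hit <- sample(study, k_plant)
    filler <- sample(setdiff(universe, study), K - k_plant)
    planted <- "TERM_PLANTED"
    terms[[planted]] <- sort(c(hit, filler))
    list(annotation = terms, planted_term = planted, seed = config$seed)
  })
}

#' Write a full synthetic input bundle plus a ground-truth sidecar
#'
#' Writes all files the pipeline reads (fingerprint TSV, compound labels,
#' disease scores, DE table, per-compound target sets, PPI edge list,
#' annotation table, expression TSV) plus `ground_truth.json` recording every
#' planted structure and the seed, and `sim_config.json` with the resolved
#' configuration.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the written file paths plus the ground
#'   truth.
#' @export
write_synthetic_bundle <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lib <- gen_compound_library(config)
  tt <- gen_target_tables(config)
  ppi <- gen_ppi_graph(config)
  expr <- gen_expression_matrix(config)
  study <- sort(unique(unlist(tt$target_sets)))
  ann <- gen_annotation(config, tt$universe, study)

  paths <- list(
    fingerprints = file.path(dir, "fingerprints.tsv"),
    labels = file.path(dir, "compound_labels.tsv"),
    disease = file.path(dir, "disease_scores.tsv"),
    deg = file.path(dir, "deg_table.tsv"),
    targets = file.path(dir, "compound_targets.tsv"),
    ppi = file.path(dir, "ppi_edges.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    expression = file.path(dir, "expression.tsv"),
    ground_truth = file.path(dir, "ground_truth.json"),
    config = file.path(dir, "sim_config.json"))

  write_fingerprints(lib$fingerprints, paths$fingerprints)
  write_tsv(data.frame(id = names(lib$labels), cluster = unname(lib$labels)),
            paths$labels)
  write_tsv(tt$disease_table, paths$disease)
  write_tsv(tt$deg_table, paths$deg)
  write_tsv(do.call(rbind, lapply(names(tt$target_sets), function(cmp)
    data.frame(compound = cmp, gene = tt$target_sets[[cmp]]))), paths$targets)
  write_tsv(ppi$edges, paths$ppi)
  write_tsv(do.call(rbind, lapply(names(ann$annotation), function(tm)
    data.frame(term = tm, gene = ann$annotation[[tm]]))), paths$annotation)
  expr_df <- data.frame(sample = rownames(expr$expr), expr$expr,
                        check.names = FALSE)
  write_tsv(expr_df, paths$expression)

  truth <- list(seed = config$seed,
                cluster_labels = as.list(lib$labels),
                core_genes = tt$core,
                target_sets = tt$target_sets,
                disease_genes = tt$disease_genes,
                clique = ppi$clique,
                planted_corr_genes = expr$planted,
                planted_term = ann$planted_term,
                query_gene = expr$query)
  jsonlite::write_json(truth, paths$ground_truth, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(config), paths$config, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(truth = truth)))
}
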