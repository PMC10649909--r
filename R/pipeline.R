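# End-to-end orchestration: resolve a configuration, run the stages in
# dependency order, write standard artifacts and a summary JSON.

.default_config <- list(
  # inputs (NULL = stage skipped where optional)
  smiles_table = NULL, fingerprint_table = NULL,
  disease_table = NULL, deg_table = NULL, compound_targets = NULL,
  ppi_edges = NULL, annotation = NULL, expression = NULL, descriptors = NULL,
  # parameters (the pipeline's fixed constants)
  seed = 1L, radius = 2L, nbits_similarity = 2048L, nbits_embedding = 1024L,
  perplexity = NULL, threshold_divisor = 24, top_k = 10L,
  p_cutoff = 0.01, q_cutoff = 0.01,
  score_thresholds = list(), deg_consensus_k = 3L, min_confidence = 0.4,
  query_gene = "NOS2",
  outdir = "csnpharm_out",
  # simulation section
  sim = list())

#' Resolve a pipeline configuration
#'
#' @param x NULL (defaults), a named list of overrides, or a path to a YAML or
#'   JSON configuration file.
#' @param ... further overrides applied on top.
#' @return a resolved configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(x = NULL, ...) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stopf("config file not found: %s", x)
    x <- if (grepl("\\.ya?ml$", x, ignore.case = TRUE)) {
      yaml::read_yaml(x)
    } else {
      jsonlite::read_json(x, simplifyVector = TRUE)
    }
  }
  cfg <- utils::modifyList(.default_config, as.list(x %||% list()))
  cfg <- utils::modifyList(cfg, list(...))
  if (cfg$threshold_divisor <= 0) stopf("threshold_divisor must be > 0")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

pipeline_log <- function(verbose, stage, fmt, ...) {
  if (isTRUE(verbose)) {
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
}

stage_error <- function(stage, e) {
  stopf("stage '%s' failed: %s", stage, conditionMessage(e))
}

require_input <- function(path, what, stage) {
  if (is.null(path)) stopf("stage '%s' needs input '%s'", stage, what)
  if (is.character(path) && !file.exists(path)) {
    stopf("stage '%s': input file not found: %s", stage, path)
  }
  path
}

#' Run the chemical-space clustering stage
#'
#' Parses the SMILES table (or reads a fingerprint table), computes the
#' similarity-variant and embedding-variant fingerprints, embeds, builds the
#' thresholded chemical-space network, clusters and scores. Deterministic for
#' a fixed seed.
#'
#' @param config a [pipeline_config()] (or anything it accepts).
#' @param verbose log stage progress to stderr.
#' @return invisibly, list with `compounds`, `simmat`, `embedding`, `net`,
#'   `clusters`, `report` and the output paths.
#' @export
run_cluster <- function(config = NULL, verbose = FALSE) {
  cfg <- pipeline_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  res <- tryCatch({
    if (!is.null(cfg$smiles_table)) {
      require_input(cfg$smiles_table, "smiles_table", "cluster")
      compounds <- parse_smiles_table(cfg$smiles_table)
      pipeline_log(verbose, "cluster", "parsed %d compounds", nrow(compounds))
      fps_sim <- library_fingerprints(compounds, cfg$radius, cfg$nbits_similarity)
      fps_emb <- library_fingerprints(compounds, cfg$radius, cfg$nbits_embedding)
    } else {
      require_input(cfg$fingerprint_table, "smiles_table/fingerprint_table",
                    "cluster")
      fps_sim <- read_fingerprints(cfg$fingerprint_table)
      fps_emb <- fps_sim
      compounds <- data.frame(id = names(fps_sim), stringsAsFactors = FALSE)
    }
    simmat <- similarity_matrix(fps_sim)
    emb <- embed_2d(fps_emb, seed = cfg$seed, perplexity = cfg$perplexity)
    net <- build_csn(emb, simmat, divisor = cfg$threshold_divisor)
    cl <- cluster_csn(net, simmat)
    pipeline_log(verbose, "cluster", "%d clusters from %d compounds",
                 length(cl$clusters), length(net$ids))
    paths <- list(embedding = file.path(cfg$outdir, "embedding.tsv"),
                  edges = file.path(cfg$outdir, "csn_edges.tsv"),
                  graphml = file.path(cfg$outdir, "csn.graphml"),
                  report = file.path(cfg$outdir, "cluster_report.tsv"))
    write_embedding(emb, paths$embedding)
    write_csn(net, paths$graphml, paths$edges)
    write_tsv(cl$report, paths$report)
    list(compounds = compounds, simmat = simmat, embedding = emb, net = net,
         clusters = cl$clusters, report = cl$report, paths = paths)
  }, error = function(e) stage_error("cluster", e))
  invisible(res)
}

#' Generate a synthetic input bundle for the pipeline
#'
#' Front end to the synthetic-data generators: writes every input file
#' [run_full()] reads, plus the ground-truth sidecar.
#'
#' @param config a [pipeline_config()] whose `sim` section (and `seed`) feed
#'   [sim_config()].
#' @param verbose log to stderr.
#' @return invisibly, the written paths and ground truth (see
#'   [write_synthetic_bundle()]).
#' @export
simulate_bundle <- function(config = NULL, verbose = FALSE) {
  cfg <- pipeline_config(config)
  sim <- do.call(sim_config, utils::modifyList(list(seed = cfg$seed),
                                               as.list(cfg$sim %||% list())))
  pipeline_log(verbose, "simulate", "writing bundle to %s (seed %d)",
               cfg$outdir, sim$seed)
  invisible(write_synthetic_bundle(sim, cfg$outdir))
}

#' Configuration pointing a pipeline run at a synthetic bundle
#'
#' @param dir directory written by [simulate_bundle()].
#' @param ... overrides passed to [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
bundle_config <- function(dir, ...) {
  pipeline_config(list(
    fingerprint_table = file.path(dir, "fingerprints.tsv"),
    disease_table = file.path(dir, "disease_scores.tsv"),
    deg_table = file.path(dir, "deg_table.tsv"),
    compound_targets = file.path(dir, "compound_targets.tsv"),
    ppi_edges = file.path(dir, "ppi_edges.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    expression = file.path(dir, "expression.tsv")), ...)
}

#' Run the full pipeline
#'
#' Stages run in dependency order: cluster -> targets -> ppi hubs ->
#' enrichment -> correlation -> descriptors. A stage whose (optional) inputs
#' are missing is skipped with a warning; the configured stages' outputs and a
#' `summary.json` (counts and seeds) are written to `outdir`.
#'
#' @param config a [pipeline_config()] (or anything it accepts).
#' @param verbose log stage progress to stderr.
#' @return invisibly, a list of per-stage results plus `summary`.
#' @export
run_full <- function(config = NULL, verbose = FALSE) {
  cfg <- pipeline_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  summary <- list(seed = cfg$seed)

  # -- cluster ----------------------------------------------------------------
  if (!is.null(cfg$smiles_table) || !is.null(cfg$fingerprint_table)) {
    results$cluster <- run_cluster(cfg, verbose = verbose)
    summary$n_compounds <- length(results$cluster$net$ids)
    summary$n_clusters <- length(results$cluster$clusters)
    summary$representatives <- vapply(results$cluster$clusters,
                                      `[[`, character(1), "representative")
  } else {
    warnf("cluster stage skipped: no smiles_table or fingerprint_table")
  }

  # -- targets ----------------------------------------------------------------
  have_targets <- !is.null(cfg$disease_table) && !is.null(cfg$deg_table) &&
    !is.null(cfg$compound_targets)
  disease <- degs <- NULL
  if (have_targets) {
    results$targets <- tryCatch({
      disease_df <- read_tsv(require_input(cfg$disease_table, "disease_table",
                                           "targets"))
      deg_df <- read_tsv(require_input(cfg$deg_table, "deg_table", "targets"))
      tgt_df <- read_tsv(require_input(cfg$compound_targets, "compound_targets",
                                       "targets"))
      disease <- filter_disease_genes(disease_df, cfg$score_thresholds)
      cons <- consensus_deg(deg_df, cfg$deg_consensus_k)
      degs <- sort(union(cons$up, cons$down))
      sets <- lapply(split(tgt_df$gene, tgt_df$compound), as_gene_set)
      inter <- lapply(sets, compound_disease_intersection, disease = disease,
                      degs = degs)
      core <- if (length(inter) >= 2L) common_core(inter) else inter[[1]]
      report <- data.frame(
        compound = names(sets), n_targets = lengths(sets),
        n_intersection = lengths(inter),
        genes = vapply(inter, paste, character(1), collapse = ","),
        stringsAsFactors = FALSE)
      write_tsv(report, file.path(cfg$outdir, "intersection_report.tsv"))
      writeLines(core, file.path(cfg$outdir, "core_genes.txt"))
      pipeline_log(verbose, "targets",
                   "%d disease genes, %d consensus DEGs, core of %d",
                   length(disease), length(degs), length(core))
      list(disease = disease, degs = cons, intersections = inter, core = core,
           report = report)
    }, error = function(e) stage_error("targets", e))
    summary$n_disease_genes <- length(results$targets$disease)
    summary$n_deg_up <- length(results$targets$degs$up)
    summary$n_deg_down <- length(results$targets$degs$down)
    summary$intersection_sizes <- lengths(results$targets$intersections)
    summary$core_size <- length(results$targets$core)
    summary$core_genes <- results$targets$core
  } else {
    warnf("targets stage skipped: disease_table, deg_table or compound_targets missing")
  }

  # -- ppi hubs ---------------------------------------------------------------
  if (!is.null(cfg$ppi_edges)) {
    results$hubs <- tryCatch({
      paths <- cfg$ppi_edges
      if (!is.list(paths) && length(paths) == 1L) {
        paths <- stats::setNames(list(paths), "all")
      }
      per <- lapply(paths, function(p) {
        g <- load_ppi(require_input(p, "ppi_edges", "hubs"), cfg$min_confidence)
        top_k_hubs(mcc_scores(g), cfg$top_k)
      })
      union_df <- hub_union(per)
      write_tsv(union_df, file.path(cfg$outdir, "hub_union.tsv"))
      for (nm in names(per)) {
        write_hub_report(per[[nm]], file.path(cfg$outdir,
                                              sprintf("hubs_%s.tsv", nm)))
      }
      pipeline_log(verbose, "hubs", "hub union of %d genes", nrow(union_df))
      list(per_compound = per, union = union_df)
    }, error = function(e) stage_error("hubs", e))
    summary$hub_union_size <- nrow(results$hubs$union)
  } else {
    warnf("hubs stage skipped: ppi_edges missing")
  }

  # -- enrichment -------------------------------------------------------------
  if (!is.null(cfg$annotation) && !is.null(results$targets)) {
    results$enrichment <- tryCatch({
      ann <- read_annotation(require_input(cfg$annotation, "annotation",
                                           "enrichment"))
      universe <- as_gene_set(unlist(ann))
      study <- sort(unique(unlist(results$targets$intersections)))
      enr <- suppressWarnings(
        enrich(study, ann, universe, cfg$p_cutoff, cfg$q_cutoff))
      write_tsv(enr, file.path(cfg$outdir, "enrichment.tsv"))
      pipeline_log(verbose, "enrichment", "%d/%d terms significant",
                   sum(enr$significant), nrow(enr))
      enr
    }, error = function(e) stage_error("enrichment", e))
    summary$n_terms_tested <- nrow(results$enrichment)
    summary$n_significant_terms <- sum(results$enrichment$significant)
  } else if (!is.null(cfg$annotation)) {
    warnf("enrichment stage skipped: needs the targets stage")
  }

  # -- correlation ------------------------------------------------------------
  if (!is.null(cfg$expression)) {
    results$correlation <- tryCatch({
      df <- read_tsv(require_input(cfg$expression, "expression", "correlation"))
      rn <- df[[1]]
      expr <- as.matrix(df[, -1, drop = FALSE])
      rownames(expr) <- rn
      scr <- correlation_screen(expr, cfg$query_gene)
      write_correlation_table(scr, file.path(cfg$outdir, "correlation.tsv"))
      pipeline_log(verbose, "correlation", "screened %d genes", nrow(scr))
      scr
    }, error = function(e) stage_error("correlation", e))
    summary$n_corr_fdr05 <- sum(results$correlation$fdr < 0.05, na.rm = TRUE)
  } else {
    warnf("correlation stage skipped: expression missing")
  }

  # -- descriptors ------------------------------------------------------------
  if (!is.null(cfg$descriptors)) {
    results$descriptors <- tryCatch({
      d <- read_descriptor_table(require_input(cfg$descriptors, "descriptors",
                                               "descriptors"))
      rk <- reactivity_ranking(d)
      val <- validate_gaps(d)
      write_tsv(rk, file.path(cfg$outdir, "reactivity_ranking.tsv"))
      write_tsv(val, file.path(cfg$outdir, "gap_validation.tsv"))
      pipeline_log(verbose, "descriptors", "most reactive: %s", rk$compound[1])
      list(ranking = rk, validation = val)
    }, error = function(e) stage_error("descriptors", e))
    summary$most_reactive <- results$descriptors$ranking$compound[1]
    summary$least_reactive <-
      results$descriptors$ranking$compound[nrow(results$descriptors$ranking)]
    summary$n_gap_flags <- sum(results$descriptors$validation$flagged)
  }

  jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg_out <- unclass(cfg)
  cfg_out$sim <- as.list(cfg_out$sim %||% list())
  jsonlite::write_json(cfg_out, file.path(cfg$outdir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  results$summary <- summary
  invisible(results)
}
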