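# Disease-gene filtering and compound/disease/DEG set-intersection logic.
#
# Gene identity throughout is the uppercased symbol string; no alias
# resolution is attempted (that needs an external database).

as_gene_set <- function(x) sort(unique(toupper(trimws(as.character(x)))))

.default_thresholds <- list(disgenet = 0.1, genecards = 5, pharmgkb = -Inf)

#' Filter scored disease-gene tables by per-source cutoffs
#'
#' Keeps genes with score strictly greater than their source's cutoff
#' (defaults: disgenet > 0.1, genecards > 5, pharmgkb keep all) and returns
#' the deduplicated union across sources.
#'
#' @param tables a data.frame (or list of data.frames, rbind-ed) with columns
#'   `gene`, `score`, `source`.
#' @param thresholds named list of per-source cutoffs; merged over the
#'   defaults.
#' @return character vector of surviving gene symbols (uppercased, sorted).
#' @export
filter_disease_genes <- function(tables, thresholds = list()) {
  if (is.data.frame(tables)) tables <- list(tables)
  df <- do.call(rbind, tables)
  if (!all(c("gene", "score", "source") %in% names(df))) {
    stopf("scored gene tables need columns gene, score, source")
  }
  th <- utils::modifyList(.default_thresholds, thresholds)
  src <- tolower(df$source)
  unknown <- setdiff(unique(src), names(th))
  if (length(unknown)) stopf("unknown source(s): %s", paste(unknown, collapse = ", "))
  if (any(!is.finite(df$score) & src != "pharmgkb")) {
    stopf("non-finite scores in scored gene table")
  }
  cut <- unlist(th[src])
  as_gene_set(df$gene[df$score > cut | src == "pharmgkb"])
}

#' Consensus differential-expression calls across methods
#'
#' A gene is kept in a direction iff at least `k` of the methods call it in
#' that direction. A single method calling one gene in both directions is an
#' error.
#'
#' @param deg data.frame with columns `gene`, `direction` ("up"/"down"),
#'   `method`; `log2fc`/`pvalue` columns are carried but not used.
#' @param k votes required (1, 2 or 3; default 3 = full intersection).
#' @return list with `up` and `down` gene vectors.
#' @export
consensus_deg <- function(deg, k = 3L) {
  k <- as.integer(k)
  if (!k %in% 1:3) stopf("k must be 1, 2 or 3")
  if (!all(c("gene", "direction", "method") %in% names(deg))) {
    stopf("DEG table needs columns gene, direction, method")
  }
  if (!all(deg$direction %in% c("up", "down"))) {
    stopf("direction must be 'up' or 'down'")
  }
  if ("log2fc" %in% names(deg)) {
    bad <- (deg$direction == "up") != (deg$log2fc >= 0)
    if (any(bad)) stopf("direction inconsistent with log2fc sign for gene(s): %s",
                        paste(unique(deg$gene[bad]), collapse = ", "))
  }
  key <- paste(deg$gene, deg$method)
  conf <- tapply(deg$direction, key, function(d) length(unique(d)) > 1L)
  if (any(conf)) {
    stopf("conflicting directions within one method for: %s",
          paste(unique(sub(" .*", "", names(conf)[conf])), collapse = ", "))
  }
  votes <- function(dirn) {
    sub <- unique(deg[deg$direction == dirn, c("gene", "method")])
    tab <- table(sub$gene)
    as_gene_set(names(tab)[tab >= k])
  }
  list(up = votes("up"), down = votes("down"))
}

#' Three-way compound/disease/DEG intersection
#'
#' @param compound_targets,disease,degs character vectors of gene symbols.
#' @return character vector: genes present in all three sets.
#' @export
compound_disease_intersection <- function(compound_targets, disease, degs) {
  Reduce(intersect, list(as_gene_set(compound_targets), as_gene_set(disease),
                         as_gene_set(degs)))
}

#' Common core of a list of gene sets (the petal-diagram centre)
#'
#' @param sets list of >= 2 character vectors.
#' @return character vector: genes present in every set.
#' @export
common_core <- function(sets) {
  if (length(sets) < 2L) stopf("common_core needs at least 2 sets")
  Reduce(intersect, lapply(sets, as_gene_set))
}

#' Read a gene-list file (one symbol per line, or a TSV with a `gene` column)
#' @param path input file.
#' @return uppercased, deduplicated, sorted character vector.
#' @export
read_gene_set <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", first) || tolower(trimws(first)) == "gene") {
    df <- read_tsv(path)
    as_gene_set(df$gene)
  } else {
    as_gene_set(readLines(path, warn = FALSE))
  }
}
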