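# PPI graphs and Maximal Clique Centrality (MCC) hub ranking.
#
# MCC(v) = sum over maximal cliques C containing v of (|C| - 1)!, the
# cytoHubba hub statistic. For a node whose neighbourhood induces no edges the
# formula reduces to its degree (each incident edge is a maximal 2-clique
# contributing 1!); isolated nodes score 0.

#' Load a PPI edge list into an undirected graph
#'
#' The first two columns are gene symbols; an optional third column is an edge
#' confidence score. Edges with score >= `min_confidence` are kept; the graph
#' is symmetrized, self-loops and duplicate edges removed. Malformed rows
#' (missing endpoints) are skipped and collected in the `errors` attribute.
#'
#' @param x a file path or a data.frame.
#' @param min_confidence minimum confidence kept (default 0.4, the STRING
#'   "medium" cutoff; scoreless tables keep every edge).
#' @return an undirected igraph object with an `errors` attribute.
#' @export
load_ppi <- function(x, min_confidence = 0.4) {
  df <- if (is.character(x)) read_tsv(x) else as.data.frame(x)
  errs <- data.frame(row = integer(0), message = character(0))
  if (nrow(df) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    attr(g, "errors") <- errs
    return(g)
  }
  a <- toupper(trimws(as.character(df[[1]])))
  b <- toupper(trimws(as.character(df[[2]])))
  score <- if (ncol(df) >= 3L) suppressWarnings(as.numeric(df[[3]])) else
    rep(Inf, nrow(df))
  bad <- !nzchar(a) | !nzchar(b) | is.na(a) | is.na(b) | is.na(score)
  if (any(bad)) {
    errs <- data.frame(row = which(bad), message = "malformed edge row")
  }
  keep <- !bad & score >= min_confidence
  g <- igraph::simplify(igraph::graph_from_data_frame(
    data.frame(from = a[keep], to = b[keep]), directed = FALSE))
  attr(g, "errors") <- errs
  g
}

#' Enumerate all maximal cliques of a graph
#'
#' Branch-and-bound enumeration with pivoting (Bron-Kerbosch, via igraph).
#' Isolated vertices are reported as singleton maximal cliques.
#'
#' @param g an igraph object.
#' @return list of character vectors (sorted members), in a deterministic
#'   order (by size, then lexicographically).
#' @export
maximal_cliques <- function(g) {
  if (igraph::vcount(g) == 0L) return(list())
  cl <- igraph::max_cliques(g, min = 1L)
  nm <- igraph::V(g)$name
  cl <- lapply(cl, function(v) sort(nm[as.integer(v)]))
  key <- vapply(cl, paste, character(1), collapse = "|")
  cl[order(lengths(cl), key)]
}

#' Maximal Clique Centrality scores
#'
#' @param g an igraph object (from [load_ppi()] or otherwise).
#' @return list with `scores` (named numeric, every vertex) and `cliques`
#'   (the maximal cliques used, size >= 2).
#' @export
mcc_scores <- function(g) {
  nm <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  scores <- stats::setNames(numeric(length(nm)), nm)
  cliques <- Filter(function(cl) length(cl) >= 2L, maximal_cliques(g))
  for (cl in cliques) {
    scores[cl] <- scores[cl] + factorial(length(cl) - 1L)
  }
  list(scores = scores, cliques = cliques)
}

#' Top-k hub genes by MCC
#'
#' Sorted by descending MCC with lexicographic tie-break, truncated at `k`
#' (never expanded beyond `k` at a tie boundary). Warns when the graph has
#' fewer than `k` nodes.
#'
#' @param r an `mcc_scores()` result, or a named numeric score vector.
#' @param k number of hubs (default 10).
#' @return data.frame with columns `gene`, `mcc`, `rank`.
#' @export
top_k_hubs <- function(r, k = 10L) {
  scores <- if (is.list(r) && !is.null(r$scores)) r$scores else r
  k <- as.integer(k)
  if (k < 1L) stopf("k must be >= 1")
  if (length(scores) < k) {
    warnf("graph has only %d nodes (< k = %d); returning all", length(scores), k)
    k <- length(scores)
  }
  ord <- order(-scores, names(scores))[seq_len(k)]
  data.frame(gene = names(scores)[ord], mcc = unname(scores[ord]),
             rank = seq_len(k), stringsAsFactors = FALSE)
}

#' Union of per-compound hub lists with provenance
#'
#' @param per_compound a (preferably named) list of hub rankings: each either
#'   a `top_k_hubs()` data.frame or a character vector of genes.
#' @return data.frame with columns `gene`, `n_compounds`, `compounds`
#'   (comma-joined contributors), sorted by gene.
#' @export
hub_union <- function(per_compound) {
  if (length(per_compound) < 1L) stopf("hub_union needs at least one list")
  nm <- names(per_compound) %||% as.character(seq_along(per_compound))
  nm[!nzchar(nm)] <- as.character(which(!nzchar(nm)))
  lists <- lapply(per_compound, function(x)
    if (is.data.frame(x)) as.character(x$gene) else as.character(x))
  genes <- sort(unique(unlist(lists)))
  prov <- vapply(genes, function(g)
    paste(nm[vapply(lists, function(l) g %in% l, logical(1))], collapse = ","),
    character(1))
  data.frame(gene = genes,
             n_compounds = lengths(regmatches(prov, gregexpr(",", prov))) + 1L,
             compounds = unname(prov), stringsAsFactors = FALSE)
}

#' Write a hub report TSV (gene, mcc, rank)
#' @param hubs a `top_k_hubs()` data.frame.
#' @param path output file.
#' @export
write_hub_report <- function(hubs, path) write_tsv(hubs, path)
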