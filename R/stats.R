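# Over-representation and correlation statistics.

#' Hypergeometric upper-tail p-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least `k` annotated genes when `n` study genes are drawn from a universe of
#' `N` genes of which `K` carry the annotation. Computed by exact summation of
#' binomial-coefficient terms on the log scale.
#'
#' @param k observed hits in the study set.
#' @param K annotated genes in the universe.
#' @param n study-set size.
#' @param N universe size.
#' @return p-value in (0, 1].
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  k <- as.integer(k); K <- as.integer(K); n <- as.integer(n); N <- as.integer(N)
  if (anyNA(c(k, K, n, N))) stopf("counts must be integers")
  if (K > N || n > N) stopf("K and n must not exceed N")
  if (k < 0L || k > min(K, n)) stopf("k must satisfy 0 <= k <= min(K, n)")
  if (k == 0L) return(1)
  x <- k:min(K, n)
  sum(exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)))
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up BH with monotonicity enforcement; input order is preserved.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Hypergeometric over-representation of a study set against term annotations
#'
#' One row per term with at least one study hit; rows passing both strict
#' cutoffs (p < p_cutoff and q < q_cutoff) are flagged significant. Study
#' genes outside the universe are dropped with a warning.
#'
#' @param study character vector of study genes.
#' @param annotation named list: term -> character vector of genes.
#' @param universe character vector of universe genes.
#' @param p_cutoff,q_cutoff strict significance cutoffs (defaults 0.01, 0.01).
#' @return data.frame (term, k, K, n, N, p, q, significant) sorted by p.
#' @export
enrich <- function(study, annotation, universe, p_cutoff = 0.01,
                   q_cutoff = 0.01) {
  universe <- as_gene_set(universe)
  if (!length(universe)) stopf("empty universe")
  study0 <- as_gene_set(study)
  study <- intersect(study0, universe)
  if (length(study) < length(study0)) {
    warnf("dropping %d study gene(s) outside the universe",
          length(study0) - length(study))
  }
  n <- length(study); N <- length(universe)
  rows <- lapply(names(annotation), function(tm) {
    genes <- intersect(as_gene_set(annotation[[tm]]), universe)
    k <- length(intersect(genes, study))
    if (k < 1L) return(NULL)
    K <- length(genes)
    data.frame(term = tm, k = k, K = K, n = n, N = N,
               p = hypergeom_pvalue(k, K, n, N), stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), significant = logical(0)))
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$p < p_cutoff & out$q < q_cutoff
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson correlation screen of an expression matrix against a query gene
#'
#' For every gene, the Pearson correlation with the query across samples, a
#' two-sided p-value from the t transform with S - 2 degrees of freedom, and a
#' BH column. Zero-variance genes are flagged (`excluded = TRUE`, NA
#' statistics) and left out of the BH adjustment. Rows are sorted by
#' descending correlation, so the query itself (r = 1) leads the table.
#'
#' @param expr numeric matrix, samples x genes, with gene column names.
#' @param query name of the query gene column.
#' @return data.frame (gene, statistic, p_value, fdr, excluded).
#' @export
correlation_screen <- function(expr, query) {
  expr <- as.matrix(expr)
  S <- nrow(expr)
  if (S < 4L) stopf("correlation screen needs at least 4 samples")
  if (!query %in% colnames(expr)) stopf("query gene '%s' not in matrix", query)
  q <- expr[, query]
  if (stats::sd(q) == 0) stopf("query gene has zero variance")
  sds <- apply(expr, 2, stats::sd)
  excluded <- sds == 0
  r <- rep(NA_real_, ncol(expr))
  r[!excluded] <- as.numeric(stats::cor(q, expr[, !excluded, drop = FALSE]))
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((S - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = S - 2, lower.tail = FALSE)
  p[!excluded & abs(r) == 1] <- 0       # exact linear dependence
  fdr <- rep(NA_real_, ncol(expr))
  fdr[!excluded] <- bh_adjust(p[!excluded])
  out <- data.frame(gene = colnames(expr), statistic = r, p_value = p,
                    fdr = fdr, excluded = excluded, stringsAsFactors = FALSE)
  out <- out[order(-out$statistic, out$gene, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a correlation screen as a Query/Statistic/p-Value/FDR (BH) TSV
#' @param screen a [correlation_screen()] data.frame.
#' @param path output file.
#' @export
write_correlation_table <- function(screen, path) {
  df <- data.frame(Query = screen$gene, Statistic = screen$statistic,
                   `p-Value` = screen$p_value, `FDR (BH)` = screen$fdr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a term-annotation TSV (columns term, gene) into a named list
#' @param path input file.
#' @return named list term -> character vector of genes.
#' @export
read_annotation <- function(path) {
  df <- read_tsv(path)
  if (!all(c("term", "gene") %in% names(df))) {
    stopf("annotation table needs columns term, gene")
  }
  lapply(split(df$gene, df$term), as_gene_set)
}
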