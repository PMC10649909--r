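# Chemical-space network: distance-thresholded graph over embedded compounds,
# connected-component clustering, MWGS and closeness scoring, representative
# selection.

#' Build the chemical-space network from an embedding and a similarity matrix
#'
#' Two compounds are joined iff their embedded Euclidean distance is strictly
#' less than theta = D_max / divisor, where D_max is the largest pairwise
#' embedded distance in the whole set. Each edge carries the Dice similarity
#' of its endpoints.
#'
#' @param e a `csn_embedding`.
#' @param s Dice similarity matrix covering the same compound ids
#'   (conventionally from the 2048-bit fingerprints).
#' @param divisor the threshold divisor (default 24: theta = D_max/24).
#' @return object of class `csn`: list with `ids`, `coords`, `edges`
#'   (data.frame from, to, dist, dice), `d_max`, `theta`, `divisor`, and the
#'   underlying igraph `graph` (all compounds as vertices).
#' @export
build_csn <- function(e, s, divisor = 24) {
  if (!inherits(e, "csn_embedding")) stopf("e must be a csn_embedding")
  ids <- rownames(e$coords)
  n <- length(ids)
  if (n < 2L) stopf("a chemical-space network needs at least 2 compounds")
  if (divisor <= 0) stopf("divisor must be > 0")
  if (!all(ids %in% rownames(s))) stopf("similarity matrix does not cover all compounds")
  D <- as.matrix(stats::dist(e$coords))
  d_max <- max(D)
  theta <- d_max / divisor
  idx <- which(upper.tri(D) & D < theta, arr.ind = TRUE)
  edges <- data.frame(
    from = ids[idx[, 1]], to = ids[idx[, 2]],
    dist = D[idx], dice = s[cbind(ids[idx[, 1]], ids[idx[, 2]])],
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = ids, x = e$coords[, 1], y = e$coords[, 2]))
  structure(list(ids = ids, coords = e$coords, edges = edges, d_max = d_max,
                 theta = theta, divisor = divisor, graph = g),
            class = "csn")
}

#' @export
print.csn <- function(x, ...) {
  cat(sprintf("<chemical-space network: %d compounds, %d edges, theta = %.4g (D_max %.4g / %g)>\n",
              length(x$ids), nrow(x$edges), x$theta, x$d_max, x$divisor))
  invisible(x)
}

#' @export
plot.csn <- function(x, ...) {
  igraph::plot.igraph(
    x$graph, layout = x$coords,
    vertex.size = 6, vertex.label.cex = 0.7,
    edge.width = if (nrow(x$edges)) 1 + 4 * x$edges$dice else 1, ...)
  invisible(x)
}

#' Cluster a chemical-space network into connected components
#'
#' Clustering is the transitive closure of the threshold edges ("molecules are
#' traversed"): every connected component, singletons included, is one
#' cluster. Clusters are ordered by their lexicographically smallest member.
#'
#' @param net a `csn`.
#' @return list of clusters, each a list with `members` (sorted ids) and `n`.
#' @export
cluster_components <- function(net) {
  comp <- igraph::components(net$graph)
  memb <- split(names(comp$membership), comp$membership)
  memb <- lapply(memb, sort)
  memb <- memb[order(vapply(memb, `[`, character(1), 1L))]
  lapply(seq_along(memb), function(i)
    structure(list(members = memb[[i]], n = length(memb[[i]]), cluster = i),
              class = "csn_cluster"))
}

#' @export
print.csn_cluster <- function(x, ...) {
  cat(sprintf("<cluster %s: %d member(s)%s>\n",
              x$cluster %||% "?", x$n,
              if (!is.null(x$representative))
                paste0(", representative ", x$representative) else ""))
  invisible(x)
}

#' Mean within-group similarity (MWGS) of each cluster member
#'
#' MWGS_i = (sum_j S_ij - 1) / n over the member's own cluster, where the sum
#' includes the self-similarity (= 1) which is then subtracted and n is the
#' cluster size. A singleton scores 0; the score reaches (n-1)/n only when all
#' pairwise similarities are 1.
#'
#' @param cluster a `csn_cluster` (or list with a `members` character vector).
#' @param s Dice similarity matrix containing all members.
#' @return named numeric vector of per-member MWGS scores.
#' @export
mwgs_scores <- function(cluster, s) {
  members <- cluster$members
  if (!all(members %in% rownames(s))) {
    stopf("cluster member(s) missing from similarity matrix: %s",
          paste(setdiff(members, rownames(s)), collapse = ", "))
  }
  n <- length(members)
  sub <- s[members, members, drop = FALSE]
  (rowSums(sub) - 1) / n
}

#' Closeness centrality of every compound in the network
#'
#' Unweighted shortest-path closeness with the Wasserman-Faust scaling
#' `((k - 1)/(n - 1)) * ((k - 1)/sum(d))`, where k is the size of the node's
#' connected component, n the total node count and sum(d) the node's total
#' geodesic distance within its component. Values lie in \[0, 1\] and are
#' comparable across components; isolated nodes score 0.
#'
#' @param net a `csn` (or any igraph in `net$graph`).
#' @return named numeric vector over all network nodes.
#' @export
closeness_scores <- function(net) {
  g <- net$graph
  n <- igraph::vcount(g)
  D <- igraph::distances(g)
  out <- vapply(seq_len(n), function(i) {
    di <- D[i, -i]
    fin <- di[is.finite(di)]
    k <- length(fin) + 1L
    if (k == 1L || n == 1L) return(0)
    ((k - 1) / (n - 1)) * ((k - 1) / sum(fin))
  }, numeric(1))
  names(out) <- igraph::V(g)$name
  out
}

#' Select the representative compound of a cluster
#'
#' The member with maximal closeness centrality; ties broken by maximal MWGS,
#' then by lexicographically smallest id. The MWGS-maximal member (the
#' alternative nomination rule) is reported alongside.
#'
#' @param cluster a `csn_cluster`.
#' @param closeness named closeness vector (from [closeness_scores()]).
#' @param mwgs named MWGS vector for the cluster (from [mwgs_scores()]).
#' @return the cluster, augmented with `closeness`, `mwgs`, `representative`,
#'   and `representative_mwgs`.
#' @export
select_representative <- function(cluster, closeness, mwgs) {
  m <- cluster$members
  cl <- closeness[m]; mw <- mwgs[m]
  ord <- order(-cl, -mw, m)
  cluster$closeness <- cl
  cluster$mwgs <- mw
  cluster$representative <- m[ord[1]]
  cluster$representative_mwgs <- m[order(-mw, m)[1]]
  cluster
}

#' Cluster a chemical-space network and score all members
#'
#' Convenience wrapper: components, MWGS, closeness and representatives in one
#' call.
#'
#' @param net a `csn`.
#' @param s Dice similarity matrix (2048-bit convention).
#' @return list with `clusters` (list of scored `csn_cluster`s) and `report`
#'   (one row per compound: id, cluster, n, mwgs, closeness,
#'   is_representative, is_representative_mwgs).
#' @export
cluster_csn <- function(net, s) {
  clusters <- cluster_components(net)
  clo <- closeness_scores(net)
  clusters <- lapply(clusters, function(cl)
    select_representative(cl, clo, mwgs_scores(cl, s)))
  report <- do.call(rbind, lapply(clusters, function(cl)
    data.frame(id = cl$members, cluster = cl$cluster, n = cl$n,
               mwgs = unname(cl$mwgs), closeness = unname(cl$closeness),
               is_representative = cl$members == cl$representative,
               is_representative_mwgs = cl$members == cl$representative_mwgs,
               stringsAsFactors = FALSE)))
  rownames(report) <- NULL
  list(clusters = clusters, report = report)
}

#' Write a chemical-space network as GraphML and an edge-list TSV
#'
#' @param net a `csn`.
#' @param graphml_path,edges_path output files (either may be NULL to skip).
#' @export
write_csn <- function(net, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(graphml_path)) {
    igraph::write_graph(net$graph, graphml_path, format = "graphml")
  }
  if (!is.null(edges_path)) {
    write_tsv(data.frame(source = net$edges$from, target = net$edges$to,
                         distance = net$edges$dist, dice = net$edges$dice,
                         stringsAsFactors = FALSE), edges_path)
  }
  invisible(net)
}
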