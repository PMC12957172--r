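#' Build a multimorbidity network
#'
#' A simple weighted undirected graph over a subgroup's retained condition
#' codes. The node set is fixed by the retained-condition list, so
#' conditions with no significant edge remain as isolated (degree-0) nodes.
#'
#' @param nodes character vector of retained condition codes.
#' @param edges data.frame `code_i`, `code_j`, `weight` (SCI in (0,1]).
#' @param label subgroup label.
#' @return object of class `mm_network`: list with `graph` (igraph),
#'   `label`, `nodes`, `edges`.
#' @export
build_network <- function(nodes, edges, label = "") {
  nodes <- sort(unique(nodes))
  if (nrow(edges)) {
    unknown <- setdiff(c(edges$code_i, edges$code_j), nodes)
    if (length(unknown))
      stopf("build_network: edge endpoint(s) not in node set: %s",
            paste(sort(unique(unknown)), collapse = ", "))
    if (any(edges$code_i == edges$code_j))
      stopf("build_network: self-loops not allowed")
    keys <- pair_key(edges$code_i, edges$code_j)
    if (anyDuplicated(keys))
      stopf("build_network: duplicate edge(s): %s",
            paste(keys[duplicated(keys)], collapse = ", "))
    if (any(!is.finite(edges$weight) | edges$weight <= 0 | edges$weight > 1))
      stopf("build_network: edge weights must lie in (0,1]")
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("code_i", "code_j", "weight"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  structure(list(graph = g, label = label, nodes = nodes,
                 edges = edges[, c("code_i", "code_j", "weight"),
                               drop = FALSE]),
            class = "mm_network")
}

#' @export
print.mm_network <- function(x, ...) {
  cat(sprintf("<mm_network> %s: %d nodes, %d edges\n",
              x$label, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Harmonic centrality
#'
#' For node v: `(1/(n-1)) * sum over u != v of 1/d(u,v)` with `1/Inf = 0`
#' for unreachable pairs; distances are unweighted hop counts, so values lie
#' in `[0,1]` and the measure is defined on disconnected graphs (isolated
#' nodes score 0).
#'
#' @param net an `mm_network`.
#' @return named numeric vector, one value per node.
#' @export
harmonic_centrality <- function(net) {
  n <- length(net$nodes)
  if (n < 2) stopf("harmonic_centrality: need at least 2 nodes")
  d <- igraph::distances(net$graph, weights = NA)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  stats::setNames(rowSums(inv) / (n - 1), net$nodes)
}

#' PageRank scores by power iteration
#'
#' PageRank on the weighted undirected graph: each edge acts as two directed
#' arcs with transition probability proportional to edge weight; dangling
#' (isolated) nodes redistribute uniformly. Power iteration with damping
#' `d` runs until the L1 change falls below `tol`.
#'
#' @param net an `mm_network`.
#' @param damping damping factor (default 0.85).
#' @param tol L1 convergence tolerance (default 1e-9).
#' @param max_iter iteration cap.
#' @return named numeric vector summing to 1.
#' @export
pagerank_scores <- function(net, damping = 0.85, tol = 1e-9, max_iter = 10000L) {
  n <- length(net$nodes)
  if (n < 1) stopf("pagerank_scores: empty node set")
  if (n == 1) return(stats::setNames(1, net$nodes))
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    ii <- match(net$edges$code_i, net$nodes)
    jj <- match(net$edges$code_j, net$nodes)
    A[cbind(ii, jj)] <- net$edges$weight
    A[cbind(jj, ii)] <- net$edges$weight
  }
  s <- colSums(A)
  dangling <- s == 0
  P <- A
  P[, !dangling] <- sweep(A[, !dangling, drop = FALSE], 2,
                          s[!dangling], "/")
  r <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    r_new <- (1 - damping) / n +
      damping * (as.vector(P %*% r) + sum(r[dangling]) / n)
    if (sum(abs(r_new - r)) < tol) {
      r <- r_new
      break
    }
    r <- r_new
  }
  stats::setNames(r / sum(r), net$nodes)
}

#' Per-node metric table
#'
#' Degree, weighted degree (sum of incident SCI weights), normalized
#' harmonic centrality and PageRank for every node of the network.
#'
#' @param net an `mm_network`.
#' @param damping PageRank damping factor.
#' @return data.frame `code`, `degree`, `weighted_degree`,
#'   `harmonic_centrality`, `pagerank`.
#' @export
node_metrics <- function(net, damping = 0.85) {
  data.frame(
    code = net$nodes,
    degree = as.integer(igraph::degree(net$graph)[net$nodes]),
    weighted_degree = as.numeric(igraph::strength(
      net$graph, weights = igraph::E(net$graph)$weight)[net$nodes]),
    harmonic_centrality = as.numeric(harmonic_centrality(net)[net$nodes]),
    pagerank = as.numeric(pagerank_scores(net, damping)[net$nodes]),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Whole-network summary
#'
#' Node and edge counts, density (`E / (n(n-1)/2)`), average degree
#' (`2E/n`), average weighted degree and average normalized harmonic
#' centrality.
#'
#' @param net an `mm_network`.
#' @return one-row data.frame `subgroup`, `n_nodes`, `n_edges`, `density`,
#'   `avg_degree`, `avg_weighted_degree`, `avg_harmonic_centrality`.
#' @export
summarize_network <- function(net) {
  n <- length(net$nodes)
  if (n < 2) stopf("summarize_network: density undefined for fewer than 2 nodes")
  m <- nrow(net$edges)
  nm <- node_metrics(net)
  data.frame(
    subgroup = net$label,
    n_nodes = n,
    n_edges = m,
    density = m / (n * (n - 1) / 2),
    avg_degree = 2 * m / n,
    avg_weighted_degree = mean(nm$weighted_degree),
    avg_harmonic_centrality = mean(nm$harmonic_centrality),
    stringsAsFactors = FALSE
  )
}

#' Hub diseases by PageRank
#'
#' The top `k` conditions ranked by PageRank score, ties broken
#' lexicographically by code.
#'
#' @param net an `mm_network`.
#' @param k number of hubs (default 10).
#' @param damping PageRank damping factor.
#' @return data.frame `rank`, `code`, `pagerank`.
#' @export
pagerank_hubs <- function(net, k = 10, damping = 0.85) {
  pr <- pagerank_scores(net, damping)
  ord <- order(-pr, names(pr))
  k <- min(k, length(pr))
  data.frame(rank = seq_len(k), code = names(pr)[ord][seq_len(k)],
             pagerank = as.numeric(pr[ord][seq_len(k)]),
             stringsAsFactors = FALSE)
}

#' ICD-chapter (system-level) aggregates
#'
#' Total degree and total weighted degree per ICD-10 chapter over the
#' network's member nodes, sorted descending by total degree.
#'
#' @param net an `mm_network`.
#' @param catalog condition catalog mapping `condition_code` to
#'   `icd10_chapter`.
#' @return data.frame `chapter`, `n_nodes`, `total_degree`,
#'   `total_weighted_degree`.
#' @export
system_aggregates <- function(net, catalog) {
  ch <- catalog$icd10_chapter[match(net$nodes, catalog$condition_code)]
  if (any(is.na(ch)))
    stopf("system_aggregates: node(s) missing from catalog: %s",
          paste(net$nodes[is.na(ch)], collapse = ", "))
  nm <- node_metrics(net)
  agg <- stats::aggregate(
    cbind(total_degree = nm$degree,
          total_weighted_degree = nm$weighted_degree) ~ chapter,
    data = data.frame(nm, chapter = ch), FUN = sum)
  cnt <- as.data.frame(table(chapter = ch), stringsAsFactors = FALSE)
  agg$n_nodes <- cnt$Freq[match(agg$chapter, cnt$chapter)]
  agg <- agg[order(-agg$total_degree, agg$chapter),
             c("chapter", "n_nodes", "total_degree", "total_weighted_degree")]
  rownames(agg) <- NULL
  agg
}

#' Export a network as GraphML
#'
#' Writes the graph with node attributes (label, chapter, metrics) and the
#' `sci_weight` edge attribute.
#'
#' @param net an `mm_network`.
#' @param catalog condition catalog for labels/chapters.
#' @param path output file path.
#' @param damping PageRank damping for the embedded node metrics.
#' @return invisibly, `path`.
#' @export
write_network_graphml <- function(net, catalog, path, damping = 0.85) {
  g <- net$graph
  nm <- node_metrics(net, damping)
  m <- match(net$nodes, catalog$condition_code)
  g <- igraph::set_vertex_attr(g, "label", value = catalog$label[m])
  g <- igraph::set_vertex_attr(g, "chapter", value = catalog$icd10_chapter[m])
  for (col in c("degree", "weighted_degree", "harmonic_centrality", "pagerank"))
    g <- igraph::set_vertex_attr(g, col, value = nm[[col]])
  if (igraph::ecount(g) > 0)
    g <- igraph::set_edge_attr(g, "sci_weight",
                               value = igraph::E(g)$weight)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
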