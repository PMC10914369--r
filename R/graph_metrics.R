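# Static centrality indices on the meta-network, and the per-link
# flexibility score contrasting the dynamic (leave-one-out) view with the
# static shortest-path view.
#
# All centralities treat the bipartite network as a single undirected,
# unweighted simple graph of N vertices; shortest paths ignore edge
# weights.

.as_igraph <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  if (is_empty(net)) stop("empty network")
  igraph::graph_from_data_frame(net$edges[, c("consumer", "resource")],
                                directed = FALSE,
                                vertices = data.frame(name = species(net)))
}

#' Vertex centralities of a bipartite network
#'
#' Degree, betweenness, eigenvector and closeness centrality on the
#' network viewed as one undirected unweighted graph of N vertices:
#' * `degree_norm`: incident edge count divided by N - 1;
#' * `betweenness_norm`: shortest-path betweenness scaled to `[0, 1]` by
#'   `2 / ((N - 1)(N - 2))`; reported as 0 (with a `degenerate` attribute)
#'   when N < 3;
#' * `eigenvector_scaled`: principal eigenvector of the adjacency matrix
#'   scaled to maximum 1, computed on the largest connected component
#'   (other components get 0);
#' * `closeness_norm`: the reciprocal of the total graph distance to the
#'   other vertices of the vertex's connected component, divided by
#'   (component size - 1).
#'
#' @param net a nonempty `bipartite_network`.
#' @return A data frame with one row per vertex: `species`, `guild`,
#'   `degree`, `degree_norm`, `betweenness_norm`, `eigenvector_scaled`,
#'   `closeness_norm`. The vertex count is in attribute `N`; attribute
#'   `degenerate` is `TRUE` when N < 3.
#' @export
vertex_centralities <- function(net) {
  g <- .as_igraph(net)
  n_vert <- igraph::vcount(g)
  deg <- igraph::degree(g)
  degenerate <- n_vert < 3L
  btw <- if (degenerate) {
    stats::setNames(rep(0, n_vert), igraph::V(g)$name)
  } else {
    igraph::betweenness(g, weights = NA, normalized = TRUE)
  }
  comp <- igraph::components(g)
  eig <- stats::setNames(rep(0, n_vert), igraph::V(g)$name)
  giant <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == giant))
  ev <- igraph::eigen_centrality(sub, weights = NA)$vector
  eig[names(ev)] <- ev
  dist_mat <- igraph::distances(g, weights = NA)
  clo <- vapply(seq_len(n_vert), function(i) {
    size <- comp$csize[comp$membership[i]]
    if (size < 2L) return(NA_real_)
    d <- dist_mat[i, ]
    (1 / sum(d[is.finite(d) & d > 0])) / (size - 1L)
  }, numeric(1))
  nm <- igraph::V(g)$name
  out <- data.frame(species = nm,
                    guild = ifelse(nm %in% net$consumers, "consumer", "resource"),
                    degree = as.integer(deg),
                    degree_norm = deg / (n_vert - 1L),
                    betweenness_norm = as.numeric(btw),
                    eigenvector_scaled = as.numeric(eig[nm]),
                    closeness_norm = clo,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "N") <- n_vert
  attr(out, "degenerate") <- degenerate
  out
}

#' Standardized edge betweenness
#'
#' Shortest-path betweenness of every edge on the unweighted undirected
#' graph, divided by the number of unordered vertex pairs N(N - 1)/2, so
#' the score is the fraction of vertex pairs whose shortest paths run
#' through the edge.
#'
#' @param net a nonempty `bipartite_network`.
#' @return A data frame with columns `consumer`, `resource`, `weight`,
#'   `edge_betweenness_std`.
#' @export
edge_betweenness_std <- function(net) {
  g <- .as_igraph(net)
  n_vert <- igraph::vcount(g)
  eb <- igraph::edge_betweenness(g, weights = NA)
  n_pairs <- n_vert * (n_vert - 1L) / 2
  ends <- igraph::as_edgelist(g)
  out <- data.frame(consumer = ends[, 1L], resource = ends[, 2L],
                    weight = net$edges$weight,
                    edge_betweenness_std = eb / n_pairs,
                    stringsAsFactors = FALSE)
  # graph_from_data_frame preserves edge order, so weights line up
  rownames(out) <- NULL
  out
}

.minmax_scale <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep(1, length(x)))  # constant guild: all 1
  (x - rng[1L]) / diff(rng)
}

#' Per-link flexibility scores
#'
#' Scores every meta-network link by the product of its two endpoints'
#' potential contributions to network flexibility: each guild's
#' `max_delta_RW` values are min-max scaled to `[0, 1]` within the guild
#' and multiplied per edge. Standardized edge betweenness is attached for
#' the static-vs-dynamic contrast, and links below a detection-count
#' threshold can be dropped (the analyses' default keeps links observed in
#' at least 10 samples).
#'
#' @param summary a [contribution_summary()] data frame covering every
#'   species of `meta`.
#' @param meta the meta-network (`bipartite_network`).
#' @param min_count drop edges with weight below this count (default 10;
#'   0 disables the filter).
#' @param scale_guilds `"both"` (default) min-max scales both guilds'
#'   contributions before multiplication; `"resources_only"` scales only
#'   the resource guild and uses consumers' raw `max_delta_RW`.
#' @return A data frame with columns `consumer`, `resource`, `weight`,
#'   `flexibility`, `edge_betweenness_std`, sorted by decreasing
#'   flexibility.
#' @export
link_flexibility <- function(summary, meta, min_count = 10,
                             scale_guilds = c("both", "resources_only")) {
  scale_guilds <- match.arg(scale_guilds)
  stopifnot(inherits(meta, "bipartite_network"))
  missing_sp <- setdiff(species(meta), summary$species)
  if (length(missing_sp) > 0L) {
    stop("species missing from contribution summary: ",
         paste(utils::head(missing_sp, 5L), collapse = ", "))
  }
  val <- stats::setNames(summary$max_delta_RW, summary$species)
  cons_raw <- val[meta$consumers]
  res_raw <- val[meta$resources]
  if (anyNA(cons_raw) || anyNA(res_raw)) {
    stop("contribution summary has missing max_delta_RW for meta-network species")
  }
  cons_scaled <- if (scale_guilds == "both") .minmax_scale(cons_raw) else cons_raw
  res_scaled <- .minmax_scale(res_raw)
  names(cons_scaled) <- meta$consumers
  names(res_scaled) <- meta$resources
  eb <- edge_betweenness_std(meta)
  keep <- eb$weight >= min_count
  out <- data.frame(consumer = eb$consumer[keep],
                    resource = eb$resource[keep],
                    weight = eb$weight[keep],
                    flexibility = cons_scaled[eb$consumer[keep]] *
                      res_scaled[eb$resource[keep]],
                    edge_betweenness_std = eb$edge_betweenness_std[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$flexibility), , drop = FALSE]
  rownames(out) <- NULL
  out
}
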