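# Data model for temporal bipartite weighted interaction networks.
#
# A "realization" is the network observed at one time point (e.g. one month);
# the "meta-network" is the union of all realizations with summed edge
# weights. Consumer and resource identifier spaces are kept strictly
# disjoint: the same label appearing in both columns is rejected.

.key_sep <- "\x1f"

.edge_keys <- function(edges) {
  paste(edges$consumer, edges$resource, sep = .key_sep)
}

# Sum weights of duplicate (consumer, resource) rows; rows come back ordered
# by consumer then resource so that equal networks compare identical.
.aggregate_edges <- function(edges) {
  if (nrow(edges) == 0L) {
    return(data.frame(consumer = character(), resource = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  }
  key <- .edge_keys(edges)
  w <- rowsum(edges$weight, key)
  i <- match(rownames(w), key)
  out <- data.frame(consumer = edges$consumer[i],
                    resource = edges$resource[i],
                    weight = as.numeric(w[, 1L]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$consumer, out$resource), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a bipartite interaction network
#'
#' A network is an edge-weighted bipartite graph over two disjoint guilds
#' (consumers and resources). Species occurrence is defined by incidence:
#' every vertex carried by the object has at least one incident edge, so
#' vertex sets are derived from the edge table, never stored independently.
#'
#' @param edges data frame with columns `consumer`, `resource`, `weight`
#'   (positive; zero-weight rows are dropped, duplicate pairs are summed).
#' @return An object of class `bipartite_network`: a list with elements
#'   `edges` (aggregated edge table), `consumers` and `resources`
#'   (sorted character vectors of occurring species).
#' @examples
#' net <- bipartite_network(data.frame(
#'   consumer = c("A", "A", "B"), resource = c("x", "y", "x"),
#'   weight = c(2, 1, 1)))
#' net$consumers
#' @export
bipartite_network <- function(edges) {
  stopifnot(is.data.frame(edges))
  required <- c("consumer", "resource", "weight")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols) > 0L) {
    stop("edge table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  edges <- data.frame(consumer = as.character(edges$consumer),
                      resource = as.character(edges$resource),
                      weight = as.numeric(edges$weight),
                      stringsAsFactors = FALSE)
  if (anyNA(edges$weight)) stop("non-numeric edge weight")
  if (any(edges$weight < 0)) stop("negative edge weight")
  edges <- edges[edges$weight > 0, , drop = FALSE]
  edges <- .aggregate_edges(edges)
  consumers <- sort(unique(edges$consumer))
  resources <- sort(unique(edges$resource))
  overlap <- intersect(consumers, resources)
  if (length(overlap) > 0L) {
    stop("identifier(s) appear in both guilds: ",
         paste(utils::head(overlap, 5L), collapse = ", "))
  }
  structure(list(edges = edges, consumers = consumers, resources = resources),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite_network: %d consumers x %d resources, %d edges, total weight %g\n",
              length(x$consumers), length(x$resources), nrow(x$edges),
              sum(x$edges$weight)))
  invisible(x)
}

#' Number of edges, total weight, species of a network
#'
#' Small accessors used throughout the package.
#' @param net a `bipartite_network`.
#' @return `n_edges()` an integer; `total_weight()` a number; `species()` a
#'   character vector (consumers then resources); `is_empty()` a logical.
#' @export
n_edges <- function(net) nrow(net$edges)

#' @rdname n_edges
#' @export
total_weight <- function(net) sum(net$edges$weight)

#' @rdname n_edges
#' @export
species <- function(net) c(net$consumers, net$resources)

#' @rdname n_edges
#' @export
is_empty <- function(net) nrow(net$edges) == 0L

#' Aggregate realizations into a meta-network
#'
#' The meta-network is the union of all interactions observed across the
#' realizations; each edge's meta weight is the sum of its weights over the
#' realizations, and the vertex sets are the unions of occurring species.
#'
#' @param realizations nonempty list of `bipartite_network` objects.
#' @return A `bipartite_network`.
#' @export
build_meta_network <- function(realizations) {
  if (length(realizations) == 0L) stop("empty list of realizations")
  stopifnot(all(vapply(realizations, inherits, logical(1), "bipartite_network")))
  all_edges <- do.call(rbind, lapply(realizations, function(n) n$edges))
  bipartite_network(all_edges)
}

#' Construct an ordered series of network realizations
#'
#' Binds T ordered realizations (e.g. monthly networks) together with their
#' derived meta-network. Realizations emptied later by species removal are
#' retained, keeping the series length stable.
#'
#' @param networks list of `bipartite_network` objects, in temporal order.
#' @param ids character vector of unique realization labels (e.g. months).
#' @return An object of class `network_series`: list with `ids`, `networks`
#'   (named by `ids`) and `meta` (a `bipartite_network`).
#' @export
network_series <- function(networks, ids = names(networks)) {
  if (length(networks) == 0L) stop("empty series")
  if (is.null(ids)) ids <- sprintf("t%02d", seq_along(networks))
  ids <- as.character(ids)
  stopifnot(length(ids) == length(networks), !anyDuplicated(ids))
  names(networks) <- ids
  nonempty <- networks[vapply(networks, Negate(is_empty), logical(1))]
  if (length(nonempty) == 0L) stop("all realizations are empty")
  # cross-realization namespace check: a label must stay in one guild
  all_cons <- unique(unlist(lapply(networks, `[[`, "consumers")))
  all_res <- unique(unlist(lapply(networks, `[[`, "resources")))
  overlap <- intersect(all_cons, all_res)
  if (length(overlap) > 0L) {
    stop("identifier(s) switch guilds across realizations: ",
         paste(utils::head(overlap, 5L), collapse = ", "))
  }
  structure(list(ids = ids, networks = networks,
                 meta = build_meta_network(nonempty)),
            class = "network_series")
}

#' @export
print.network_series <- function(x, ...) {
  cat(sprintf("network_series: %d realizations (%s)\n", length(x$ids),
              paste(x$ids, collapse = ", ")))
  cat("meta: ")
  print(x$meta)
  invisible(x)
}

#' Convert edge weights to proportions
#'
#' Divides every edge weight by the network's total weight, so that weights
#' sum to one. Interaction counts are converted to proportions before any
#' quantitative (Bray-Curtis) comparison, mirroring the standard treatment
#' of detection-count data.
#'
#' @param net a `bipartite_network` with positive total weight.
#' @return A `bipartite_network` whose edge weights sum to 1.
#' @export
to_proportions <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  tot <- total_weight(net)
  if (tot <= 0) stop("cannot convert an empty (zero-total) network to proportions")
  net$edges$weight <- net$edges$weight / tot
  net
}

#' Remove a species from a network or series
#'
#' Deletes every edge incident to the given species; vertices left without
#' edges drop out (occurrence is defined by incidence). On a
#' `network_series` the species is removed from every realization and the
#' meta-network is rebuilt from the reduced realizations, i.e. the species
#' is removed "from the dataset". Realizations emptied by the removal are
#' retained as empty networks so the series keeps its length. Removing an
#' absent species is a no-op.
#'
#' @param obj a `bipartite_network` or `network_series`.
#' @param species_id character vector of species to remove (either guild).
#' @return An object of the same class as `obj`.
#' @export
remove_species <- function(obj, species_id) UseMethod("remove_species")

#' @export
remove_species.bipartite_network <- function(obj, species_id) {
  keep <- !(obj$edges$consumer %in% species_id | obj$edges$resource %in% species_id)
  edges <- obj$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  obj$edges <- edges
  obj$consumers <- sort(unique(edges$consumer))
  obj$resources <- sort(unique(edges$resource))
  obj
}

#' @export
remove_species.network_series <- function(obj, species_id) {
  reduced <- lapply(obj$networks, remove_species, species_id = species_id)
  names(reduced) <- obj$ids
  nonempty <- reduced[vapply(reduced, Negate(is_empty), logical(1))]
  if (length(nonempty) == 0L) stop("removal empties every realization")
  structure(list(ids = obj$ids, networks = reduced,
                 meta = build_meta_network(nonempty)),
            class = "network_series")
}

#' Align the edges of two networks and classify them
#'
#' Builds aligned weight vectors over the union of the two networks' edges
#' and classifies each edge as `shared` (present in both), `unique_rw`
#' (present in one network only, but both endpoints occur in both networks:
#' its absence is attributable to interaction rewiring) or `unique_st`
#' (at least one endpoint occurs in only one network: attributable to
#' species turnover). The classification drives the rewiring/turnover
#' partition of network dissimilarity.
#'
#' @param m,n `bipartite_network` objects over compatible ID spaces.
#' @return An object of class `edge_alignment`: list with `table` (data
#'   frame: consumer, resource, `u` and `v` aligned weights, `class`) and
#'   `counts` (a, b, c, b_rw, c_rw, b_st, c_st with b = b_rw + b_st and
#'   c = c_rw + c_st).
#' @export
align_edges <- function(m, n) {
  stopifnot(inherits(m, "bipartite_network"), inherits(n, "bipartite_network"))
  bad <- union(intersect(c(m$consumers, n$consumers), c(m$resources, n$resources)),
               character())
  if (length(bad) > 0L) {
    stop("consumer/resource namespaces overlap across networks: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  km <- .edge_keys(m$edges)
  kn <- .edge_keys(n$edges)
  keys <- c(km, kn[!(kn %in% km)])
  im <- match(keys, km)
  i_n <- match(keys, kn)
  consumer <- ifelse(is.na(im), n$edges$consumer[i_n], m$edges$consumer[im])
  resource <- ifelse(is.na(im), n$edges$resource[i_n], m$edges$resource[im])
  u <- ifelse(is.na(im), 0, m$edges$weight[im])
  v <- ifelse(is.na(i_n), 0, n$edges$weight[i_n])
  shared_c <- intersect(m$consumers, n$consumers)
  shared_r <- intersect(m$resources, n$resources)
  both_end <- consumer %in% shared_c & resource %in% shared_r
  cls <- ifelse(u > 0 & v > 0, "shared",
                ifelse(both_end, "unique_rw", "unique_st"))
  tab <- data.frame(consumer = consumer, resource = resource, u = u, v = v,
                    class = cls, stringsAsFactors = FALSE)
  counts <- list(
    a = sum(cls == "shared"),
    b = sum(u > 0 & v == 0),
    c = sum(v > 0 & u == 0),
    b_rw = sum(u > 0 & v == 0 & cls == "unique_rw"),
    c_rw = sum(v > 0 & u == 0 & cls == "unique_rw"),
    b_st = sum(u > 0 & v == 0 & cls == "unique_st"),
    c_st = sum(v > 0 & u == 0 & cls == "unique_st"))
  structure(list(table = tab, counts = counts), class = "edge_alignment")
}

#' Read a long-format interaction table into a network series
#'
#' Ingests a delimited text file with one row per (realization, consumer,
#' resource) interaction count — e.g. monthly predator-prey detection
#' counts. Zero-count rows are dropped and duplicate rows are summed.
#' Lines starting with `#` are treated as comments.
#'
#' @param path path to the delimited file (with header).
#' @param delim field delimiter; default tab.
#' @param columns named character vector mapping the roles `realization`,
#'   `consumer`, `resource`, `count` to column names in the file.
#' @param realization_order optional character vector giving the temporal
#'   order of realization labels; default is first-appearance order.
#' @return A `network_series`.
#' @export
read_interaction_table <- function(path, delim = "\t",
                                   columns = c(realization = "realization",
                                               consumer = "consumer",
                                               resource = "resource",
                                               count = "count"),
                                   realization_order = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  roles <- c("realization", "consumer", "resource", "count")
  stopifnot(all(roles %in% names(columns)))
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           comment.char = "#", quote = "",
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(unname(columns[roles]), names(raw))
  if (length(missing_cols) > 0L) {
    stop("input lacks required column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- data.frame(realization = raw[[columns[["realization"]]]],
                   consumer = raw[[columns[["consumer"]]]],
                   resource = raw[[columns[["resource"]]]],
                   weight = suppressWarnings(as.numeric(raw[[columns[["count"]]]])),
                   stringsAsFactors = FALSE)
  bad <- which(is.na(df$weight))
  if (length(bad) > 0L) {
    stop("non-numeric count at data row ", bad[1L])
  }
  bad <- which(df$weight < 0)
  if (length(bad) > 0L) {
    stop("negative count at data row ", bad[1L])
  }
  df <- df[df$weight > 0, , drop = FALSE]
  if (nrow(df) == 0L) stop("no interactions left after dropping zero counts")
  ids <- if (is.null(realization_order)) unique(df$realization) else as.character(realization_order)
  unknown <- setdiff(df$realization, ids)
  if (length(unknown) > 0L) {
    stop("realization label(s) absent from realization_order: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  networks <- lapply(ids, function(id) {
    bipartite_network(df[df$realization == id, c("consumer", "resource", "weight")])
  })
  network_series(networks, ids = ids)
}

#' Write a network series as a long-format interaction table
#'
#' Inverse of [read_interaction_table()]: one row per realization edge.
#'
#' @param series a `network_series`.
#' @param path output file path.
#' @param delim field delimiter; default tab.
#' @param provenance optional named list written as `# key: value` header
#'   comment lines for reproducibility.
#' @return Invisibly, the written data frame.
#' @export
write_interaction_table <- function(series, path, delim = "\t",
                                    provenance = NULL) {
  stopifnot(inherits(series, "network_series"))
  rows <- lapply(series$ids, function(id) {
    e <- series$networks[[id]]$edges
    if (nrow(e) == 0L) return(NULL)
    data.frame(realization = id, consumer = e$consumer, resource = e$resource,
               count = e$weight, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  .write_table_with_header(df, path, delim = delim, provenance = provenance)
  invisible(df)
}

#' Write one realization as a wide incidence matrix
#'
#' Exports a consumers x resources weight matrix (TSV) for use with
#' general bipartite-network tooling.
#'
#' @param net a `bipartite_network`.
#' @param path output file path.
#' @return Invisibly, the incidence matrix.
#' @export
write_incidence_matrix <- function(net, path) {
  stopifnot(inherits(net, "bipartite_network"))
  mat <- matrix(0, nrow = length(net$consumers), ncol = length(net$resources),
                dimnames = list(net$consumers, net$resources))
  if (nrow(net$edges) > 0L) {
    mat[cbind(net$edges$consumer, net$edges$resource)] <- net$edges$weight
  }
  utils::write.table(data.frame(consumer = rownames(mat), mat,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mat)
}

# shared writer: optional provenance header comments, then a TSV body
.write_table_with_header <- function(df, path, delim = "\t", provenance = NULL) {
  con <- file(path, open = "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    for (k in names(provenance)) {
      writeLines(sprintf("# %s: %s", k, paste(provenance[[k]], collapse = " ")), con)
    }
  }
  utils::write.table(df, con, sep = delim, quote = FALSE, row.names = FALSE)
}
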