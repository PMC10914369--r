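# Pairwise network dissimilarity and its additive rewiring/turnover
# partition.
#
# Total interaction dissimilarity betaINT between two networks is split as
# betaINT = betaRW + betaST, where betaRW is dissimilarity among species
# occurring in both networks (interaction rewiring) and betaST is
# dissimilarity due to interactions involving species found in only one of
# them (species turnover). Two partitioning frameworks are provided:
#
#  * framework1 (subtraction-based): betaRW is the dissimilarity of the
#    shared-species subnetworks with its own denominator; betaST is
#    obtained as betaINT - betaRW. Additivity is not guaranteed.
#  * framework2 (common-denominator): betaRW and betaST are computed
#    directly over the full edge union with a single common denominator,
#    so betaINT = betaRW + betaST holds exactly.
#
# With the binary Sorensen metric and edge-class counts a (shared),
# b/c (one-sided), b'/c' (one-sided rewiring) and bST/cST (one-sided
# turnover, bST = b - b', cST = c - c'):
#   betaINT = (b + c) / (2a + b + c)
#   framework1: betaRW = (b' + c') / (2a' + b' + c')     (a' = a)
#   framework2: betaRW = (b' + c') / (2a + b + c)
#               betaST = (bST + cST) / (2a + b + c)
# The quantitative analogue replaces counts by Bray-Curtis sums over the
# aligned (optionally proportion-converted) weight vectors.

.new_beta_partition <- function(beta_s, beta_int, beta_rw, beta_st,
                                framework, metric, proportions,
                                degenerate = FALSE) {
  structure(list(beta_s = beta_s, beta_int = beta_int, beta_rw = beta_rw,
                 beta_st = beta_st, framework = framework, metric = metric,
                 proportions = proportions, degenerate = degenerate),
            class = "beta_partition")
}

#' @export
print.beta_partition <- function(x, ...) {
  cat(sprintf("beta partition (%s, %s%s)%s\n", x$framework, x$metric,
              if (x$proportions) ", proportions" else "",
              if (x$degenerate) " [degenerate]" else ""))
  cat(sprintf("  beta_S = %.4g  beta_INT = %.4g  beta_RW = %.4g  beta_ST = %.4g\n",
              x$beta_s, x$beta_int, x$beta_rw, x$beta_st))
  invisible(x)
}

# species-composition dissimilarity; quantitative uses the concatenated
# consumer+resource marginal interaction weights as the abundance surrogate,
# normalized per network when proportions are on
.beta_species <- function(m, n, metric, proportions) {
  sm <- species(m)
  sn <- species(n)
  if (metric == "sorensen") {
    a <- length(intersect(sm, sn))
    b <- length(setdiff(sm, sn))
    cc <- length(setdiff(sn, sm))
    den <- 2 * a + b + cc
    return(if (den == 0) NA_real_ else (b + cc) / den)
  }
  marg <- function(net) {
    w <- c(rowsum(net$edges$weight, net$edges$consumer)[, 1L],
           rowsum(net$edges$weight, net$edges$resource)[, 1L])
    if (proportions && sum(w) > 0) w <- w / sum(w)
    w
  }
  wm <- marg(m)
  wn <- marg(n)
  all_sp <- union(names(wm), names(wn))
  u <- ifelse(all_sp %in% names(wm), wm[all_sp], 0)
  v <- ifelse(all_sp %in% names(wn), wn[all_sp], 0)
  u[is.na(u)] <- 0
  v[is.na(v)] <- 0
  den <- sum(u + v)
  if (den == 0) NA_real_ else sum(abs(u - v)) / den
}

#' Partition the dissimilarity between two networks
#'
#' Computes species-composition dissimilarity (`beta_s`), total interaction
#' dissimilarity (`beta_int`) and its decomposition into rewiring
#' (`beta_rw`) and species-turnover (`beta_st`) components for a pair of
#' bipartite networks, under the chosen partitioning framework and metric.
#'
#' The package default — `framework2`, Bray-Curtis, proportions on — gives
#' an exactly additive partition of quantitative dissimilarity and is the
#' configuration used throughout the downstream analyses.
#'
#' @param m,n `bipartite_network` objects to compare.
#' @param framework `"framework2"` (common denominator, exactly additive)
#'   or `"framework1"` (shared-subnetwork dissimilarity, turnover by
#'   subtraction).
#' @param metric `"bray_curtis"` (quantitative) or `"sorensen"` (binary).
#' @param proportions logical; convert each network's weights to
#'   proportions (sum 1) before quantitative comparison. Ignored by the
#'   binary metric.
#' @return A `beta_partition` object. If either network is empty the
#'   components are `NA` and the `degenerate` flag is set.
#' @examples
#' m <- bipartite_network(data.frame(consumer = c("A", "A"),
#'                                   resource = c("x", "y"),
#'                                   weight = c(3, 1)))
#' n <- bipartite_network(data.frame(consumer = c("A", "A"),
#'                                   resource = c("x", "y"),
#'                                   weight = c(1, 1)))
#' partition_pair(m, n)  # beta_int = 0.25, all of it rewiring
#' @export
partition_pair <- function(m, n,
                           framework = c("framework2", "framework1"),
                           metric = c("bray_curtis", "sorensen"),
                           proportions = TRUE) {
  framework <- match.arg(framework)
  metric <- match.arg(metric)
  stopifnot(inherits(m, "bipartite_network"), inherits(n, "bipartite_network"))
  if (is_empty(m) || is_empty(n)) {
    return(.new_beta_partition(NA_real_, NA_real_, NA_real_, NA_real_,
                               framework, metric, proportions,
                               degenerate = TRUE))
  }
  beta_s <- .beta_species(m, n, metric, proportions)
  if (metric == "bray_curtis" && proportions) {
    m <- to_proportions(m)
    n <- to_proportions(n)
  }
  al <- align_edges(m, n)
  if (metric == "sorensen") {
    ct <- al$counts
    den <- 2 * ct$a + ct$b + ct$c
    beta_int <- (ct$b + ct$c) / den
    if (framework == "framework2") {
      beta_rw <- (ct$b_rw + ct$c_rw) / den
      beta_st <- (ct$b_st + ct$c_st) / den
    } else {
      # shared-species subnetworks; edges common to both networks always
      # have both endpoints shared, so a' = a
      den_rw <- 2 * ct$a + ct$b_rw + ct$c_rw
      beta_rw <- if (den_rw == 0) 0 else (ct$b_rw + ct$c_rw) / den_rw
      beta_st <- beta_int - beta_rw
    }
  } else {
    tab <- al$table
    num <- abs(tab$u - tab$v)
    den <- sum(tab$u + tab$v)
    beta_int <- sum(num) / den
    on_shared <- tab$class %in% c("shared", "unique_rw")
    if (framework == "framework2") {
      beta_rw <- sum(num[on_shared]) / den
      beta_st <- sum(num[!on_shared]) / den
    } else {
      den_rw <- sum(tab$u[on_shared] + tab$v[on_shared])
      beta_rw <- if (den_rw == 0) 0 else sum(num[on_shared]) / den_rw
      beta_st <- beta_int - beta_rw
    }
  }
  .new_beta_partition(beta_s, beta_int, beta_rw, beta_st,
                      framework, metric, proportions)
}

.partition_row <- function(pair_id, part) {
  data.frame(pair_id = pair_id,
             beta_s = part$beta_s,
             beta_int = part$beta_int,
             beta_rw = part$beta_rw,
             beta_st = part$beta_st,
             rw_ratio = if (!part$degenerate && !is.na(part$beta_int) &&
                            part$beta_int > 0) part$beta_rw / part$beta_int
                        else NA_real_,
             degenerate = part$degenerate,
             stringsAsFactors = FALSE)
}

.series_dissim_table <- function(rows, mode, framework, metric, proportions) {
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  attr(out, "framework") <- framework
  attr(out, "metric") <- metric
  attr(out, "proportions") <- proportions
  class(out) <- c("series_dissimilarity", "data.frame")
  out
}

#' Dissimilarity between consecutive realizations
#'
#' Partitions network dissimilarity for every pair of adjacent realizations
#' in temporal order (T realizations give T-1 rows), e.g. April-to-May
#' transitions of a monthly network series. The `rw_ratio` column reports
#' the share of architectural change due to rewiring, `beta_rw / beta_int`
#' (`NA` when `beta_int` is 0).
#'
#' @inheritParams partition_pair
#' @param series a `network_series` with at least two realizations.
#' @return A data frame of class `series_dissimilarity` with columns
#'   `pair_id`, `beta_s`, `beta_int`, `beta_rw`, `beta_st`, `rw_ratio`,
#'   `degenerate`; settings are carried in attributes.
#' @export
consecutive_dissimilarity <- function(series,
                                      framework = c("framework2", "framework1"),
                                      metric = c("bray_curtis", "sorensen"),
                                      proportions = TRUE) {
  framework <- match.arg(framework)
  metric <- match.arg(metric)
  stopifnot(inherits(series, "network_series"))
  t_len <- length(series$ids)
  if (t_len < 2L) stop("need at least two realizations")
  rows <- lapply(seq_len(t_len - 1L), function(i) {
    part <- partition_pair(series$networks[[i]], series$networks[[i + 1L]],
                           framework = framework, metric = metric,
                           proportions = proportions)
    .partition_row(paste(series$ids[i], series$ids[i + 1L], sep = "-"), part)
  })
  .series_dissim_table(rows, "consecutive", framework, metric, proportions)
}

#' Dissimilarity between each realization and the meta-network
#'
#' Compares every realization against the full meta-network (which includes
#' the realization's own edges), yielding the primed dissimilarity indices:
#' one row per realization with `beta_int` = betaINT', `beta_rw` = betaRW',
#' `beta_st` = betaST' and `beta_s` = betaS'. These are the quantities whose
#' leave-one-species-out changes define species contributions to network
#' flexibility.
#'
#' @inheritParams partition_pair
#' @param series a `network_series`.
#' @return A `series_dissimilarity` data frame with T rows; `pair_id` is the
#'   realization label.
#' @export
vs_meta_dissimilarity <- function(series,
                                  framework = c("framework2", "framework1"),
                                  metric = c("bray_curtis", "sorensen"),
                                  proportions = TRUE) {
  framework <- match.arg(framework)
  metric <- match.arg(metric)
  stopifnot(inherits(series, "network_series"))
  rows <- lapply(seq_along(series$ids), function(i) {
    part <- partition_pair(series$networks[[i]], series$meta,
                           framework = framework, metric = metric,
                           proportions = proportions)
    .partition_row(series$ids[i], part)
  })
  .series_dissim_table(rows, "vs_meta", framework, metric, proportions)
}

#' Write a dissimilarity table as tidy TSV
#'
#' One row per pair, with the analysis settings appended as columns and an
#' optional provenance comment header.
#'
#' @param table a `series_dissimilarity` data frame.
#' @param path output file path.
#' @param provenance optional named list of header comments.
#' @return Invisibly, the written data frame.
#' @export
write_dissimilarity_table <- function(table, path, provenance = NULL) {
  stopifnot(inherits(table, "series_dissimilarity"))
  df <- as.data.frame(table)
  df$framework <- attr(table, "framework")
  df$metric <- attr(table, "metric")
  df$proportions <- attr(table, "proportions")
  .write_table_with_header(df, path, provenance = provenance)
  invisible(df)
}
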