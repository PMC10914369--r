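# Leave-one-species-out contributions to network flexibility.
#
# For species i and realization t, the contribution to a primed
# dissimilarity component X' (X in RW, INT, ST, S) is
#
#   delta_X,i(t) = X'(t) - X'_{-i}(t),
#
# where X'_{-i} is recomputed after removing species i from the dataset:
# from every realization AND from the meta-network (which is rebuilt from
# the reduced realizations), with proportions recomputed on the reduced
# networks. A species' potential contribution to flexibility is the maximum
# of delta_RW,i(t) over the time series; species attaining large positive
# maxima are "network coordinators". Deltas may be negative (a species can
# stabilize apparent rewiring) and are never clipped.

.component_cols <- c(RW = "beta_rw", INT = "beta_int", ST = "beta_st",
                     S = "beta_s")

#' Leave-one-out dissimilarity deltas for one species
#'
#' For each realization, computes the primed dissimilarity component for
#' the full series and for the series with `species_id` removed, and
#' returns the difference (full minus reduced). Rows where either
#' computation is degenerate (e.g. the removal empties the realization) are
#' flagged; they are excluded from maxima by [contribution_summary()].
#'
#' @inheritParams partition_pair
#' @param series a `network_series`.
#' @param species_id a single species identifier present in the
#'   meta-network (either guild).
#' @param components character subset of `c("RW", "INT", "ST", "S")`:
#'   rewiring, total interaction, species-turnover and species-composition
#'   components.
#' @param reduced_meta logical; if `TRUE` (default) the meta-network used
#'   for the reduced computation is rebuilt from the reduced realizations
#'   (removal "from the dataset"). If `FALSE` the realization is reduced
#'   but compared against the original full meta-network.
#' @param full_table optional precomputed [vs_meta_dissimilarity()] table
#'   for the full series with identical settings (performance hook used by
#'   [contribution_summary()]).
#' @return A data frame with columns `species`, `realization`, `component`,
#'   `delta`, `degenerate`.
#' @export
species_delta <- function(series, species_id,
                          components = c("RW", "INT", "ST", "S"),
                          framework = c("framework2", "framework1"),
                          metric = c("bray_curtis", "sorensen"),
                          proportions = TRUE,
                          reduced_meta = TRUE,
                          full_table = NULL) {
  framework <- match.arg(framework)
  metric <- match.arg(metric)
  stopifnot(inherits(series, "network_series"), length(species_id) == 1L)
  components <- match.arg(components, several.ok = TRUE)
  if (!(species_id %in% species(series$meta))) {
    stop("species not present in the meta-network: ", species_id)
  }
  if (is.null(full_table)) {
    full_table <- vs_meta_dissimilarity(series, framework = framework,
                                        metric = metric,
                                        proportions = proportions)
  }
  reduced_series <- tryCatch(remove_species(series, species_id),
                             error = function(e) NULL)
  if (is.null(reduced_series)) {
    # removal empties every realization: degenerate everywhere
    out <- do.call(rbind, lapply(components, function(comp) {
      data.frame(species = species_id, realization = series$ids,
                 component = comp, delta = NA_real_, degenerate = TRUE,
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    return(out)
  }
  if (!reduced_meta) reduced_series$meta <- series$meta
  reduced_table <- vs_meta_dissimilarity(reduced_series, framework = framework,
                                         metric = metric,
                                         proportions = proportions)
  rows <- lapply(components, function(comp) {
    col <- .component_cols[[comp]]
    degen <- full_table$degenerate | reduced_table$degenerate
    data.frame(species = species_id,
               realization = series$ids,
               component = comp,
               delta = ifelse(degen, NA_real_,
                              full_table[[col]] - reduced_table[[col]]),
               degenerate = degen,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-species maxima of leave-one-out deltas
#'
#' Runs [species_delta()] for every species occurring in the meta-network
#' (or a subset) and summarizes each species by the maximum of its deltas
#' across the non-degenerate realizations — `max_delta_RW` being the
#' species' potential contribution to network flexibility. Cost scales as
#' O(S x T) pairwise partitions.
#'
#' @inheritParams species_delta
#' @param species optional character vector restricting the summary to
#'   these species (all meta-network species by default).
#' @return A data frame with one row per species: `species`, `guild`
#'   (`consumer`/`resource`), `max_delta_RW`, `max_delta_INT`,
#'   `max_delta_ST`, `max_delta_S` (`NA` for components not requested or
#'   for species degenerate in every realization) and `n_eval`, the number
#'   of realizations that entered the maxima.
#' @export
contribution_summary <- function(series,
                                 framework = c("framework2", "framework1"),
                                 metric = c("bray_curtis", "sorensen"),
                                 proportions = TRUE,
                                 components = c("RW", "INT", "ST", "S"),
                                 species = NULL,
                                 reduced_meta = TRUE) {
  framework <- match.arg(framework)
  metric <- match.arg(metric)
  components <- match.arg(components, several.ok = TRUE)
  stopifnot(inherits(series, "network_series"))
  all_sp <- species(series$meta)
  if (is.null(species)) {
    species <- all_sp
  } else {
    unknown <- setdiff(species, all_sp)
    if (length(unknown) > 0L) {
      stop("species not present in the meta-network: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    }
  }
  full_table <- vs_meta_dissimilarity(series, framework = framework,
                                      metric = metric,
                                      proportions = proportions)
  rows <- lapply(species, function(sp) {
    deltas <- species_delta(series, sp, components = components,
                            framework = framework, metric = metric,
                            proportions = proportions,
                            reduced_meta = reduced_meta,
                            full_table = full_table)
    ok <- !deltas$degenerate
    max_of <- function(comp) {
      if (!(comp %in% components)) return(NA_real_)
      d <- deltas$delta[deltas$component == comp & ok]
      if (length(d) == 0L) NA_real_ else max(d)
    }
    data.frame(species = sp,
               guild = if (sp %in% series$meta$consumers) "consumer" else "resource",
               max_delta_RW = max_of("RW"),
               max_delta_INT = max_of("INT"),
               max_delta_ST = max_of("ST"),
               max_delta_S = max_of("S"),
               n_eval = sum(ok & deltas$component == components[1L]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "framework") <- framework
  attr(out, "metric") <- metric
  attr(out, "proportions") <- proportions
  out
}

#' Write a contribution summary as tidy TSV
#'
#' @param summary the data frame returned by [contribution_summary()].
#' @param path output file path.
#' @param provenance optional named list of header comments.
#' @return Invisibly, the written data frame.
#' @export
write_contribution_summary <- function(summary, path, provenance = NULL) {
  df <- data.frame(species = summary$species, guild = summary$guild,
                   max_dRW = summary$max_delta_RW,
                   max_dINT = summary$max_delta_INT,
                   max_dST = summary$max_delta_ST,
                   max_dS = summary$max_delta_S,
                   n_eval = summary$n_eval, stringsAsFactors = FALSE)
  .write_table_with_header(df, path, provenance = provenance)
  invisible(df)
}
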