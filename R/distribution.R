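## Step 5B: pattern distribution among models -- per-model injective
## embedding counts, the feature-matrix CSV, and the generated
## graph-database (Cypher) query per pattern.

#' Generate the Cypher query for a pattern's distribution
#'
#' Emits the query dialect used to interrogate a model graph database: a
#' MATCH over the model/document anchor plus one relationship clause per
#' pattern edge, a WHERE clause with all pairwise node inequalities (nodes
#' are not allowed to be equal, which also excludes degenerate cycles), and
#' a DISTINCT model-id/filename/count RETURN ordered by descending count.
#'
#' @param pattern a \code{pattern} or a non-empty \code{reaction_graph}.
#' @return a single character string with the query text.
#' @export
pattern_to_graph_query <- function(pattern) {
  g <- if (inherits(pattern, "pattern")) pattern$graph else pattern
  stopifnot(inherits(g, "reaction_graph"))
  if (!nrow(g$nodes)) stop("pattern_to_graph_query requires a non-empty pattern")
  ids <- g$nodes$id
  anchor_rows <- which(g$nodes$kind == "SBML_REACTION")
  anchor <- ids[if (length(anchor_rows)) anchor_rows[1] else 1L]
  anchor_rel <- if (length(anchor_rows)) "HAS_REACTION" else "HAS_SPECIES"
  edge_clauses <- if (nrow(g$edges)) {
    sprintf("%s-[: %s]->%s", g$edges$from, g$edges$role, g$edges$to)
  } else character(0)
  match_parts <- c("(m: SBML_MODEL)-->(d: DOCUMENT)",
                   sprintf("m-[%s]->%s", anchor_rel, anchor),
                   edge_clauses)
  ineq <- character(0)
  if (length(ids) > 1) {
    pairs <- utils::combn(ids, 2)
    ineq <- sprintf("%s<>%s", pairs[1, ], pairs[2, ])
  }
  query <- paste0("MATCH ", paste(match_parts, collapse = ",\n   "))
  if (length(ineq))
    query <- paste0(query, "\nWHERE ", paste(ineq, collapse = " AND "))
  paste0(query, "\nRETURN DISTINCT ID(m), d.FILENAME, COUNT(", anchor,
         ") AS sum ORDER BY sum DESC")
}

#' Write one Cypher query file per pattern
#'
#' @param patterns a \code{pattern_set}.
#' @param dir output directory; files are named
#'   \code{<frequency>_<index>.cypher} after the pattern ids.
#' @return character vector of paths, invisibly.
#' @export
write_pattern_queries <- function(patterns, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (p in patterns$patterns) {
    path <- file.path(dir, paste0(p$pattern_id, ".cypher"))
    writeLines(pattern_to_graph_query(p), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Distribution of one pattern among models
#'
#' @param models model-record data frame (\code{model_id}, \code{model_name}).
#' @param networks a \code{network_set} covering those models.
#' @param pattern a \code{pattern} or \code{reaction_graph}.
#' @param mode label mode for matching.
#' @param orbit see \code{\link{count_embeddings}}.
#' @return data frame (\code{model_id}, \code{model_name}, \code{count})
#'   for models with at least one embedding, ordered by descending count.
#' @export
pattern_distribution <- function(models, networks, pattern,
                                 mode = "structural", orbit = FALSE) {
  g <- if (inherits(pattern, "pattern")) pattern$graph else pattern
  counts <- vapply(models$model_id, function(mid) {
    nets <- networks$networks[networks$info$model_id == mid]
    count_embeddings(g, nets, mode = mode, orbit = orbit)
  }, numeric(1))
  out <- data.frame(model_id = models$model_id,
                    model_name = models$model_name,
                    count = unname(counts), stringsAsFactors = FALSE)
  out <- out[out$count > 0, , drop = FALSE]
  out <- out[order(-out$count, out$model_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the model-by-pattern feature matrix
#'
#' One row per model (identified by id and name in the first two columns)
#' and one column per pattern, holding the number of injective embeddings
#' of the pattern in the model's reaction networks; each row is a feature
#' vector for one model.  Pattern columns are ordered by descending mining
#' frequency, ties broken by pattern id.
#'
#' @param models model-record data frame with unique \code{model_id}.
#' @param networks a \code{network_set} covering those models.
#' @param patterns a \code{pattern_set}.
#' @param mode label mode for matching.
#' @param path optional CSV output path (comma-separated, header row, UTF-8).
#' @param orbit report orbit counts instead of raw assignment counts.
#' @return data frame of class \code{feature_matrix}.
#' @export
build_feature_matrix <- function(models, networks, patterns,
                                 mode = "structural", path = NULL,
                                 orbit = FALSE) {
  if (anyDuplicated(models$model_id))
    stop("duplicate model ids: ",
         paste(unique(models$model_id[duplicated(models$model_id)]), collapse = ", "))
  plist <- patterns$patterns
  if (length(plist)) {
    sup <- vapply(plist, function(p) p$support, integer(1))
    pid <- vapply(plist, function(p) p$pattern_id, character(1))
    if (anyDuplicated(pid)) stop("duplicate pattern ids")
    plist <- plist[order(-sup, pid)]
    pid <- pid[order(-sup, pid)]
  } else pid <- character(0)
  out <- data.frame(model_id = models$model_id,
                    model_name = models$model_name,
                    stringsAsFactors = FALSE)
  nets_by_model <- lapply(models$model_id, function(mid)
    networks$networks[networks$info$model_id == mid])
  for (k in seq_along(plist)) {
    out[[pid[k]]] <- vapply(nets_by_model, function(nets)
      count_embeddings(plist[[k]]$graph, nets, mode = mode, orbit = orbit),
      numeric(1))
  }
  class(out) <- c("feature_matrix", class(out))
  if (!is.null(path))
    utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  out
}
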