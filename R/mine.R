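#' Mining configuration
#'
#' Frequency thresholds are absolute graph counts, as in transaction-based
#' frequent subgraph mining: a pattern is frequent when it occurs in at least
#' \code{min_support} and at most \code{max_support} of the graphs, where each
#' graph counts at most once no matter how many embeddings it contains.
#'
#' @param min_support minimum number of supporting graphs (>= 1).
#' @param max_support maximum number of supporting graphs; defaults to the
#'   corpus size at mining time.
#' @param max_edges cap on pattern size in edges (a pattern with k edges has
#'   at most k + 1 entities).  Subgraph isomorphism is NP-complete, so large
#'   caps combined with low thresholds can exhaust memory or time; the
#'   default of 10 keeps desk-scale runs tractable.
#' @param support_unit \code{"network"} counts connected reaction networks
#'   (the miner's native transaction); \code{"model"} counts distinct source
#'   models, so several networks of one model count once.
#' @param mode \code{"structural"} (labels are node kinds) or \code{"sbo"}
#'   (labels refined by SBO terms).
#' @param max_patterns capacity guard: mining stops with a capacity error
#'   when more than this many patterns would be emitted.
#' @return an object of class \code{mining_config}.
#' @export
mining_config <- function(min_support = 2L, max_support = NULL,
                          max_edges = 10L,
                          support_unit = c("network", "model"),
                          mode = c("structural", "sbo"),
                          max_patterns = 100000L) {
  support_unit <- match.arg(support_unit)
  mode <- match.arg(mode)
  min_support <- as.integer(min_support)
  if (is.na(min_support) || min_support < 1L)
    stop_config("min_support must be a positive integer (got ", min_support, ")")
  if (!is.null(max_support)) {
    max_support <- as.integer(max_support)
    if (is.na(max_support) || max_support < min_support)
      stop_config("max_support must be >= min_support")
  }
  max_edges <- as.integer(max_edges)
  if (is.na(max_edges) || max_edges < 0L)
    stop_config("max_edges must be a non-negative integer")
  structure(list(min_support = min_support, max_support = max_support,
                 max_edges = max_edges, support_unit = support_unit,
                 mode = mode, max_patterns = as.integer(max_patterns)),
            class = "mining_config")
}

stop_config <- function(...) {
  stop(structure(class = c("config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_capacity <- function(...) {
  stop(structure(class = c("capacity_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Mine all frequent connected subgraphs of a network set
#'
#' A gSpan-style extension-based search over canonical DFS codes.  Starting
#' from frequent node labels and frequent single edges, patterns grow one
#' edge at a time along the rightmost path of their canonical code; branches
#' whose code is not minimal are pruned, so every pattern is enumerated
#' exactly once, and branches whose support falls below \code{min_support}
#' are pruned by anti-monotonicity.  All frequent connected subgraphs up to
#' \code{max_edges} edges are returned, not only maximal ones, including
#' frequent single-node patterns.
#'
#' @param networks a \code{network_set}.
#' @param config a \code{mining_config}.
#' @return an object of class \code{pattern_set}: a list of \code{pattern}
#'   objects (fields \code{graph}, \code{support}, \code{supporting_networks},
#'   \code{supporting_models}, \code{pattern_id}, \code{lineage}) plus the
#'   configuration and corpus sizes.  Output order is deterministic
#'   (DFS-lexicographic).
#' @export
mine <- function(networks, config = mining_config()) {
  stopifnot(inherits(networks, "network_set"), inherits(config, "mining_config"))
  n_graphs <- length(networks)
  n_models <- length(unique(networks$info$model_id))
  n_units <- if (config$support_unit == "network") n_graphs else n_models
  max_support <- if (is.null(config$max_support)) n_units else config$max_support
  result <- list()
  if (n_graphs == 0L)
    return(pattern_set(result, config, n_graphs, n_models))

  mode <- config$mode
  label_table <- sort(unique(unlist(
    lapply(networks$networks, graph_node_labels, mode = mode))), method = "radix")
  G <- lapply(networks$networks, as_igr, mode = mode, label_table = label_table)
  unit_of <- if (config$support_unit == "network") seq_len(n_graphs)
             else match(networks$info$model_id, unique(networks$info$model_id))

  state <- new.env(parent = emptyenv())
  state$patterns <- list()
  state$n <- 0L

  emit <- function(code, root_label_int, graphs, lineage) {
    if (state$n >= config$max_patterns)
      stop_capacity("pattern capacity exceeded (max_patterns = ",
                    config$max_patterns,
                    "); raise the support thresholds or lower max_edges")
    state$n <- state$n + 1L
    sup_nets <- networks$info$network_id[graphs]
    sup_models <- unique(networks$info$model_id[graphs])
    support <- if (config$support_unit == "network") length(sup_nets)
               else length(sup_models)
    state$patterns[[state$n]] <- structure(list(
      graph = graph_from_code_matrix(code, label_table, root_label_int),
      support = support,
      support_unit = config$support_unit,
      supporting_networks = sup_nets,
      supporting_models = sup_models,
      n_edges = nrow(code), n_nodes = if (nrow(code)) max(code[, 1:2]) else 1L,
      lineage = lineage, pattern_id = NA_character_), class = "pattern")
  }

  unit_support <- function(graphs) length(unique(unit_of[graphs]))

  ## frequent single-node patterns (extension search starts from edges, so
  ## node patterns are seeded separately from frequent node labels)
  lineage_counter <- 0L
  for (lab in seq_along(label_table)) {
    graphs <- which(vapply(G, function(g) any(g$vl == lab), logical(1)))
    sup <- unit_support(graphs)
    if (sup >= config$min_support && sup <= max_support) {
      lineage_counter <- lineage_counter + 1L
      emit(matrix(integer(0), 0, 6), lab, graphs, lineage_counter)
    }
  }

  ## seed single-edge codes: the minimal orientation of every graph edge
  seeds <- new.env(parent = emptyenv())
  for (gi in seq_len(n_graphs)) {
    g <- G[[gi]]
    for (e in seq_along(g$elab)) {
      a <- g$efrom[e]; b <- g$eto[e]
      t0 <- c(1L, 2L, g$vl[a], g$elab[e], 0L, g$vl[b])
      t1 <- c(1L, 2L, g$vl[b], g$elab[e], 1L, g$vl[a])
      if (vec_cmp(t0[3:6], t1[3:6]) <= 0L) {
        tuple <- t0; nodes <- c(a, b)
      } else {
        tuple <- t1; nodes <- c(b, a)
      }
      key <- paste(tuple[3:6], collapse = ",")
      entry <- if (is.null(seeds[[key]])) list(tuple = tuple, embs = list())
               else seeds[[key]]
      entry$embs[[length(entry$embs) + 1L]] <-
        list(g = gi, nodes = nodes, edges = e)
      seeds[[key]] <- entry
    }
  }

  grow <- function(code, embs, lineage) {
    if (!is_min_code(code)) return(invisible())
    graphs <- sort(unique(vapply(embs, function(e) e$g, integer(1))))
    sup <- unit_support(graphs)
    if (sup < config$min_support) return(invisible())
    if (sup <= max_support) emit(code, NULL, graphs, lineage)
    if (nrow(code) >= config$max_edges) return(invisible())
    ## collect rightmost extensions over all embeddings, grouped by tuple
    exts <- new.env(parent = emptyenv())
    for (emb in embs) {
      for (ext in embedding_extensions(G[[emb$g]], code,
                                       list(nodes = emb$nodes, edges = emb$edges))) {
        key <- paste(ext$tuple, collapse = ",")
        entry <- if (is.null(exts[[key]])) list(tuple = ext$tuple, embs = list())
                 else exts[[key]]
        entry$embs[[length(entry$embs) + 1L]] <-
          list(g = emb$g, nodes = ext$nodes, edges = ext$edges)
        exts[[key]] <- entry
      }
    }
    keys <- ls(exts)
    if (!length(keys)) return(invisible())
    keymat <- t(vapply(keys, function(k) ext_key(exts[[k]]$tuple), numeric(6)))
    for (k in keys[do.call(order, as.data.frame(keymat))]) {
      entry <- exts[[k]]
      grow(rbind(code, entry$tuple, deparse.level = 0), entry$embs, lineage)
    }
    invisible()
  }

  seed_keys <- ls(seeds)
  if (length(seed_keys)) {
    keymat <- t(vapply(seed_keys, function(k) as.numeric(seeds[[k]]$tuple[3:6]),
                       numeric(4)))
    for (k in seed_keys[do.call(order, as.data.frame(keymat))]) {
      entry <- seeds[[k]]
      graphs <- unique(vapply(entry$embs, function(e) e$g, integer(1)))
      if (unit_support(graphs) < config$min_support) next
      lineage_counter <- lineage_counter + 1L
      grow(matrix(entry$tuple, 1, 6), entry$embs, lineage_counter)
    }
  }

  patterns <- state$patterns
  ## pattern id: frequency plus a disambiguating index within equal support
  if (length(patterns)) {
    sup <- vapply(patterns, function(p) p$support, integer(1))
    idx <- stats::ave(seq_along(sup), sup, FUN = seq_along)
    for (k in seq_along(patterns))
      patterns[[k]]$pattern_id <- paste0(sup[k], "_", idx[k])
  }
  pattern_set(patterns, config, n_graphs, n_models)
}

pattern_set <- function(patterns, config, n_networks, n_models) {
  structure(list(patterns = patterns, config = config,
                 n_networks = n_networks, n_models = n_models),
            class = "pattern_set")
}

#' @export
length.pattern_set <- function(x) length(x$patterns)

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern_set> %d frequent pattern(s) from %d network(s) / %d model(s)\n",
              length(x$patterns), x$n_networks, x$n_models))
  cat(sprintf("  min_support = %d, max_edges = %d, unit = %s, mode = %s\n",
              x$config$min_support, x$config$max_edges,
              x$config$support_unit, x$config$mode))
  invisible(x)
}

#' @export
print.pattern <- function(x, ...) {
  cat(sprintf("<pattern %s> %d node(s), %d edge(s), support %d (%s unit)\n",
              x$pattern_id, x$n_nodes, x$n_edges, x$support, x$support_unit))
  invisible(x)
}

#' Summarise a pattern set as a data frame
#'
#' @param object a \code{pattern_set}.
#' @param ... unused.
#' @return data frame with one row per pattern: id, entity/edge counts,
#'   support and number of supporting models.
#' @export
summary.pattern_set <- function(object, ...) {
  if (!length(object$patterns)) {
    return(data.frame(pattern_id = character(0), n_nodes = integer(0),
                      n_edges = integer(0), support = integer(0),
                      n_models = integer(0), stringsAsFactors = FALSE))
  }
  data.frame(
    pattern_id = vapply(object$patterns, function(p) p$pattern_id, character(1)),
    n_nodes = vapply(object$patterns, function(p) p$n_nodes, integer(1)),
    n_edges = vapply(object$patterns, function(p) p$n_edges, integer(1)),
    support = vapply(object$patterns, function(p) p$support, integer(1)),
    n_models = vapply(object$patterns, function(p) length(p$supporting_models),
                      integer(1)),
    stringsAsFactors = FALSE)
}
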