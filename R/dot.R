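## DOT (Graphviz digraph dialect) readers and writers.
##
## Two flavours are produced: plain network files, one digraph per connected
## reaction network preceded by a "# connected reaction network k" comment,
## and pattern files, where nodes are renamed Node_0..Node_k in DFS
## discovery order and each digraph is followed by a trailing
## "#=> frequency[, id, id,]" comment carrying the pattern's support and the
## supporting network/model identifiers.

dot_quote <- function(x) {
  needs <- !grepl("^[A-Za-z0-9_]+$", x)
  ifelse(needs, paste0("\"", gsub("\"", "\\\\\"", x), "\""), x)
}

node_label_string <- function(kind, sbo) {
  ifelse(is.na(sbo), kind, paste0(kind, "|", sbo))
}

format_dot_graph <- function(g, name = NULL) {
  header <- if (is.null(name)) "digraph {" else
    paste0("digraph ", dot_quote(as.character(name)), " {")
  labels <- node_label_string(g$nodes$kind, g$nodes$sbo)
  node_lines <- sprintf(" %s [label = %s];",
                        dot_quote(g$nodes$id), dot_quote(labels))
  edge_lines <- if (nrow(g$edges)) {
    sprintf(" %s -> %s [label = %s];",
            dot_quote(g$edges$from), dot_quote(g$edges$to),
            dot_quote(g$edges$role))
  } else character(0)
  c(header, node_lines, edge_lines)
}

#' Write graphs to a DOT file
#'
#' For a \code{network_set}, each connected reaction network becomes one
#' digraph preceded by a comment with its provenance.  For a
#' \code{pattern_set}, each pattern becomes one digraph named by its
#' extension lineage, with a trailing \code{#=> frequency[, ids,]} comment
#' listing its support and supporting identifiers.
#'
#' @param x a \code{network_set}, \code{pattern_set}, or single
#'   \code{reaction_graph}.
#' @param path output file.
#' @param ids_from for pattern sets, which supporting identifiers to attach:
#'   \code{"model"} (model names/ids, as in the published pattern files) or
#'   \code{"network"}.
#' @return \code{path}, invisibly.
#' @export
write_dot <- function(x, path, ids_from = c("model", "network")) {
  ids_from <- match.arg(ids_from)
  lines <- character(0)
  if (inherits(x, "reaction_graph")) {
    lines <- c(format_dot_graph(x), "}")
  } else if (inherits(x, "network_set")) {
    for (k in seq_along(x$networks)) {
      lines <- c(lines,
                 sprintf("# connected reaction network %d (%s)",
                         k, x$info$network_id[k]),
                 format_dot_graph(x$networks[[k]]), "}", "")
    }
  } else if (inherits(x, "pattern_set")) {
    for (p in x$patterns) {
      ids <- if (ids_from == "model") p$supporting_models else p$supporting_networks
      lines <- c(lines,
                 format_dot_graph(p$graph, name = p$lineage),
                 sprintf("}#=> %d[, %s,]", p$support, paste(ids, collapse = ", ")),
                 "")
    }
  } else stop("write_dot: unsupported object of class ", class(x)[1])
  writeLines(lines, path)
  invisible(path)
}

normalize_node_kind <- function(label) {
  up <- toupper(label)
  ifelse(up == "SBML_REACTION", "SBML_REACTION",
         ifelse(up == "SBML_SPECIES", "SBML_SPECIES", NA_character_))
}

dot_parse_error <- function(line_no, line, why) {
  stop(sprintf("DOT parse error at line %d (%s): %s", line_no, why, trimws(line)))
}

## strip one level of single/double quotes, including the curly typographic
## quotes that appear in published listings
dot_unquote <- function(x) {
  x <- trimws(x)
  gsub("^[\"'‘’“”]|[\"'‘’“”]$", "", x)
}

#' Read a DOT file of labelled digraphs
#'
#' Parses the digraph dialect used throughout the workflow: node statements
#' \code{id [label = X];}, edge statements \code{a -> b [label = X];},
#' optional digraph names, plain \code{#} comments, and the trailing
#' \code{#=> frequency[, ids,]} pattern annotation.  Quoted and unquoted
#' labels are both accepted.
#'
#' @param path DOT file.
#' @return a list of class \code{dot_graphs}; each element has fields
#'   \code{graph} (a \code{reaction_graph}), \code{name} (digraph name or
#'   \code{NA}), \code{frequency} (integer or \code{NA}) and
#'   \code{supporting_ids} (character).
#' @export
read_dot <- function(path) {
  lines <- readLines(path, warn = FALSE)
  graphs <- list()
  cur <- NULL
  rx_node <- "^\\s*(\"[^\"]*\"|[‘’'][^'‘’]*[‘’']|[A-Za-z0-9_.]+)\\s*\\[\\s*label\\s*=\\s*([^\\]]*?)\\s*\\]\\s*;?\\s*$"
  rx_edge <- "^\\s*(\"[^\"]*\"|[‘’'][^'‘’]*[‘’']|[A-Za-z0-9_.]+)\\s*->\\s*(\"[^\"]*\"|[‘’'][^'‘’]*[‘’']|[A-Za-z0-9_.]+)\\s*\\[\\s*label\\s*=\\s*([^\\]]*?)\\s*\\]\\s*;?\\s*$"
  finish <- function(cur, trailer) {
    freq <- NA_integer_; ids <- character(0)
    if (!is.na(trailer) && nzchar(trailer)) {
      m <- regmatches(trailer, regexec("^#\\s*=>\\s*(\\d+)\\s*(\\[(.*)\\])?", trailer))[[1]]
      if (length(m) < 2) stop("malformed frequency comment: ", trailer)
      freq <- as.integer(m[2])
      if (length(m) >= 4 && nzchar(m[4])) {
        ids <- trimws(strsplit(m[4], ",")[[1]])
        ids <- ids[nzchar(ids) & ids != "…"]
      }
    }
    nodes <- cur$nodes[!duplicated(cur$nodes$id), , drop = FALSE]
    edges <- unique(cur$edges)
    list(graph = reaction_graph(nodes, edges), name = cur$name,
         frequency = freq, supporting_ids = ids)
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    stripped <- trimws(line)
    if (!nzchar(stripped)) next
    if (is.null(cur)) {
      if (grepl("^#", stripped)) next
      m <- regmatches(stripped, regexec("^digraph\\s*(\\S+)?\\s*\\{\\s*$", stripped))[[1]]
      if (!length(m)) dot_parse_error(ln, line, "expected 'digraph {'")
      nm <- if (length(m) >= 2 && nzchar(m[2])) dot_unquote(m[2]) else NA_character_
      cur <- list(name = nm, nodes = empty_node_table(), edges = empty_edge_table())
      next
    }
    if (grepl("^\\}", stripped)) {
      trailer <- trimws(sub("^\\}", "", stripped))
      graphs[[length(graphs) + 1L]] <-
        finish(cur, if (nzchar(trailer)) trailer else NA_character_)
      cur <- NULL
      next
    }
    if (grepl("^#", stripped)) next
    me <- regmatches(stripped, regexec(rx_edge, stripped, perl = TRUE))[[1]]
    if (length(me)) {
      from <- dot_unquote(me[2]); to <- dot_unquote(me[3])
      role <- toupper(dot_unquote(me[4]))
      if (!role %in% EDGE_ROLES) dot_parse_error(ln, line, "unknown edge label")
      cur$edges <- rbind(cur$edges,
                         data.frame(from = from, to = to, role = role,
                                    stringsAsFactors = FALSE))
      next
    }
    mn <- regmatches(stripped, regexec(rx_node, stripped, perl = TRUE))[[1]]
    if (length(mn)) {
      id <- dot_unquote(mn[2])
      label <- dot_unquote(mn[3])
      parts <- strsplit(label, "|", fixed = TRUE)[[1]]
      kind <- normalize_node_kind(parts[1])
      if (is.na(kind)) dot_parse_error(ln, line, "unknown node label")
      sbo <- if (length(parts) > 1) parts[2] else NA_character_
      cur$nodes <- rbind(cur$nodes,
                         data.frame(id = id, kind = kind, sbo = sbo,
                                    stringsAsFactors = FALSE))
      next
    }
    if (identical(stripped, "…") || identical(stripped, "...")) next
    dot_parse_error(ln, line, "unrecognised statement")
  }
  if (!is.null(cur)) stop("DOT parse error: unterminated digraph at end of file")
  structure(graphs, class = "dot_graphs")
}

#' Convert parsed DOT graphs into a network set
#'
#' @param graphs a \code{dot_graphs} object from \code{\link{read_dot}}.
#' @param model_id provenance assigned to every graph.
#' @return a \code{network_set} (graphs are re-split into weakly-connected
#'   components, so a file holding one big digraph is handled too).
#' @export
networks_from_dot <- function(graphs, model_id = "dot") {
  sets <- list(); k <- 0L
  for (entry in graphs) {
    k <- k + 1L
    sets[[k]] <- split_components(entry$graph, model_id = model_id)
  }
  if (!length(sets)) return(network_set())
  merged <- combine_network_sets(sets)
  merged$info$component_index <- seq_len(nrow(merged$info))
  merged$info$network_id <- paste0(model_id, "#", merged$info$component_index)
  merged
}
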