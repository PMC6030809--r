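## Controlled vocabularies of the bipartite reaction-network graph model.
NODE_KINDS   <- c("SBML_REACTION", "SBML_SPECIES")
EDGE_ROLES   <- c("IS_REACTANT", "IS_MODIFIER", "HAS_PRODUCT")
EXPORT_ROLES <- c("HAS_REACTANT", "HAS_MODIFIER", "HAS_PRODUCT")

empty_node_table <- function() {
  data.frame(id = character(0), kind = character(0), sbo = character(0),
             stringsAsFactors = FALSE)
}

empty_edge_table <- function() {
  data.frame(from = character(0), to = character(0), role = character(0),
             stringsAsFactors = FALSE)
}

#' Construct a labelled reaction-network digraph
#'
#' The central container of the package: a directed bipartite graph whose
#' nodes are SBML species and reactions and whose edges carry the
#' participation role of a species in a reaction.  Reactant and modifier
#' edges run species -> reaction, product edges run reaction -> species.
#'
#' @param nodes data frame with columns \code{id} (character, unique),
#'   \code{kind} (\code{"SBML_REACTION"} or \code{"SBML_SPECIES"}) and
#'   optionally \code{sbo} (SBO accession of the form \code{SBO:0000NNN},
#'   or \code{NA} when unannotated).
#' @param edges data frame with columns \code{from}, \code{to} (node ids)
#'   and \code{role} (one of \code{IS_REACTANT}, \code{IS_MODIFIER},
#'   \code{HAS_PRODUCT}).
#' @param validate check the bipartite and edge-direction invariants.
#' @return an object of class \code{reaction_graph}.
#' @export
reaction_graph <- function(nodes = empty_node_table(),
                           edges = empty_edge_table(),
                           validate = TRUE) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(nodes$sbo)) nodes$sbo <- rep(NA_character_, nrow(nodes))
  nodes$id <- as.character(nodes$id)
  nodes$kind <- as.character(nodes$kind)
  nodes$sbo <- as.character(nodes$sbo)
  if (nrow(edges)) {
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    edges$role <- as.character(edges$role)
  } else {
    edges <- empty_edge_table()
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  g <- structure(list(nodes = nodes, edges = edges), class = "reaction_graph")
  if (validate) validate_reaction_graph(g)
  g
}

#' Validate the invariants of a reaction graph
#'
#' Checks unique node ids, known node kinds and edge roles, bipartiteness,
#' the role-dependent edge directions, and the absence of duplicate
#' \code{(from, to, role)} triples.
#'
#' @param g a \code{reaction_graph}.
#' @return \code{g}, invisibly; stops with an informative error otherwise.
#' @export
validate_reaction_graph <- function(g) {
  stopifnot(inherits(g, "reaction_graph"))
  nodes <- g$nodes; edges <- g$edges
  if (anyDuplicated(nodes$id))
    stop("duplicate node ids: ", paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  bad_kind <- setdiff(unique(nodes$kind), NODE_KINDS)
  if (length(bad_kind))
    stop("unknown node kind(s): ", paste(bad_kind, collapse = ", "))
  if (!nrow(edges)) return(invisible(g))
  bad_role <- setdiff(unique(edges$role), EDGE_ROLES)
  if (length(bad_role))
    stop("unknown edge role(s): ", paste(bad_role, collapse = ", "))
  kind <- stats::setNames(nodes$kind, nodes$id)
  missing <- setdiff(unique(c(edges$from, edges$to)), nodes$id)
  if (length(missing))
    stop("edges reference undeclared node(s): ", paste(missing, collapse = ", "))
  kf <- kind[edges$from]; kt <- kind[edges$to]
  if (any(kf == kt))
    stop("graph is not bipartite: edge joins two nodes of kind ", kf[which(kf == kt)[1]])
  in_roles <- edges$role %in% c("IS_REACTANT", "IS_MODIFIER")
  bad_dir <- (in_roles & !(kf == "SBML_SPECIES" & kt == "SBML_REACTION")) |
             (!in_roles & !(kf == "SBML_REACTION" & kt == "SBML_SPECIES"))
  if (any(bad_dir))
    stop("edge direction violates role convention for role ", edges$role[which(bad_dir)[1]])
  key <- paste(edges$from, edges$to, edges$role, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (from, to, role) edge triples")
  invisible(g)
}

#' @export
print.reaction_graph <- function(x, ...) {
  cat(sprintf("<reaction_graph> %d nodes (%d reactions, %d species), %d edges\n",
              nrow(x$nodes), sum(x$nodes$kind == "SBML_REACTION"),
              sum(x$nodes$kind == "SBML_SPECIES"), nrow(x$edges)))
  invisible(x)
}

#' Node labels of a graph under a mining mode
#'
#' In structural mode the label is the node kind alone; in SBO mode the label
#' refines the kind with the node's SBO accession (unannotated nodes keep the
#' bare kind).
#'
#' @param g a \code{reaction_graph}.
#' @param mode \code{"structural"} or \code{"sbo"}.
#' @return character vector of labels, parallel to \code{g$nodes}.
#' @export
graph_node_labels <- function(g, mode = c("structural", "sbo")) {
  mode <- match.arg(mode)
  if (!nrow(g$nodes)) return(character(0))
  if (mode == "structural") return(g$nodes$kind)
  ifelse(is.na(g$nodes$sbo), g$nodes$kind, paste0(g$nodes$kind, "|", g$nodes$sbo))
}

#' Convert exported edge tuples into a labelled digraph
#'
#' Takes the reaction-centric export tuples (reaction id, HAS_* role, species
#' id) and builds the mining graph: the edge direction is adjusted so that
#' reactants and modifiers point into the reaction and products point out of
#' it, and nodes are labelled as reaction or species by their position in the
#' tuple.
#'
#' @param tuples data frame with columns \code{reaction_id}, \code{role}
#'   (\code{HAS_REACTANT}, \code{HAS_MODIFIER} or \code{HAS_PRODUCT}) and
#'   \code{species_id}.
#' @param sbo optional data frame with columns \code{element_id} and
#'   \code{term}, attaching SBO accessions to nodes.
#' @return a \code{reaction_graph}.
#' @export
orient_edges <- function(tuples, sbo = NULL) {
  if (is.null(tuples) || !nrow(tuples)) return(reaction_graph())
  tuples <- as.data.frame(tuples, stringsAsFactors = FALSE)
  stopifnot(all(c("reaction_id", "role", "species_id") %in% names(tuples)))
  bad <- setdiff(unique(as.character(tuples$role)), EXPORT_ROLES)
  if (length(bad))
    stop("unknown participant role(s): ", paste(bad, collapse = ", "))
  rid <- as.character(tuples$reaction_id)
  sid <- as.character(tuples$species_id)
  role <- as.character(tuples$role)
  clash <- intersect(unique(rid), unique(sid))
  if (length(clash))
    stop("identifier(s) used both as reaction and species: ",
         paste(clash, collapse = ", "))
  out <- role == "HAS_PRODUCT"
  edges <- data.frame(
    from = ifelse(out, rid, sid),
    to   = ifelse(out, sid, rid),
    role = ifelse(out, "HAS_PRODUCT",
                  ifelse(role == "HAS_REACTANT", "IS_REACTANT", "IS_MODIFIER")),
    stringsAsFactors = FALSE)
  edges <- unique(edges)
  nodes <- rbind(
    data.frame(id = unique(rid), kind = "SBML_REACTION", stringsAsFactors = FALSE),
    data.frame(id = unique(sid), kind = "SBML_SPECIES", stringsAsFactors = FALSE))
  nodes$sbo <- NA_character_
  if (!is.null(sbo) && nrow(sbo)) {
    sbo <- as.data.frame(sbo, stringsAsFactors = FALSE)
    idx <- match(nodes$id, as.character(sbo$element_id))
    nodes$sbo <- as.character(sbo$term)[idx]
  }
  reaction_graph(nodes, edges)
}

#' A set of connected reaction networks with model provenance
#'
#' @param networks list of connected \code{reaction_graph} objects.
#' @param info data frame with one row per network: \code{network_id},
#'   \code{model_id}, \code{component_index}.
#' @return an object of class \code{network_set}.
#' @export
network_set <- function(networks = list(), info = NULL) {
  if (is.null(info)) {
    info <- data.frame(network_id = character(0), model_id = character(0),
                       component_index = integer(0), stringsAsFactors = FALSE)
  }
  stopifnot(length(networks) == nrow(info))
  structure(list(networks = networks, info = info), class = "network_set")
}

#' @export
print.network_set <- function(x, ...) {
  cat(sprintf("<network_set> %d connected networks from %d model(s)\n",
              length(x$networks), length(unique(x$info$model_id))))
  invisible(x)
}

#' @export
length.network_set <- function(x) length(x$networks)

#' Concatenate network sets
#'
#' @param ... \code{network_set} objects.
#' @return a single \code{network_set}.
#' @export
combine_network_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !inherits(sets[[1]], "network_set"))
    sets <- sets[[1]]
  networks <- do.call(c, c(lapply(sets, function(s) s$networks), list(list())))
  info <- do.call(rbind, c(lapply(sets, function(s) s$info),
                           list(network_set()$info)))
  rownames(info) <- NULL
  network_set(networks, info)
}

#' Split a graph into its weakly-connected reaction networks
#'
#' Each connected component becomes its own network; components from one
#' model stay node-disjoint and are not further associated with each other
#' beyond the retained model provenance.  Connectivity ignores edge
#' direction, so a species that is product of one reaction and reactant of
#' another joins the two reactions into one network.
#'
#' @param g a \code{reaction_graph} (possibly disconnected).
#' @param model_id provenance identifier recorded with every component.
#' @return a \code{network_set}.
#' @export
split_components <- function(g, model_id = "model") {
  validate_reaction_graph(g)
  if (!nrow(g$nodes)) return(network_set())
  ig <- igraph::graph_from_data_frame(
    g$edges[, c("from", "to"), drop = FALSE],
    directed = TRUE, vertices = g$nodes$id)
  memb <- igraph::components(ig, mode = "weak")$membership
  memb <- memb[g$nodes$id]
  comp_ids <- sort(unique(memb))
  networks <- vector("list", length(comp_ids))
  for (k in seq_along(comp_ids)) {
    ids <- g$nodes$id[memb == comp_ids[k]]
    sub_nodes <- g$nodes[g$nodes$id %in% ids, , drop = FALSE]
    sub_edges <- g$edges[g$edges$from %in% ids & g$edges$to %in% ids, , drop = FALSE]
    networks[[k]] <- reaction_graph(sub_nodes, sub_edges, validate = FALSE)
  }
  info <- data.frame(
    network_id = paste0(model_id, "#", seq_along(comp_ids)),
    model_id = model_id,
    component_index = seq_along(comp_ids),
    stringsAsFactors = FALSE)
  network_set(networks, info)
}

#' Test two reaction graphs for label-preserving isomorphism
#'
#' @param g1,g2 \code{reaction_graph} objects.
#' @param mode label mode, see \code{\link{graph_node_labels}}.
#' @return logical.
#' @export
graphs_isomorphic <- function(g1, g2, mode = "structural") {
  if (nrow(g1$nodes) != nrow(g2$nodes) || nrow(g1$edges) != nrow(g2$edges))
    return(FALSE)
  l1 <- sort(graph_node_labels(g1, mode)); l2 <- sort(graph_node_labels(g2, mode))
  if (!identical(l1, l2)) return(FALSE)
  if (nrow(g1$nodes) == 0) return(TRUE)
  identical(dfs_code_key(minimum_dfs_code(g1, mode)),
            dfs_code_key(minimum_dfs_code(g2, mode)))
}
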