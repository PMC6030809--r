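## Injective label-preserving embeddings of a pattern into a host graph.
##
## An embedding maps pattern nodes to pairwise-distinct host nodes such that
## labels match and every pattern edge (with its direction and role) is
## present between the images -- a non-induced subgraph embedding, mirroring
## the node-inequality semantics of the generated graph-database queries.

## Backtracking matcher; returns the number of injective assignments, or
## stops at the first one when count_all = FALSE (returning 0 or 1).
match_embeddings <- function(pattern, g, mode = "structural", count_all = TRUE) {
  np <- nrow(pattern$nodes)
  ng <- nrow(g$nodes)
  if (np == 0L) return(0L)
  if (np > ng) return(0L)
  pl <- graph_node_labels(pattern, mode)
  gl <- graph_node_labels(g, mode)
  ## visit pattern nodes in a connectivity order so every node after the
  ## first is constrained by at least one already-assigned neighbour
  pe_from <- match(pattern$edges$from, pattern$nodes$id)
  pe_to <- match(pattern$edges$to, pattern$nodes$id)
  pe_role <- match(pattern$edges$role, EDGE_ROLES)
  ord <- integer(0); seen <- logical(np)
  queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]; ord <- c(ord, v)
    nb <- unique(c(pe_to[pe_from == v], pe_from[pe_to == v]))
    nb <- nb[!seen[nb]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  if (length(ord) < np)
    stop("pattern must be connected for embedding counting")
  pos <- match(seq_len(np), ord)
  ## for each step k, the pattern edges joining ord[k] to earlier nodes
  constraints <- lapply(seq_len(np), function(k) {
    v <- ord[k]
    rows <- which((pe_from == v & pos[pe_to] < k) | (pe_to == v & pos[pe_from] < k))
    rows
  })
  ## host edge lookup and adjacency by (role, direction)
  ge_from <- match(g$edges$from, g$nodes$id)
  ge_to <- match(g$edges$to, g$nodes$id)
  ge_role <- match(g$edges$role, EDGE_ROLES)
  gkey <- paste(ge_from, ge_to, ge_role)
  assigned <- integer(np)   # pattern index -> host index
  used <- logical(ng)
  count <- 0L
  recurse <- function(k) {
    if (k > np) {
      count <<- count + 1L
      return(!count_all)     # TRUE aborts the search
    }
    v <- ord[k]
    for (h in which(gl == pl[v] & !used)) {
      ok <- TRUE
      for (r in constraints[[k]]) {
        a <- if (pe_from[r] == v) h else assigned[pe_from[r]]
        b <- if (pe_to[r] == v) h else assigned[pe_to[r]]
        if (!(paste(a, b, pe_role[r]) %in% gkey)) { ok <- FALSE; break }
      }
      if (!ok) next
      assigned[v] <<- h; used[h] <<- TRUE
      done <- recurse(k + 1L)
      used[h] <<- FALSE
      if (done) return(TRUE)
    }
    FALSE
  }
  recurse(1L)
  count
}

#' Does a host graph contain a pattern?
#'
#' True exactly when an injective node mapping from the pattern into the
#' graph exists that preserves node labels, edge presence, edge direction and
#' edge labels (a non-induced embedding).
#'
#' @param pattern a connected \code{reaction_graph}.
#' @param g a \code{reaction_graph}.
#' @param mode label mode, \code{"structural"} or \code{"sbo"}.
#' @return logical.
#' @export
supports <- function(pattern, g, mode = "structural") {
  match_embeddings(pattern, g, mode = mode, count_all = FALSE) > 0L
}

#' Count injective embeddings of a pattern in a model's networks
#'
#' Counts every injective node assignment separately, summed over the
#' model's networks; automorphic re-assignments of the same node set count
#' as distinct embeddings, mirroring the row count of the generated
#' graph-database query with its pairwise node-inequality clauses.  With
#' \code{orbit = TRUE} the raw count is divided by the pattern's
#' automorphism count, giving the number of distinct sub-network
#' occurrences instead.
#'
#' @param pattern a connected \code{reaction_graph}.
#' @param model_networks a list of \code{reaction_graph} objects (or a
#'   single graph).
#' @param mode label mode.
#' @param orbit divide by the automorphism count of the pattern.
#' @return a non-negative number (integer unless \code{orbit} divides it).
#' @export
count_embeddings <- function(pattern, model_networks, mode = "structural",
                             orbit = FALSE) {
  if (inherits(model_networks, "reaction_graph"))
    model_networks <- list(model_networks)
  total <- sum(vapply(model_networks, function(g)
    match_embeddings(pattern, g, mode = mode, count_all = TRUE), integer(1)))
  if (orbit) {
    aut <- match_embeddings(pattern, pattern, mode = mode, count_all = TRUE)
    total <- total / aut
  }
  total
}
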