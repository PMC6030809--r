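# Independent oracles: exhaustive enumeration, kept free of the package's
# DFS-code and backtracking machinery so they can stand as ground truth.

# all injective node assignments of `pattern` into `g` (naive: every
# label-compatible assignment is generated, then every pattern edge checked)
oracle_embeddings <- function(pattern, g, mode = "structural") {
  pl <- graph_node_labels(pattern, mode)
  gl <- graph_node_labels(g, mode)
  np <- length(pl)
  if (np == 0 || np > length(gl)) return(0L)
  gkey <- paste(g$edges$from, g$edges$to, g$edges$role)
  count <- 0L
  assign_next <- function(k, used, map) {
    if (k > np) {
      for (e in seq_len(nrow(pattern$edges))) {
        a <- map[[pattern$edges$from[e]]]
        b <- map[[pattern$edges$to[e]]]
        if (!(paste(a, b, pattern$edges$role[e]) %in% gkey)) return(invisible())
      }
      count <<- count + 1L
      return(invisible())
    }
    for (h in which(gl == pl[k] & !used)) {
      used[h] <- TRUE
      map[[pattern$nodes$id[k]]] <- g$nodes$id[h]
      assign_next(k + 1, used, map)
      used[h] <- FALSE
    }
  }
  assign_next(1L, logical(length(gl)), list())
  count
}

oracle_supports <- function(pattern, g, mode = "structural") {
  oracle_embeddings(pattern, g, mode) > 0L
}

# label-preserving digraph isomorphism by brute force: bijective node map
# preserving all edges; with equal edge counts that is an isomorphism
oracle_isomorphic <- function(g1, g2, mode = "structural") {
  if (nrow(g1$nodes) != nrow(g2$nodes) || nrow(g1$edges) != nrow(g2$edges))
    return(FALSE)
  if (!identical(sort(graph_node_labels(g1, mode)),
                 sort(graph_node_labels(g2, mode)))) return(FALSE)
  if (nrow(g1$nodes) == 0) return(TRUE)
  oracle_embeddings(g1, g2, mode) > 0L
}

# every connected subgraph of g with <= max_edges edges (plus single nodes),
# enumerated as growing connected edge subsets
oracle_subgraphs <- function(g, max_edges) {
  out <- lapply(seq_len(nrow(g$nodes)), function(k)
    reaction_graph(g$nodes[k, , drop = FALSE]))
  m <- nrow(g$edges)
  if (m == 0 || max_edges == 0) return(out)
  seen <- new.env(parent = emptyenv())
  frontier <- lapply(seq_len(m), function(e) e)
  for (e in frontier) seen[[paste(e, collapse = ",")]] <- TRUE
  build <- function(subset) {
    edges <- g$edges[subset, , drop = FALSE]
    ids <- unique(c(edges$from, edges$to))
    reaction_graph(g$nodes[g$nodes$id %in% ids, , drop = FALSE], edges)
  }
  out <- c(out, lapply(frontier, build))
  size <- 1L
  while (size < max_edges && length(frontier)) {
    nxt <- list()
    for (subset in frontier) {
      nodes <- unique(c(g$edges$from[subset], g$edges$to[subset]))
      cand <- setdiff(which(g$edges$from %in% nodes | g$edges$to %in% nodes),
                      subset)
      for (e in cand) {
        key <- paste(sort(c(subset, e)), collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          nxt[[length(nxt) + 1L]] <- sort(c(subset, e))
        }
      }
    }
    out <- c(out, lapply(nxt, build))
    frontier <- nxt
    size <- size + 1L
  }
  out
}

# cheap invariant for bucketing candidate isomorphs before pairwise checks
oracle_invariant <- function(g, mode = "structural") {
  labels <- graph_node_labels(g, mode)
  deg_out <- table(factor(g$edges$from, levels = g$nodes$id))
  deg_in <- table(factor(g$edges$to, levels = g$nodes$id))
  paste(nrow(g$nodes), nrow(g$edges),
        paste(sort(paste(labels, deg_out, deg_in)), collapse = "&"),
        paste(sort(g$edges$role), collapse = "&"))
}

# exhaustive frequent-subgraph mining by full enumeration; returns a list of
# list(graph, support) for all isomorphism classes within [min, max] support
oracle_mine <- function(networks, min_support, max_support = NULL,
                        max_edges = 5, support_unit = "network",
                        mode = "structural") {
  n_units <- if (support_unit == "network") length(networks$networks)
             else length(unique(networks$info$model_id))
  if (is.null(max_support)) max_support <- n_units
  unit_of <- if (support_unit == "network") seq_along(networks$networks)
             else match(networks$info$model_id, unique(networks$info$model_id))
  classes <- list()     # list of list(graph, inv, units)
  for (k in seq_along(networks$networks)) {
    subs <- oracle_subgraphs(networks$networks[[k]], max_edges)
    for (s in subs) {
      inv <- oracle_invariant(s, mode)
      hit <- NULL
      for (ci in seq_along(classes)) {
        if (classes[[ci]]$inv == inv &&
            oracle_isomorphic(classes[[ci]]$graph, s, mode)) { hit <- ci; break }
      }
      if (is.null(hit)) {
        classes[[length(classes) + 1L]] <- list(graph = s, inv = inv,
                                                units = unit_of[k])
      } else {
        classes[[hit]]$units <- union(classes[[hit]]$units, unit_of[k])
      }
    }
  }
  out <- list()
  for (cl in classes) {
    sup <- length(cl$units)
    if (sup >= min_support && sup <= max_support)
      out[[length(out) + 1L]] <- list(graph = cl$graph, support = sup)
  }
  out
}

# match mined patterns against an oracle result: equal class count, and a
# support-preserving isomorphic partner for every oracle class
expect_same_pattern_sets <- function(mined, oracle, mode = "structural") {
  expect_equal(length(mined$patterns), length(oracle))
  used <- logical(length(mined$patterns))
  for (o in oracle) {
    hit <- FALSE
    for (k in seq_along(mined$patterns)) {
      if (used[k]) next
      p <- mined$patterns[[k]]
      if (p$support == o$support &&
          oracle_isomorphic(p$graph, o$graph, mode)) {
        used[k] <- TRUE; hit <- TRUE; break
      }
    }
    if (!hit) {
      fail(sprintf("oracle pattern (%d nodes, %d edges, support %d) not mined",
                   nrow(o$graph$nodes), nrow(o$graph$edges), o$support))
      return(invisible())
    }
  }
  succeed()
}
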