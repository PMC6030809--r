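## DFS-code machinery: canonical forms for labelled directed multigraphs.
##
## A DFS code is an ordered list of edge tuples (i, j, li, le, dir, lj) where
## i, j are 1-based discovery indices, li/lj node labels, le the edge label
## and dir flags whether the stored graph edge runs i->j (0) or j->i (1);
## the direction flag is ordered after the edge label, extending the
## undirected gSpan tuple order to digraphs.  The lexicographic minimum over
## all DFS traversals is a canonical form: equal minimum codes <=> label-
## preserving digraph isomorphism.

## ---- internal integer graph representation ------------------------------

## igr: list(n, vl (int labels), efrom, eto, elab (parallel int vectors),
##           inc (per node, incident edge ids))
as_igr <- function(g, mode = "structural", label_table = NULL) {
  labels <- graph_node_labels(g, mode)
  if (is.null(label_table))
    label_table <- sort(unique(labels), method = "radix")
  vl <- match(labels, label_table)
  if (anyNA(vl)) stop("node label missing from label table")
  efrom <- match(g$edges$from, g$nodes$id)
  eto <- match(g$edges$to, g$nodes$id)
  elab <- match(g$edges$role, EDGE_ROLES)
  n <- nrow(g$nodes)
  inc <- vector("list", n)
  for (k in seq_len(n)) inc[[k]] <- integer(0)
  for (e in seq_along(efrom)) {
    inc[[efrom[e]]] <- c(inc[[efrom[e]]], e)
    if (eto[e] != efrom[e]) inc[[eto[e]]] <- c(inc[[eto[e]]], e)
  }
  list(n = n, vl = vl, efrom = efrom, eto = eto, elab = elab, inc = inc,
       label_table = label_table)
}

## Sort key under which candidate extensions of a shared code prefix order
## identically to the gSpan tuple order: backward before forward, backward by
## ascending target, forward by descending source, then (li, le, dir, lj).
ext_key <- function(tuple) {
  fwd <- tuple[1] < tuple[2]
  c(if (fwd) 1L else 0L,
    if (fwd) -tuple[1] else tuple[2],
    tuple[3:6])
}

vec_cmp <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(-1L)
    if (a[k] > b[k]) return(1L)
  }
  0L
}

## Rightmost path of a code matrix (vector of indices from root to rightmost
## vertex).  Forward rows have i < j; the path chains forward-edge parents.
rightmost_path <- function(code) {
  fwd <- code[, 1] < code[, 2]
  r <- max(code[, 2][fwd], 1L)
  path <- r
  while (r != 1L) {
    r <- code[fwd & code[, 2] == r, 1][1]
    path <- c(r, path)
  }
  path
}

## Enumerate the admissible rightmost extensions of one embedding.
## emb: list(nodes = graph nodes by discovery index, edges = used edge ids)
## Returns list of list(tuple, nodes, edges).
embedding_extensions <- function(G, code, emb) {
  out <- list()
  if (nrow(code) == 0) stop("embedding_extensions requires a non-empty code")
  path <- rightmost_path(code)
  r <- path[length(path)]
  nodes <- emb$nodes
  used <- emb$edges
  ## last backward target from the rightmost vertex (validity constraint)
  bwd <- code[, 1] == r & code[, 2] < code[, 1]
  min_bwd_j <- if (any(bwd)) max(code[bwd, 2]) else 0L
  gu <- nodes[r]
  for (e in G$inc[[gu]]) {
    if (e %in% used) next
    a <- G$efrom[e]; b <- G$eto[e]
    ov <- if (a == gu) b else a
    v <- match(ov, nodes)
    if (!is.na(v) && v != r && v %in% path && v > min_bwd_j) {
      dir <- if (a == gu) 0L else 1L
      out[[length(out) + 1L]] <- list(
        tuple = c(r, v, G$vl[gu], G$elab[e], dir, G$vl[ov]),
        nodes = nodes, edges = c(used, e))
    }
  }
  for (v in rev(path)) {
    gv <- nodes[v]
    for (e in G$inc[[gv]]) {
      if (e %in% used) next
      a <- G$efrom[e]; b <- G$eto[e]
      w <- if (a == gv) b else a
      if (!is.na(match(w, nodes))) next
      dir <- if (a == gv) 0L else 1L
      out[[length(out) + 1L]] <- list(
        tuple = c(v, r + 1L, G$vl[gv], G$elab[e], dir, G$vl[w]),
        nodes = c(nodes, w), edges = c(used, e))
    }
  }
  out
}

## Build the minimum DFS code of a connected igr.  When `limit` (a code
## matrix) is supplied, construction stops as soon as the true minimum drops
## below the limit; used for the gSpan is-minimal test.
min_code_igr <- function(G, limit = NULL) {
  m <- length(G$elab)
  if (m == 0L)
    return(list(code = matrix(integer(0), 0, 6), minimal = TRUE))
  ## seed: minimal single-edge tuple over both orientations of every edge
  best <- NULL; embs <- list()
  for (e in seq_len(m)) {
    a <- G$efrom[e]; b <- G$eto[e]
    for (orient in 0:1) {
      u <- if (orient == 0L) a else b
      w <- if (orient == 0L) b else a
      tuple <- c(1L, 2L, G$vl[u], G$elab[e], orient, G$vl[w])
      cmp <- if (is.null(best)) -1L else vec_cmp(tuple[3:6], best[3:6])
      if (cmp < 0L) {
        best <- tuple
        embs <- list(list(nodes = c(u, w), edges = e))
      } else if (cmp == 0L) {
        embs[[length(embs) + 1L]] <- list(nodes = c(u, w), edges = e)
      }
    }
  }
  code <- matrix(best, 1, 6)
  if (!is.null(limit) && vec_cmp(ext_key(best), ext_key(limit[1, ])) < 0L)
    return(list(code = code, minimal = FALSE))
  while (nrow(code) < m) {
    best_key <- NULL; best_tuple <- NULL; new_embs <- list()
    for (emb in embs) {
      for (ext in embedding_extensions(G, code, emb)) {
        key <- ext_key(ext$tuple)
        cmp <- if (is.null(best_key)) -1L else vec_cmp(key, best_key)
        if (cmp < 0L) {
          best_key <- key; best_tuple <- ext$tuple
          new_embs <- list(list(nodes = ext$nodes, edges = ext$edges))
        } else if (cmp == 0L) {
          new_embs[[length(new_embs) + 1L]] <- list(nodes = ext$nodes, edges = ext$edges)
        }
      }
    }
    k <- nrow(code) + 1L
    if (!is.null(limit)) {
      cmp <- vec_cmp(best_key, ext_key(limit[k, ]))
      if (cmp < 0L)
        return(list(code = rbind(code, best_tuple, deparse.level = 0), minimal = FALSE))
    }
    code <- rbind(code, best_tuple, deparse.level = 0)
    embs <- new_embs
  }
  list(code = code, minimal = TRUE)
}

## Rebuild an igr from a code matrix (node labels from tuple fields).
igr_from_code <- function(code, root_label = NULL) {
  if (nrow(code) == 0) {
    vl <- as.integer(root_label)
    return(list(n = 1L, vl = vl, efrom = integer(0), eto = integer(0),
                elab = integer(0), inc = list(integer(0)), label_table = NULL))
  }
  n <- max(code[, 1:2])
  vl <- integer(n)
  for (r in seq_len(nrow(code))) {
    vl[code[r, 1]] <- code[r, 3]
    vl[code[r, 2]] <- code[r, 6]
  }
  src <- ifelse(code[, 5] == 0L, code[, 1], code[, 2])
  dst <- ifelse(code[, 5] == 0L, code[, 2], code[, 1])
  inc <- vector("list", n)
  for (k in seq_len(n)) inc[[k]] <- integer(0)
  for (e in seq_len(nrow(code))) {
    inc[[src[e]]] <- c(inc[[src[e]]], e)
    inc[[dst[e]]] <- c(inc[[dst[e]]], e)
  }
  list(n = n, vl = vl, efrom = as.integer(src), eto = as.integer(dst),
       elab = as.integer(code[, 4]), inc = inc, label_table = NULL)
}

## gSpan minimality test for a code matrix.
is_min_code <- function(code) {
  if (nrow(code) == 0) return(TRUE)
  min_code_igr(igr_from_code(code), limit = code)$minimal
}

## ---- public canonical form ----------------------------------------------

#' Minimum DFS code of a connected labelled digraph
#'
#' Computes the canonical DFS code: two connected reaction graphs have equal
#' minimum codes exactly when a label-preserving digraph isomorphism exists
#' between them.  Node labels are compared in C-locale lexicographic order
#' (so \code{SBML_REACTION} sorts before \code{SBML_SPECIES}, and SBO-refined
#' labels order by kind then term); edge labels order
#' \code{IS_REACTANT < IS_MODIFIER < HAS_PRODUCT}; the direction flag orders
#' after the edge label.
#'
#' @param g a connected \code{reaction_graph} with at least one node.
#' @param mode label mode, \code{"structural"} or \code{"sbo"}.
#' @return an object of class \code{dfs_code}: a list with \code{n_nodes},
#'   \code{root_label} (label of the first discovered node) and \code{edges},
#'   a data frame of decoded tuples \code{(i, j, li, le, dir, lj)} using
#'   0-based discovery indices.
#' @export
minimum_dfs_code <- function(g, mode = c("structural", "sbo")) {
  mode <- match.arg(mode)
  if (nrow(g$nodes) == 0) stop("minimum_dfs_code requires a non-empty graph")
  if (length(split_components(g)) != 1L)
    stop("minimum_dfs_code requires a connected graph")
  if (nrow(g$edges) == 0) {
    return(structure(list(n_nodes = 1L,
                          root_label = graph_node_labels(g, mode),
                          edges = decode_code_matrix(matrix(integer(0), 0, 6), NULL)),
                     class = "dfs_code"))
  }
  G <- as_igr(g, mode)
  code <- min_code_igr(G)$code
  structure(list(n_nodes = max(code[, 1:2]),
                 root_label = G$label_table[code[1, 3]],
                 edges = decode_code_matrix(code, G$label_table)),
            class = "dfs_code")
}

decode_code_matrix <- function(code, label_table) {
  if (nrow(code) == 0) {
    return(data.frame(i = integer(0), j = integer(0), li = character(0),
                      le = character(0), dir = integer(0), lj = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(i = code[, 1] - 1L, j = code[, 2] - 1L,
             li = label_table[code[, 3]],
             le = EDGE_ROLES[code[, 4]],
             dir = code[, 5],
             lj = label_table[code[, 6]],
             stringsAsFactors = FALSE)
}

#' Canonical string key of a DFS code
#'
#' @param code a \code{dfs_code}.
#' @return a single character string; equal keys identify isomorphic graphs.
#' @export
dfs_code_key <- function(code) {
  stopifnot(inherits(code, "dfs_code"))
  if (!nrow(code$edges)) return(paste0("v:", code$root_label))
  paste(apply(code$edges, 1, paste, collapse = "|"), collapse = ";")
}

#' @export
print.dfs_code <- function(x, ...) {
  cat(sprintf("<dfs_code> %d node(s), %d edge tuple(s)\n", x$n_nodes, nrow(x$edges)))
  if (nrow(x$edges)) print(x$edges) else cat("  root label:", x$root_label, "\n")
  invisible(x)
}

## Decode a code matrix into a reaction_graph with Node_0..Node_k ids in
## discovery order.  Labels of the form KIND or KIND|SBO:0000NNN.
graph_from_code_matrix <- function(code, label_table, root_label_int = NULL) {
  G <- igr_from_code(code)
  if (nrow(code) == 0) G$vl <- as.integer(root_label_int)
  labels <- label_table[G$vl]
  kind <- sub("\\|.*$", "", labels)
  sbo <- ifelse(grepl("|", labels, fixed = TRUE), sub("^[^|]*\\|", "", labels),
                NA_character_)
  ids <- paste0("Node_", seq_len(G$n) - 1L)
  nodes <- data.frame(id = ids, kind = kind, sbo = sbo, stringsAsFactors = FALSE)
  edges <- if (length(G$elab)) {
    data.frame(from = ids[G$efrom], to = ids[G$eto],
               role = EDGE_ROLES[G$elab], stringsAsFactors = FALSE)
  } else empty_edge_table()
  reaction_graph(nodes, edges)
}
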