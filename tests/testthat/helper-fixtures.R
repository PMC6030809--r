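# Shared fixtures built in code.

extdata <- function(name) {
  system.file("extdata", name, package = "sbmlpatterns", mustWork = TRUE)
}

# cdc2k worked example: dephosphorylation produces the kinase that the
# phosphorylation consumes
cdc2k_tuples <- function() {
  data.frame(reaction_id = c("100233", "100229"),
             role = c("HAS_PRODUCT", "HAS_REACTANT"),
             species_id = c("100186", "100186"),
             stringsAsFactors = FALSE)
}

# two-edge chain S -IS_REACTANT-> R -HAS_PRODUCT-> S2
chain_graph <- function() {
  reaction_graph(
    data.frame(id = c("S", "R", "S2"),
               kind = c("SBML_SPECIES", "SBML_REACTION", "SBML_SPECIES"),
               stringsAsFactors = FALSE),
    data.frame(from = c("S", "R"), to = c("R", "S2"),
               role = c("IS_REACTANT", "HAS_PRODUCT"),
               stringsAsFactors = FALSE))
}

single_species <- function(id = "X") {
  reaction_graph(data.frame(id = id, kind = "SBML_SPECIES",
                            stringsAsFactors = FALSE))
}

single_reaction <- function(id = "RX") {
  reaction_graph(data.frame(id = id, kind = "SBML_REACTION",
                            stringsAsFactors = FALSE))
}

# random bipartite reaction network as a reaction_graph (caller seeds RNG)
random_network <- function(n_species = 4, n_reactions = 3, n_edges = 6,
                           prefix = "g") {
  sp <- paste0(prefix, "_s", seq_len(n_species))
  rx <- paste0(prefix, "_r", seq_len(n_reactions))
  pool <- expand.grid(reaction_id = rx, species_id = sp,
                      role = c("HAS_REACTANT", "HAS_MODIFIER", "HAS_PRODUCT"),
                      stringsAsFactors = FALSE)
  take <- pool[sample(nrow(pool), min(n_edges, nrow(pool))), ]
  orient_edges(take)
}

# a random connected pattern: a connected subgraph of a random network
random_pattern <- function(max_edges = 4, prefix = "p") {
  repeat {
    g <- random_network(3, 3, 6, prefix = prefix)
    comps <- split_components(g, "tmp")
    if (!length(comps)) next
    comp <- comps$networks[[which.max(vapply(comps$networks,
                                             function(x) nrow(x$edges), integer(1)))]]
    if (!nrow(comp$edges)) next
    k <- sample(seq_len(min(max_edges, nrow(comp$edges))), 1)
    sub <- connected_edge_subgraph(comp, k)
    if (!is.null(sub)) return(sub)
  }
}

# grow a connected subgraph of k edges by randomised BFS over edges
connected_edge_subgraph <- function(g, k) {
  if (nrow(g$edges) < k) return(NULL)
  chosen <- sample(nrow(g$edges), 1)
  repeat {
    if (length(chosen) == k) break
    nodes <- unique(c(g$edges$from[chosen], g$edges$to[chosen]))
    cand <- setdiff(which(g$edges$from %in% nodes | g$edges$to %in% nodes), chosen)
    if (!length(cand)) return(NULL)
    chosen <- c(chosen, if (length(cand) == 1) cand else sample(cand, 1))
  }
  edges <- g$edges[chosen, , drop = FALSE]
  ids <- unique(c(edges$from, edges$to))
  reaction_graph(g$nodes[g$nodes$id %in% ids, , drop = FALSE], edges)
}

# tiny corpus of class network_set from a list of graphs, one model each
as_corpus <- function(graphs, model_ids = NULL) {
  if (is.null(model_ids)) model_ids <- paste0("m", seq_along(graphs))
  combine_network_sets(mapply(split_components, graphs, model_ids,
                              SIMPLIFY = FALSE))
}

# minimal SBML document assembled in code
sbml_text <- function(body, level = 3) {
  ns <- if (level == 3) "http://www.sbml.org/sbml/level3/version1/core"
        else "http://www.sbml.org/sbml/level2/version4"
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         '<sbml xmlns="', ns, '" level="', level, '" version="1">\n',
         body, '\n</sbml>\n')
}

write_sbml_fixture <- function(body, level = 3) {
  path <- tempfile(fileext = ".xml")
  writeLines(sbml_text(body, level), path)
  path
}
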