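test_that("thresholds above the corpus size yield no patterns", {
  nets <- as_corpus(list(chain_graph(), single_species()))
  ps <- mine(nets, mining_config(min_support = length(nets) + 1))
  expect_length(ps$patterns, 0)
})

test_that("the worked two-chains-plus-species corpus yields its five patterns", {
  # chain twice and a lone species: expected patterns enumerated by hand and
  # confirmed by the exhaustive oracle
  nets <- as_corpus(list(chain_graph(), chain_graph(), single_species()))
  cfg <- mining_config(min_support = 2, max_support = 3)
  ps <- mine(nets, cfg)
  expect_length(ps$patterns, 5)
  got <- summary(ps)
  # species node support 3; reaction node 2; both single edges 2; chain 2
  expect_equal(sort(got$support), c(2, 2, 2, 2, 3))
  species_node <- which(got$n_nodes == 1 & got$support == 3)
  expect_length(species_node, 1)
  expect_equal(ps$patterns[[species_node]]$graph$nodes$kind, "SBML_SPECIES")
  expect_same_pattern_sets(ps, oracle_mine(nets, 2, 3, max_edges = 5))
})

test_that("mining agrees exactly with exhaustive enumeration", {
  set.seed(101)
  for (rep in 1:4) {
    graphs <- lapply(1:6, function(i)
      random_network(sample(2:4, 1), sample(2:3, 1), sample(2:6, 1),
                     prefix = paste0("o", rep, "_", i)))
    nets <- as_corpus(graphs)
    minsup <- sample(2:3, 1)
    ps <- mine(nets, mining_config(min_support = minsup, max_edges = 3))
    expect_same_pattern_sets(ps, oracle_mine(nets, minsup, max_edges = 3))
  }
})

test_that("max_support filters emission without losing sub-patterns", {
  nets <- as_corpus(list(chain_graph(), chain_graph(), single_species()))
  ps <- mine(nets, mining_config(min_support = 2, max_support = 2))
  got <- summary(ps)
  expect_true(all(got$support == 2))
  # the ubiquitous species node (support 3) is excluded
  expect_false(any(got$n_nodes == 1 & got$support == 3))
  expect_same_pattern_sets(ps, oracle_mine(nets, 2, 2, max_edges = 5))
})

test_that("anti-monotonicity and canonicality hold on random corpora", {
  set.seed(102)
  for (rep in 1:12) {
    graphs <- lapply(1:5, function(i)
      random_network(sample(2:4, 1), sample(2:3, 1), sample(2:5, 1),
                     prefix = paste0("am", rep, "_", i)))
    nets <- as_corpus(graphs)
    ps <- mine(nets, mining_config(min_support = 2, max_edges = 4))
    keys <- vapply(ps$patterns, function(p)
      dfs_code_key(minimum_dfs_code(p$graph)), character(1))
    # canonicality: no two emitted patterns are isomorphic
    expect_false(anyDuplicated(keys) > 0)
    sup_of <- setNames(vapply(ps$patterns, function(p) p$support, integer(1)), keys)
    for (p in ps$patterns) {
      if (p$n_edges == 0) next
      # every connected one-edge-deleted subgraph is emitted with >= support
      for (e in seq_len(nrow(p$graph$edges))) {
        sub_edges <- p$graph$edges[-e, , drop = FALSE]
        ids <- unique(c(sub_edges$from, sub_edges$to))
        if (!length(ids)) next
        sub <- reaction_graph(p$graph$nodes[p$graph$nodes$id %in% ids, ,
                                            drop = FALSE], sub_edges)
        if (length(split_components(sub, "t")) != 1) next
        key <- dfs_code_key(minimum_dfs_code(sub))
        expect_true(key %in% keys)
        expect_gte(unname(sup_of[key]), p$support)
      }
    }
  }
})

test_that("supports() matches brute force and its documented examples", {
  g <- chain_graph()
  expect_true(supports(g, g))                      # identity embedding
  expect_true(supports(single_species("q"), g))    # node pattern
  expect_false(supports(cycle_motif(), g))
  set.seed(103)
  for (rep in 1:20) {
    pat <- random_pattern(3, prefix = paste0("sp", rep))
    host <- random_network(4, 3, 7, prefix = paste0("sh", rep))
    expect_equal(supports(pat, host), oracle_supports(pat, host))
  }
})

test_that("mining is deterministic across runs", {
  set.seed(104)
  graphs <- lapply(1:5, function(i) random_network(3, 3, 6, prefix = paste0("d", i)))
  nets <- as_corpus(graphs)
  cfg <- mining_config(min_support = 2, max_edges = 4)
  ps1 <- mine(nets, cfg)
  ps2 <- mine(nets, cfg)
  expect_identical(summary(ps1), summary(ps2))
  expect_identical(lapply(ps1$patterns, function(p) p$graph),
                   lapply(ps2$patterns, function(p) p$graph))
})

test_that("support units: networks count components, models count sources", {
  # one model split into two identical components, another with one
  two_comp <- reaction_graph(
    rbind(chain_graph()$nodes,
          within(chain_graph()$nodes, id <- paste0(id, "b"))),
    rbind(chain_graph()$edges,
          within(chain_graph()$edges, { from <- paste0(from, "b")
                                        to <- paste0(to, "b") })))
  nets <- combine_network_sets(split_components(two_comp, "m1"),
                               split_components(chain_graph(), "m2"))
  expect_equal(length(nets), 3)
  by_net <- mine(nets, mining_config(min_support = 3, support_unit = "network"))
  by_model <- mine(nets, mining_config(min_support = 2, support_unit = "model"))
  chain_key <- dfs_code_key(minimum_dfs_code(chain_graph()))
  find_chain <- function(ps) {
    hit <- vapply(ps$patterns, function(p)
      identical(dfs_code_key(minimum_dfs_code(p$graph)), chain_key), logical(1))
    ps$patterns[hit]
  }
  expect_equal(find_chain(by_net)[[1]]$support, 3)
  expect_equal(find_chain(by_model)[[1]]$support, 2)
  expect_length(find_chain(by_model)[[1]]$supporting_models, 2)
})

test_that("configuration and capacity errors are typed", {
  nets <- as_corpus(list(chain_graph()))
  expect_error(mining_config(min_support = 0), class = "config_error")
  expect_error(mining_config(min_support = 3, max_support = 2),
               class = "config_error")
  expect_error(
    mine(as_corpus(list(chain_graph(), chain_graph())),
         mining_config(min_support = 1, max_patterns = 2)),
    class = "capacity_error")
})

test_that("pattern ids pair the frequency with a disambiguating index", {
  nets <- as_corpus(list(chain_graph(), chain_graph(), single_species()))
  ps <- mine(nets, mining_config(min_support = 2))
  ids <- vapply(ps$patterns, function(p) p$pattern_id, character(1))
  expect_false(anyDuplicated(ids) > 0)
  expect_true(all(grepl("^[0-9]+_[0-9]+$", ids)))
  sup <- vapply(ps$patterns, function(p) p$support, integer(1))
  expect_equal(as.integer(sub("_.*", "", ids)), sup)
})
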