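test_that("count_embeddings matches its worked examples", {
  # one species-node pattern against four species
  g4 <- reaction_graph(data.frame(id = paste0("s", 1:4), kind = "SBML_SPECIES"))
  expect_equal(count_embeddings(single_species(), g4), 4)
  # species feeding three reactions: the single-edge pattern embeds 3 times
  star <- orient_edges(data.frame(reaction_id = paste0("r", 1:3),
                                  role = "HAS_REACTANT", species_id = "s"))
  edge_pat <- orient_edges(data.frame(reaction_id = "r", role = "HAS_REACTANT",
                                      species_id = "s"))
  expect_equal(count_embeddings(edge_pat, star), 3)
  # the two-species/two-reaction cycle in itself: two rotations
  expect_equal(count_embeddings(cycle_motif(), cycle_motif()), 2)
  # orbit counting quotients the automorphisms away
  expect_equal(count_embeddings(cycle_motif(), cycle_motif(), orbit = TRUE), 1)
})

test_that("count_embeddings equals exhaustive assignment enumeration", {
  set.seed(111)
  for (rep in 1:60) {
    pat <- random_pattern(3, prefix = paste0("ce", rep))
    host <- random_network(sample(3:5, 1), sample(2:3, 1), sample(4:8, 1),
                           prefix = paste0("ch", rep))
    expect_equal(count_embeddings(pat, host), oracle_embeddings(pat, host))
    # presence and positive counts coincide
    expect_equal(supports(pat, host), count_embeddings(pat, host) > 0)
  }
})

test_that("adding edges to a pattern never increases its embedding count", {
  set.seed(112)
  for (rep in 1:15) {
    host <- random_network(4, 3, 8, prefix = paste0("mo", rep))
    pat <- random_pattern(4, prefix = paste0("mp", rep))
    base <- count_embeddings(pat, host)
    if (nrow(pat$edges) < 2) next
    for (e in seq_len(nrow(pat$edges))) {
      sub_edges <- pat$edges[-e, , drop = FALSE]
      ids <- unique(c(sub_edges$from, sub_edges$to))
      sub <- reaction_graph(pat$nodes[pat$nodes$id %in% ids, , drop = FALSE],
                            sub_edges)
      if (length(split_components(sub, "t")) != 1) next
      expect_gte(count_embeddings(sub, host), base)
    }
  }
})

test_that("the generated query mirrors the database dialect", {
  # the five-node example pattern: 1 anchor + 4 relationship clauses and
  # C(5,2) = 10 pairwise inequalities
  entries <- read_dot(extdata("pattern_example.dot"))
  q <- pattern_to_graph_query(entries[[1]]$graph)
  expect_match(q, "MATCH \\(m: SBML_MODEL\\)-->\\(d: DOCUMENT\\)")
  expect_match(q, "m-\\[HAS_REACTION\\]->Node_0")
  expect_equal(lengths(regmatches(q, gregexpr("-\\[: ", q))), 4)
  expect_equal(lengths(regmatches(q, gregexpr("<>", q))), 10)
  expect_equal(length(unique(unlist(
    regmatches(q, gregexpr("Node_[0-9]+", q))))), 5)
  expect_match(q, "RETURN DISTINCT ID\\(m\\), d.FILENAME, COUNT\\(Node_0\\) AS sum ORDER BY sum DESC")

  # single edge: one relationship clause, one inequality
  q1 <- pattern_to_graph_query(entries[[2]]$graph)
  expect_equal(lengths(regmatches(q1, gregexpr("-\\[: ", q1))), 1)
  expect_equal(lengths(regmatches(q1, gregexpr("<>", q1))), 1)

  # random k-node patterns: C(k,2) inequalities, one clause per edge
  set.seed(113)
  for (rep in 1:10) {
    pat <- random_pattern(4, prefix = paste0("q", rep))
    q <- pattern_to_graph_query(pat)
    k <- nrow(pat$nodes)
    expect_equal(lengths(regmatches(q, gregexpr("<>", q))), choose(k, 2))
    expect_equal(lengths(regmatches(q, gregexpr("-\\[: ", q))), nrow(pat$edges))
    for (role in unique(pat$edges$role))
      expect_match(q, paste0("-\\[: ", role, "\\]->"))
  }
  expect_error(pattern_to_graph_query(reaction_graph()), "non-empty")
})

test_that("species-only patterns anchor through the species relation", {
  q <- pattern_to_graph_query(single_species("Node_0"))
  expect_match(q, "m-\\[HAS_SPECIES\\]->Node_0")
})

test_that("feature matrix layout, ordering and CSV dialect", {
  set.seed(114)
  corpus <- generate_corpus(synth_config(n_models = 5, seed = 114))
  nets <- corpus_networks(corpus)
  ps <- mine(nets, mining_config(min_support = 4, max_edges = 2,
                                 support_unit = "model"))
  expect_gt(length(ps), 1)
  path <- withr::local_tempfile(fileext = ".csv")
  fm <- build_feature_matrix(corpus$models, nets, ps, path = path)
  expect_equal(names(fm)[1:2], c("model_id", "model_name"))
  expect_equal(ncol(fm), 2 + length(ps))
  # columns ordered by descending support, ties by pattern id
  sup <- as.integer(sub("_.*", "", names(fm)[-(1:2)]))
  expect_true(all(diff(sup) <= 0))
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(dim(back), dim(fm))
  expect_equal(back$model_id, fm$model_id)
  # zero patterns: only the two model columns remain
  fm0 <- build_feature_matrix(corpus$models, nets,
                              mine(nets, mining_config(min_support = 6,
                                                       support_unit = "model")))
  expect_equal(ncol(fm0), 2)
  # duplicate model ids are refused
  dup <- rbind(corpus$models, corpus$models[1, ])
  expect_error(build_feature_matrix(dup, nets, ps), "duplicate model ids")
})

test_that("positive cells agree with the miner's model-level support", {
  set.seed(115)
  corpus <- generate_corpus(synth_config(n_models = 6, seed = 115))
  nets <- corpus_networks(corpus)
  ps <- mine(nets, mining_config(min_support = 3, max_edges = 2,
                                 support_unit = "model"))
  fm <- build_feature_matrix(corpus$models, nets, ps)
  for (p in ps$patterns) {
    cells <- fm[[p$pattern_id]]
    expect_equal(sum(cells > 0), length(p$supporting_models))
    expect_setequal(fm$model_id[cells > 0], p$supporting_models)
  }
})

test_that("planted copies guarantee at least their embedding count", {
  set.seed(116)
  corpus <- generate_corpus(synth_config(
    n_models = 8, seed = 116,
    planted = list(list(pattern = cycle_motif(), fraction = 0.5,
                        fuse_prob = 0))))
  nets <- corpus_networks(corpus)
  planted_models <- corpus$planted$model_id
  expect_length(planted_models, 4)
  for (mid in planted_models) {
    n <- count_embeddings(cycle_motif(),
                          nets$networks[nets$info$model_id == mid])
    expect_gte(n, 2)  # one planted copy = 2 rotational assignments
  }
})

test_that("per-pattern distribution lists supporting models by count", {
  set.seed(117)
  corpus <- generate_corpus(synth_config(n_models = 5, seed = 117))
  nets <- corpus_networks(corpus)
  edge_pat <- orient_edges(data.frame(reaction_id = "r", role = "HAS_REACTANT",
                                      species_id = "s"))
  d <- pattern_distribution(corpus$models, nets, edge_pat)
  expect_true(all(d$count > 0))
  expect_true(all(diff(d$count) <= 0))
  expect_true(all(d$model_id %in% corpus$models$model_id))
})
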