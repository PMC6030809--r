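test_that("orient_edges adjusts directions and labels by role", {
  g <- orient_edges(cdc2k_tuples())
  expect_s3_class(g, "reaction_graph")
  # product stays reaction -> species, reactant flips to species -> reaction
  expect_true(any(g$edges$from == "100233" & g$edges$to == "100186" &
                  g$edges$role == "HAS_PRODUCT"))
  expect_true(any(g$edges$from == "100186" & g$edges$to == "100229" &
                  g$edges$role == "IS_REACTANT"))
  expect_equal(sort(g$nodes$kind[match(c("100233", "100229", "100186"), g$nodes$id)]),
               c("SBML_REACTION", "SBML_REACTION", "SBML_SPECIES"))
  # modifiers are ingoing too
  gm <- orient_edges(data.frame(reaction_id = "r", role = "HAS_MODIFIER",
                                species_id = "s"))
  expect_equal(gm$edges$from, "s")
  expect_equal(gm$edges$role, "IS_MODIFIER")
})

test_that("orient_edges rejects unknown roles and empty input is empty", {
  expect_error(orient_edges(data.frame(reaction_id = "r", role = "HAS_THING",
                                       species_id = "s")),
               "unknown participant role")
  g <- orient_edges(data.frame(reaction_id = character(0), role = character(0),
                               species_id = character(0)))
  expect_equal(nrow(g$nodes), 0)
  expect_equal(nrow(g$edges), 0)
})

test_that("graph invariants are enforced on construction", {
  # non-bipartite edge
  expect_error(reaction_graph(
    data.frame(id = c("a", "b"), kind = "SBML_SPECIES"),
    data.frame(from = "a", to = "b", role = "IS_REACTANT")),
    "bipartite")
  # wrong direction for role
  expect_error(reaction_graph(
    data.frame(id = c("r", "s"), kind = c("SBML_REACTION", "SBML_SPECIES")),
    data.frame(from = "r", to = "s", role = "IS_REACTANT")),
    "direction")
  # duplicate edge triple
  expect_error(reaction_graph(
    data.frame(id = c("r", "s"), kind = c("SBML_REACTION", "SBML_SPECIES")),
    data.frame(from = c("s", "s"), to = c("r", "r"),
               role = c("IS_REACTANT", "IS_REACTANT"))),
    "duplicate")
  # species both reactant and product of one reaction is legal (two roles)
  g <- orient_edges(data.frame(reaction_id = "r",
                               role = c("HAS_REACTANT", "HAS_PRODUCT"),
                               species_id = "s"))
  expect_equal(nrow(g$edges), 2)
})

test_that("split_components finds weakly-connected reaction networks", {
  # the cdc2k pair joins through the shared species into one network
  ns <- split_components(orient_edges(cdc2k_tuples()), "cdc2k")
  expect_equal(length(ns), 1)
  expect_equal(nrow(ns$networks[[1]]$nodes), 3)
  expect_equal(nrow(ns$networks[[1]]$edges), 2)
  # empty graph
  expect_equal(length(split_components(reaction_graph(), "empty")), 0)
})

test_that("split_components recovers a known disjoint union and is idempotent", {
  set.seed(71)
  for (rep in 1:5) {
    k <- sample(2:4, 1)
    parts <- lapply(seq_len(k), function(i) {
      repeat {
        g <- random_network(3, 2, 4, prefix = paste0("c", rep, "_", i))
        if (length(split_components(g, "x")) == 1) return(g)
      }
    })
    whole <- reaction_graph(do.call(rbind, lapply(parts, `[[`, "nodes")),
                            do.call(rbind, lapply(parts, `[[`, "edges")))
    ns <- split_components(whole, "m")
    expect_equal(length(ns), k)
    got <- lapply(ns$networks, function(g) sort(g$nodes$id))
    want <- lapply(parts, function(g) sort(g$nodes$id))
    expect_setequal(vapply(got, paste, character(1), collapse = ","),
                    vapply(want, paste, character(1), collapse = ","))
    # union of components equals the input
    expect_setequal(unlist(got), whole$nodes$id)
    expect_equal(sum(vapply(ns$networks, function(g) nrow(g$edges), integer(1))),
                 nrow(whole$edges))
    # idempotence: re-splitting each member yields itself
    for (comp in ns$networks) {
      again <- split_components(comp, "m")
      expect_equal(length(again), 1)
      expect_setequal(again$networks[[1]]$nodes$id, comp$nodes$id)
    }
  }
})

test_that("DOT writer/reader round-trips label-preserving graphs", {
  set.seed(72)
  for (rep in 1:25) {
    g <- random_network(sample(2:5, 1), sample(2:4, 1), sample(2:7, 1),
                        prefix = paste0("rt", rep))
    ns <- split_components(g, "m")
    path <- withr::local_tempfile(fileext = ".dot")
    write_dot(ns, path)
    back <- networks_from_dot(read_dot(path), "m")
    expect_equal(length(back), length(ns))
    for (k in seq_along(ns$networks)) {
      partner <- which(vapply(back$networks, oracle_isomorphic,
                              logical(1), g2 = ns$networks[[k]]))
      expect_true(length(partner) >= 1)
    }
  }
})

test_that("DOT reader parses the cdc2k network file and quoting variants", {
  entries <- read_dot(extdata("cdc2k_network.dot"))
  expect_length(entries, 1)
  g <- entries[[1]]$graph
  expect_setequal(g$nodes$id, c("100233", "100186", "100229"))
  expect_equal(g$nodes$kind[g$nodes$id == "100186"], "SBML_SPECIES")
  expect_equal(nrow(g$edges), 2)
  # quoted labels and mixed-case kinds are accepted on read
  path <- withr::local_tempfile(fileext = ".dot")
  writeLines(c("digraph {",
               ' a [label = "SBML_Reaction"];',
               " b [label = SBML_Species];",
               ' b -> a [label = "IS_REACTANT"];',
               "}"), path)
  g2 <- read_dot(path)[[1]]$graph
  expect_equal(sort(g2$nodes$kind), c("SBML_REACTION", "SBML_SPECIES"))
  # malformed input reports the line number
  writeLines(c("digraph {", " a <- b;", "}"), path)
  expect_error(read_dot(path), "line 2")
})

test_that("edge JSON dialect reads, writes and round-trips", {
  tup <- read_edge_json(extdata("cdc2k_edges.json"))
  expect_equal(nrow(tup), 2)
  expect_equal(tup$reaction_id, c("100233", "100229"))
  expect_equal(tup$role, c("HAS_PRODUCT", "HAS_REACTANT"))
  expect_equal(tup$species_id, c("100186", "100186"))

  path <- withr::local_tempfile(fileext = ".json")
  # empty data array
  writeLines('{"columns": ["ID(reaction)", "TYPE(edge)", "ID(species)"], "data": []}',
             path)
  expect_equal(nrow(read_edge_json(path)), 0)
  # missing columns is a format error
  writeLines('{"data": []}', path)
  expect_error(read_edge_json(path), "format error")
  # round trip of random tuples
  set.seed(73)
  for (rep in 1:10) {
    n <- sample(1:8, 1)
    tup <- data.frame(reaction_id = paste0("r", sample(9, n, TRUE)),
                      role = sample(c("HAS_REACTANT", "HAS_MODIFIER",
                                      "HAS_PRODUCT"), n, TRUE),
                      species_id = paste0("s", sample(9, n, TRUE)),
                      stringsAsFactors = FALSE)
    write_edge_json(tup, path)
    expect_equal(read_edge_json(path), tup)
  }
})

test_that("bipartite and direction invariants survive the whole chain", {
  set.seed(74)
  for (rep in 1:10) {
    g <- random_network(4, 3, 7, prefix = paste0("inv", rep))
    ns <- split_components(g, "m")
    for (comp in ns$networks) expect_silent(validate_reaction_graph(comp))
    path <- withr::local_tempfile(fileext = ".dot")
    write_dot(ns, path)
    for (entry in read_dot(path)) expect_silent(validate_reaction_graph(entry$graph))
  }
})
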