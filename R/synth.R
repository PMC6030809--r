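## Synthetic corpus generator.  Emulates the structure of small curated
## reaction-network models: bipartite species/reaction graphs with
## configurable size ranges, participation-role probabilities, optional SBO
## labels and planted patterns, plus a ground-truth ledger so every pipeline
## stage can be checked against construction.

#' Synthetic corpus configuration
#'
#' Defaults mirror the sizes typical of small curated models: most contain
#' 3-11 species and 3-12 reactions, and most reactions have two or three
#' participating species.  Role probabilities default to reactant- and
#' product-heavy reactions (the commonest encoded reaction shapes are two
#' reactants with one product, and one reactant with one product) with
#' occasional modifiers.
#'
#' @param n_models number of models.
#' @param species_range,reactions_range integer ranges (inclusive) sampled
#'   uniformly per model.
#' @param role_probs named probabilities for \code{reactant}, \code{modifier},
#'   \code{product} participation; must sum to 1.
#' @param participants_range range of participating species per reaction.
#' @param sbo_vocabulary optional list with data frames \code{species} and
#'   \code{reactions}, each with columns \code{term} and \code{weight}; when
#'   supplied, every node is annotated with a sampled SBO term.
#' @param planted list of planted patterns, each a list with \code{pattern}
#'   (a connected \code{reaction_graph}), \code{fraction} of models to plant
#'   into, and optional \code{fuse_prob} (probability of fusing one planted
#'   species with an existing species, creating overlapping context;
#'   default 0.25).
#' @param seed integer seed; the corpus is reproducible for a fixed seed.
#' @return an object of class \code{synth_config}.
#' @export
synth_config <- function(n_models = 30L,
                         species_range = c(3L, 11L),
                         reactions_range = c(3L, 12L),
                         role_probs = c(reactant = 0.45, modifier = 0.10,
                                        product = 0.45),
                         participants_range = c(2L, 3L),
                         sbo_vocabulary = NULL,
                         planted = list(),
                         seed = 1L) {
  stopifnot(length(species_range) == 2, length(reactions_range) == 2,
            length(participants_range) == 2)
  if (n_models < 0) stop_config("n_models must be >= 0")
  if (abs(sum(role_probs) - 1) > 1e-8)
    stop_config("role_probs must sum to 1")
  if (!all(c("reactant", "modifier", "product") %in% names(role_probs)))
    stop_config("role_probs must name reactant, modifier and product")
  if (participants_range[2] > species_range[1])
    stop_config("participants_per_reaction can exceed the species count: ",
                "max participants ", participants_range[2],
                " > min species ", species_range[1])
  for (p in planted) {
    stopifnot(inherits(p$pattern, "reaction_graph"))
    if (p$fraction < 0 || p$fraction > 1)
      stop_config("planted fraction must lie in [0, 1]")
  }
  structure(list(n_models = as.integer(n_models),
                 species_range = as.integer(species_range),
                 reactions_range = as.integer(reactions_range),
                 role_probs = role_probs[c("reactant", "modifier", "product")],
                 participants_range = as.integer(participants_range),
                 sbo_vocabulary = sbo_vocabulary,
                 planted = planted, seed = as.integer(seed)),
            class = "synth_config")
}

ROLE_TO_EXPORT <- c(reactant = "HAS_REACTANT", modifier = "HAS_MODIFIER",
                    product = "HAS_PRODUCT")

#' The two-species/two-reaction cycle motif
#'
#' The smallest biologically meaningful cycle: two species and two
#' reactions, each species the reactant of one reaction and the product of
#' the other (e.g. production and degradation of a protein, or a
#' phosphorylation/de-phosphorylation pair).
#'
#' @param sbo optional named list with \code{species} and \code{reaction}
#'   SBO terms to attach (length-2 character vectors recycled from length 1).
#' @return a \code{reaction_graph}.
#' @export
cycle_motif <- function(sbo = NULL) {
  nodes <- data.frame(
    id = c("S1", "R1", "S2", "R2"),
    kind = c("SBML_SPECIES", "SBML_REACTION", "SBML_SPECIES", "SBML_REACTION"),
    sbo = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(sbo)) {
    nodes$sbo[c(1, 3)] <- rep_len(sbo$species, 2)
    nodes$sbo[c(2, 4)] <- rep_len(sbo$reaction, 2)
  }
  edges <- data.frame(
    from = c("S1", "R1", "S2", "R2"),
    to   = c("R1", "S2", "R2", "S1"),
    role = c("IS_REACTANT", "HAS_PRODUCT", "IS_REACTANT", "HAS_PRODUCT"),
    stringsAsFactors = FALSE)
  reaction_graph(nodes, edges)
}

sample_range <- function(range) {
  if (range[1] == range[2]) range[1] else sample(range[1]:range[2], 1L)
}

## Convert a planted reaction_graph into export tuples with fresh node ids.
plant_pattern <- function(pattern, prefix, fuse_with = NULL, fuse_prob = 0) {
  ids <- paste0(prefix, "_", pattern$nodes$id)
  names(ids) <- pattern$nodes$id
  fused <- NA_character_
  if (!is.null(fuse_with) && length(fuse_with) &&
      stats::runif(1) < fuse_prob) {
    sp <- pattern$nodes$id[pattern$nodes$kind == "SBML_SPECIES"]
    if (length(sp)) {
      pick <- if (length(sp) == 1L) sp else sample(sp, 1L)
      host <- if (length(fuse_with) == 1L) fuse_with else sample(fuse_with, 1L)
      ids[pick] <- host
      fused <- host
    }
  }
  is_prod <- pattern$edges$role == "HAS_PRODUCT"
  tuples <- data.frame(
    reaction_id = ifelse(is_prod, ids[pattern$edges$from], ids[pattern$edges$to]),
    role = ifelse(is_prod, "HAS_PRODUCT",
                  ifelse(pattern$edges$role == "IS_REACTANT",
                         "HAS_REACTANT", "HAS_MODIFIER")),
    species_id = ifelse(is_prod, ids[pattern$edges$to], ids[pattern$edges$from]),
    stringsAsFactors = FALSE)
  sbo <- data.frame(element_id = unname(ids), term = pattern$nodes$sbo,
                    stringsAsFactors = FALSE)
  list(tuples = tuples, sbo = sbo, node_ids = unname(ids), fused = fused)
}

#' Generate a synthetic model corpus with ground truth
#'
#' Every model is a random bipartite reaction network drawn from the
#' configured size and role distributions; planted patterns are inserted as
#' fresh subnetworks (optionally fused into the random context through one
#' shared species).  The returned ledger records, per model, the exact edge
#' list and every planted pattern copy, so parsers, miners and counters can
#' be validated against construction.
#'
#' @param config a \code{\link{synth_config}}.
#' @return an object of class \code{synthetic_corpus}: list with
#'   \code{models} (data frame of model records), \code{tuples} and
#'   \code{sbo} (named lists of per-model data frames), \code{planted}
#'   (data frame: model_id, pattern index, fused host or NA) and
#'   \code{config}.
#' @export
generate_corpus <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_models
  model_ids <- if (n) sprintf("SYN%03d", seq_len(n)) else character(0)
  tuples <- stats::setNames(vector("list", n), model_ids)
  sbo <- stats::setNames(vector("list", n), model_ids)
  kinds <- stats::setNames(vector("list", n), model_ids)
  planted_log <- list()

  ## which models receive which planted pattern (chosen before generation)
  plant_assign <- lapply(config$planted, function(p) {
    k <- round(p$fraction * n)
    if (k > 0) sort(sample(seq_len(n), k)) else integer(0)
  })

  vocab <- config$sbo_vocabulary
  draw_term <- function(tab, k) {
    if (is.null(tab)) return(rep(NA_character_, k))
    sample(tab$term, k, replace = TRUE, prob = tab$weight)
  }

  for (m in seq_len(n)) {
    mid <- model_ids[m]
    n_s <- sample_range(config$species_range)
    n_r <- sample_range(config$reactions_range)
    sp_ids <- sprintf("%s_S%02d", mid, seq_len(n_s))
    rx_ids <- sprintf("%s_R%02d", mid, seq_len(n_r))
    rows <- list()
    for (r in seq_len(n_r)) {
      n_p <- sample_range(config$participants_range)
      roles <- sample(names(config$role_probs), n_p, replace = TRUE,
                      prob = config$role_probs)
      for (role in unique(roles)) {
        k <- sum(roles == role)
        chosen <- sample(sp_ids, min(k, n_s))
        rows[[length(rows) + 1L]] <- data.frame(
          reaction_id = rx_ids[r], role = ROLE_TO_EXPORT[[role]],
          species_id = chosen, stringsAsFactors = FALSE)
      }
    }
    mt <- unique(do.call(rbind, rows))
    msbo <- data.frame(
      element_id = c(sp_ids, rx_ids),
      term = c(draw_term(vocab$species, n_s), draw_term(vocab$reactions, n_r)),
      stringsAsFactors = FALSE)
    mkinds <- data.frame(
      element_id = c(sp_ids, rx_ids),
      kind = rep(c("SBML_SPECIES", "SBML_REACTION"), c(n_s, n_r)),
      stringsAsFactors = FALSE)
    for (pi in seq_along(config$planted)) {
      if (!m %in% plant_assign[[pi]]) next
      p <- config$planted[[pi]]
      fuse_prob <- if (is.null(p$fuse_prob)) 0.25 else p$fuse_prob
      copy <- plant_pattern(p$pattern, sprintf("%s_P%d", mid, pi),
                            fuse_with = sp_ids, fuse_prob = fuse_prob)
      ## planted nodes without their own SBO term draw from the vocabulary
      if (!is.null(vocab)) {
        miss <- is.na(copy$sbo$term)
        if (any(miss)) {
          kinds <- p$pattern$nodes$kind[miss]
          copy$sbo$term[miss] <- ifelse(
            kinds == "SBML_SPECIES",
            draw_term(vocab$species, sum(miss)),
            draw_term(vocab$reactions, sum(miss)))
        }
      }
      mt <- unique(rbind(mt, copy$tuples))
      keep <- !copy$sbo$element_id %in% msbo$element_id
      msbo <- rbind(msbo, copy$sbo[keep, , drop = FALSE])
      mkinds <- rbind(mkinds, data.frame(
        element_id = copy$sbo$element_id[keep],
        kind = p$pattern$nodes$kind[keep], stringsAsFactors = FALSE))
      planted_log[[length(planted_log) + 1L]] <- data.frame(
        model_id = mid, pattern = pi, fused = copy$fused,
        stringsAsFactors = FALSE)
    }
    rownames(mt) <- NULL
    tuples[[m]] <- mt
    sbo[[m]] <- msbo
    kinds[[m]] <- mkinds
  }
  models <- data.frame(model_id = model_ids,
                       model_name = if (n) sprintf("synthetic model %d", seq_len(n))
                                    else character(0),
                       source_path = rep(NA_character_, n),
                       stringsAsFactors = FALSE)
  planted <- if (length(planted_log)) do.call(rbind, planted_log) else
    data.frame(model_id = character(0), pattern = integer(0),
               fused = character(0), stringsAsFactors = FALSE)
  structure(list(models = models, tuples = tuples, sbo = sbo,
                 kinds = kinds, planted = planted, config = config),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus> %d model(s), %d planted pattern copies (seed %d)\n",
              nrow(x$models), nrow(x$planted), x$config$seed))
  invisible(x)
}

#' Parsed-model view of a synthetic corpus
#'
#' @param corpus a \code{synthetic_corpus}.
#' @return list shaped like \code{\link{read_sbml_directory}} output, so the
#'   downstream pipeline treats generated and parsed corpora uniformly.
#' @export
corpus_models <- function(corpus) {
  lapply(seq_len(nrow(corpus$models)), function(k) {
    kinds <- corpus$kinds[[k]]
    list(model = corpus$models[k, , drop = FALSE],
         tuples = corpus$tuples[[k]],
         sbo = corpus$sbo[[k]],
         species = kinds$element_id[kinds$kind == "SBML_SPECIES"],
         reactions = kinds$element_id[kinds$kind == "SBML_REACTION"])
  })
}

#' Networks of a synthetic corpus
#'
#' @param corpus a \code{synthetic_corpus}.
#' @param mode label mode passed through to network assembly.
#' @param require_sbo see \code{\link{networks_from_models}}.
#' @return a \code{network_set}.
#' @export
corpus_networks <- function(corpus, mode = "structural", require_sbo = TRUE) {
  networks_from_models(corpus_models(corpus), mode = mode,
                       require_sbo = require_sbo)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

sbo_attr <- function(term) {
  ifelse(is.na(term), "", sprintf(' sboTerm="%s"', term))
}

#' Write one synthetic model as an SBML Level 3 file
#'
#' @param corpus a \code{synthetic_corpus}.
#' @param index model index within the corpus.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_sbml <- function(corpus, index, path) {
  mid <- corpus$models$model_id[index]
  name <- corpus$models$model_name[index]
  tuples <- corpus$tuples[[index]]
  sbo <- corpus$sbo[[index]]
  term_of <- stats::setNames(sbo$term, sbo$element_id)
  kinds <- corpus$kinds[[index]]
  species_ids <- kinds$element_id[kinds$kind == "SBML_SPECIES"]
  rx_ids <- kinds$element_id[kinds$kind == "SBML_REACTION"]
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    sprintf('  <model id="%s" name="%s">', xml_escape(mid), xml_escape(name)),
    '    <listOfSpecies>',
    sprintf('      <species id="%s" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"%s/>',
            xml_escape(species_ids), sbo_attr(term_of[species_ids])),
    '    </listOfSpecies>',
    '    <listOfReactions>')
  for (rid in rx_ids) {
    rt <- tuples[tuples$reaction_id == rid, , drop = FALSE]
    lines <- c(lines, sprintf('      <reaction id="%s" reversible="false"%s>',
                              xml_escape(rid), sbo_attr(term_of[rid])))
    blocks <- list(c("HAS_REACTANT", "listOfReactants", "speciesReference"),
                   c("HAS_MODIFIER", "listOfModifiers", "modifierSpeciesReference"),
                   c("HAS_PRODUCT", "listOfProducts", "speciesReference"))
    for (b in blocks) {
      sp <- rt$species_id[rt$role == b[1]]
      if (!length(sp)) next
      const <- if (b[3] == "speciesReference") ' constant="true"' else ''
      lines <- c(lines, sprintf('        <%s>', b[2]),
                 sprintf('          <%s species="%s"%s/>', b[3], xml_escape(sp), const),
                 sprintf('        </%s>', b[2]))
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>', '  </model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}

#' Write a whole synthetic corpus as SBML files
#'
#' @param corpus a \code{synthetic_corpus}.
#' @param dir output directory (created if missing).
#' @return character vector of file paths, invisibly.
#' @export
write_sbml_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(corpus$models$model_id, ".xml"))
  for (k in seq_len(nrow(corpus$models))) write_sbml(corpus, k, paths[k])
  invisible(paths)
}
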