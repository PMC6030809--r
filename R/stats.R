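## Corpus-level quantitative analysis: node-type and edge totals, per-model
## averages, role participation totals and the reaction-class histogram
## (the (reactants, modifiers, products) participation signature of each
## reaction node, counting distinct species per role).

#' Reaction classes of a model's edge tuples
#'
#' @param tuples data frame (\code{reaction_id}, \code{role},
#'   \code{species_id}) with export roles.
#' @return data frame with one row per reaction appearing in the tuples:
#'   \code{reaction_id}, \code{n_reactants}, \code{n_modifiers},
#'   \code{n_products}, \code{n_participants}.
#' @export
reaction_classes <- function(tuples) {
  if (is.null(tuples) || !nrow(tuples)) {
    return(data.frame(reaction_id = character(0), n_reactants = integer(0),
                      n_modifiers = integer(0), n_products = integer(0),
                      n_participants = integer(0), stringsAsFactors = FALSE))
  }
  tab <- table(factor(tuples$reaction_id),
               factor(tuples$role, levels = EXPORT_ROLES))
  out <- data.frame(reaction_id = rownames(tab),
                    n_reactants = as.integer(tab[, "HAS_REACTANT"]),
                    n_modifiers = as.integer(tab[, "HAS_MODIFIER"]),
                    n_products = as.integer(tab[, "HAS_PRODUCT"]),
                    stringsAsFactors = FALSE)
  out$n_participants <- out$n_reactants + out$n_modifiers + out$n_products
  out
}

#' Quantitative key-figure analysis of a model corpus
#'
#' @param models list of parsed models (from \code{\link{parse_sbml_model}},
#'   \code{\link{read_sbml_directory}} or \code{\link{corpus_models}}).
#' @param overflow reaction classes with more participants than this are
#'   pooled into a single \code{">overflow"} histogram bucket (the usual
#'   presentation caps at six).
#' @return an object of class \code{corpus_stats}: totals, means,
#'   role-participation totals and the reaction-class histogram
#'   (\code{class_histogram}: one row per distinct (reactants, modifiers,
#'   products) signature with its reaction count and participant bucket).
#' @export
corpus_statistics <- function(models, overflow = 6L) {
  n_species <- vapply(models, function(m) length(m$species), integer(1))
  n_reactions <- vapply(models, function(m) length(m$reactions), integer(1))
  all_classes <- do.call(rbind, c(lapply(models, function(m)
    reaction_classes(m$tuples)), list(reaction_classes(NULL))))
  role_totals <- c(reactant = sum(all_classes$n_reactants),
                   modifier = sum(all_classes$n_modifiers),
                   product = sum(all_classes$n_products))
  if (nrow(all_classes)) {
    key <- paste(all_classes$n_reactants, all_classes$n_modifiers,
                 all_classes$n_products, sep = "/")
    tab <- table(key)
    parts <- do.call(rbind, strsplit(names(tab), "/"))
    hist <- data.frame(n_reactants = as.integer(parts[, 1]),
                       n_modifiers = as.integer(parts[, 2]),
                       n_products = as.integer(parts[, 3]),
                       count = as.integer(tab), stringsAsFactors = FALSE)
    total <- hist$n_reactants + hist$n_modifiers + hist$n_products
    hist$bucket <- ifelse(total > overflow, paste0(">", overflow),
                          as.character(total))
    hist <- hist[order(-hist$count,
                       hist$n_reactants, hist$n_modifiers, hist$n_products), ]
    rownames(hist) <- NULL
  } else {
    hist <- data.frame(n_reactants = integer(0), n_modifiers = integer(0),
                       n_products = integer(0), count = integer(0),
                       bucket = character(0), stringsAsFactors = FALSE)
  }
  structure(list(
    models_total = length(models),
    models_with_species = sum(n_species > 0),
    models_with_reactions = sum(n_reactions > 0),
    total_species_nodes = sum(n_species),
    total_reaction_nodes = sum(n_reactions),
    mean_species_per_model = if (length(models)) sum(n_species) / length(models) else 0,
    mean_reactions_per_model = if (length(models)) sum(n_reactions) / length(models) else 0,
    role_totals = role_totals,
    class_histogram = hist), class = "corpus_stats")
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat(sprintf("<corpus_stats> %d model(s): %d with species, %d with reactions\n",
              x$models_total, x$models_with_species, x$models_with_reactions))
  cat(sprintf("  %d species nodes (mean %.1f/model), %d reaction nodes (mean %.1f/model)\n",
              x$total_species_nodes, x$mean_species_per_model,
              x$total_reaction_nodes, x$mean_reactions_per_model))
  cat(sprintf("  participations: %d reactant, %d modifier, %d product\n",
              x$role_totals["reactant"], x$role_totals["modifier"],
              x$role_totals["product"]))
  invisible(x)
}

#' Write a corpus statistics report
#'
#' @param stats a \code{corpus_stats}.
#' @param path JSON output path.
#' @param histogram_csv optional CSV path for the reaction-class histogram.
#' @return \code{path}, invisibly.
#' @export
write_stats_report <- function(stats, path, histogram_csv = NULL) {
  obj <- unclass(stats)
  obj$role_totals <- as.list(obj$role_totals)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(histogram_csv))
    utils::write.csv(stats$class_histogram, histogram_csv, row.names = FALSE)
  invisible(path)
}
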