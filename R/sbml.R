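## SBML ingest: models are reduced to their reaction networks -- one edge
## tuple per distinct (reaction, role, species) participation.  Entities
## connected only through rules (assignment/rate rules) form no explicit
## reaction edges and are deliberately ignored.

#' Normalize an SBO term string
#'
#' Accepts the canonical \code{SBO:0000NNN} accession or a bare integer and
#' returns the canonical form.  Malformed terms are reported as a warning
#' and treated as unannotated.
#'
#' @param text raw attribute text (may be \code{NA}).
#' @return the normalized accession, or \code{NA_character_} when absent or
#'   malformed.
#' @export
normalize_sbo_term <- function(text) {
  if (length(text) == 0 || is.na(text) || !nzchar(trimws(text)))
    return(NA_character_)
  text <- trimws(text)
  if (grepl("^SBO:[0-9]{7}$", text)) return(text)
  if (grepl("^[0-9]{1,7}$", text))
    return(sprintf("SBO:%07d", as.integer(text)))
  warning("malformed SBO term '", text, "' treated as unannotated")
  NA_character_
}

#' Extract the SBO annotation of an SBML element
#'
#' @param element an \code{xml2} node for a species or reaction.
#' @return a one-row data frame with \code{element_id} and \code{term}
#'   (normalized accession or \code{NA}).
#' @export
extract_sbo_term <- function(element) {
  data.frame(element_id = xml2::xml_attr(element, "id"),
             term = normalize_sbo_term(xml2::xml_attr(element, "sboTerm")),
             stringsAsFactors = FALSE)
}

#' Parse an SBML model into edge tuples and SBO annotations
#'
#' Reads an SBML Level 2 or 3 file and extracts the reaction network as a
#' set of three-tuples (reaction id, participation role, species id).
#' Repeated listings of the same species in the same role of one reaction
#' collapse to a single tuple (the graph model carries no stoichiometric
#' multiplicity); a species that is both reactant and product of one
#' reaction yields two tuples with different roles.  Species and reactions
#' defined only through rules yield no tuples.
#'
#' @param path SBML file.
#' @return a list with components \code{model} (one-row data frame:
#'   \code{model_id}, \code{model_name}, \code{source_path}), \code{tuples}
#'   (data frame \code{reaction_id}, \code{role}, \code{species_id}) and
#'   \code{sbo} (data frame \code{element_id}, \code{term} covering every
#'   declared species and reaction).
#' @export
parse_sbml_model <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("failed to parse SBML file ", path, ": ", conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing"))
    stop("failed to parse SBML file ", path, ": no <model> element")
  base <- tools::file_path_sans_ext(basename(path))
  model_id <- xml2::xml_attr(model, "id")
  if (is.na(model_id)) model_id <- base
  model_name <- xml2::xml_attr(model, "name")
  if (is.na(model_name)) model_name <- basename(path)

  species <- xml2::xml_find_all(model, "./listOfSpecies/species")
  reactions <- xml2::xml_find_all(model, "./listOfReactions/reaction")
  sbo <- rbind(
    do.call(rbind, c(lapply(species, extract_sbo_term), list(NULL))),
    do.call(rbind, c(lapply(reactions, extract_sbo_term), list(NULL))))
  if (is.null(sbo))
    sbo <- data.frame(element_id = character(0), term = character(0),
                      stringsAsFactors = FALSE)

  tuples <- list()
  role_paths <- c(HAS_REACTANT = "./listOfReactants/speciesReference",
                  HAS_MODIFIER = "./listOfModifiers/modifierSpeciesReference",
                  HAS_PRODUCT  = "./listOfProducts/speciesReference")
  for (rn in seq_along(reactions)) {
    rid <- xml2::xml_attr(reactions[[rn]], "id")
    if (is.na(rid)) rid <- paste0(base, "_reaction_", rn)
    for (role in names(role_paths)) {
      refs <- xml2::xml_find_all(reactions[[rn]], role_paths[[role]])
      sp <- unique(xml2::xml_attr(refs, "species"))
      sp <- sp[!is.na(sp)]
      if (length(sp))
        tuples[[length(tuples) + 1L]] <-
          data.frame(reaction_id = rid, role = role, species_id = sp,
                     stringsAsFactors = FALSE)
    }
  }
  tuples <- if (length(tuples)) unique(do.call(rbind, tuples)) else
    data.frame(reaction_id = character(0), role = character(0),
               species_id = character(0), stringsAsFactors = FALSE)
  rownames(tuples) <- NULL
  list(model = data.frame(model_id = model_id, model_name = model_name,
                          source_path = path, stringsAsFactors = FALSE),
       tuples = tuples, sbo = sbo,
       species = xml2::xml_attr(species, "id"),
       reactions = xml2::xml_attr(reactions, "id"))
}

#' Parse a directory of SBML files
#'
#' @param dir directory scanned (non-recursively) for \code{.xml} and
#'   \code{.sbml} files.
#' @return list of \code{\link{parse_sbml_model}} results, one per file,
#'   with unique model ids enforced across the run (duplicates are suffixed).
#' @export
read_sbml_directory <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(xml|sbml)$", full.names = TRUE))
  models <- lapply(files, parse_sbml_model)
  ids <- vapply(models, function(m) m$model$model_id, character(1))
  if (anyDuplicated(ids)) {
    ids <- make.unique(ids, sep = "_")
    for (k in seq_along(models)) models[[k]]$model$model_id <- ids[k]
  }
  models
}

## Does every node appearing in a model's reaction network carry an SBO term?
sbo_complete <- function(parsed) {
  if (!nrow(parsed$tuples)) return(FALSE)
  nodes <- unique(c(parsed$tuples$reaction_id, parsed$tuples$species_id))
  terms <- parsed$sbo$term[match(nodes, parsed$sbo$element_id)]
  all(!is.na(terms))
}

#' Build connected reaction networks from parsed models
#'
#' Runs edge orientation and component splitting for every model and pools
#' the resulting networks with model provenance.  In SBO mode, models enter
#' the corpus only when every species and reaction node of their networks
#' carries an SBO term (the strictest reading of annotation validity;
#' disable with \code{require_sbo = FALSE}).
#'
#' @param models list of \code{\link{parse_sbml_model}} results.
#' @param mode \code{"structural"} or \code{"sbo"}.
#' @param require_sbo in SBO mode, drop models with unannotated network
#'   nodes.
#' @return a \code{network_set}.
#' @export
networks_from_models <- function(models, mode = c("structural", "sbo"),
                                 require_sbo = TRUE) {
  mode <- match.arg(mode)
  if (mode == "sbo" && require_sbo)
    models <- Filter(sbo_complete, models)
  sets <- lapply(models, function(m)
    split_components(orient_edges(m$tuples, sbo = m$sbo),
                     model_id = m$model$model_id))
  if (!length(sets)) return(network_set())
  combine_network_sets(sets)
}

#' Model records of a parsed corpus
#'
#' @param models list of \code{\link{parse_sbml_model}} results.
#' @return data frame with one row per model.
#' @export
model_records <- function(models) {
  out <- do.call(rbind, c(lapply(models, function(m) m$model), list(NULL)))
  if (is.null(out))
    out <- data.frame(model_id = character(0), model_name = character(0),
                      source_path = character(0), stringsAsFactors = FALSE)
  if (anyDuplicated(out$model_id)) stop("duplicate model ids in corpus")
  out
}
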