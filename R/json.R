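## The JSON edge-list dialect of the network export: an object with
## "columns" = ["ID(reaction)", "TYPE(edge)", "ID(species)"] and "data" = an
## array of three-element rows, one per (reaction, role, species)
## participation.

EDGE_JSON_COLUMNS <- c("ID(reaction)", "TYPE(edge)", "ID(species)")

#' Write edge tuples as a JSON edge list
#'
#' @param tuples data frame with columns \code{reaction_id}, \code{role}
#'   (\code{HAS_REACTANT}/\code{HAS_MODIFIER}/\code{HAS_PRODUCT}) and
#'   \code{species_id}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_edge_json <- function(tuples, path) {
  tuples <- as.data.frame(tuples, stringsAsFactors = FALSE)
  data <- unname(lapply(seq_len(nrow(tuples)), function(k)
    list(as.character(tuples$reaction_id[k]), as.character(tuples$role[k]),
         as.character(tuples$species_id[k]))))
  jsonlite::write_json(list(columns = EDGE_JSON_COLUMNS, data = data),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a JSON edge list into edge tuples
#'
#' @param path JSON file in the edge-list dialect (columns + data rows).
#' @return data frame with columns \code{reaction_id}, \code{role},
#'   \code{species_id}, one row per data row.
#' @export
read_edge_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$columns) || is.null(obj$data))
    stop("edge JSON format error in ", path, ": missing 'columns' or 'data'")
  cols <- unlist(obj$columns)
  if (length(cols) != 3 || !identical(cols, EDGE_JSON_COLUMNS))
    stop("edge JSON format error in ", path, ": columns must be ",
         paste(EDGE_JSON_COLUMNS, collapse = ", "))
  if (!length(obj$data)) {
    return(data.frame(reaction_id = character(0), role = character(0),
                      species_id = character(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(obj$data, function(row) {
    if (length(row) != 3)
      stop("edge JSON format error in ", path, ": data row of length ", length(row))
    vapply(row, as.character, character(1))
  })
  m <- do.call(rbind, rows)
  data.frame(reaction_id = m[, 1], role = m[, 2], species_id = m[, 3],
             stringsAsFactors = FALSE)
}
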