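## Step 5A: SBGN process-description style rendering of mined patterns.
## Node and edge roles are expressed purely by shape: a rounded rectangle
## for an entity (species), a small square for a process (reaction), a plain
## line for the reactant role, a filled arrow for the product role and a
## circle-headed line for the modifier role.  In structural mode no text is
## drawn; in SBO mode the term is written inside the glyph.

#' SBGN-style render configuration
#'
#' @param format image format, \code{"png"} (default) or \code{"pdf"}.
#' @param mode \code{"structural"} (no textual labels) or \code{"sbo"}
#'   (SBO terms drawn inside glyphs).
#' @param width,height image size in pixels (PNG) or inches (PDF).
#' @return an object of class \code{render_style}.
#' @export
render_style <- function(format = c("png", "pdf"),
                         mode = c("structural", "sbo"),
                         width = 480, height = 480) {
  structure(list(format = match.arg(format), mode = match.arg(mode),
                 width = width, height = height), class = "render_style")
}

ARROWHEAD <- c(IS_REACTANT = "none", IS_MODIFIER = "odot", HAS_PRODUCT = "normal")

#' Styled DOT text of a pattern
#'
#' A pure function of the pattern and style: the emitted text encodes the
#' SBGN glyph and arc conventions as Graphviz shape/arrowhead attributes,
#' one shape statement per node and one arc statement per edge, and is
#' byte-identical across runs.
#'
#' @param pattern a \code{pattern} or non-empty \code{reaction_graph}.
#' @param style a \code{\link{render_style}}.
#' @return character vector of DOT lines.
#' @export
styled_dot <- function(pattern, style = render_style()) {
  g <- if (inherits(pattern, "pattern")) pattern$graph else pattern
  stopifnot(inherits(g, "reaction_graph"))
  if (!nrow(g$nodes)) stop("cannot render an empty pattern")
  labels <- if (style$mode == "sbo")
    ifelse(is.na(g$nodes$sbo), "", g$nodes$sbo) else rep("", nrow(g$nodes))
  is_rx <- g$nodes$kind == "SBML_REACTION"
  node_lines <- ifelse(
    is_rx,
    sprintf(" %s [shape = square, width = 0.25, fixedsize = %s, label = \"%s\"];",
            dot_quote(g$nodes$id), ifelse(nzchar(labels), "false", "true"), labels),
    sprintf(" %s [shape = box, style = rounded, label = \"%s\"];",
            dot_quote(g$nodes$id), labels))
  edge_lines <- if (nrow(g$edges)) {
    sprintf(" %s -> %s [arrowhead = %s];",
            dot_quote(g$edges$from), dot_quote(g$edges$to),
            unname(ARROWHEAD[g$edges$role]))
  } else character(0)
  c("digraph pattern {", " graph [rankdir = LR];", node_lines, edge_lines, "}")
}

## Deterministic layered layout: reactions and species alternate in columns
## by graph distance from an arbitrary root; good enough for small motifs.
pattern_layout <- function(g) {
  n <- nrow(g$nodes)
  ig <- igraph::graph_from_data_frame(g$edges[, c("from", "to"), drop = FALSE],
                                      directed = FALSE, vertices = g$nodes$id)
  d <- suppressWarnings(igraph::distances(ig, v = g$nodes$id[1]))[1, g$nodes$id]
  d[!is.finite(d)] <- max(d[is.finite(d)]) + 1
  x <- as.numeric(d)
  y <- stats::ave(seq_len(n), x, FUN = function(ix) seq_along(ix) - (length(ix) + 1) / 2)
  cbind(x = x, y = y)
}

draw_glyphs <- function(g, style) {
  xy <- pattern_layout(g)
  graphics::par(mar = c(0.5, 0.5, 0.5, 0.5))
  graphics::plot(NA, xlim = range(xy[, 1]) + c(-0.6, 0.6),
                 ylim = range(xy[, 2]) + c(-0.6, 0.6),
                 axes = FALSE, xlab = "", ylab = "", asp = 1)
  idx <- stats::setNames(seq_len(nrow(g$nodes)), g$nodes$id)
  ## arcs first so glyphs overprint their ends
  for (e in seq_len(nrow(g$edges))) {
    a <- xy[idx[g$edges$from[e]], ]; b <- xy[idx[g$edges$to[e]], ]
    role <- g$edges$role[e]
    if (role == "HAS_PRODUCT") {
      graphics::arrows(a[1], a[2], b[1], b[2], length = 0.1, lwd = 2)
    } else {
      graphics::segments(a[1], a[2], b[1], b[2], lwd = 2)
      if (role == "IS_MODIFIER") {
        m <- a + 0.82 * (b - a)
        graphics::symbols(m[1], m[2], circles = 0.06, inches = FALSE,
                          add = TRUE, bg = "white", lwd = 2)
      }
    }
  }
  lab <- if (style$mode == "sbo") ifelse(is.na(g$nodes$sbo), "", g$nodes$sbo)
         else rep("", nrow(g$nodes))
  for (k in seq_len(nrow(g$nodes))) {
    if (g$nodes$kind[k] == "SBML_REACTION") {
      graphics::rect(xy[k, 1] - 0.1, xy[k, 2] - 0.1,
                     xy[k, 1] + 0.1, xy[k, 2] + 0.1, col = "white", lwd = 2)
    } else {
      graphics::rect(xy[k, 1] - 0.3, xy[k, 2] - 0.18,
                     xy[k, 1] + 0.3, xy[k, 2] + 0.18, col = "white", lwd = 2)
      ## rounded-corner hint on the entity glyph
      graphics::points(c(xy[k, 1] - 0.3, xy[k, 1] + 0.3), rep(xy[k, 2], 2),
                       pch = 16, col = "white", cex = 1.2)
    }
    if (nzchar(lab[k]))
      graphics::text(xy[k, 1], xy[k, 2] - 0.28, lab[k], cex = 0.55)
  }
  invisible()
}

#' Render a pattern as styled DOT plus an image file
#'
#' The styled DOT file is always written.  The image is produced by the
#' Graphviz \code{dot} executable when one is on the PATH; otherwise the
#' package's own glyph renderer draws the pattern via the R graphics
#' devices.  If no image device is available either, a warning of class
#' \code{render_backend_warning} is raised and only the DOT file remains.
#'
#' @param pattern a \code{pattern} or non-empty \code{reaction_graph}.
#' @param path_base output path without extension; produces
#'   \code{<path_base>.dot} and \code{<path_base>.<format>}.
#' @param style a \code{\link{render_style}}.
#' @return named character vector of the files written, invisibly.
#' @export
render_pattern <- function(pattern, path_base, style = render_style()) {
  dot_path <- paste0(path_base, ".dot")
  writeLines(styled_dot(pattern, style), dot_path)
  img_path <- paste0(path_base, ".", style$format)
  g <- if (inherits(pattern, "pattern")) pattern$graph else pattern
  dot_bin <- Sys.which("dot")
  if (nzchar(dot_bin)) {
    status <- system2(dot_bin, c(paste0("-T", style$format), dot_path,
                                 "-o", img_path))
    if (status == 0) return(invisible(c(dot = dot_path, image = img_path)))
  }
  ok <- tryCatch({
    if (style$format == "png") {
      if (!capabilities("png")) stop("no png device")
      grDevices::png(img_path, width = style$width, height = style$height)
    } else {
      grDevices::pdf(img_path, width = style$width / 96, height = style$height / 96)
    }
    on.exit(grDevices::dev.off(), add = TRUE)
    draw_glyphs(g, style)
    TRUE
  }, error = function(e) {
    warning(structure(class = c("render_backend_warning", "warning", "condition"),
                      list(message = paste0("no rendering backend available (",
                                            conditionMessage(e),
                                            "); styled DOT written to ", dot_path),
                           call = sys.call(-1))))
    FALSE
  })
  files <- c(dot = dot_path)
  if (ok) files <- c(files, image = img_path)
  invisible(files)
}

#' Split a mined-pattern DOT file into one file per pattern
#'
#' File names combine the pattern's frequency and a disambiguating index:
#' \code{<frequency>_<index>.dot}, with the index counting patterns of equal
#' frequency in file order.
#'
#' @param path DOT file in the mined-pattern dialect (with \code{#=>}
#'   frequency trailers).
#' @param dir output directory.
#' @return data frame with columns \code{path} and \code{frequency},
#'   invisibly.
#' @export
split_pattern_file <- function(path, dir) {
  graphs <- read_dot(path)
  freqs <- vapply(graphs, function(x) x$frequency, integer(1))
  if (anyNA(freqs))
    stop("malformed frequency comment: pattern file entries must carry '#=> n'")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- stats::ave(seq_along(freqs), freqs, FUN = seq_along)
  paths <- file.path(dir, sprintf("%d_%d.dot", freqs, idx))
  for (k in seq_along(graphs)) {
    lines <- c(format_dot_graph(graphs[[k]]$graph, name = graphs[[k]]$name),
               sprintf("}#=> %d[, %s,]", freqs[k],
                       paste(graphs[[k]]$supporting_ids, collapse = ", ")))
    writeLines(lines, paths[k])
  }
  invisible(data.frame(path = paths, frequency = freqs, stringsAsFactors = FALSE))
}
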