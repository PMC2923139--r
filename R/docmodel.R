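# Section-tree document model.
#
# A document is modelled as a tree of typed sections ("section tree"):
# the root spans the whole paper; title, author block, abstract (with
# optional titled subsections), body sections nested up to three levels,
# and minor sections (acknowledgements, references) hang below it. Tables
# and figures are treated as floating material and always attach directly
# to the root, since in print they need not sit inside the section that
# references them. Depth-first pre-order over the tree reproduces the
# logical reading order.
#
# Internally the tree is stored flat: a tibble of nodes in pre-order with
# parent pointers, which keeps every user-facing verb a plain data-frame
# operation.

SECTION_TYPES <- c(
  "root", "paperTitle", "authors", "abstract", "subAbstract",
  "majorSection", "subMajorSection", "subSubMajorSection",
  "minorSection", "table", "figure"
)

DETECTOR_SECTION_TYPES <- c(
  "majorSection", "subMajorSection", "subSubMajorSection", "table", "figure"
)

# Cell/row delimiter used when flattening table grids. "@" is outside the
# sequence alphabet and outside every separator the detectors accept, so no
# detector match can ever span two cells.
TABLE_CELL_DELIM <- " @ "

new_document <- function(paper_id, nodes, source_format) {
  structure(
    list(paper_id = paper_id, nodes = nodes, source_format = source_format),
    class = "prx_document"
  )
}

#' @export
print.prx_document <- function(x, ...) {
  cat("<prx_document> ", x$paper_id, " (", x$source_format, "), ",
      nrow(x$nodes), " nodes\n", sep = "")
  counts <- table(x$nodes$section_type)
  cat("  ", paste0(names(counts), ":", as.integer(counts), collapse = " "), "\n", sep = "")
  invisible(x)
}

# mutable node accumulator used by the parsers
node_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env$add <- function(parent_id, section_type, section_title = NA_character_,
                      section_text = NA_character_) {
    id <- length(env$rows) + 1L
    env$rows[[id]] <- tibble::tibble(
      node_id = id,
      parent_id = parent_id,
      section_type = section_type,
      section_title = section_title %||% NA_character_,
      section_text = section_text %||% NA_character_
    )
    id
  }
  env$tibble <- function() dplyr::bind_rows(env$rows)
  env
}

#' Build a single-section document from plain text
#'
#' Plain-text input carries no structural markup, so sectioning is skipped:
#' the full text is stored verbatim in one body section under the root. A
#' warning is raised because skipping sectioning can reduce extraction
#' accuracy (prose from excluded regions such as references is scanned too).
#'
#' @param text The document text (a character vector; multiple elements are
#'   joined with newlines). May be empty.
#' @param paper_id Identifier recorded with every result from this document.
#' @return A `prx_document`.
#' @export
#' @examples
#' doc <- suppressWarnings(parse_plain_text("Primers were 5'-ACGT-3'.", "ex1"))
#' iter_reading_order(doc)
parse_plain_text <- function(text, paper_id = "document") {
  if (is.null(text)) text <- ""
  text <- paste(as.character(text), collapse = "\n")
  nb <- node_builder()
  root <- nb$add(NA_integer_, "root")
  nb$add(root, "majorSection", section_title = NA_character_, section_text = text)
  rlang::warn(
    paste0("plain-text input for '", paper_id,
           "': document sectioning skipped; extraction accuracy may decrease."),
    class = "prx_plain_text_warning"
  )
  new_document(paper_id, nb$tibble(), "plain")
}

#' Flatten a table grid into detector-safe text
#'
#' Joins cell texts left-to-right, top-to-bottom with the artificial
#' delimiter `" @ "`. The delimiter character is outside the sequence
#' alphabet and outside the separators the detectors tolerate, so a
#' detector match can never merge the contents of two cells (or two rows).
#'
#' @param grid A list of rows, each a character vector of cell texts. Rows
#'   may be ragged; empty cells are allowed.
#' @return A single string.
#' @export
#' @examples
#' flatten_table(list(c("a", "b"), c("c", "d")))
flatten_table <- function(grid) {
  cells <- unlist(grid, use.names = FALSE)
  if (is.null(cells)) return("")
  paste(cells, collapse = TABLE_CELL_DELIM)
}

jats_text <- function(node) {
  if (length(node) == 0L) return(NA_character_)
  txt <- xml2::xml_text(node)
  txt <- stringr::str_squish(txt)
  if (identical(txt, "")) NA_character_ else txt
}

jats_paragraph_text <- function(sec) {
  ps <- xml2::xml_find_all(sec, "./p")
  if (length(ps) == 0L) return(NA_character_)
  paste(vapply(ps, xml2::xml_text, character(1L)), collapse = "\n")
}

jats_table_grid <- function(tw) {
  trs <- xml2::xml_find_all(tw, ".//tr")
  purrr::map(trs, function(tr) {
    cells <- xml2::xml_find_all(tr, "./td | ./th")
    vapply(cells, xml2::xml_text, character(1L))
  })
}

#' Build the section tree from JATS-style full-text XML
#'
#' Maps the usual JATS elements onto section-tree node types: article title
#' to `paperTitle`, the contributor block to `authors`, the abstract to
#' `abstract` (titled abstract subsections become `subAbstract` children),
#' body `<sec>` nesting at depths 1/2/3 to `majorSection` /
#' `subMajorSection` / `subSubMajorSection` (deeper nesting stays at the
#' deepest named level), and acknowledgements / reference list to
#' `minorSection`. Every `<table-wrap>` becomes one `table` node and every
#' `<fig>` one `figure` node; both are attached as children of the root --
#' after the body children -- regardless of where they sit in the XML.
#' Table grids are flattened with [flatten_table()]; figures carry their
#' caption text only.
#'
#' @param xml A file path or a string of well-formed XML.
#' @param paper_id Identifier for the document; when `NULL`, taken from the
#'   first `<article-id>` if present.
#' @return A `prx_document`.
#' @export
parse_jats <- function(xml, paper_id = NULL) {
  doc <- tryCatch(
    xml2::read_xml(xml),
    error = function(e) {
      rlang::abort(
        paste0("malformed XML: ", conditionMessage(e)),
        class = "prx_parse_error", parent = e
      )
    }
  )

  if (is.null(paper_id)) {
    pid <- xml2::xml_find_first(doc, ".//front//article-id")
    paper_id <- jats_text(pid) %||% "article"
    if (is.na(paper_id)) paper_id <- "article"
  }

  nb <- node_builder()
  root <- nb$add(NA_integer_, "root")

  title <- xml2::xml_find_first(doc, ".//front//article-title")
  if (length(title) > 0L && !inherits(title, "xml_missing")) {
    nb$add(root, "paperTitle", section_text = jats_text(title))
  }

  contribs <- xml2::xml_find_all(doc, ".//front//contrib-group//name | .//front//contrib-group//string-name")
  if (length(contribs) > 0L) {
    names_txt <- vapply(contribs, function(n) stringr::str_squish(xml2::xml_text(n)), character(1L))
    nb$add(root, "authors", section_text = paste(names_txt, collapse = "; "))
  }

  abstract <- xml2::xml_find_first(doc, ".//front//abstract")
  if (length(abstract) > 0L && !inherits(abstract, "xml_missing")) {
    ab_secs <- xml2::xml_find_all(abstract, "./sec")
    ab_id <- nb$add(root, "abstract",
                    section_title = jats_text(xml2::xml_find_first(abstract, "./title")) %|NA|% "Abstract",
                    section_text = if (length(ab_secs) == 0L) jats_paragraph_text(abstract) else NA_character_)
    for (s in ab_secs) {
      nb$add(ab_id, "subAbstract",
             section_title = jats_text(xml2::xml_find_first(s, "./title")),
             section_text = jats_paragraph_text(s))
    }
  }

  body_level <- c("majorSection", "subMajorSection", "subSubMajorSection")
  walk_sec <- function(sec, parent_id, depth) {
    type <- body_level[[min(depth, 3L)]]
    id <- nb$add(parent_id, type,
                 section_title = jats_text(xml2::xml_find_first(sec, "./title")),
                 section_text = jats_paragraph_text(sec))
    for (child in xml2::xml_find_all(sec, "./sec")) {
      walk_sec(child, id, depth + 1L)
    }
    id
  }
  body <- xml2::xml_find_first(doc, ".//body")
  if (length(body) > 0L && !inherits(body, "xml_missing")) {
    for (sec in xml2::xml_find_all(body, "./sec")) {
      walk_sec(sec, root, 1L)
    }
  }

  for (ack in xml2::xml_find_all(doc, ".//back/ack")) {
    nb$add(root, "minorSection",
           section_title = jats_text(xml2::xml_find_first(ack, "./title")) %|NA|% "Acknowledgements",
           section_text = jats_paragraph_text(ack))
  }
  for (rl in xml2::xml_find_all(doc, ".//back/ref-list")) {
    refs <- xml2::xml_find_all(rl, "./ref")
    nb$add(root, "minorSection",
           section_title = jats_text(xml2::xml_find_first(rl, "./title")) %|NA|% "References",
           section_text = if (length(refs) > 0L) {
             paste(vapply(refs, function(r) stringr::str_squish(xml2::xml_text(r)), character(1L)),
                   collapse = "\n")
           } else {
             jats_text(rl)
           })
  }

  # floating material: always children of root, after the body children
  for (tw in xml2::xml_find_all(doc, ".//table-wrap")) {
    label <- jats_text(xml2::xml_find_first(tw, "./label"))
    caption <- jats_text(xml2::xml_find_first(tw, "./caption"))
    ttl <- paste(stats::na.omit(c(label, caption)), collapse = ": ")
    nb$add(root, "table",
           section_title = if (identical(ttl, "")) NA_character_ else ttl,
           section_text = flatten_table(jats_table_grid(tw)))
  }
  for (fig in xml2::xml_find_all(doc, ".//fig")) {
    nb$add(root, "figure",
           section_title = jats_text(xml2::xml_find_first(fig, "./label")),
           section_text = jats_text(xml2::xml_find_first(fig, "./caption")))
  }

  new_document(paper_id, nb$tibble(), "jats")
}

`%|NA|%` <- function(x, y) if (is.null(x) || (length(x) == 1L && is.na(x))) y else x

#' Traverse a document in reading order
#'
#' Depth-first pre-order traversal from the root; concatenating the
#' `section_text` column of the result reproduces the document's logical
#' reading order.
#'
#' @param doc A `prx_document`.
#' @return A tibble of nodes (one row per node, root first) with columns
#'   `node_id`, `parent_id`, `section_type`, `section_title`, `section_text`.
#' @export
iter_reading_order <- function(doc) {
  stopifnot(inherits(doc, "prx_document"))
  nodes <- doc$nodes
  if (nrow(nodes) == 0L) return(nodes)
  children <- split(nodes$node_id, factor(nodes$parent_id, levels = nodes$node_id))
  order <- integer(0)
  visit <- function(id) {
    order[[length(order) + 1L]] <<- id
    for (ch in children[[as.character(id)]]) visit(ch)
  }
  roots <- nodes$node_id[is.na(nodes$parent_id)]
  for (r in roots) visit(r)
  nodes[match(order, nodes$node_id), , drop = FALSE]
}

#' Serialize a document's text in reading order
#'
#' @param doc A `prx_document`.
#' @param collapse Separator between section texts (default `""`, so a
#'   plain-text document round-trips verbatim).
#' @return A single string.
#' @export
serialize_document <- function(doc, collapse = "") {
  nodes <- iter_reading_order(doc)
  texts <- nodes$section_text[!is.na(nodes$section_text)]
  paste(texts, collapse = collapse)
}

#' Select the sections fed to the sequence detectors
#'
#' Primer and probe sequences are reported in the main body, tables and
#' figure captions. This returns, in reading order, exactly the nodes whose
#' type is `majorSection`, `subMajorSection`, `subSubMajorSection`, `table`
#' or `figure`; title, authors, abstract and minor sections (references,
#' acknowledgements) are excluded.
#'
#' @param doc A `prx_document`.
#' @return A tibble of detector-eligible nodes in reading order.
#' @export
select_detector_sections <- function(doc) {
  nodes <- iter_reading_order(doc)
  nodes[nodes$section_type %in% DETECTOR_SECTION_TYPES, , drop = FALSE]
}

#' Dump a section tree as JSON
#'
#' Debug representation: nested objects with fields `type`, `title`, `text`
#' and `children`.
#'
#' @param doc A `prx_document`.
#' @param path Optional file to write to.
#' @return The JSON string, invisibly when `path` is given.
#' @export
document_to_json <- function(doc, path = NULL) {
  nodes <- doc$nodes
  children <- split(nodes$node_id, factor(nodes$parent_id, levels = nodes$node_id))
  as_list <- function(id) {
    row <- nodes[nodes$node_id == id, ]
    kids <- children[[as.character(id)]]
    list(
      type = row$section_type,
      title = row$section_title,
      text = row$section_text,
      children = lapply(kids, as_list)
    )
  }
  root <- nodes$node_id[is.na(nodes$parent_id)][1L]
  json <- jsonlite::toJSON(as_list(root), auto_unbox = TRUE, null = "null", na = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
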