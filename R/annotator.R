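# Organism/gene annotation of refined sequences.
#
# A refined sequence is sent to a sequence-lookup backend (in production a
# local mirror of a nucleotide database; here any function returning ranked
# hits). Each hit carries an organism name and optional gene names. The hit
# is then scored against the document itself: spelling variants of the
# organism name (leading-word prefixes, plus genus-abbreviated forms such as
# "B. melitensis") are searched case-insensitively as whole words, and the
# confidence score grows with the word length l of the longest matched
# variant relative to the full name length L, plus a bonus when a longest
# match co-occurs with the sequence in the same section. Scores live on a
# 0-100 scale.
#
# The scoring curve CS_L(l) is linear in l: 100 at l = L, 40 at l = 1,
# i.e. CS_L(l) = 100 - 60 * (L - l) / (L - 1) (and CS_1(1) = 100), which
# reproduces the anchor CS_3(2) = 70. The co-occurrence bonus is +20 points,
# capped so the total never exceeds 100.

#' Generate spelling variants of an organism name
#'
#' Organism names grow more specific by post-positive words, so variants are
#' the leading-word prefixes of the name; for every multi-word prefix a
#' genus-abbreviated form ("B. melitensis" for "Brucella melitensis") is
#' added. Abbreviation does not reduce a variant's covered-word count `l`.
#'
#' @param organism_name Name of one or more whitespace-separated words.
#' @return Tibble with columns `variant` and `l` (covered-word count).
#' @export
#' @examples
#' generate_variants("Brucella Mellitensis 16M")
generate_variants <- function(organism_name) {
  if (!rlang::is_scalar_character(organism_name) ||
      is.na(organism_name) || stringr::str_trim(organism_name) == "") {
    rlang::abort("`organism_name` must be a non-empty string.", class = "prx_domain_error")
  }
  words <- stringr::str_split_1(stringr::str_squish(organism_name), " ")
  L <- length(words)
  prefixes <- tibble::tibble(
    variant = vapply(seq_len(L), function(k) paste(words[1:k], collapse = " "), character(1L)),
    l = seq_len(L)
  )
  abbreviated <- if (L >= 2L) {
    tibble::tibble(
      variant = vapply(2:L, function(k) {
        paste(c(paste0(substr(words[1L], 1L, 1L), "."), words[2:k]), collapse = " ")
      }, character(1L)),
      l = 2:L
    )
  } else {
    NULL
  }
  dplyr::distinct(dplyr::bind_rows(prefixes, abbreviated))
}

# whole-word, case-insensitive, punctuation-tolerant term search;
# returns node_ids of sections whose title or text contains the term
find_term_nodes <- function(doc, term) {
  stopifnot(inherits(doc, "prx_document"))
  escaped <- gsub("([^[:alnum:] ])", "\\\\\\1", term) # escape every regex metacharacter
  pat <- stringr::regex(paste0("(?<![[:alnum:]])", escaped, "(?![[:alnum:]])"),
                        ignore_case = TRUE)
  nodes <- doc$nodes
  text <- paste(
    ifelse(is.na(nodes$section_title), "", nodes$section_title),
    ifelse(is.na(nodes$section_text), "", nodes$section_text)
  )
  nodes$node_id[stringr::str_detect(text, pat)]
}

#' Match organism-name variants against a document
#'
#' Searches every section (title and text, case-insensitive, whole words)
#' for the given spelling variants and summarises the best evidence: `l` is
#' the covered-word count of the longest matched variant (0 when none
#' match), and `cooccurs` reports whether some match of that length lies in
#' the same section as the sequence.
#'
#' @param doc A `prx_document`.
#' @param variants Tibble from [generate_variants()].
#' @param node_id Section node holding the sequence (`NA` for no
#'   co-occurrence assessment).
#' @return One-row tibble with `L` (full name word count), `l`, `cooccurs`
#'   and `matched_variants` (list column).
#' @export
match_organism <- function(doc, variants, node_id = NA_integer_) {
  stopifnot(is.data.frame(variants), all(c("variant", "l") %in% names(variants)))
  hits <- purrr::map(variants$variant, function(v) find_term_nodes(doc, v))
  matched <- lengths(hits) > 0L
  l <- if (any(matched)) max(variants$l[matched]) else 0L
  cooccurs <- FALSE
  if (l > 0L && !is.na(node_id)) {
    longest <- matched & variants$l == l
    cooccurs <- any(vapply(hits[longest], function(ns) node_id %in% ns, logical(1L)))
  }
  tibble::tibble(
    L = max(variants$l),
    l = as.integer(l),
    cooccurs = cooccurs,
    matched_variants = list(variants$variant[matched])
  )
}

#' Organism confidence score
#'
#' Linear document-evidence score for an organism assignment: 0 when no
#' variant matched; otherwise `100 - 60 * (L - l) / (L - 1)` (100 for a
#' one-word name), plus 20 points when a longest match co-occurs with the
#' sequence in the same section, capped at 100. Monotone non-decreasing in
#' `l` for fixed `L`.
#'
#' @param L Word count of the full organism name (>= 1). Vectorised.
#' @param l Covered-word count of the longest matched variant, `0 <= l <= L`.
#' @param cooccurs Logical: does a longest match share a section with the
#'   sequence?
#' @return Numeric score(s) in `[0, 100]`.
#' @export
#' @examples
#' organism_confidence(3, 2)        # 70
#' organism_confidence(3, 2, TRUE)  # 90
organism_confidence <- function(L, l, cooccurs = FALSE) {
  if (!is.numeric(L) || !is.numeric(l) || any(is.na(L)) || any(is.na(l))) {
    rlang::abort("`L` and `l` must be numeric.", class = "prx_domain_error")
  }
  n <- max(length(L), length(l), length(cooccurs))
  L <- rep_len(L, n); l <- rep_len(l, n); cooccurs <- rep_len(as.logical(cooccurs), n)
  if (any(L < 1) || any(l < 0) || any(l > L)) {
    rlang::abort("require L >= 1 and 0 <= l <= L.", class = "prx_domain_error")
  }
  base <- ifelse(L == 1, 100, 100 - 60 * (L - l) / (L - 1))
  score <- pmin(100, base + 20 * cooccurs)
  ifelse(l == 0, 0, score)
}

#' Gene confidence score
#'
#' 80 points when the gene name appears anywhere in the document text, plus
#' 20 when it co-occurs with the sequence in the same section; 0 when the
#' name does not appear.
#'
#' @param appears_in_text Logical.
#' @param cooccurs_with_sequence Logical; implies `appears_in_text`.
#' @return Numeric score(s): 0, 80 or 100.
#' @export
#' @examples
#' gene_confidence(TRUE, FALSE) # 80
#' gene_confidence(TRUE, TRUE)  # 100
gene_confidence <- function(appears_in_text, cooccurs_with_sequence = FALSE) {
  appears <- as.logical(appears_in_text)
  cooccurs <- as.logical(cooccurs_with_sequence)
  if (any(cooccurs & !appears)) {
    rlang::abort("a gene name cannot co-occur without appearing in the text.",
                 class = "prx_domain_error")
  }
  80 * appears + 20 * (appears & cooccurs)
}

#' Tibble-backed sequence-lookup backend
#'
#' Wraps a hit table into the backend contract used by [annotate()]: a
#' function taking a query sequence and returning its hits ordered by rank.
#' Stands in for a local nucleotide-database mirror in tests and fixtures.
#'
#' @param hits Tibble with columns `sequence`, `identifier`, `organism_name`
#'   and optionally `rank` (ordering; default = row order) and `gene_names`
#'   (semicolon-separated string or list column).
#' @return A function `backend(sequence)` returning a tibble of hits with a
#'   `gene_names` list column.
#' @export
lookup_backend <- function(hits) {
  stopifnot(is.data.frame(hits),
            all(c("sequence", "identifier", "organism_name") %in% names(hits)))
  hits <- tibble::as_tibble(hits)
  if (!"rank" %in% names(hits)) hits$rank <- seq_len(nrow(hits))
  if (!"gene_names" %in% names(hits)) hits$gene_names <- list(character(0))
  if (is.character(hits$gene_names)) {
    hits$gene_names <- purrr::map(hits$gene_names, function(g) {
      if (is.na(g) || g == "") character(0) else stringr::str_split_1(g, ";\\s*")
    })
  }
  stopifnot(all(nchar(hits$identifier) > 0L), all(nchar(hits$organism_name) > 0L))
  function(sequence) {
    dplyr::arrange(hits[hits$sequence == sequence, , drop = FALSE], .data$rank)
  }
}

#' Read a sequence-lookup fixture from TSV
#'
#' Columns: `sequence`, `rank`, `identifier`, `organism_name`, `gene_names`
#' (semicolon-separated, possibly empty).
#'
#' @param path TSV file path.
#' @return A backend function (see [lookup_backend()]).
#' @export
read_lookup_tsv <- function(path) {
  hits <- readr::read_tsv(path, col_types = readr::cols(
    sequence = readr::col_character(),
    rank = readr::col_integer(),
    identifier = readr::col_character(),
    organism_name = readr::col_character(),
    gene_names = readr::col_character()
  ))
  lookup_backend(hits)
}

#' Write a sequence-lookup fixture to TSV
#'
#' @param hits Hit tibble as accepted by [lookup_backend()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_lookup_tsv <- function(hits, path) {
  out <- tibble::as_tibble(hits)
  if (!"rank" %in% names(out)) out$rank <- seq_len(nrow(out))
  if (!"gene_names" %in% names(out)) out$gene_names <- ""
  if (is.list(out$gene_names)) {
    out$gene_names <- vapply(out$gene_names, paste, character(1L), collapse = ";")
  }
  readr::write_tsv(out[, c("sequence", "rank", "identifier", "organism_name", "gene_names")], path)
  invisible(path)
}

#' Annotate one refined sequence
#'
#' Queries the backend, keeps the best `max_hits` hits in backend order, and
#' scores each hit's organism name against the document. The hit with the
#' highest organism confidence wins (ties to the earlier hit); the winning
#' hit's gene names are scored the same way and the best one is reported.
#' An empty hit list yields an unannotated record (absent names, zero
#' scores).
#'
#' @param sequence The sequence string.
#' @param doc The source `prx_document`.
#' @param backend A backend function (see [lookup_backend()]).
#' @param node_id Section node holding the sequence (for co-occurrence).
#' @param max_hits Number of top hits to consider (default 10).
#' @return One-row tibble: `paper`, `sequence`, `organism_name`,
#'   `organism_cs`, `gene_name`, `gene_cs`, `n_hits`.
#' @export
annotate_sequence <- function(sequence, doc, backend, node_id = NA_integer_, max_hits = 10L) {
  stopifnot(rlang::is_scalar_character(sequence), is.function(backend))
  hits <- backend(sequence)
  if (!is.data.frame(hits)) {
    rlang::abort("backend must return a data frame of hits.", class = "prx_backend_error")
  }
  hits <- utils::head(hits, max_hits)
  empty <- tibble::tibble(
    paper = doc$paper_id, sequence = sequence,
    organism_name = NA_character_, organism_cs = 0,
    gene_name = NA_character_, gene_cs = 0, n_hits = nrow(hits)
  )
  if (nrow(hits) == 0L) return(empty)

  org_cs <- vapply(seq_len(nrow(hits)), function(i) {
    m <- match_organism(doc, generate_variants(hits$organism_name[i]), node_id)
    organism_confidence(m$L, m$l, m$cooccurs)
  }, numeric(1L))
  best <- which.max(org_cs) # ties -> earliest hit

  genes <- hits$gene_names[[best]]
  gene_name <- NA_character_
  gene_cs <- 0
  if (length(genes) > 0L) {
    scores <- vapply(genes, function(g) {
      nodes <- find_term_nodes(doc, g)
      gene_confidence(length(nodes) > 0L,
                      !is.na(node_id) && node_id %in% nodes)
    }, numeric(1L))
    gb <- which.max(scores) # ties -> first gene
    gene_name <- genes[[gb]]
    gene_cs <- scores[[gb]]
  }
  tibble::tibble(
    paper = doc$paper_id, sequence = sequence,
    organism_name = hits$organism_name[[best]], organism_cs = org_cs[[best]],
    gene_name = gene_name, gene_cs = gene_cs, n_hits = nrow(hits)
  )
}

#' Annotate refined sequences against a document
#'
#' Runs [annotate_sequence()] for every row. A backend failure on one
#' sequence raises a warning carrying that sequence and the pipeline
#' continues with the remaining ones (the failed row is reported
#' unannotated).
#'
#' @param sequences A `prx_refinement` or a tibble with columns `sequence`
#'   and (optionally) `node_id`.
#' @param doc The source `prx_document`.
#' @param backend A backend function (see [lookup_backend()]).
#' @param max_hits Number of top hits to consider per sequence.
#' @return Tibble of annotation records, one row per input sequence.
#' @export
annotate <- function(sequences, doc, backend, max_hits = 10L) {
  if (inherits(sequences, "prx_refinement")) sequences <- sequences$sequences
  stopifnot(is.data.frame(sequences), "sequence" %in% names(sequences))
  node_ids <- if ("node_id" %in% names(sequences)) sequences$node_id else rep(NA_integer_, nrow(sequences))
  rows <- purrr::map(seq_len(nrow(sequences)), function(i) {
    tryCatch(
      annotate_sequence(sequences$sequence[i], doc, backend, node_ids[i], max_hits),
      error = function(e) {
        rlang::warn(
          paste0("annotation failed for sequence '", sequences$sequence[i], "': ",
                 conditionMessage(e)),
          class = "prx_annotation_error"
        )
        tibble::tibble(
          paper = doc$paper_id, sequence = sequences$sequence[i],
          organism_name = NA_character_, organism_cs = 0,
          gene_name = NA_character_, gene_cs = 0, n_hits = NA_integer_
        )
      }
    )
  })
  dplyr::bind_rows(rows)
}
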