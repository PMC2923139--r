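# End-to-end extraction pipeline.

#' Extract refined sequences from one document
#'
#' Convenience wrapper chaining [scan_document()] and [refine()].
#'
#' @param doc A `prx_document`.
#' @param scan A [scan_config()].
#' @param refiner A [refiner_config()].
#' @return A `prx_refinement` (see [refine()]).
#' @export
extract_sequences <- function(doc, scan = scan_config(), refiner = refiner_config()) {
  refine(scan_document(doc, scan), refiner)
}

read_input <- function(input, name, format) {
  is_path <- length(input) == 1L && !grepl("[<\n]", input) && file.exists(input)
  if (format == "jats") {
    parse_jats(input, paper_id = name)
  } else {
    text <- if (is_path) paste(readr::read_lines(input), collapse = "\n") else input
    withCallingHandlers(
      parse_plain_text(text, paper_id = name),
      prx_plain_text_warning = function(w) rlang::cnd_muffle(w)
    )
  }
}

#' Run the full extraction pipeline over a batch of documents
#'
#' For every input: parse to a section tree, scan the detector-eligible
#' sections with the detector cascade, refine the candidates with the rule
#' engine and, when a backend is supplied, annotate the surviving sequences
#' with organism/gene names and confidence scores. A failure on one document
#' is recorded and the batch continues.
#'
#' @param inputs Named character vector: file paths or document contents
#'   (names become paper ids; file basenames are used as a fallback).
#' @param format `"txt"` for plain text or `"jats"` for JATS-style XML.
#' @param scan A [scan_config()].
#' @param refiner A [refiner_config()].
#' @param backend Optional lookup backend (see [lookup_backend()]).
#' @param max_hits Top hits consulted per sequence when annotating.
#' @return An object of class `prx_run`: list with
#'   * `sequences`: tibble (`paper_id`, `node_id`, `section_type`,
#'     `detector`, `sequence`);
#'   * `annotations`: tibble of annotation records, or `NULL` without a
#'     backend;
#'   * `counts`: per-paper tibble of phase tallies (sections scanned,
#'     candidates, rule firings, sequences out, annotated);
#'   * `errors`: tibble (`paper_id`, `message`), empty on full success.
#' @export
run_pipeline <- function(inputs, format = c("txt", "jats"),
                         scan = scan_config(), refiner = refiner_config(),
                         backend = NULL, max_hits = 10L) {
  format <- rlang::arg_match(format)
  ids <- names(inputs)
  if (is.null(ids)) ids <- rep(NA_character_, length(inputs))
  seqs <- list(); anns <- list(); counts <- list(); errors <- list()

  for (i in seq_along(inputs)) {
    name <- ids[[i]]
    if (is.na(name) || name == "") {
      name <- if (file.exists(inputs[[i]])) {
        sub("\\.[^.]*$", "", basename(inputs[[i]]))
      } else {
        paste0("doc", i)
      }
    }
    res <- tryCatch({
      doc <- read_input(inputs[[i]], name, format)
      candidates <- scan_document(doc, scan)
      refinement <- refine(candidates, refiner)
      annotation <- if (!is.null(backend) && nrow(refinement$sequences) > 0L) {
        annotate(refinement, doc, backend, max_hits = max_hits)
      }
      list(
        sequences = refinement$sequences,
        annotations = annotation,
        counts = tibble::tibble(
          paper_id = doc$paper_id,
          sections_scanned = nrow(select_detector_sections(doc)),
          candidates = refinement$n_candidates,
          rules_fired = nrow(refinement$trace),
          sequences = nrow(refinement$sequences),
          annotated = if (is.null(annotation)) 0L else sum(!is.na(annotation$organism_name))
        )
      )
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <- tibble::tibble(
        paper_id = name, message = conditionMessage(res)
      )
    } else {
      seqs[[length(seqs) + 1L]] <- res$sequences
      if (!is.null(res$annotations)) anns[[length(anns) + 1L]] <- res$annotations
      counts[[length(counts) + 1L]] <- res$counts
    }
  }

  empty_seqs <- tibble::tibble(
    candidate_id = integer(), paper_id = character(), node_id = integer(),
    section_type = character(), section_title = character(),
    detector = integer(), sequence = character()
  )
  structure(
    list(
      sequences = if (length(seqs)) dplyr::bind_rows(seqs) else empty_seqs,
      annotations = if (length(anns)) dplyr::bind_rows(anns) else NULL,
      counts = dplyr::bind_rows(counts),
      errors = if (length(errors)) dplyr::bind_rows(errors) else
        tibble::tibble(paper_id = character(), message = character())
    ),
    class = "prx_run"
  )
}

#' @export
print.prx_run <- function(x, ...) {
  cat("<prx_run> ", nrow(x$counts), " documents, ", nrow(x$sequences),
      " sequences", sep = "")
  if (!is.null(x$annotations)) cat(", ", nrow(x$annotations), " annotated", sep = "")
  if (nrow(x$errors) > 0L) cat(", ", nrow(x$errors), " failures", sep = "")
  cat("\n")
  print(x$counts, ...)
  invisible(x)
}

#' Export extracted sequences as FASTA
#'
#' Headers carry the provenance `paper_id|node_id|detector`. Sequences are
#' written verbatim (case and degenerate symbols preserved).
#'
#' @param sequences Tibble with columns `sequence`, `paper_id` and
#'   optionally `node_id`, `detector` (e.g. `prx_run$sequences` or
#'   a `prx_refinement`'s `sequences`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_fasta <- function(sequences, path) {
  if (inherits(sequences, "prx_refinement")) sequences <- sequences$sequences
  stopifnot(is.data.frame(sequences), all(c("paper_id", "sequence") %in% names(sequences)))
  rlang::check_installed("Biostrings", reason = "to write FASTA output")
  node <- if ("node_id" %in% names(sequences)) sequences$node_id else NA
  det <- if ("detector" %in% names(sequences)) sequences$detector else NA
  headers <- paste(sequences$paper_id, node, det, sep = "|")
  set <- Biostrings::BStringSet(stats::setNames(sequences$sequence, headers))
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
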