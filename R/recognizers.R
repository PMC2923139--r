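# Candidate sequence recognition.
#
# Three detectors scan section text in a fixed priority cascade, most
# specific first:
#
#   1. delimited  -- runs of alphabet symbols (blanks/dashes/newlines
#      allowed inside) opened, and optionally closed, by the 5'/3'
#      delimiter strings; the prime is optional ("5-...-3" also counts).
#      The opening delimiter must abut the sequence directly or via a dash;
#      a space-separated "3' AAGCT ..." is left to detector 3.
#   2. triplets   -- at least three whitespace-separated groups, all of
#      exactly three alphabet symbols except the last, which may be shorter.
#   3. generic    -- maximal stretches of alphabet runs (and colons) joined
#      by blanks, dashes, colons or newlines; any other character ends the
#      stretch. No minimum length: junk is left for the refiner to discard.
#
# A span claimed by a higher-priority detector is masked before the lower
# detectors run, so claimed spans never overlap. Matched regions are
# tokenized into maximal alphabet runs; blanks, dashes and newlines are
# dropped, while each colon is kept as its own ":" token because the
# refinement rules split on it.

MASK_CHAR <- "\u0001"

prime_class <- "['′’]"
seq_sep_class <- "[ \t\r\n-]"

delimited_pattern <- function() {
  SIG <- sigma_class()
  paste0(
    "(?<![0-9A-Za-z])",
    "(?:(5)|(3))", prime_class, "?",         # opening delimiter
    "(?:-\\s*|(?=", SIG, "))",               # attached directly or via dash
    SIG, "(?:", seq_sep_class, "*", SIG, ")*", # body: alphabet runs + separators
    "(?:[ \t\r\n]*-?[ \t\r\n]*(?:(?(1)3|5))", prime_class, "?(?![0-9A-Za-z]))?" # optional closing
  )
}

generic_pattern <- function() {
  SIG <- sigma_class()
  paste0("(?:", SIG, "|:)(?:", seq_sep_class, "*(?:", SIG, "|:))*")
}

match_spans <- function(text, pattern) {
  m <- gregexpr(pattern, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(tibble::tibble(start = integer(), end = integer()))
  tibble::tibble(start = as.integer(m), end = as.integer(m) + attr(m, "match.length") - 1L)
}

#' Tokenize a matched text region
#'
#' Converts the region matched by a detector into its token list: maximal
#' runs over the 30-symbol alphabet, in order. Blanks, dashes and newline
#' characters are dropped (they are implicit separators); each colon is kept
#' as its own `":"` token, since the refinement stage splits on it. Case is
#' preserved.
#'
#' @param region A single string.
#' @return Character vector of tokens.
#' @export
#' @examples
#' tokenize_region("CGT CCM\nARR-GGA-WAC-TGA")
tokenize_region <- function(region) {
  stopifnot(rlang::is_scalar_character(region))
  pat <- paste0("(?:", sigma_class(), ")+|:")
  m <- gregexpr(pat, region, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(character(0))
  as.character(regmatches(region, list(m))[[1L]])
}

span_tbl <- function(start, end, tokens, detector) {
  tibble::tibble(
    detector = rep(detector, length(start)),
    start = as.integer(start),
    end = as.integer(end),
    tokens = tokens
  )
}

#' Detector 1: delimiter-anchored sequences
#'
#' Finds spans of alphabet symbols (possibly containing blanks, dashes and
#' newlines) opened by one of the delimiter strings `5'`, `3'`, `5`, `3` and
#' optionally closed by the complementary delimiter. The opening delimiter
#' must be attached to the sequence directly or via a dash. Delimiters are
#' excluded from the token list.
#'
#' @param text Section text to scan.
#' @return A tibble with columns `detector`, `start`, `end` (character span
#'   of the full match, 1-based, inclusive) and `tokens` (list column).
#' @export
#' @examples
#' detect_delimited("(5'-TGCCATTGCCAAAGAGAC-3')")
detect_delimited <- function(text) {
  stopifnot(rlang::is_scalar_character(text))
  spans <- match_spans(text, delimited_pattern())
  toks <- purrr::map2(spans$start, spans$end, function(s, e) {
    region <- substr(text, s, e)
    # strip delimiters before tokenizing: drop leading 5/3(') (+dash), trailing (dash+)3/5(')
    region <- sub(paste0("^[53]", prime_class, "?-?"), "", region)
    region <- sub(paste0("[ \t\r\n]*-?[ \t\r\n]*[53]", prime_class, "?$"), "", region)
    tokenize_region(region)
  })
  span_tbl(spans$start, spans$end, toks, 1L)
}

#' Detector 2: triplet-grouped sequences
#'
#' Finds runs of at least three whitespace-separated groups of alphabet
#' symbols where every group but the last has exactly three symbols and the
#' last has three or fewer. Groups may be separated by newlines.
#'
#' @inheritParams detect_delimited
#' @inherit detect_delimited return
#' @export
#' @examples
#' detect_triplets("CTC AAG TTC TCA GGA TCC A")
detect_triplets <- function(text) {
  stopifnot(rlang::is_scalar_character(text))
  runs <- match_spans(text, paste0("(?:", sigma_class(), ")+"))
  n <- nrow(runs)
  out_start <- integer(0); out_end <- integer(0); out_tokens <- list()
  if (n > 0L) {
    len <- runs$end - runs$start + 1L
    ws_gap <- function(i) {
      gap <- substr(text, runs$end[i] + 1L, runs$start[i + 1L] - 1L)
      grepl("^[ \t\r\n]+$", gap)
    }
    i <- 1L
    while (i <= n) {
      if (len[i] != 3L) { i <- i + 1L; next }
      j <- i
      while (j + 1L <= n && len[j + 1L] == 3L && ws_gap(j)) j <- j + 1L
      k <- j
      if (j + 1L <= n && len[j + 1L] < 3L && ws_gap(j)) k <- j + 1L
      if (k - i + 1L >= 3L) {
        out_start <- c(out_start, runs$start[i])
        out_end <- c(out_end, runs$end[k])
        out_tokens <- c(out_tokens, list(substring(text, runs$start[i:k], runs$end[i:k])))
        i <- k + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  span_tbl(out_start, out_end, out_tokens, 2L)
}

#' Detector 3: generic alphabet stretches
#'
#' Finds maximal stretches of alphabet runs joined by blanks, colons, dashes
#' or newlines. Any other character terminates the stretch. There is no
#' minimum length by default -- short junk is discarded downstream by the
#' refinement rules.
#'
#' @inheritParams detect_delimited
#' @param min_span_symbols Minimum number of alphabet symbols a stretch must
#'   contain to be reported (default 1; colons do not count).
#' @inherit detect_delimited return
#' @export
#' @examples
#' detect_generic("gATACCCCATATgAATgCgAT")
detect_generic <- function(text, min_span_symbols = 1L) {
  stopifnot(rlang::is_scalar_character(text))
  spans <- match_spans(text, generic_pattern())
  toks <- purrr::map2(spans$start, spans$end, function(s, e) tokenize_region(substr(text, s, e)))
  keep <- vapply(toks, function(tk) sum(nchar(tk[tk != ":"])) >= min_span_symbols, logical(1L))
  span_tbl(spans$start[keep], spans$end[keep], toks[keep], 3L)
}

mask_spans <- function(chars, spans) {
  for (i in seq_len(nrow(spans))) {
    chars[spans$start[i]:spans$end[i]] <- MASK_CHAR
  }
  chars
}

#' Scanner configuration
#'
#' @param min_span_symbols Passed to [detect_generic()].
#' @return A list of class `prx_scan_config`.
#' @export
scan_config <- function(min_span_symbols = 1L) {
  stopifnot(is.numeric(min_span_symbols), min_span_symbols >= 1)
  structure(list(min_span_symbols = as.integer(min_span_symbols)),
            class = "prx_scan_config")
}

# run the full cascade over one piece of section text
scan_section_text <- function(text, config = scan_config()) {
  if (is.na(text) || identical(text, "")) {
    return(span_tbl(integer(0), integer(0), list(), integer(0)))
  }
  d1 <- detect_delimited(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  masked1 <- paste(mask_spans(chars, d1), collapse = "")
  d2 <- detect_triplets(masked1)
  chars2 <- strsplit(masked1, "", fixed = TRUE)[[1L]]
  masked2 <- paste(mask_spans(chars2, d2), collapse = "")
  d3 <- detect_generic(masked2, min_span_symbols = config$min_span_symbols)
  out <- dplyr::bind_rows(d1, d2, d3)
  out <- out[!vapply(out$tokens, function(tk) length(tk) == 0L, logical(1L)), , drop = FALSE]
  dplyr::arrange(out, .data$start, .data$detector)
}

#' Scan a document for candidate sequences
#'
#' Applies the detector cascade (1 then 2 then 3) to every detector-eligible
#' section of the document, in reading order. A character span claimed by a
#' higher-priority detector is masked before lower-priority detectors run,
#' so detector claims never overlap; a lower detector id therefore signals
#' higher confidence in the match.
#'
#' @param doc A `prx_document`.
#' @param config A [scan_config()].
#' @return A tibble of candidates with one row per detector match: columns
#'   `candidate_id`, `paper_id`, `node_id`, `section_type`, `section_title`,
#'   `detector`, `start`, `end` (span in the section text) and `tokens`
#'   (list column of token vectors).
#' @export
scan_document <- function(doc, config = scan_config()) {
  stopifnot(inherits(doc, "prx_document"))
  sections <- select_detector_sections(doc)
  per_section <- purrr::pmap(
    list(sections$node_id, sections$section_type, sections$section_title, sections$section_text),
    function(node_id, section_type, section_title, section_text) {
      if (is.na(section_text) || identical(section_text, "")) return(NULL)
      hits <- scan_section_text(section_text, config)
      if (nrow(hits) == 0L) return(NULL)
      tibble::tibble(
        paper_id = doc$paper_id,
        node_id = node_id,
        section_type = section_type,
        section_title = section_title,
        hits
      )
    }
  )
  out <- dplyr::bind_rows(per_section)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      paper_id = character(), node_id = integer(), section_type = character(),
      section_title = character(), detector = integer(), start = integer(),
      end = integer(), tokens = list()
    )
  }
  dplyr::mutate(out, candidate_id = dplyr::row_number(), .before = 1L)
}

#' Dump candidates as JSON lines
#'
#' One JSON object per candidate with the paper id, section provenance,
#' detector id, token list and character span.
#'
#' @param candidates Tibble from [scan_document()].
#' @param path Optional file to write to.
#' @return Character vector of JSON lines, invisibly when `path` is given.
#' @export
candidates_to_jsonl <- function(candidates, path = NULL) {
  lines <- purrr::pmap_chr(
    list(candidates$paper_id, candidates$node_id, candidates$detector,
         candidates$tokens, candidates$start, candidates$end),
    function(paper_id, node_id, detector, tokens, start, end) {
      jsonlite::toJSON(
        list(paper_id = paper_id, section_path = node_id, detector_id = detector,
             tokens = as.list(tokens), span = c(start, end)),
        auto_unbox = TRUE
      )
    }
  )
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
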