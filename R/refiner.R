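# Forward-chaining refinement of candidate token lists.
#
# Candidates straight from the detectors are noisy: prose words over the
# alphabet ("and", "standard"), dye labels printed next to probes
# ("TAMRA T"), and pairs of sequences merged across a linking word. A small
# rule base cleans them up:
#
#   R1  discard facts with fewer than l_min symbols in total
#   R2  strip a problem affix matched at the tail
#   R3  strip a problem affix matched at the head
#   R4  discard facts whose every token is a dictionary word
#   R5  split a fact around a problem affix matched strictly inside it
#   R6  drop a leading dictionary word of length >= 3
#   R7  drop a trailing dictionary word of length >= 3
#   R8  concatenate the remaining tokens into a single refined sequence
#
# Rules are tried in priority order R1 > ... > R8; within a rule, facts are
# tried in insertion order (FIFO), and facts produced by a firing are
# appended at the end. Facts refined by R8 are final and leave the active
# set, which (together with every other rule strictly shrinking the active
# token count) guarantees termination. Matching against the dictionary and
# the affix list is case-insensitive; sequence content is never re-cased.

#' Seed list of problem affixes
#'
#' Token sequences that contaminate or join recognized sequences: the TAMRA
#' dye label (with and without its linker base), the linking word "and", and
#' label colons as produced by the tokenizer (`F:`/`R:` primer labels). This
#' is a small curated seed list; extend or replace it via [refiner_config()]
#' or [read_affix_list()].
#'
#' @return A list of character vectors, each one affix (an ordered token
#'   sequence).
#' @export
seed_affixes <- function() {
  list(
    c("TAMRA"),
    c("TAMRA", "T"),
    c("and"),
    c(":"),
    c("R", ":"),
    c("F", ":")
  )
}

#' Seed dictionary of problem English words
#'
#' English words spelled entirely with alphabet symbols, which the generic
#' detector inevitably picks up from prose. A small curated seed list;
#' extend or replace it via [refiner_config()] or [read_dictionary()].
#' Deliberately excludes "DNA" and "RNA": those tokens are handled by the
#' length rule, not the dictionary rules.
#'
#' @return Character vector of words.
#' @export
seed_dictionary <- function() {
  c(
    "a", "abstract", "add", "and", "ant", "art", "as", "assay", "assays", "at", "band",
    "bands", "bad", "bat", "brand", "brands", "by", "can", "cash", "catch",
    "data", "dark", "day", "days", "draw", "dry", "gas", "grab", "gram",
    "grams", "grand", "grant", "grants", "gray", "had", "hand", "hands",
    "has", "man", "many", "mass", "match", "may", "sand", "say", "smart",
    "standard", "standards", "start", "starts", "stay", "strand", "strands",
    "than", "that", "thaw", "want", "wants", "was", "wash", "way", "ways"
  )
}

#' Refiner configuration
#'
#' @param l_min Minimum total number of symbols (characters over all tokens)
#'   a fact must keep to survive rule R1. Default 7, the shortest query
#'   length for which a sequence-similarity lookup still returns results;
#'   a 7-symbol sequence survives (the rule discards strictly shorter facts).
#' @param affixes List of problem affixes, each an ordered character vector
#'   of tokens. Matching is case-insensitive.
#' @param dictionary Character vector of problem words over the alphabet.
#'   Matching is case-insensitive.
#' @return A list of class `prx_refiner_config`.
#' @export
refiner_config <- function(l_min = 7L, affixes = seed_affixes(), dictionary = seed_dictionary()) {
  stopifnot(is.numeric(l_min), length(l_min) == 1L, l_min >= 1)
  if (!is.list(affixes) || length(affixes) == 0L ||
      !all(vapply(affixes, function(a) is.character(a) && length(a) >= 1L && all(nchar(a) > 0L), logical(1L)))) {
    rlang::abort("`affixes` must be a non-empty list of non-empty character vectors.",
                 class = "prx_config_error")
  }
  if (!is.character(dictionary) || !all(is_sigma_plus(dictionary))) {
    rlang::abort("`dictionary` must contain only words over the 30-symbol alphabet.",
                 class = "prx_config_error")
  }
  structure(
    list(l_min = as.integer(l_min), affixes = affixes,
         dictionary = dictionary, dictionary_lower = tolower(dictionary)),
    class = "prx_refiner_config"
  )
}

#' Read a problem-word dictionary from file
#'
#' One word per line; blank lines and lines starting with `#` are skipped.
#'
#' @param path File path.
#' @return Character vector of words.
#' @export
read_dictionary <- function(path) {
  lines <- readr::read_lines(path)
  lines <- stringr::str_trim(lines)
  lines[lines != "" & !stringr::str_starts(lines, "#")]
}

#' Read a problem-affix list from file
#'
#' One affix per line, tokens separated by whitespace.
#'
#' @param path File path.
#' @return List of character vectors.
#' @export
read_affix_list <- function(path) {
  lines <- read_dictionary(path)
  lapply(stringr::str_split(lines, "\\s+"), function(x) x[x != ""])
}

#' Match a problem affix at the tail of a token sequence
#'
#' Tries every affix against a suffix of `s`. Among matches, the longest (in
#' tokens) wins, ties going to the match starting earlier in the sequence;
#' for tail matches equal length implies equal position, so the tie rule is
#' vacuous here.
#'
#' @param s Character vector of tokens.
#' @param affixes List of affixes (character vectors). Case-insensitive.
#' @return 1-based position of the first token of the matched affix, or
#'   `NA_integer_` if no affix matches.
#' @export
#' @examples
#' affix_in_sequence_tail(c("TTACTCATGCCATACATAAATGGATA", "TAMRA", "T"), seed_affixes())
affix_in_sequence_tail <- function(s, affixes) {
  n <- length(s)
  sl <- tolower(s)
  best <- 0L
  for (a in affixes) {
    k <- length(a)
    if (k <= n && k > best && identical(sl[(n - k + 1L):n], tolower(a))) best <- k
  }
  if (best == 0L) NA_integer_ else n - best + 1L
}

#' Match a problem affix at the head of a token sequence
#'
#' Symmetric to [affix_in_sequence_tail()]: tries every affix against a
#' prefix of `s` and returns the 1-based position of the *last* token of the
#' longest match.
#'
#' @inheritParams affix_in_sequence_tail
#' @return 1-based position of the last token of the matched affix, or
#'   `NA_integer_`.
#' @export
#' @examples
#' affix_in_sequence_head(c("and", "CTAGTTT", "ACGTAGGGT"), seed_affixes())
affix_in_sequence_head <- function(s, affixes) {
  n <- length(s)
  sl <- tolower(s)
  best <- 0L
  for (a in affixes) {
    k <- length(a)
    if (k <= n && k > best && identical(sl[1L:k], tolower(a))) best <- k
  }
  if (best == 0L) NA_integer_ else best
}

#' Match a problem affix strictly inside a token sequence
#'
#' Tries every affix against interior subsequences of `s` -- matches must
#' exclude both the head and the tail token. The longest match wins; ties of
#' equal length go to the match occurring first.
#'
#' @inheritParams affix_in_sequence_tail
#' @return Integer vector `c(position, size)` (1-based position of the first
#'   matched token, number of tokens matched), or `NULL` if no interior
#'   match exists.
#' @export
#' @examples
#' affix_within_sequence(c("ACGTTTACGT", "TAMRA", "and", "CGATGGGA"), seed_affixes())
affix_within_sequence <- function(s, affixes) {
  n <- length(s)
  if (n < 3L) return(NULL)
  sl <- tolower(s)
  best_k <- 0L
  best_i <- NA_integer_
  for (a in affixes) {
    k <- length(a)
    if (k > n - 2L) next
    al <- tolower(a)
    for (i in 2L:(n - k)) {
      if (identical(sl[i:(i + k - 1L)], al)) {
        # longest match wins; equal lengths go to the earliest position
        if (k > best_k || (k == best_k && i < best_i)) {
          best_k <- k
          best_i <- i
        }
        break # later occurrences of this affix cannot improve
      }
    }
  }
  if (best_k == 0L) NULL else c(position = best_i, size = best_k)
}

#' Dictionary membership
#'
#' Case-insensitive membership of a token in the problem-word dictionary.
#'
#' @param token A token (or vector of tokens).
#' @param config A [refiner_config()] (or a plain character dictionary).
#' @return Logical vector.
#' @export
in_dictionary <- function(token, config = refiner_config()) {
  dict <- if (inherits(config, "prx_refiner_config")) config$dictionary_lower else tolower(config)
  tolower(token) %in% dict
}

new_fact <- function(id, root, tokens, origin_start) {
  list(id = id, root = root, tokens = tokens, origin_start = origin_start,
       status = "active")
}

#' Fire the single highest-priority applicable rule
#'
#' Evaluates rules R1..R8 in priority order against the active facts in
#' insertion order and applies the first applicable (rule, fact) pair. Facts
#' produced by a firing are appended to the facts base; facts emptied by
#' affix or word stripping are discarded silently.
#'
#' @param facts A facts base: list of facts as built by [refine()]; each
#'   fact is a list with `tokens`, `status`, `root`, `origin_start`.
#' @param config A [refiner_config()].
#' @return A list with `rule` (e.g. `"R2"`, or `NULL` when no rule applies),
#'   `fact` (index of the fact the rule fired on), and `facts` (updated
#'   facts base).
#' @export
fire_one <- function(facts, config = refiner_config()) {
  active <- which(vapply(facts, function(f) f$status == "active", logical(1L)))

  push <- function(facts, root, tokens, origin_start) {
    if (length(tokens) == 0L) return(facts) # emptied facts are dropped silently
    facts[[length(facts) + 1L]] <- new_fact(length(facts) + 1L, root, tokens, origin_start)
    facts
  }
  done <- function(rule, fi, facts) list(rule = rule, fact = fi, facts = facts)

  for (fi in active) { # R1
    f <- facts[[fi]]
    if (sum(nchar(f$tokens)) < config$l_min) {
      facts[[fi]]$status <- "discarded"
      return(done("R1", fi, facts))
    }
  }
  for (fi in active) { # R2
    f <- facts[[fi]]
    i <- affix_in_sequence_tail(f$tokens, config$affixes)
    if (!is.na(i)) {
      facts[[fi]]$status <- "discarded"
      facts <- push(facts, f$root, f$tokens[seq_len(i - 1L)], f$origin_start)
      return(done("R2", fi, facts))
    }
  }
  for (fi in active) { # R3
    f <- facts[[fi]]
    i <- affix_in_sequence_head(f$tokens, config$affixes)
    if (!is.na(i)) {
      n <- length(f$tokens)
      facts[[fi]]$status <- "discarded"
      keep <- if (i < n) (i + 1L):n else integer(0)
      facts <- push(facts, f$root, f$tokens[keep], f$origin_start + i)
      return(done("R3", fi, facts))
    }
  }
  for (fi in active) { # R4
    f <- facts[[fi]]
    if (all(in_dictionary(f$tokens, config))) {
      facts[[fi]]$status <- "discarded"
      return(done("R4", fi, facts))
    }
  }
  for (fi in active) { # R5
    f <- facts[[fi]]
    hit <- affix_within_sequence(f$tokens, config$affixes)
    if (!is.null(hit)) {
      i <- hit[["position"]]; k <- hit[["size"]]; n <- length(f$tokens)
      facts[[fi]]$status <- "discarded"
      facts <- push(facts, f$root, f$tokens[seq_len(i - 1L)], f$origin_start)
      facts <- push(facts, f$root, f$tokens[(i + k):n], f$origin_start + i + k - 1L)
      return(done("R5", fi, facts))
    }
  }
  for (fi in active) { # R6
    f <- facts[[fi]]
    if (in_dictionary(f$tokens[1L], config) && nchar(f$tokens[1L]) >= 3L) {
      n <- length(f$tokens)
      facts[[fi]]$status <- "discarded"
      keep <- if (n > 1L) 2L:n else integer(0)
      facts <- push(facts, f$root, f$tokens[keep], f$origin_start + 1L)
      return(done("R6", fi, facts))
    }
  }
  for (fi in active) { # R7
    f <- facts[[fi]]
    n <- length(f$tokens)
    if (in_dictionary(f$tokens[n], config) && nchar(f$tokens[n]) >= 3L) {
      facts[[fi]]$status <- "discarded"
      facts <- push(facts, f$root, f$tokens[seq_len(n - 1L)], f$origin_start)
      return(done("R7", fi, facts))
    }
  }
  for (fi in active) { # R8
    f <- facts[[fi]]
    if (length(f$tokens) >= 2L) {
      facts[[fi]]$tokens <- paste(f$tokens, collapse = "")
      facts[[fi]]$status <- "refined"
      return(done("R8", fi, facts))
    }
  }
  list(rule = NULL, fact = NA_integer_, facts = facts)
}

#' Refine a single candidate token list
#'
#' Runs the rule engine to fixpoint on one token list. Convenience wrapper
#' used for tracing individual refinements; [refine()] is the tibble-first
#' interface.
#'
#' @param tokens Character vector of tokens.
#' @param config A [refiner_config()].
#' @return A list with `sequences` (character vector of surviving sequences,
#'   ordered by their position in the input) and `trace` (character vector
#'   of fired rule ids, in firing order).
#' @export
#' @examples
#' refine_tokens(c("CATATTCACCTTTTCAGGCGTTTTGACCGT", "TAMRA", "T"))
refine_tokens <- function(tokens, config = refiner_config()) {
  res <- refine_engine(list(tokens), config)
  list(sequences = res$survivors$sequence, trace = res$log$rule)
}

# core engine: token_lists is a list of character vectors (one per root)
refine_engine <- function(token_lists, config) {
  facts <- purrr::imap(token_lists, function(tokens, i) new_fact(i, i, tokens, 1L))
  log_rule <- character(0)
  log_root <- integer(0)
  max_firings <- sum(lengths(token_lists)) + 1L
  repeat {
    step <- fire_one(facts, config)
    if (is.null(step$rule)) break
    log_rule <- c(log_rule, step$rule)
    log_root <- c(log_root, facts[[step$fact]]$root)
    facts <- step$facts
    if (length(log_rule) > max_firings) {
      rlang::abort("rule engine exceeded its termination bound; this is a bug.",
                   class = "prx_internal_error")
    }
  }
  keep <- vapply(facts, function(f) f$status != "discarded", logical(1L))
  survivors <- facts[keep]
  survivors_tbl <- tibble::tibble(
    root = vapply(survivors, function(f) f$root, integer(1L)),
    origin_start = vapply(survivors, function(f) f$origin_start, integer(1L)),
    sequence = vapply(survivors, function(f) paste(f$tokens, collapse = ""), character(1L)),
    status = vapply(survivors, function(f) f$status, character(1L))
  )
  survivors_tbl <- dplyr::arrange(survivors_tbl, .data$root, .data$origin_start)
  list(
    survivors = survivors_tbl,
    log = tibble::tibble(step = seq_along(log_rule), root = log_root, rule = log_rule)
  )
}

#' Refine detected candidates into final sequences
#'
#' Adds every candidate token list to the facts base and runs the
#' forward-chaining rule engine to fixpoint. At the fixpoint every surviving
#' fact is a single string over the alphabet with at least `l_min` symbols.
#' Output is deterministic for a fixed input and configuration.
#'
#' @param candidates Tibble from [scan_document()] (any tibble with a
#'   `tokens` list column works; provenance columns `candidate_id`,
#'   `paper_id`, `node_id`, `section_type`, `detector` are carried through
#'   when present).
#' @param config A [refiner_config()].
#' @return An object of class `prx_refinement`: a list with
#'   * `sequences`: tibble of surviving sequences with their source
#'     candidate's provenance, ordered by candidate and position;
#'   * `trace`: tibble of fired rules (`step`, `candidate`, `rule`) in
#'     firing order.
#' @export
refine <- function(candidates, config = refiner_config()) {
  stopifnot(is.data.frame(candidates), "tokens" %in% names(candidates))
  res <- refine_engine(candidates$tokens, config)
  prov_cols <- intersect(
    c("candidate_id", "paper_id", "node_id", "section_type", "section_title", "detector"),
    names(candidates)
  )
  seqs <- dplyr::bind_cols(
    candidates[res$survivors$root, prov_cols, drop = FALSE],
    res$survivors[, c("sequence", "origin_start")]
  )
  seqs <- tibble::as_tibble(seqs)
  trace <- res$log
  if ("candidate_id" %in% names(candidates)) {
    trace$candidate <- candidates$candidate_id[trace$root]
  } else {
    trace$candidate <- trace$root
  }
  structure(
    list(
      sequences = seqs[, setdiff(names(seqs), "origin_start"), drop = FALSE],
      trace = trace[, c("step", "candidate", "rule")],
      n_candidates = nrow(candidates),
      config = config
    ),
    class = "prx_refinement"
  )
}

#' @export
print.prx_refinement <- function(x, ...) {
  cat("<prx_refinement> ", x$n_candidates, " candidates -> ",
      nrow(x$sequences), " sequences (", nrow(x$trace), " rule firings)\n", sep = "")
  print(x$sequences, ...)
  invisible(x)
}
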