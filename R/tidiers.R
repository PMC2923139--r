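# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a refinement result
#'
#' @param x A `prx_refinement`.
#' @param ... Unused.
#' @return The tibble of surviving sequences with provenance.
#' @export
tidy.prx_refinement <- function(x, ...) {
  x$sequences
}

#' One-row summary of a refinement
#'
#' @param x A `prx_refinement`.
#' @param ... Unused.
#' @return Tibble with `n_candidates`, `n_rules_fired`, `n_sequences`.
#' @export
glance.prx_refinement <- function(x, ...) {
  tibble::tibble(
    n_candidates = x$n_candidates,
    n_rules_fired = nrow(x$trace),
    n_sequences = nrow(x$sequences)
  )
}

#' Tidy a pipeline run
#'
#' @param x A `prx_run`.
#' @param ... Unused.
#' @return The sequence tibble, joined with annotations when present.
#' @export
tidy.prx_run <- function(x, ...) {
  if (is.null(x$annotations)) return(x$sequences)
  dplyr::left_join(
    x$sequences,
    dplyr::rename(x$annotations, paper_id = "paper"),
    by = c("paper_id", "sequence")
  )
}

#' One-row summary of a pipeline run
#'
#' @param x A `prx_run`.
#' @param ... Unused.
#' @return Tibble of total documents, candidates, sequences, annotations and
#'   failures.
#' @export
glance.prx_run <- function(x, ...) {
  tibble::tibble(
    n_documents = nrow(x$counts),
    n_candidates = sum(x$counts$candidates),
    n_sequences = nrow(x$sequences),
    n_annotated = if (is.null(x$annotations)) 0L else sum(!is.na(x$annotations$organism_name)),
    n_failures = nrow(x$errors)
  )
}

#' Tidy a detection evaluation
#'
#' @param x A `prx_detection_eval`.
#' @param ... Unused.
#' @return Long tibble with `metric` and `value` columns.
#' @export
tidy.prx_detection_eval <- function(x, ...) {
  tidyr::pivot_longer(
    tibble::as_tibble(x),
    cols = dplyr::everything(),
    names_to = "metric", values_to = "value"
  )
}

#' One-row summary of a detection evaluation
#'
#' @param x A `prx_detection_eval`.
#' @param ... Unused.
#' @return The evaluation row as a plain tibble.
#' @export
glance.prx_detection_eval <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Tidy a fixture
#'
#' @param x A `prx_fixture`.
#' @param ... Unused.
#' @return The manifest tibble of planted sequences.
#' @export
tidy.prx_fixture <- function(x, ...) {
  x$manifest
}

#' One-row summary of a fixture
#'
#' @param x A `prx_fixture`.
#' @param ... Unused.
#' @return Tibble of document/sequence counts per pattern.
#' @export
glance.prx_fixture <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_documents = nrow(x$documents), n_sequences = nrow(x$manifest)),
    tidyr::pivot_wider(
      dplyr::count(x$manifest, .data$pattern),
      names_from = "pattern", values_from = "n", names_prefix = "n_"
    )
  )
}
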