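# Information-extraction evaluation.

new_detection_eval <- function(tp, fp, fn, precision, recall, f_measure) {
  out <- tibble::tibble(tp = tp, fp = fp, fn = fn,
                        precision = precision, recall = recall, f_measure = f_measure)
  class(out) <- c("prx_detection_eval", class(out))
  out
}

#' Detection metrics from raw counts
#'
#' Precision `tp / (tp + fp)` and recall `tp / (tp + fn)` as percentages,
#' and F-measure `2PR / (P + R)` as a fraction.
#'
#' @param tp,fp,fn Non-negative counts of true positives, false positives
#'   and false negatives.
#' @return A one-row tibble of class `prx_detection_eval` with columns `tp`,
#'   `fp`, `fn`, `precision` (%), `recall` (%), `f_measure`.
#' @export
#' @examples
#' detection_metrics(tp = 3830, fp = 79, fn = 169)
detection_metrics <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fp == 0) {
    rlang::warn("no predictions: precision is undefined and reported as 0.",
                class = "prx_eval_warning")
    p <- 0
  } else {
    p <- tp / (tp + fp)
  }
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  new_detection_eval(tp, fp, fn, 100 * p, 100 * r, f)
}

#' Evaluate detected sequences against a gold standard
#'
#' Sequences are matched by exact string (case-sensitive) within a paper:
#' the scoring key is the pair (`paper_id`, `sequence`), so repeated
#' occurrences inside one paper count once and prediction order is
#' irrelevant.
#'
#' @param predicted,gold Data frames with columns `paper_id` and `sequence`.
#' @return A one-row tibble of class `prx_detection_eval` (see
#'   [detection_metrics()]).
#' @export
evaluate_detection <- function(predicted, gold) {
  stopifnot(all(c("paper_id", "sequence") %in% names(predicted)),
            all(c("paper_id", "sequence") %in% names(gold)))
  pred_keys <- dplyr::distinct(tibble::as_tibble(predicted)[, c("paper_id", "sequence")])
  gold_keys <- dplyr::distinct(tibble::as_tibble(gold)[, c("paper_id", "sequence")])
  tp <- nrow(dplyr::inner_join(pred_keys, gold_keys, by = c("paper_id", "sequence")))
  fp <- nrow(pred_keys) - tp
  fn <- nrow(gold_keys) - tp
  detection_metrics(tp, fp, fn)
}

#' Annotation rate
#'
#' Share of correctly annotated sequences, as a percentage.
#'
#' @param n_correct,n_total Counts; `n_total > 0`.
#' @return `100 * n_correct / n_total`.
#' @export
#' @examples
#' annotation_rate(2936, 3830)
annotation_rate <- function(n_correct, n_total) {
  stopifnot(n_total > 0, n_correct >= 0, n_correct <= n_total)
  100 * n_correct / n_total
}

#' Evaluate annotation records against gold labels
#'
#' Joins on (`paper`, `sequence`); an organism annotation is correct when it
#' equals the gold organism name (case-insensitive); gene annotations are
#' assessed among the sequences whose organism was correct.
#'
#' @param records Annotation tibble from [annotate()] (columns `paper`,
#'   `sequence`, `organism_name`, `gene_name`).
#' @param gold Tibble with columns `paper`, `sequence`, `organism_name`,
#'   `gene_name` (use the fixture manifest via [fixture_gold()]).
#' @return One-row tibble: `n_sequences`, `n_organism_correct`,
#'   `organism_rate` (%), `n_gene_eligible`, `n_gene_correct`, `gene_rate`
#'   (% of organism-correct sequences; `NA` when none).
#' @export
evaluate_annotation <- function(records, gold) {
  stopifnot(all(c("paper", "sequence", "organism_name") %in% names(records)),
            all(c("paper", "sequence", "organism_name") %in% names(gold)))
  joined <- dplyr::inner_join(
    tibble::as_tibble(records),
    dplyr::distinct(tibble::as_tibble(gold)[, intersect(c("paper", "sequence", "organism_name", "gene_name"), names(gold))]),
    by = c("paper", "sequence"), suffix = c("", "_gold")
  )
  org_ok <- !is.na(joined$organism_name) &
    tolower(joined$organism_name) == tolower(joined$organism_name_gold)
  n <- nrow(joined)
  n_org <- sum(org_ok)
  gene_ok <- logical(0)
  if ("gene_name_gold" %in% names(joined)) {
    eligible <- joined[org_ok, , drop = FALSE]
    gene_ok <- !is.na(eligible$gene_name) &
      tolower(eligible$gene_name) == tolower(eligible$gene_name_gold)
  }
  tibble::tibble(
    n_sequences = n,
    n_organism_correct = n_org,
    organism_rate = if (n > 0) annotation_rate(n_org, n) else NA_real_,
    n_gene_eligible = n_org,
    n_gene_correct = sum(gene_ok),
    gene_rate = if (n_org > 0) annotation_rate(sum(gene_ok), n_org) else NA_real_
  )
}
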