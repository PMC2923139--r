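# Independent brute-force oracles and small generators shared across tests.

# enumerate every (affix, offset) pair and apply the stated selection rule:
# longest match wins, ties of equal length to the earliest position
brute_matches <- function(s, affixes) {
  n <- length(s)
  sl <- tolower(s)
  out <- list()
  for (a in affixes) {
    k <- length(a)
    if (k > n) next
    al <- tolower(a)
    for (i in seq_len(n - k + 1L)) {
      if (identical(sl[i:(i + k - 1L)], al)) {
        out[[length(out) + 1L]] <- c(i = i, k = k)
      }
    }
  }
  out
}

pick_best <- function(matches) {
  if (length(matches) == 0L) return(NULL)
  ks <- vapply(matches, `[[`, numeric(1), "k")
  is <- vapply(matches, `[[`, numeric(1), "i")
  keep <- which(ks == max(ks))
  matches[[keep[which.min(is[keep])]]]
}

oracle_tail <- function(s, affixes) {
  n <- length(s)
  m <- Filter(function(x) x[["i"]] + x[["k"]] - 1L == n, brute_matches(s, affixes))
  best <- pick_best(m)
  if (is.null(best)) NA_integer_ else as.integer(best[["i"]])
}

oracle_head <- function(s, affixes) {
  m <- Filter(function(x) x[["i"]] == 1L, brute_matches(s, affixes))
  best <- pick_best(m)
  if (is.null(best)) NA_integer_ else as.integer(best[["k"]])
}

oracle_within <- function(s, affixes) {
  n <- length(s)
  m <- Filter(function(x) x[["i"]] >= 2L && x[["i"]] + x[["k"]] - 1L <= n - 1L,
              brute_matches(s, affixes))
  best <- pick_best(m)
  if (is.null(best)) NULL else c(position = as.integer(best[["i"]]), size = as.integer(best[["k"]]))
}

# random token lists mixing sequence runs, affix tokens, dictionary words and colons
random_tokens <- function(n) {
  pool <- c("TAMRA", "T", "and", ":", "standard", "was", "RNA", "DNA",
            "ACGTACG", "TTGACCGTAA", "gattaca", "CCMARRGG", "AT")
  sample(pool, n, replace = TRUE)
}

random_sigma_string <- function(len) {
  paste(sample(primerminer::sigma_symbols(), len, replace = TRUE), collapse = "")
}

# minimal JATS article builder
make_jats <- function(body_secs = "", abstract = NULL, tables = "", figures = "",
                      title = "A study", authors = TRUE, back = TRUE) {
  paste0(
    "<article><front><article-meta>",
    "<title-group><article-title>", title, "</article-title></title-group>",
    if (authors) paste0("<contrib-group><contrib><name><surname>Doe</surname>",
                        "<given-names>J.</given-names></name></contrib></contrib-group>"),
    if (!is.null(abstract)) paste0("<abstract>", abstract, "</abstract>"),
    "</article-meta></front><body>",
    paste(body_secs, collapse = ""), tables, figures,
    "</body>",
    if (back) paste0("<back><ack><p>Thanks.</p></ack>",
                     "<ref-list><title>References</title>",
                     "<ref><mixed-citation>One citation.</mixed-citation></ref></ref-list></back>"),
    "</article>"
  )
}

sec <- function(title, text, inner = "") {
  paste0("<sec><title>", title, "</title><p>", text, "</p>", inner, "</sec>")
}

table_wrap <- function(rows, label = "Table 1", caption = "Primers") {
  cells <- vapply(rows, function(r) {
    paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>")
  }, character(1))
  paste0("<table-wrap><label>", label, "</label><caption><p>", caption,
         "</p></caption><table><tbody>", paste(cells, collapse = ""),
         "</tbody></table></table-wrap>")
}

# the organism-scoring worked example: a two-section document where
# "Brucella" and "Brucella Mellitensis" occur in the background and
# "B. Mellitensis" co-occurs with the sequence in the methods section
worked_example_doc <- function(sequence = "TGCCATTGCCAAAGAGAC") {
  xml <- make_jats(body_secs = c(
    sec("Background",
        "Brucella infections are studied here. Brucella Mellitensis strains were typed."),
    sec("Methods",
        paste0("Primers for B. Mellitensis were (5'-", sequence, "-3') in all assays."))
  ))
  parse_jats(xml, paper_id = "worked-example")
}
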