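test_that("organism name variants are prefixes plus genus-abbreviated forms", {
  v <- generate_variants("Brucella Mellitensis 16M")
  expect_setequal(
    paste(v$variant, v$l),
    c("Brucella 1", "Brucella Mellitensis 2", "Brucella Mellitensis 16M 3",
      "B. Mellitensis 2", "B. Mellitensis 16M 3")
  )
  v1 <- generate_variants("Brucella")
  expect_identical(v1$variant, "Brucella")
  expect_identical(v1$l, 1L)

  v2 <- generate_variants("Escherichia coli")
  expect_setequal(paste(v2$variant, v2$l),
                  c("Escherichia 1", "Escherichia coli 2", "E. coli 2"))

  expect_error(generate_variants("  "), class = "prx_domain_error")
})

test_that("variant matching reports the longest match and section co-occurrence", {
  doc <- worked_example_doc()
  methods_id <- doc$nodes$node_id[doc$nodes$section_title %in% "Methods"]
  v <- generate_variants("Brucella Mellitensis 16M")

  m <- match_organism(doc, v, node_id = methods_id)
  expect_identical(m$L, 3L)
  expect_identical(m$l, 2L) # full 3-word name is absent from the document
  expect_true(m$cooccurs)   # "B. Mellitensis" sits in the methods section
  expect_setequal(m$matched_variants[[1]],
                  c("Brucella", "Brucella Mellitensis", "B. Mellitensis"))

  # same matches, but the sequence in the background section: the longest
  # matches there are length 2 as well, via "Brucella Mellitensis"
  bg_id <- doc$nodes$node_id[doc$nodes$section_title %in% "Background"]
  m2 <- match_organism(doc, v, node_id = bg_id)
  expect_true(m2$cooccurs)

  # no variant present at all
  m3 <- match_organism(doc, generate_variants("Vibrio cholerae"), methods_id)
  expect_identical(m3$l, 0L)
  expect_false(m3$cooccurs)

  # matching is whole-word: "Brucellaceae" must not count as "Brucella"
  doc2 <- suppressWarnings(parse_plain_text("The family Brucellaceae was studied.", "ww"))
  m4 <- match_organism(doc2, generate_variants("Brucella"), NA_integer_)
  expect_identical(m4$l, 0L)
})

test_that("organism confidence is anchored, monotone and capped", {
  expect_identical(organism_confidence(3, 2, FALSE), 70)
  expect_identical(organism_confidence(3, 2, TRUE), 90)
  expect_identical(organism_confidence(3, 3, TRUE), 100) # capped at 100
  expect_identical(organism_confidence(1, 1, FALSE), 100)
  expect_identical(organism_confidence(5, 0, TRUE), 0)   # no match, no score

  for (L in 2:10) {
    scores <- organism_confidence(rep(L, L), 1:L)
    expect_true(all(diff(scores) >= 0))
    expect_true(all(scores >= 0 & scores <= 100))
    expect_identical(scores[L], 100)
    expect_identical(scores[1], 40)
    with_bonus <- organism_confidence(rep(L, L), 1:L, TRUE)
    expect_true(all(with_bonus <= 100))
  }
  expect_error(organism_confidence(3, 4), class = "prx_domain_error")
  expect_error(organism_confidence(0, 0), class = "prx_domain_error")
})

test_that("gene confidence takes the three documented values", {
  expect_identical(gene_confidence(FALSE, FALSE), 0)
  expect_identical(gene_confidence(TRUE, FALSE), 80)
  expect_identical(gene_confidence(TRUE, TRUE), 100)
  expect_error(gene_confidence(FALSE, TRUE), class = "prx_domain_error")
})

test_that("annotate_sequence picks the best-scoring hit and gene", {
  doc <- worked_example_doc()
  methods_id <- doc$nodes$node_id[doc$nodes$section_title %in% "Methods"]
  seqs <- "TGCCATTGCCAAAGAGAC"

  # worked example: one hit, no genes -> organism scored 90, gene absent
  be <- lookup_backend(tibble::tibble(
    sequence = seqs, identifier = "GI0000001", organism_name = "Brucella Mellitensis 16M"
  ))
  rec <- annotate_sequence(seqs, doc, be, node_id = methods_id)
  expect_identical(rec$organism_name, "Brucella Mellitensis 16M")
  expect_identical(rec$organism_cs, 90)
  expect_true(is.na(rec$gene_name))
  expect_identical(rec$gene_cs, 0)

  # two hits: the document-supported organism wins over an unsupported one
  be2 <- lookup_backend(tibble::tibble(
    sequence = seqs, rank = 1:2, identifier = c("GI1", "GI2"),
    organism_name = c("Vibrio cholerae", "Brucella Mellitensis 16M")
  ))
  rec2 <- annotate_sequence(seqs, doc, be2, node_id = methods_id)
  expect_identical(rec2$organism_name, "Brucella Mellitensis 16M")

  # ties go to the earlier hit
  be3 <- lookup_backend(tibble::tibble(
    sequence = seqs, rank = 1:2, identifier = c("GI1", "GI2"),
    organism_name = c("Vibrio cholerae", "Yersinia pestis")
  ))
  rec3 <- annotate_sequence(seqs, doc, be3, node_id = methods_id)
  expect_identical(rec3$organism_name, "Vibrio cholerae")
  expect_identical(rec3$organism_cs, 0)

  # empty hit list -> unannotated record
  rec4 <- annotate_sequence("AAAAACCCCC", doc, be, node_id = methods_id)
  expect_true(is.na(rec4$organism_name))
  expect_identical(rec4$organism_cs, 0)
  expect_identical(rec4$n_hits, 0L)
})

test_that("only the top ten hits are consulted", {
  doc <- worked_example_doc()
  methods_id <- doc$nodes$node_id[doc$nodes$section_title %in% "Methods"]
  s <- "TGCCATTGCCAAAGAGAC"
  # hit 11 is the only one the document supports; it must be ignored
  hits <- tibble::tibble(
    sequence = s, rank = 1:11,
    identifier = sprintf("GI%02d", 1:11),
    organism_name = c(rep("Vibrio cholerae", 10), "Brucella Mellitensis 16M")
  )
  rec <- annotate_sequence(s, doc, lookup_backend(hits), node_id = methods_id)
  expect_identical(rec$organism_name, "Vibrio cholerae")
  expect_identical(rec$organism_cs, 0)
})

test_that("gene scores reflect where the gene name occurs", {
  xml <- make_jats(body_secs = c(
    sec("Methods", "The primer (5'-TGCCATTGCCAAAGAGAC-3') amplifies B. Mellitensis."),
    sec("Results", "Strong omp31 signals were seen.")
  ))
  doc <- parse_jats(xml, "genes")
  methods_id <- doc$nodes$node_id[doc$nodes$section_title %in% "Methods"]
  mk_backend <- function(genes) lookup_backend(tibble::tibble(
    sequence = "TGCCATTGCCAAAGAGAC", identifier = "GI1",
    organism_name = "Brucella Mellitensis 16M", gene_names = genes
  ))
  # appears in another section only
  rec <- annotate_sequence("TGCCATTGCCAAAGAGAC", doc, mk_backend("omp31"), methods_id)
  expect_identical(rec$gene_name, "omp31")
  expect_identical(rec$gene_cs, 80)
  # absent from the text
  rec2 <- annotate_sequence("TGCCATTGCCAAAGAGAC", doc, mk_backend("bcsp31"), methods_id)
  expect_identical(rec2$gene_cs, 0)
  # the better-supported gene among several wins
  rec3 <- annotate_sequence("TGCCATTGCCAAAGAGAC", doc, mk_backend("bcsp31;omp31"), methods_id)
  expect_identical(rec3$gene_name, "omp31")
  expect_identical(rec3$gene_cs, 80)
})

test_that("a failing backend warns and the batch continues", {
  doc <- worked_example_doc()
  flaky <- function(sequence) {
    if (sequence == "AAAAAAAA") stop("backend down")
    tibble::tibble(sequence = sequence, identifier = "GI1",
                   organism_name = "Brucella Mellitensis 16M",
                   gene_names = list(character(0)), rank = 1L)
  }
  tbl <- tibble::tibble(sequence = c("AAAAAAAA", "TGCCATTGCCAAAGAGAC"),
                        node_id = rep(doc$nodes$node_id[doc$nodes$section_title %in% "Methods"], 2))
  expect_warning(res <- annotate(tbl, doc, flaky), class = "prx_annotation_error")
  expect_identical(nrow(res), 2L)
  expect_true(is.na(res$organism_name[1]))
  expect_identical(res$organism_name[2], "Brucella Mellitensis 16M")
})

test_that("lookup fixtures round-trip through TSV", {
  hits <- tibble::tibble(
    sequence = c("ACGTACGT", "ACGTACGT"), rank = 1:2,
    identifier = c("GI1", "GI2"),
    organism_name = c("Brucella melitensis 16M", "Vibrio cholerae"),
    gene_names = c("bcsp31;omp31", "")
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lookup_tsv(hits, path)
  backend <- read_lookup_tsv(path)
  res <- backend("ACGTACGT")
  expect_identical(nrow(res), 2L)
  expect_identical(res$gene_names[[1]], c("bcsp31", "omp31"))
  expect_identical(res$gene_names[[2]], character(0))
  expect_identical(backend("TTTT")$sequence, character(0))
})
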