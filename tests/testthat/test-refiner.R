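test_that("affix matching at tail, head and interior follows the stated selection", {
  la <- seed_affixes()
  expect_identical(affix_in_sequence_tail(c("TTACTCATGCCATACATAAATGGATA", "TAMRA", "T"), la), 2L)
  expect_identical(affix_in_sequence_tail(c("ACGTACGT"), la), NA_integer_)
  # longest tail match wins over a shorter one further right
  la2 <- list(c("T"), c("TAMRA", "T"))
  expect_identical(affix_in_sequence_tail(c("ACGTACGTAC", "TAMRA", "T"), la2), 2L)

  expect_identical(affix_in_sequence_head(c("and", "CTAGTTT", "ACGTAGGGT"), la), 1L)
  expect_identical(affix_in_sequence_head(c("CTAGTTT", "and"), la), NA_integer_)
  la3 <- list(c(":"), c(":", ":"))
  expect_identical(affix_in_sequence_head(c(":", ":", "SEQSYMB"), la3), 2L)

  expect_identical(affix_within_sequence(c("ACGTTTACGT", "TAMRA", "and", "CGATGGGA"), la),
                   c(position = 2L, size = 1L))
  # head-only occurrences are not interior matches
  expect_null(affix_within_sequence(c("and", "ACGTACG", "TGCATGC"), la))
  # the longer interior match beats an earlier shorter one
  s <- c("AAAAAAA", "and", "CCCCCCC", "GGGGGGG", "TAMRA", "T", "TTTTTTT")
  expect_identical(affix_within_sequence(s, la), c(position = 5L, size = 2L))
})

test_that("affix functions agree with brute-force enumeration on random inputs", {
  withr::local_seed(55)
  la <- seed_affixes()
  for (i in 1:200) {
    s <- random_tokens(sample(1:9, 1))
    expect_identical(affix_in_sequence_tail(s, la), oracle_tail(s, la))
    expect_identical(affix_in_sequence_head(s, la), oracle_head(s, la))
    expect_identical(affix_within_sequence(s, la), oracle_within(s, la))
  }
})

test_that("dictionary membership is case-insensitive and excludes nucleic-acid tokens", {
  cfg <- refiner_config()
  expect_true(in_dictionary("standard", cfg))
  expect_true(in_dictionary("STANDARD", cfg))
  expect_false(in_dictionary("TGCCATTGCCAAAGAGAC", cfg))
  expect_false(in_dictionary("RNA", cfg))
  expect_false(in_dictionary("DNA", cfg))
})

test_that("single rule firings behave as specified", {
  cfg <- refiner_config()
  facts <- list(list(id = 1L, root = 1L, tokens = "DNA", origin_start = 1L, status = "active"))
  step <- fire_one(facts, cfg)
  expect_identical(step$rule, "R1")
  expect_identical(step$facts[[1]]$status, "discarded")

  facts <- list(list(id = 1L, root = 1L, tokens = c("AAC", "TCG", "A"),
                     origin_start = 1L, status = "active"))
  step <- fire_one(facts, cfg)
  expect_identical(step$rule, "R8")
  expect_identical(step$facts[[1]]$tokens, "AACTCGA")
  expect_identical(step$facts[[1]]$status, "refined")

  facts <- list(list(id = 1L, root = 1L,
                     tokens = c("CATATTCACCTTTTCAGGCGTTTTGACCGT", "TAMRA", "T"),
                     origin_start = 1L, status = "active"))
  step <- fire_one(facts, cfg)
  expect_identical(step$rule, "R2")
  kept <- step$facts[[2]]
  expect_identical(kept$tokens, "CATATTCACCTTTTCAGGCGTTTTGACCGT")

  # nothing applicable -> no rule
  facts <- list(list(id = 1L, root = 1L, tokens = "CATATTCACCTTTTCAGG",
                     origin_start = 1L, status = "active"))
  expect_null(fire_one(facts, cfg)$rule)
})

test_that("the length rule keeps a seven-symbol sequence and drops a six-symbol one", {
  expect_identical(refine_tokens("ACGTACG")$sequences, "ACGTACG")
  res <- refine_tokens("ACGTAC")
  expect_identical(res$sequences, character(0))
  expect_identical(res$trace, "R1")
})

test_that("facts emptied by stripping are discarded silently", {
  # the tail affix covers the whole fact: stripping empties it, no output
  res <- refine_tokens(c("TAMRA", "T"), refiner_config(l_min = 2))
  expect_identical(res$sequences, character(0))
  expect_identical(res$trace, "R2")
})

test_that("refinement splits recursively merged sequences into all parts", {
  withr::local_seed(66)
  for (k in 1:4) {
    parts <- vapply(seq_len(k + 1), function(...) {
      paste(sample(c("A", "C", "G", "T"), sample(8:14, 1), replace = TRUE), collapse = "")
    }, character(1))
    tokens <- head(as.vector(rbind(parts, "and")), -1L)
    res <- refine_tokens(tokens)
    expect_identical(res$sequences, parts)
  }
})

test_that("every firing shrinks the active token count, bounding the run", {
  withr::local_seed(88)
  cfg <- refiner_config()
  for (i in 1:40) {
    tokens <- random_tokens(sample(1:12, 1))
    res <- refine_tokens(tokens, cfg)
    expect_lte(length(res$trace), length(tokens))
    # fixpoint: every survivor is a single alphabet string of length >= l_min
    if (length(res$sequences) > 0) {
      expect_true(all(nchar(res$sequences) >= cfg$l_min))
      expect_true(all(grepl("^[ABCDGHKMNRSTVWYabcdghkmnrstvwy]+$", res$sequences)))
    }
  }
})

test_that("refine() carries provenance and per-candidate traces", {
  cands <- tibble::tibble(
    candidate_id = 1:2,
    paper_id = "p1",
    node_id = c(3L, 4L),
    detector = c(1L, 3L),
    tokens = list(c("ACGTACGTAC", "TAMRA", "T"), c("than", "standard"))
  )
  ref <- refine(cands)
  expect_identical(ref$sequences$sequence, "ACGTACGTAC")
  expect_identical(ref$sequences$node_id, 3L)
  expect_identical(ref$trace$rule[ref$trace$candidate == 1L], "R2")
  expect_identical(ref$trace$rule[ref$trace$candidate == 2L], "R4")
  expect_identical(glance(ref)$n_sequences, 1L)
  expect_identical(tidy(ref), ref$sequences)
})

test_that("configuration is validated and loadable from files", {
  expect_error(refiner_config(l_min = 0))
  expect_error(refiner_config(affixes = list()), class = "prx_config_error")
  expect_error(refiner_config(dictionary = c("oops!")), class = "prx_config_error")

  dict_file <- system.file("extdata", "seed_dictionary.txt", package = "primerminer")
  affix_file <- system.file("extdata", "seed_affixes.txt", package = "primerminer")
  expect_identical(read_dictionary(dict_file), seed_dictionary())
  expect_identical(read_affix_list(affix_file), seed_affixes())
})
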