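test_that("plain-text parsing stores the full text in one body section", {
  expect_warning(doc <- parse_plain_text("Primers were 5'-ACGT-3'.", "p1"),
                 class = "prx_plain_text_warning")
  nodes <- iter_reading_order(doc)
  expect_identical(nodes$section_type, c("root", "majorSection"))
  expect_identical(nodes$section_text[2], "Primers were 5'-ACGT-3'.")

  empty <- suppressWarnings(parse_plain_text("", "p0"))
  expect_identical(iter_reading_order(empty)$section_text[2], "")
})

test_that("plain documents round-trip through reading-order serialization", {
  withr::local_seed(5)
  texts <- c("", "a\nb\nc", "Table @ cell", paste(sample(letters, 200, TRUE), collapse = " "))
  for (txt in texts) {
    doc <- suppressWarnings(parse_plain_text(txt, "rt"))
    expect_identical(serialize_document(doc), txt)
  }
})

test_that("table grids flatten with the artificial cell delimiter", {
  expect_identical(flatten_table(list(c("a", "b"), c("c", "d"))), "a @ b @ c @ d")
  expect_identical(
    flatten_table(list(c("Stx1", "GTA CGT CTT TAC TGA TGA TTG ATA GTG GCA CAG GG", "35", "73.5"))),
    "Stx1 @ GTA CGT CTT TAC TGA TGA TTG ATA GTG GCA CAG GG @ 35 @ 73.5"
  )
  expect_identical(flatten_table(list("")), "")
  expect_identical(flatten_table(list()), "")
  expect_identical(flatten_table(list(c("a", ""), "b")), "a @  @ b") # ragged + empty cell
})

test_that("JATS elements map onto the declared section types", {
  xml <- make_jats(
    abstract = paste0("<sec><title>Aims</title><p>One.</p></sec>",
                      "<sec><title>Findings</title><p>Two.</p></sec>"),
    body_secs = c(
      sec("Methods", "methods text",
          inner = sec("PCR", "pcr text", inner = sec("Cycling", "cycling text",
                                                     inner = sec("Deep", "deep text")))),
      sec("Results", "results text")
    )
  )
  doc <- parse_jats(xml, "j1")
  n <- doc$nodes
  expect_identical(n$section_type[n$section_title %in% "Methods"], "majorSection")
  expect_identical(n$section_type[n$section_title %in% "PCR"], "subMajorSection")
  expect_identical(n$section_type[n$section_title %in% "Cycling"], "subSubMajorSection")
  # nesting below three named levels stays at the deepest level
  expect_identical(n$section_type[n$section_title %in% "Deep"], "subSubMajorSection")
  expect_identical(n$section_type[n$section_title %in% c("Aims", "Findings")],
                   c("subAbstract", "subAbstract"))
  expect_true("paperTitle" %in% n$section_type)
  expect_true("authors" %in% n$section_type)
  expect_identical(sum(n$section_type == "minorSection"), 2L) # ack + references
})

test_that("tables and figures become children of the root wherever they sit", {
  xml <- make_jats(
    body_secs = sec("Methods", "text before table",
                    inner = table_wrap(list(c("P1", "ACG TGC AAA")))),
    figures = "<fig><label>Figure 1</label><caption><p>A gel.</p></caption></fig>"
  )
  doc <- parse_jats(xml, "j2")
  n <- doc$nodes
  root_id <- n$node_id[n$section_type == "root"]
  tbl <- n[n$section_type == "table", ]
  fig <- n[n$section_type == "figure", ]
  expect_identical(tbl$parent_id, root_id)
  expect_identical(fig$parent_id, root_id)
  expect_identical(tbl$section_text, "P1 @ ACG TGC AAA")
  expect_identical(fig$section_text, "A gel.")
  expect_match(tbl$section_title, "Table 1")
})

test_that("malformed XML raises a parse error naming the location", {
  err <- tryCatch(parse_jats("<article><body><sec></article>", "bad"), error = identity)
  expect_s3_class(err, "prx_parse_error")
  expect_match(conditionMessage(err), "malformed XML")
})

test_that("reading order is depth-first pre-order", {
  xml <- make_jats(
    abstract = paste0("<sec><title>A1</title><p>a1</p></sec>",
                      "<sec><title>A2</title><p>a2</p></sec>",
                      "<sec><title>A3</title><p>a3</p></sec>"),
    body_secs = c(sec("Methods", "m", inner = paste0(sec("M1", "m1"), sec("M2", "m2"))),
                  sec("Results", "r"))
  )
  doc <- parse_jats(xml, "j3")
  ord <- iter_reading_order(doc)
  titles <- ord$section_title
  # abstract subsections are visited before any body subsection
  expect_lt(max(which(titles %in% c("A1", "A2", "A3"))),
            min(which(titles %in% c("M1", "M2"))))
  # children directly follow their parent, in document order
  expect_identical(titles[which(titles == "Methods") + 1:2], c("M1", "M2"))
  expect_identical(ord$section_type[1], "root")
  expect_identical(nrow(ord), nrow(doc$nodes)) # every node exactly once
})

test_that("detector section selection admits exactly the main-content types", {
  xml <- make_jats(
    abstract = "<p>abstract text</p>",
    body_secs = c(sec("Methods", "m", inner = sec("M1", "m1")), sec("Results", "r")),
    tables = table_wrap(list(c("x", "y"))),
    figures = "<fig><caption><p>cap</p></caption></fig>"
  )
  doc <- parse_jats(xml, "j4")
  sel <- select_detector_sections(doc)
  expect_setequal(unique(sel$section_type),
                  c("majorSection", "subMajorSection", "table", "figure"))
  expect_false(any(sel$section_type %in%
                     c("root", "paperTitle", "authors", "abstract", "subAbstract", "minorSection")))
  # plain documents: the single body section is the only candidate
  plain <- suppressWarnings(parse_plain_text("text", "p"))
  expect_identical(nrow(select_detector_sections(plain)), 1L)
})

test_that("selection soundness and float placement hold on generated trees", {
  withr::local_seed(77)
  for (i in 1:10) {
    n_major <- sample(1:3, 1)
    body <- vapply(seq_len(n_major), function(j) {
      inner <- if (runif(1) < 0.5) sec(paste0("S", j), "inner") else ""
      has_table <- runif(1) < 0.5
      sec(paste0("Sec", j), "body text",
          inner = paste0(inner, if (has_table) table_wrap(list(c("a", "b")))))
    }, character(1))
    doc <- parse_jats(make_jats(body_secs = body, abstract = "<p>abs</p>"), paste0("r", i))
    n <- doc$nodes
    root_id <- n$node_id[n$section_type == "root"]
    expect_true(all(n$parent_id[n$section_type %in% c("table", "figure")] == root_id))
    sel <- select_detector_sections(doc)
    expect_true(all(sel$section_type %in%
                      c("majorSection", "subMajorSection", "subSubMajorSection", "table", "figure")))
  }
})

test_that("the JSON dump mirrors the tree structure", {
  xml <- make_jats(body_secs = sec("Methods", "m"))
  doc <- parse_jats(xml, "j5")
  parsed <- jsonlite::fromJSON(document_to_json(doc), simplifyVector = FALSE)
  expect_identical(parsed$type, "root")
  types <- vapply(parsed$children, `[[`, character(1), "type")
  expect_true("majorSection" %in% types)
  methods <- parsed$children[[which(types == "majorSection")[1]]]
  expect_identical(methods$title, "Methods")
  expect_identical(methods$text, "m")
})
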