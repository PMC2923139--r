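# Deterministic synthetic corpus generator.
#
# Builds small full-text articles (plain text and JATS XML renderings of the
# same content) with primer/probe sequences planted in the three
# representation patterns the detectors target: 5'/3'-delimited, groups of
# three, and generic stretches. Optional noise reproduces the artefacts the
# refiner exists for: line-wrapping with a dash, "and"-merged pairs, and a
# trailing "TAMRA T" dye label. Distractor prose includes words spelled
# entirely over the sequence alphabet ("standard", "assay", "and", "DNA"),
# which the generic detector necessarily picks up and the rule base must
# discard. Every document gets an organism (full name in the background
# section, genus-abbreviated form co-occurring with the sequences in the
# methods section) and a gene name, and the accompanying lookup table maps
# each planted sequence to its true organism/gene, so the whole pipeline --
# detection, refinement and annotation -- can be exercised and scored
# offline against the manifest.
#
# All randomness flows from the `seed` argument; the same seed yields
# byte-identical documents, manifest and lookup table.

#' Built-in organism/gene pool for fixtures
#'
#' A small pool of microorganism names (binomial plus strain, as a
#' nucleotide database would print them) with plausible marker genes. Purely
#' illustrative; no external taxonomy is consulted.
#'
#' @return Tibble with columns `organism` and `genes` (list column).
#' @export
default_organism_pool <- function() {
  tibble::tibble(
    organism = c(
      "Brucella melitensis 16M",
      "Escherichia coli O157",
      "Staphylococcus aureus",
      "Mycobacterium tuberculosis H37Rv",
      "Salmonella enterica Typhimurium",
      "Dengue virus 2"
    ),
    genes = list(
      c("IS711", "bcsp31"),
      c("stx1", "eae"),
      c("mecA", "nuc"),
      c("IS6110", "rpoB"),
      c("invA"),
      c("NS1")
    )
  )
}

#' Fixture generator configuration
#'
#' @param n_documents Number of articles to generate.
#' @param seqs_per_pattern Named integer vector: how many sequences per
#'   document are rendered in each representation pattern (`delimited`,
#'   `triplet`, `generic`).
#' @param p_wrap Probability that a sequence is line-wrapped (dash-broken
#'   for delimited/generic mentions; a newline between groups for triplets).
#' @param p_merge Probability that two consecutive same-pattern sequences
#'   are merged into one mention linked by "and".
#' @param p_tamra Probability that a mention carries a trailing "TAMRA T"
#'   dye label.
#' @param p_degenerate Probability that a sequence contains one degenerate
#'   (wobble) symbol.
#' @param p_lowercase Probability that a sequence is printed in lowercase.
#' @param seq_len_range Length range (in symbols) of planted sequences;
#'   minimum 7 so every planted sequence survives the length rule.
#' @param organisms Organism/gene pool, see [default_organism_pool()].
#' @param gene_cooccur Should the gene name be mentioned in the methods
#'   section (co-occurring with the sequences) rather than only in results?
#' @param n_decoy_hits Extra lower-rank lookup hits per sequence, pointing
#'   at an organism never mentioned in the documents.
#' @return A list of class `prx_fixture_config`.
#' @export
fixture_config <- function(n_documents = 6L,
                           seqs_per_pattern = c(delimited = 2L, triplet = 2L, generic = 2L),
                           p_wrap = 0.25, p_merge = 0, p_tamra = 0,
                           p_degenerate = 0.1, p_lowercase = 0.1,
                           seq_len_range = c(18L, 27L),
                           organisms = default_organism_pool(),
                           gene_cooccur = TRUE,
                           n_decoy_hits = 1L) {
  probs <- c(p_wrap = p_wrap, p_merge = p_merge, p_tamra = p_tamra,
             p_degenerate = p_degenerate, p_lowercase = p_lowercase)
  if (!setequal(names(seqs_per_pattern), c("delimited", "triplet", "generic")) ||
      any(seqs_per_pattern < 0)) {
    rlang::abort("`seqs_per_pattern` needs non-negative counts named delimited/triplet/generic.",
                 class = "prx_config_error")
  }
  if (any(probs < 0 | probs > 1)) {
    rlang::abort("noise probabilities must lie in [0, 1].", class = "prx_config_error")
  }
  if (n_documents < 0 || length(seq_len_range) != 2L || seq_len_range[1L] < 7L ||
      seq_len_range[2L] < seq_len_range[1L]) {
    rlang::abort("invalid document count or sequence length range (minimum length 7).",
                 class = "prx_config_error")
  }
  stopifnot(is.data.frame(organisms), all(c("organism", "genes") %in% names(organisms)))
  structure(
    list(n_documents = as.integer(n_documents),
         seqs_per_pattern = seqs_per_pattern[c("delimited", "triplet", "generic")],
         p_wrap = p_wrap, p_merge = p_merge, p_tamra = p_tamra,
         p_degenerate = p_degenerate, p_lowercase = p_lowercase,
         seq_len_range = as.integer(seq_len_range),
         organisms = tibble::as_tibble(organisms),
         gene_cooccur = isTRUE(gene_cooccur),
         n_decoy_hits = as.integer(n_decoy_hits)),
    class = "prx_fixture_config"
  )
}

# prose filler: every alphabet-only run in these sentences is either shorter
# than the default l_min or a seed-dictionary word, so a pipeline run over
# them yields no surviving sequences
fixture_prose <- function() {
  c(
    "Amplification was performed following the standard protocol in a thermal cycler.",
    "Reaction mixtures contained buffer, nucleotides and polymerase.",
    "Samples were processed in duplicate and stored at low temperature.",
    "The assay was validated against reference material.",
    "Thermal cycling began with an initial denaturation step.",
    "Melting curves were inspected for every reaction.",
    "Probes were labelled with TAMRA at the terminal base.",
    "Negative controls contained water instead of template DNA.",
    "Each data point represents the mean of two measurements."
  )
}

abbreviate_genus <- function(organism) {
  words <- stringr::str_split_1(stringr::str_squish(organism), " ")
  if (length(words) < 2L) return(organism)
  paste(paste0(substr(words[1L], 1L, 1L), "."), words[2L])
}

group_triplets <- function(s) {
  starts <- seq(1L, nchar(s), by = 3L)
  paste(substring(s, starts, pmin(starts + 2L, nchar(s))), collapse = " ")
}

wrap_dash <- function(s) {
  cut <- nchar(s) %/% 2L
  paste0(substr(s, 1L, cut), "-\n", substr(s, cut + 1L, nchar(s)))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Generate a synthetic article corpus with known ground truth
#'
#' Produces `n_documents` articles, each rendered both as plain text and as
#' JATS XML, a manifest of every planted sequence (its exact string,
#' representation pattern, noise flags, placement and true organism/gene
#' label), and a lookup table for the annotation backend. Deterministic:
#' the same `seed` and configuration give byte-identical output.
#'
#' @param config A [fixture_config()].
#' @param seed Integer seed driving all randomness.
#' @return An object of class `prx_fixture`: list with `documents` (tibble:
#'   `paper_id`, `plain_text`, `jats_xml`), `manifest`, `lookup`, `config`,
#'   `seed`.
#' @export
#' @examples
#' fx <- generate_fixture(fixture_config(n_documents = 1), seed = 42)
#' fx$manifest
generate_fixture <- function(config = fixture_config(), seed = 1L) {
  stopifnot(inherits(config, "prx_fixture_config"))
  withr::local_seed(as.integer(seed))

  used <- character(0)
  rand_seq <- function() {
    repeat {
      len <- sample(config$seq_len_range[1L]:config$seq_len_range[2L], 1L)
      s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
      if (stats::runif(1) < config$p_degenerate) {
        pos <- sample(2:(len - 1L), 1L)
        substr(s, pos, pos) <- sample(c("R", "Y", "M", "K", "S", "W"), 1L)
      }
      if (stats::runif(1) < config$p_lowercase) s <- tolower(s)
      if (!s %in% used) {
        used <<- c(used, s)
        return(s)
      }
    }
  }

  prose <- fixture_prose()
  pick_prose <- function(n) paste(sample(prose, n), collapse = " ")

  manifest_rows <- list()
  lookup_rows <- list()
  doc_rows <- list()
  gi_counter <- 0L
  decoy <- "Pseudomonas fluorescens SBW25"

  for (d in seq_len(config$n_documents)) {
    paper_id <- sprintf("SYNTH%03d", d)
    org_row <- config$organisms[(d - 1L) %% nrow(config$organisms) + 1L, ]
    organism <- org_row$organism[[1L]]
    gene <- sample(org_row$genes[[1L]], 1L)

    # plan mentions: merge consecutive same-pattern sequences with prob p_merge
    mentions <- list() # each: list(pattern, seqs, wrapped, tamra, placement)
    tri_count <- 0L
    for (pattern in c("delimited", "triplet", "generic")) {
      n_seqs <- config$seqs_per_pattern[[pattern]]
      i <- 1L
      while (i <= n_seqs) {
        take2 <- i + 1L <= n_seqs && stats::runif(1) < config$p_merge
        seqs <- vapply(seq_len(1L + take2), function(...) rand_seq(), character(1L))
        placement <- "methods"
        if (pattern == "triplet") {
          tri_count <- tri_count + 1L
          if (tri_count %% 2L == 0L) placement <- "table"
        }
        mentions[[length(mentions) + 1L]] <- list(
          pattern = pattern, seqs = seqs,
          wrapped = stats::runif(1) < config$p_wrap,
          tamra = stats::runif(1) < config$p_tamra,
          placement = placement
        )
        i <- i + 1L + take2
      }
    }

    methods_sentences <- character(0)
    table_rows <- list(c("Primer", "Sequence", "Length", "Tm"))
    mention_idx <- 0L
    for (m in mentions) {
      mention_idx <- mention_idx + 1L
      if (m$placement == "table") {
        cell <- paste(vapply(m$seqs, group_triplets, character(1L)), collapse = " and ")
        if (m$tamra) cell <- paste(cell, "TAMRA T")
        table_rows[[length(table_rows) + 1L]] <- c(
          sprintf("P%d-F", mention_idx), cell,
          as.character(sum(nchar(m$seqs))), sprintf("%.1f", 55 + stats::runif(1) * 15)
        )
        next
      }
      rendered <- switch(
        m$pattern,
        delimited = {
          parts <- vapply(m$seqs, function(s) if (m$wrapped) wrap_dash(s) else s, character(1L))
          x <- paste(parts, collapse = " and ")
          if (m$tamra) x <- paste(x, "TAMRA T")
          switch(sample(3L, 1L),
                 sprintf("(5'-%s-3')", x),
                 sprintf("5'-%s-3'", x),
                 sprintf("5-%s-3", x))
        },
        generic = {
          parts <- vapply(m$seqs, function(s) if (m$wrapped) wrap_dash(s) else s, character(1L))
          x <- paste(parts, collapse = " and ")
          if (m$tamra) x <- paste(x, "TAMRA T")
          sprintf("(%s)", x)
        },
        triplet = {
          grouped <- vapply(m$seqs, group_triplets, character(1L))
          x <- paste(grouped, collapse = " and ")
          if (m$wrapped) x <- sub(" ", "\n", x) # groups may span lines
          if (m$tamra) x <- paste(x, "TAMRA T")
          paste0(": ", x, ".")
        }
      )
      sentence <- switch(
        m$pattern,
        delimited = sprintf("The primer %s was used for amplification.", rendered),
        generic = sprintf("The amplified fragment matched %s in all isolates.", rendered),
        triplet = sprintf("The probe used was%s Reactions ran in duplicate.", rendered)
      )
      methods_sentences <- c(methods_sentences, sentence)
    }

    abbrev <- abbreviate_genus(organism)
    methods_text <- paste(
      c(sprintf("All assays targeted %s isolates.", abbrev),
        if (config$gene_cooccur) sprintf("Primers amplify a fragment of the %s gene.", gene),
        methods_sentences,
        pick_prose(2L)),
      collapse = " "
    )
    background_text <- paste(
      sprintf("Detection of %s remains important for surveillance.", organism),
      pick_prose(1L)
    )
    results_text <- paste(
      c(if (!config$gene_cooccur) sprintf("Signals specific for %s were detected in most samples.", gene),
        "Detection limits were comparable across runs.",
        pick_prose(1L)),
      collapse = " "
    )
    abstract_text <- "Rapid molecular detection methods were evaluated on archived clinical samples."
    title <- sprintf("Molecular detection assay %d", d)
    fig_caption <- "Gel electrophoresis of amplification products."

    # manifest + lookup rows
    for (m in mentions) {
      for (s in m$seqs) {
        manifest_rows[[length(manifest_rows) + 1L]] <- tibble::tibble(
          paper_id = paper_id, sequence = s, pattern = m$pattern,
          placement = m$placement, wrapped = m$wrapped,
          merged = length(m$seqs) > 1L, tamra = m$tamra,
          organism_name = organism, gene_name = gene
        )
        gi_counter <- gi_counter + 1L
        lookup_rows[[length(lookup_rows) + 1L]] <- tibble::tibble(
          sequence = s, rank = 1L, identifier = sprintf("GI%07d", gi_counter),
          organism_name = organism, gene_names = gene
        )
        for (k in seq_len(config$n_decoy_hits)) {
          gi_counter <- gi_counter + 1L
          lookup_rows[[length(lookup_rows) + 1L]] <- tibble::tibble(
            sequence = s, rank = 1L + k, identifier = sprintf("GI%07d", gi_counter),
            organism_name = decoy, gene_names = ""
          )
        }
      }
    }

    flat_table <- flatten_table(table_rows)
    plain_text <- paste(
      c(title, "A. Lopez; B. Cole",
        "Abstract", abstract_text,
        "Background", background_text,
        "Methods", methods_text,
        flat_table,
        "Results", results_text,
        "Figure 1", fig_caption,
        "References", "1. Prior work on detection assays."),
      collapse = "\n\n"
    )

    table_xml <- paste(
      vapply(table_rows, function(r) {
        paste0("<tr>", paste0("<td>", xml_escape(r), "</td>", collapse = ""), "</tr>")
      }, character(1L)),
      collapse = ""
    )
    jats_xml <- paste0(
      "<article><front><article-meta>",
      "<article-id>", paper_id, "</article-id>",
      "<title-group><article-title>", xml_escape(title), "</article-title></title-group>",
      "<contrib-group><contrib><name><surname>Author</surname>",
      "<given-names>A.</given-names></name></contrib></contrib-group>",
      "<abstract><p>", xml_escape(abstract_text), "</p></abstract>",
      "</article-meta></front><body>",
      "<sec><title>Background</title><p>", xml_escape(background_text), "</p></sec>",
      "<sec><title>Methods</title><p>", xml_escape(methods_text), "</p>",
      "<table-wrap><label>Table 1</label><caption><p>Primers used in this study</p></caption>",
      "<table><tbody>", table_xml, "</tbody></table></table-wrap>",
      "</sec>",
      "<sec><title>Results</title><p>", xml_escape(results_text), "</p>",
      "<fig><label>Figure 1</label><caption><p>", xml_escape(fig_caption), "</p></caption></fig>",
      "</sec></body><back>",
      "<ack><title>Acknowledgements</title><p>We thank the laboratory staff.</p></ack>",
      "<ref-list><title>References</title>",
      "<ref><mixed-citation>Prior work on detection assays.</mixed-citation></ref>",
      "</ref-list></back></article>"
    )

    doc_rows[[length(doc_rows) + 1L]] <- tibble::tibble(
      paper_id = paper_id, plain_text = plain_text, jats_xml = jats_xml
    )
  }

  structure(
    list(
      documents = dplyr::bind_rows(doc_rows),
      manifest = dplyr::bind_rows(manifest_rows),
      lookup = dplyr::bind_rows(lookup_rows),
      config = config,
      seed = as.integer(seed)
    ),
    class = "prx_fixture"
  )
}

#' @export
print.prx_fixture <- function(x, ...) {
  cat("<prx_fixture> seed ", x$seed, ": ", nrow(x$documents), " documents, ",
      nrow(x$manifest), " planted sequences\n", sep = "")
  invisible(x)
}

#' Gold-standard tables from a fixture manifest
#'
#' @param fixture A `prx_fixture`.
#' @param purpose `"detection"` for a (`paper_id`, `sequence`) key table,
#'   `"annotation"` for (`paper`, `sequence`, `organism_name`, `gene_name`).
#' @return A tibble.
#' @export
fixture_gold <- function(fixture, purpose = c("detection", "annotation")) {
  purpose <- rlang::arg_match(purpose)
  m <- fixture$manifest
  if (purpose == "detection") {
    dplyr::distinct(m[, c("paper_id", "sequence")])
  } else {
    dplyr::distinct(tibble::tibble(
      paper = m$paper_id, sequence = m$sequence,
      organism_name = m$organism_name, gene_name = m$gene_name
    ))
  }
}

#' Write a fixture corpus to disk
#'
#' Writes one `.txt` and one `.xml` file per document plus `manifest.tsv`
#' and `lookup.tsv`.
#'
#' @param fixture A `prx_fixture`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(fixture$documents))) {
    row <- fixture$documents[i, ]
    writeLines(row$plain_text, file.path(dir, paste0(row$paper_id, ".txt")))
    writeLines(row$jats_xml, file.path(dir, paste0(row$paper_id, ".xml")))
  }
  readr::write_tsv(fixture$manifest, file.path(dir, "manifest.tsv"))
  write_lookup_tsv(fixture$lookup, file.path(dir, "lookup.tsv"))
  invisible(dir)
}
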