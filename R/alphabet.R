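# The degenerate-nucleotide alphabet used throughout the package.
#
# Primer/probe sequences printed in articles use the IUPAC nucleotide code:
# the four bases plus eleven wildcard letters, each standing for a set of
# permissible bases. Both cases occur in print, so the working alphabet
# (Sigma) has 30 symbols: 15 uppercase letters and their lowercase twins.

SIGMA_UPPER <- c("A", "B", "C", "D", "G", "H", "K", "M", "N", "R", "S", "T", "V", "W", "Y")

# per-symbol permissible nucleotides and complements (uppercase key)
IUPAC_EXPANSION <- list(
  A = "A",
  B = c("C", "G", "T"),
  C = "C",
  D = c("A", "G", "T"),
  G = "G",
  H = c("A", "C", "T"),
  K = c("G", "T"),
  M = c("A", "C"),
  N = c("A", "C", "G", "T"),
  R = c("A", "G"),
  S = c("C", "G"),
  T = "T",
  V = c("A", "C", "G"),
  W = c("A", "T"),
  Y = c("C", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", B = "V", C = "G", D = "H", G = "C", H = "D", K = "M", M = "K",
  N = "N", R = "Y", S = "S", T = "A", V = "B", W = "W", Y = "R"
)

#' The 30-symbol degenerate nucleotide alphabet
#'
#' Returns the symbols of the working alphabet Sigma: the 15 uppercase IUPAC
#' nucleotide letters (four bases and eleven wildcards) together with their
#' lowercase counterparts, as they appear verbatim in article text.
#'
#' @return A character vector of 30 single-character symbols.
#' @export
#' @examples
#' length(sigma_symbols())
sigma_symbols <- function() {
  c(SIGMA_UPPER, tolower(SIGMA_UPPER))
}

# regex character class matching one Sigma symbol
sigma_class <- function() {
  paste0("[", paste0(SIGMA_UPPER, collapse = ""),
         paste0(tolower(SIGMA_UPPER), collapse = ""), "]")
}

# TRUE for strings entirely over Sigma (Sigma+), vectorised
is_sigma_plus <- function(x) {
  !is.na(x) & nchar(x) > 0L &
    grepl(paste0("^(?:", sigma_class(), ")+$"), x, perl = TRUE)
}

#' Expand a degenerate symbol to its permissible nucleotides
#'
#' @param symbol A single alphabet symbol (case-insensitive).
#' @return Character vector of the nucleotides the symbol may stand for,
#'   e.g. `c("G", "T")` for `"K"`.
#' @export
#' @examples
#' expand_symbol("K")
#' expand_symbol("n")
expand_symbol <- function(symbol) {
  if (!rlang::is_scalar_character(symbol) || nchar(symbol) != 1L) {
    rlang::abort("`symbol` must be a single character.", class = "prx_domain_error")
  }
  key <- toupper(symbol)
  if (!key %in% SIGMA_UPPER) {
    rlang::abort(
      paste0("'", symbol, "' is not a symbol of the degenerate nucleotide alphabet."),
      class = "prx_domain_error"
    )
  }
  IUPAC_EXPANSION[[key]]
}

#' Reverse complement over the degenerate alphabet
#'
#' Maps every symbol to its IUPAC complement (wildcards map to the wildcard
#' covering the complementary base set, e.g. R to Y, N to N) and reverses the
#' string. Case is preserved position-wise.
#'
#' @param x Character vector of sequences over the 30-symbol alphabet.
#' @return Character vector of reverse-complemented sequences.
#' @export
#' @examples
#' reverse_complement("ACGT")
#' reverse_complement("AAKC")
reverse_complement <- function(x) {
  if (!is.character(x)) {
    rlang::abort("`x` must be a character vector.", class = "prx_domain_error")
  }
  bad <- !is.na(x) & nchar(x) > 0L & !is_sigma_plus(x)
  if (any(bad)) {
    rlang::abort(
      paste0("sequence contains symbols outside the degenerate alphabet: ",
             paste0("'", utils::head(x[bad], 3L), "'", collapse = ", ")),
      class = "prx_domain_error"
    )
  }
  from <- paste0(paste0(SIGMA_UPPER, collapse = ""), paste0(tolower(SIGMA_UPPER), collapse = ""))
  to <- paste0(paste0(IUPAC_COMPLEMENT[SIGMA_UPPER], collapse = ""),
               paste0(tolower(IUPAC_COMPLEMENT[SIGMA_UPPER]), collapse = ""))
  complemented <- chartr(from, to, x)
  vapply(complemented, function(s) {
    if (is.na(s)) return(NA_character_)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}
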