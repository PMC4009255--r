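#' Normalize a term to its canonical matching form
#'
#' Dictionary terms and sentence text are matched on a shared canonical form:
#' diacritics are folded to their base characters ("Sjögren" to "sjogren"),
#' all characters are lowercased, every punctuation or symbol character is
#' replaced by a single space (so that "hnf-3-gamma" keeps its token
#' boundaries as "hnf 3 gamma"), and runs of whitespace are collapsed.
#' Greek glyphs are letters, not symbols, and pass through unchanged; their
#' interconversion with spelled-out names is handled by
#' [generate_greek_variants()].
#'
#' The transformation is idempotent: `normalize_term(normalize_term(x))`
#' equals `normalize_term(x)`.
#'
#' @param term Character vector of terms. Elements must be non-empty.
#' @return Character vector of normalized forms, same length as `term`.
#' @examples
#' normalize_term(c("FALDH deficiency", "hnf-3-gamma"))
#' normalize_term("Sjögren-Larsson syndrome")
#' @export
normalize_term <- function(term) {
  if (length(term) == 0L) return(character())
  if (anyNA(term) || any(!nzchar(term))) {
    abort("`term` must not contain empty or missing values.")
  }
  x <- stringi::stri_trans_general(term, "Latin-ASCII")
  x <- stringi::stri_trans_tolower(x)
  x <- gsub("[\\p{P}\\p{S}]", " ", x, perl = TRUE)
  str_squish(x)
}

#' Remove bracketed prefix and suffix labels from a term
#'
#' Source vocabularies attach classification labels that never occur in
#' natural language, such as the prefix in "\[X\]Gastric neurosis" or the
#' suffix in "Leber Congenital Amaurosis \[Disease/Finding\]". Both are
#' stripped; terms without labels are returned unchanged.
#'
#' @param term Character vector of terms.
#' @return Character vector with labels removed and whitespace trimmed.
#' @examples
#' strip_affix_labels("[X]Gastric neurosis")
#' strip_affix_labels("Leber Congenital Amaurosis [Disease/Finding]")
#' @export
strip_affix_labels <- function(term) {
  x <- sub("^\\s*\\[[^][]*\\]\\s*", "", term)
  x <- sub("\\s*\\[[^][]*\\]\\s*$", "", x)
  trimws(x)
}

#' Generate separator variants of an acronym-style gene symbol
#'
#' A gene acronym composed of a letter block followed by a digit block is
#' written in the literature with several separators: "IL2", "IL 2", "IL-2"
#' and "IL(2)" all denote interleukin 2. For a conforming symbol the full
#' variant set is returned (the input itself included); symbols that do not
#' match the letters-then-digits shape are returned as a singleton set.
#'
#' @param symbol A single gene symbol.
#' @return Character vector of unique variants, always containing `symbol`.
#' @examples
#' generate_acronym_variants("IL2")
#' generate_acronym_variants("CD")
#' @export
generate_acronym_variants <- function(symbol) {
  stopifnot(is.character(symbol), length(symbol) == 1L, !is.na(symbol))
  m <- regmatches(
    symbol,
    regexec("^([A-Za-z]+)(?:[ -]|\\s?\\()?([0-9]+)\\)?$", symbol)
  )[[1]]
  if (length(m) == 0L) return(symbol)
  letters_part <- m[2]
  digits_part <- m[3]
  unique(c(
    symbol,
    paste0(letters_part, digits_part),
    paste(letters_part, digits_part),
    paste0(letters_part, "-", digits_part),
    paste0(letters_part, "(", digits_part, ")")
  ))
}

.roman_max <- 30L

#' Generate Roman-numeral variants of a term
#'
#' Disease names frequently interchange Arabic and Roman numbering
#' ("deficiency type 4" vs "deficiency type IV"). For each standalone Arabic
#' number token valued 1 to 30, a variant with the uppercase Roman form is
#' produced; larger numbers (years, database identifiers) are left alone.
#' The original term is always included.
#'
#' @param term A single term.
#' @return Character vector of unique variants, always containing `term`.
#' @examples
#' generate_numeral_variants("Adenylosuccinate lyase deficiency type 4")
#' @export
generate_numeral_variants <- function(term) {
  stopifnot(is.character(term), length(term) == 1L, !is.na(term))
  out <- term
  hits <- gregexpr("(?<![[:alnum:]])[0-9]+(?![[:alnum:]])", term, perl = TRUE)[[1]]
  if (hits[1] != -1L) {
    for (k in seq_along(hits)) {
      start <- hits[k]
      len <- attr(hits, "match.length")[k]
      val <- suppressWarnings(as.integer(substr(term, start, start + len - 1L)))
      if (!is.na(val) && val >= 1L && val <= .roman_max) {
        variant <- paste0(
          substr(term, 1L, start - 1L),
          as.character(as.roman(val)),
          substr(term, start + len, nchar(term))
        )
        out <- c(out, variant)
      }
    }
  }
  unique(out)
}

.greek_names <- c(
  "alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta", "theta",
  "iota", "kappa", "lambda", "mu", "nu", "xi", "omicron", "pi", "rho",
  "sigma", "tau", "upsilon", "phi", "chi", "psi", "omega"
)
.greek_glyphs <- c(
  "α", "β", "γ", "δ", "ε", "ζ", "η",
  "θ", "ι", "κ", "λ", "μ", "ν", "ξ",
  "ο", "π", "ρ", "σ", "τ", "υ", "φ",
  "χ", "ψ", "ω"
)

#' Generate Greek-letter variants of a term
#'
#' Terms are written both with spelled-out Greek letter names ("HP1-alpha")
#' and with glyphs ("HP1-α"); both cases occur in abstracts, so both
#' directions are generated. Names are replaced only when they stand alone
#' between non-letter boundaries, so "betaine" is untouched. The original
#' term is always included.
#'
#' @param term A single term.
#' @return Character vector of unique variants, always containing `term`.
#' @examples
#' generate_greek_variants("HP1-alpha")
#' generate_greek_variants("HP1-β")
#' @export
generate_greek_variants <- function(term) {
  stopifnot(is.character(term), length(term) == 1L, !is.na(term))
  out <- term
  to_glyph <- term
  for (k in seq_along(.greek_names)) {
    to_glyph <- gsub(
      paste0("(?<![A-Za-z])", .greek_names[k], "(?![A-Za-z])"),
      .greek_glyphs[k], to_glyph,
      perl = TRUE, ignore.case = TRUE
    )
  }
  to_name <- term
  for (k in seq_along(.greek_names)) {
    to_name <- gsub(.greek_glyphs[k], .greek_names[k], to_name, fixed = TRUE)
  }
  unique(c(out, to_glyph, to_name))
}

#' Generate the full variant set for a dictionary term
#'
#' Applies the acronym separator template (gene symbols only), the
#' Arabic-to-Roman numeral rule, and Greek letter/glyph interconversion, in
#' composition: numeral and Greek variants are expanded on every acronym
#' variant. The output always contains the input term.
#'
#' @param term A single term.
#' @param entity_class `"GENE"` or `"DISEASE"`; acronym separator variants
#'   are generated only for genes.
#' @return Character vector of unique variants.
#' @export
term_variants <- function(term, entity_class = c("GENE", "DISEASE")) {
  entity_class <- match.arg(entity_class)
  base <- if (entity_class == "GENE") generate_acronym_variants(term) else term
  expanded <- unlist(lapply(base, generate_numeral_variants), use.names = FALSE)
  expanded <- unlist(lapply(expanded, generate_greek_variants), use.names = FALSE)
  unique(expanded)
}
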