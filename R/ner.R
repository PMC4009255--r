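#' Compile a curated lexicon into a multi-pattern matcher
#'
#' Every distinct normalized term of the lexicon becomes a pattern keyed to
#' the set of concepts it can denote. Patterns equal to a stop word, or
#' shorter than three characters, are excluded. The index is a hash over
#' token sequences, so a sentence is scanned in a single left-to-right pass.
#'
#' @param lex A non-empty [lexicon()], typically after [curate_lexicon()].
#' @param stopwords Character vector of stop words (normalized with
#'   [normalize_term()] before comparison).
#' @return An object of class `marker_index`.
#' @export
compile_patterns <- function(lex, stopwords = character()) {
  stopifnot(inherits(lex, "marker_lexicon"))
  if (nrow(lex) == 0L) abort("Cannot compile patterns from an empty lexicon.")
  entity_class <- unique(lex$entity_class)
  if (length(entity_class) != 1L) {
    abort("A matcher index holds a single entity class; split the lexicon first.")
  }
  stopwords <- if (length(stopwords)) normalize_term(stopwords) else character()
  pat <- lex |>
    distinct(.data$normalized, .data$concept_id) |>
    filter(nchar(.data$normalized) >= 3L, !(.data$normalized %in% stopwords))
  if (nrow(pat) == 0L) abort("No patterns survive stop-word and length filtering.")
  tab <- pat |>
    group_by(.data$normalized) |>
    summarise(concept_ids = list(sort(unique(.data$concept_id))), .groups = "drop")
  env <- new.env(hash = TRUE, parent = emptyenv(), size = nrow(tab) * 2L)
  for (k in seq_len(nrow(tab))) {
    assign(tab$normalized[k], tab$concept_ids[[k]], envir = env)
  }
  structure(
    list(
      patterns = env,
      entity_class = entity_class,
      max_tokens = max(stringi::stri_count_fixed(tab$normalized, " ")) + 1L,
      n_patterns = nrow(tab)
    ),
    class = "marker_index"
  )
}

#' @export
print.marker_index <- function(x, ...) {
  cat(sprintf("<marker_index> %s: %d patterns (max %d tokens)\n",
              x$entity_class, x$n_patterns, x$max_tokens))
  invisible(x)
}

# Normalize a sentence like normalize_term() while keeping, for every
# character of the normalized string, the 1-based index of the original
# character it came from. Returns list(norm, map).
normalize_with_offsets <- function(text) {
  if (is.na(text) || !nzchar(text)) {
    return(list(norm = "", map = integer()))
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  folded <- stringi::stri_trans_general(chars, "Latin-ASCII")
  folded <- stringi::stri_trans_tolower(folded)
  folded <- gsub("[\\p{P}\\p{S}]", " ", folded, perl = TRUE)
  folded <- gsub("\\s+", " ", folded)
  widths <- nchar(folded)
  orig <- rep.int(seq_along(chars), widths)
  out <- unlist(strsplit(folded, "", fixed = TRUE), use.names = FALSE)
  if (is.null(out)) out <- character()
  is_sp <- out == " "
  drop <- is_sp & c(TRUE, is_sp[-length(is_sp)])
  out <- out[!drop]
  orig <- orig[!drop]
  if (length(out) && out[length(out)] == " ") {
    out <- out[-length(out)]
    orig <- orig[-length(orig)]
  }
  if (length(out) && out[1] == " ") {  # defensive; drop handles position 1
    out <- out[-1]
    orig <- orig[-1]
  }
  list(norm = paste(out, collapse = ""), map = orig)
}

#' Tag entity mentions in one sentence
#'
#' The sentence is normalized with the same pipeline as the dictionary
#' terms (with an offset map back to the original text) and scanned left to
#' right: at each token boundary the longest matching pattern is taken, and
#' scanning resumes after it, so mentions of one entity class never overlap
#' and a longer term always shadows its sub-terms ("acute lymphoblastic
#' leukemia" over "leukemia"). Each mention is normalized to its concept
#' identifier(s); a term shared by several concepts yields one mention
#' flagged `ambiguous` with all candidate identifiers.
#'
#' @param text A single sentence string (original, un-normalized text).
#' @param index A `marker_index` from [compile_patterns()].
#' @return A tibble with columns `char_start`, `char_end` (0-based,
#'   half-open, into `text`), `surface`, `entity_class`, `concept_ids`
#'   (list-column), `ambiguous`.
#' @export
tag_sentence <- function(text, index) {
  stopifnot(inherits(index, "marker_index"))
  empty <- tibble(
    char_start = integer(), char_end = integer(), surface = character(),
    entity_class = character(), concept_ids = list(), ambiguous = logical()
  )
  nw <- normalize_with_offsets(text)
  if (!nzchar(nw$norm)) return(empty)
  tokens <- strsplit(nw$norm, " ", fixed = TRUE)[[1]]
  tok_start <- c(1L, cumsum(nchar(tokens) + 1L)[-length(tokens)] + 1L)
  tok_end <- tok_start + nchar(tokens) - 1L  # norm-string positions
  n_tok <- length(tokens)
  hits <- list()
  i <- 1L
  while (i <= n_tok) {
    matched_len <- 0L
    for (len in seq.int(min(index$max_tokens, n_tok - i + 1L), 1L)) {
      key <- paste(tokens[i:(i + len - 1L)], collapse = " ")
      ids <- get0(key, envir = index$patterns, inherits = FALSE)
      if (!is.null(ids)) {
        s_norm <- tok_start[i]
        e_norm <- tok_end[i + len - 1L]
        start0 <- nw$map[s_norm] - 1L
        end0 <- nw$map[e_norm]
        hits[[length(hits) + 1L]] <- list(
          char_start = start0, char_end = end0,
          surface = substr(text, start0 + 1L, end0),
          concept_ids = ids
        )
        matched_len <- len
        break
      }
    }
    i <- i + max(matched_len, 1L)
  }
  if (!length(hits)) return(empty)
  tibble(
    char_start = purrr::map_int(hits, "char_start"),
    char_end = purrr::map_int(hits, "char_end"),
    surface = purrr::map_chr(hits, "surface"),
    entity_class = index$entity_class,
    concept_ids = purrr::map(hits, "concept_ids"),
    ambiguous = purrr::map_int(hits, \(h) length(h$concept_ids)) > 1L
  )
}

#' Tag all sentences of a corpus with gene and disease mentions
#'
#' Runs [tag_sentence()] over every title, body and conclusions sentence of
#' every document, for both entity classes independently (a gene mention and
#' a disease mention may overlap; two mentions of the same class never do).
#'
#' @param docs A document tibble as returned by [read_corpus()], or a
#'   pre-computed sentence tibble from [corpus_sentences()].
#' @param gene_index,disease_index `marker_index` objects; either may be
#'   `NULL` to tag a single class.
#' @return A mention tibble: `pmid`, `section`, `sentence_index`,
#'   `char_start`, `char_end` (offsets into the sentence), `surface`,
#'   `entity_class`, `concept_ids` (list-column), `ambiguous`.
#' @export
tag_corpus <- function(docs, gene_index = NULL, disease_index = NULL) {
  if (is.null(gene_index) && is.null(disease_index)) {
    abort("Provide at least one matcher index.")
  }
  sents <- if (all(c("section", "index", "text") %in% names(docs))) {
    docs
  } else {
    corpus_sentences(docs)
  }
  tag_with <- function(idx) {
    if (is.null(idx) || nrow(sents) == 0L) return(NULL)
    res <- purrr::map(sents$text, tag_sentence, index = idx)
    keep <- purrr::map_int(res, nrow) > 0L
    if (!any(keep)) return(NULL)
    meta <- sents[rep(seq_len(nrow(sents)), purrr::map_int(res, nrow)),
                  c("pmid", "section", "index")]
    bind_cols(
      tibble(pmid = meta$pmid, section = meta$section, sentence_index = meta$index),
      bind_rows(res)
    )
  }
  out <- bind_rows(tag_with(gene_index), tag_with(disease_index))
  if (nrow(out) == 0L) {
    return(tibble(
      pmid = character(), section = character(), sentence_index = integer(),
      char_start = integer(), char_end = integer(), surface = character(),
      entity_class = character(), concept_ids = list(), ambiguous = logical()
    ))
  }
  arrange(out, match(.data$pmid, unique(sents$pmid)),
          match(.data$section, c("TITLE", "BODY", "CONCLUSIONS")),
          .data$sentence_index, .data$char_start, .data$entity_class)
}

#' Export mentions to TSV
#'
#' Concept identifier sets are semicolon-joined for the flat file.
#'
#' @param mentions A mention tibble from [tag_corpus()].
#' @param path Output path.
#' @return `mentions`, invisibly.
#' @export
write_mentions_tsv <- function(mentions, path) {
  flat <- mentions |>
    mutate(concept_ids = purrr::map_chr(.data$concept_ids, paste, collapse = ";"))
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(mentions)
}
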