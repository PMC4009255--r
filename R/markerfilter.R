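#' Find sentences containing a biomarker trigger term
#'
#' A sentence "triggers" when its normalized text contains at least one
#' biomarker trigger term ("biomarker", "biological marker", "marker", ...)
#' at token boundaries — "serum marker" triggers, "remarkable" does not.
#' The trigger vocabulary is seeded from the MeSH "Biological Markers"
#' entry terms and is user-editable ([default_triggers()]).
#'
#' @param sentences A sentence tibble from [corpus_sentences()].
#' @param triggers Character vector of trigger terms (normalized internally).
#' @return A tibble of sentence keys: `pmid`, `section`, `index`.
#' @export
find_trigger_sentences <- function(sentences, triggers) {
  triggers <- unique(normalize_term(triggers))
  if (!length(triggers)) abort("Trigger list must be non-empty.")
  fake_lex <- lexicon(tibble(
    concept_id = paste0("gene:trigger", seq_along(triggers)),
    entity_class = "GENE",
    preferred_name = triggers,
    surface = triggers,
    normalized = triggers
  ))
  idx <- compile_patterns(fake_lex)
  hit <- purrr::map_lgl(sentences$text, \(s) nrow(tag_sentence(s, idx)) > 0L)
  sentences[hit, c("pmid", "section", "index")]
}

#' Restrict a lexicon to concepts co-mentioned with biomarker triggers
#'
#' Implements biomarker rule filtering: a concept is kept exactly when it
#' has at least one mention in a sentence that also contains a biomarker
#' trigger term (entities named next to "marker"-type words are very likely
#' biomarkers themselves). All term entries of a retained concept are kept
#' in full; the same procedure applies to gene and disease lexicons alike.
#'
#' @param lex The [lexicon()] the mentions were tagged with.
#' @param mentions A mention tibble from [tag_corpus()].
#' @param trigger_sentences Sentence keys from [find_trigger_sentences()].
#' @return The biomarker-specific sub-lexicon (a `marker_lexicon`).
#' @export
filter_lexicon <- function(lex, mentions, trigger_sentences) {
  stopifnot(inherits(lex, "marker_lexicon"))
  if (nrow(mentions) == 0L || nrow(trigger_sentences) == 0L) {
    return(lexicon(lex[0L, , drop = FALSE]))
  }
  in_trigger <- mentions |>
    semi_join(
      trigger_sentences |> rename(sentence_index = "index"),
      by = c("pmid", "section", "sentence_index")
    )
  keep_ids <- unique(unlist(in_trigger$concept_ids, use.names = FALSE))
  out <- lex |> filter(.data$concept_id %in% keep_ids)
  lexicon(out)
}

#' Default biomarker trigger terms
#'
#' Entry-term style variants of the MeSH "Biological Markers" concept,
#' shipped as `inst/extdata/triggers.txt`.
#'
#' @return Character vector of normalized trigger terms.
#' @export
default_triggers <- function() {
  read_term_file(system.file("extdata", "triggers.txt", package = "markermine"))
}

#' Default stop-word list
#'
#' A small English function-word list applied when compiling matcher
#' patterns, shipped as `inst/extdata/stopwords.txt`.
#'
#' @return Character vector of normalized stop words.
#' @export
default_stopwords <- function() {
  read_term_file(system.file("extdata", "stopwords.txt", package = "markermine"))
}

#' Default generic-term blocklist
#'
#' Very general single-word terms removed during curation (e.g. "disease",
#' "syndrome"), shipped as `inst/extdata/blocklist.txt`.
#'
#' @return Character vector of normalized blocked terms.
#' @export
default_blocklist <- function() {
  read_term_file(system.file("extdata", "blocklist.txt", package = "markermine"))
}
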