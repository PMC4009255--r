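#' Construct a lexicon from a term-entry table
#'
#' A lexicon is a tidy table with one row per (concept, term entry): each row
#' carries the concept identifier (namespaced as `gene:<NCBI Gene id>` or
#' `disease:<UMLS CUI>`), its entity class and preferred name, the surface
#' term, the normalized matching form, and the entry provenance (`SOURCE` or
#' `GENERATED_VARIANT`). Disease concepts may carry UMLS semantic type codes
#' (semicolon-joined).
#'
#' @param entries A data frame with columns `concept_id`, `entity_class`,
#'   `preferred_name`, `surface`, and optionally `normalized`, `provenance`,
#'   `semantic_types`. Missing `normalized` is computed with
#'   [normalize_term()]; missing `provenance` defaults to `"SOURCE"`.
#' @return A tibble of class `marker_lexicon`.
#' @examples
#' lexicon(data.frame(
#'   concept_id = "gene:3569", entity_class = "GENE",
#'   preferred_name = "interleukin 6", surface = "IL6"
#' ))
#' @export
lexicon <- function(entries) {
  entries <- as_tibble(entries)
  required <- c("concept_id", "entity_class", "preferred_name", "surface")
  missing <- setdiff(required, names(entries))
  if (length(missing)) {
    abort(paste0("Lexicon is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (!"normalized" %in% names(entries)) {
    entries$normalized <- if (nrow(entries)) normalize_term(entries$surface) else character()
  }
  if (!"provenance" %in% names(entries)) {
    entries$provenance <- rep("SOURCE", nrow(entries))
  }
  if (!"semantic_types" %in% names(entries)) {
    entries$semantic_types <- rep(NA_character_, nrow(entries))
  }
  entries <- entries[, c("concept_id", "entity_class", "preferred_name",
                         "semantic_types", "surface", "normalized", "provenance")]
  validate_lexicon(entries)
  structure(entries, class = c("marker_lexicon", class(as_tibble(entries))))
}

.disease_semtypes <- c("T019", "T020", "T047", "T048", "T050", "T184", "T190", "T191")

validate_lexicon <- function(entries) {
  bad_class <- setdiff(unique(entries$entity_class), c("GENE", "DISEASE"))
  if (length(bad_class)) {
    abort(paste0("Unknown entity_class: ", paste(bad_class, collapse = ", ")))
  }
  ns <- ifelse(entries$entity_class == "GENE", "gene:", "disease:")
  if (any(substr(entries$concept_id, 1L, nchar(ns)) != ns)) {
    abort("concept_id namespace must match entity_class (gene:<id> / disease:<CUI>).")
  }
  cls_per_id <- tapply(entries$entity_class, entries$concept_id,
                       function(x) length(unique(x)))
  if (any(cls_per_id > 1L)) {
    abort("A concept_id maps to more than one entity_class.")
  }
  st <- entries$semantic_types[!is.na(entries$semantic_types) & nzchar(entries$semantic_types)]
  if (length(st)) {
    codes <- unique(unlist(strsplit(st, ";", fixed = TRUE)))
    bad <- setdiff(codes, .disease_semtypes)
    if (length(bad)) {
      abort(paste0("Semantic types outside the disease set: ", paste(bad, collapse = ", ")))
    }
  }
  invisible(entries)
}

#' @export
print.marker_lexicon <- function(x, ...) {
  cat(sprintf(
    "<marker_lexicon> %d concepts, %d entries (%s)\n",
    dplyr::n_distinct(x$concept_id), nrow(x),
    paste(unique(x$entity_class), collapse = "+")
  ))
  NextMethod()
}

#' Curate and extend a lexicon
#'
#' Applies the dictionary curation rules: bracketed affix labels are removed;
#' terms shorter than three characters are dropped (short acronyms are too
#' ambiguous to match); surface variants are generated (acronym separators
#' for genes, Arabic/Roman numerals, Greek names/glyphs); every entry is
#' normalized (diacritic folding, lowercasing, punctuation removal); entries
#' whose normalized form is on the generic-term blocklist are dropped; and
#' duplicate (normalized, concept) pairs are collapsed. The length threshold
#' is applied to the label-stripped source surface, before variant
#' generation.
#'
#' @param lex A [lexicon()].
#' @param blocklist Character vector of very general terms to remove
#'   (e.g. "disease", "syndrome"); compared on normalized forms.
#' @return A curated `marker_lexicon`; generated entries carry provenance
#'   `"GENERATED_VARIANT"`.
#' @export
curate_lexicon <- function(lex, blocklist = character()) {
  stopifnot(inherits(lex, "marker_lexicon"))
  if (nrow(lex) == 0L) return(lex)
  blocklist <- if (length(blocklist)) normalize_term(blocklist) else character()

  base <- lex |>
    mutate(surface = strip_affix_labels(.data$surface)) |>
    filter(nchar(.data$surface) >= 3L)
  if (nrow(base) == 0L) {
    return(lexicon(base |> mutate(normalized = character(0))))
  }

  expanded <- base |>
    mutate(.variants = map2(.data$surface, .data$entity_class, term_variants)) |>
    tidyr::unnest(.variants, keep_empty = FALSE) |>
    mutate(
      provenance = ifelse(.data$.variants == .data$surface,
                          .data$provenance, "GENERATED_VARIANT"),
      surface = .data$.variants
    ) |>
    select(-".variants") |>
    mutate(normalized = normalize_term(.data$surface)) |>
    filter(nzchar(.data$normalized), !(.data$normalized %in% blocklist)) |>
    arrange(.data$concept_id, .data$normalized,
            match(.data$provenance, c("SOURCE", "GENERATED_VARIANT"))) |>
    distinct(.data$concept_id, .data$normalized, .keep_all = TRUE)

  lexicon(expanded)
}

#' Build a lexicon by cross-reference integration of source vocabularies
#'
#' Source vocabulary rows that cite each other through cross-references
#' describe the same concept: all rows in a connected component of the
#' cross-reference graph collapse into a single concept carrying the union
#' of their terms. Rows without links become singleton concepts. When one
#' source contributes two or more distinct identifiers to a single component
#' the links are contradictory; the union is still taken and a warning is
#' emitted.
#'
#' @param tables A data frame (or list of data frames, row-bound) with
#'   columns `source`, `source_id`, `term`, `xrefs` (semicolon-joined
#'   `source:source_id` keys, possibly empty) and optionally
#'   `semantic_type`.
#' @param entity_class `"GENE"` or `"DISEASE"`.
#' @param id_source Source whose identifiers name the merged concepts
#'   (e.g. `"ncbi_gene"`); defaults to the first source appearing in the
#'   table. Components without a row from `id_source` fall back to the
#'   first row in the component.
#' @return A `marker_lexicon` with provenance `"SOURCE"` for every entry.
#' @export
merge_sources <- function(tables, entity_class = c("GENE", "DISEASE"),
                          id_source = NULL) {
  entity_class <- match.arg(entity_class)
  if (is.data.frame(tables)) tables <- list(tables)
  rows <- bind_rows(lapply(tables, as_tibble))
  required <- c("source", "source_id", "term", "xrefs")
  missing <- setdiff(required, names(rows))
  if (length(missing)) {
    abort(paste0("Source table is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (nrow(rows) == 0L) {
    return(lexicon(tibble(
      concept_id = character(), entity_class = character(),
      preferred_name = character(), surface = character()
    )))
  }
  id_source <- id_source %||% rows$source[1]

  node_key <- paste0(rows$source, ":", rows$source_id)
  nodes <- unique(node_key)
  edge_list <- purrr::map2(node_key, rows$xrefs, function(from, xr) {
    if (is.na(xr) || !nzchar(xr)) return(NULL)
    to <- strsplit(xr, ";", fixed = TRUE)[[1]]
    to <- trimws(to[nzchar(trimws(to))])
    if (!length(to)) return(NULL)
    cbind(from, to)
  })
  edges <- do.call(rbind, edge_list)
  all_nodes <- unique(c(nodes, if (!is.null(edges)) as.vector(edges)))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(all_nodes), name = all_nodes)
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, t(matrix(match(edges, all_nodes), ncol = 2)))
  }
  comp <- igraph::components(g)$membership
  rows$component <- comp[match(node_key, all_nodes)]

  # contradictory cross-references: one source, two ids, same component
  clash <- rows |>
    distinct(.data$component, .data$source, .data$source_id) |>
    count(.data$component, .data$source) |>
    filter(.data$n > 1L)
  if (nrow(clash)) {
    warn(sprintf(
      "Cross-references merge %d distinct identifier(s) from a single source; union taken.",
      nrow(clash)
    ))
  }

  prefix <- if (entity_class == "GENE") "gene:" else "disease:"
  concepts <- rows |>
    group_by(.data$component) |>
    summarise(
      concept_id = {
        pick_row <- which(.data$source == id_source)
        idx <- if (length(pick_row)) pick_row[1] else 1L
        paste0(prefix, .data$source_id[idx])
      },
      preferred_name = {
        pick_row <- which(.data$source == id_source)
        idx <- if (length(pick_row)) pick_row[1] else 1L
        .data$term[idx]
      },
      .groups = "drop"
    )

  entries <- rows |>
    left_join(concepts, by = "component") |>
    transmute(
      concept_id = .data$concept_id,
      entity_class = entity_class,
      preferred_name = .data$preferred_name,
      semantic_types = if ("semantic_type" %in% names(rows)) {
        .data$semantic_type
      } else {
        NA_character_
      },
      surface = .data$term
    ) |>
    distinct()
  lexicon(entries)
}

#' Summary statistics of a lexicon
#'
#' Ambiguity is the mean, over distinct normalized terms, of the number of
#' concepts each term maps to; it quantifies how often one term can refer to
#' several concepts. Variability is the mean, over concepts, of the number
#' of distinct normalized terms per concept; a curation process should raise
#' variability while keeping ambiguity near 1.
#'
#' @param lex A non-empty [lexicon()].
#' @return A one-row tibble with `n_concepts`, `n_terms` (distinct
#'   normalized terms), `n_entries` (distinct term-concept pairs),
#'   `ambiguity`, and `variability`.
#' @export
lexicon_stats <- function(lex) {
  stopifnot(inherits(lex, "marker_lexicon"))
  if (nrow(lex) == 0L) abort("Cannot compute statistics of an empty lexicon.")
  incidence <- distinct(lex, .data$normalized, .data$concept_id)
  per_term <- count(incidence, .data$normalized)
  per_concept <- count(incidence, .data$concept_id)
  tibble(
    n_concepts = nrow(per_concept),
    n_terms = nrow(per_term),
    n_entries = nrow(incidence),
    ambiguity = mean(per_term$n),
    variability = mean(per_concept$n)
  )
}

#' Read a source vocabulary table
#'
#' Expects a TSV with header columns `source`, `source_id`, `term`, `xrefs`
#' (semicolon-separated cross-reference keys) and optionally
#' `semantic_type`, as exported from gene/disease vocabularies.
#'
#' @param path Path to the TSV file.
#' @return A tibble suitable for [merge_sources()].
#' @export
read_source_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

#' Read and write lexicons as TSV
#'
#' The on-disk format has one row per entry with columns `concept_id`,
#' `entity_class`, `preferred_name`, `semantic_types`, `surface`,
#' `normalized`, `provenance`.
#'
#' @param path File path.
#' @return `read_lexicon_tsv()` returns a `marker_lexicon`;
#'   `write_lexicon_tsv()` returns `lex` invisibly.
#' @export
read_lexicon_tsv <- function(path) {
  lexicon(readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  ))
}

#' @param lex A `marker_lexicon`.
#' @rdname read_lexicon_tsv
#' @export
write_lexicon_tsv <- function(lex, path) {
  stopifnot(inherits(lex, "marker_lexicon"))
  readr::write_tsv(as_tibble(unclass_lexicon(lex)), path, progress = FALSE)
  invisible(lex)
}

unclass_lexicon <- function(lex) {
  class(lex) <- setdiff(class(lex), "marker_lexicon")
  lex
}

#' Read a one-term-per-line word list
#'
#' Used for stop words, biomarker trigger terms, and the generic-term
#' blocklist. Blank lines and `#` comments are ignored; terms are returned
#' in normalized form.
#'
#' @param path Path to a UTF-8 text file, one term per line.
#' @return Character vector of normalized terms.
#' @export
read_term_file <- function(path) {
  x <- readr::read_lines(path, progress = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(normalize_term(x))
}
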