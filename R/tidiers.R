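#' Tidy a ranked association table
#'
#' Returns the association records as a plain tibble with a `rank` column,
#' one row per disease-gene pair in score order.
#'
#' @param x A `marker_associations` object from [score_associations()].
#' @param ... Unused.
#' @return A tibble: `rank`, `disease_id`, `gene_id`, `n_abstracts`, `idf`,
#'   `af_sum`, `score`.
#' @exportS3Method generics::tidy
tidy.marker_associations <- function(x, ...) {
  as_tibble(x) |>
    mutate(rank = row_number(), .before = 1L)
}

#' Glance at a ranked association table
#'
#' @param x A `marker_associations` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_associations`, `n_genes`, `n_diseases`,
#'   `n_abstracts` (the `|A|` used in the idf), `top_score`.
#' @exportS3Method generics::glance
glance.marker_associations <- function(x, ...) {
  tibble(
    n_associations = nrow(x),
    n_genes = n_distinct(x$gene_id),
    n_diseases = n_distinct(x$disease_id),
    n_abstracts = attr(x, "n_total_abstracts"),
    top_score = if (nrow(x)) max(x$score) else NA_real_
  )
}

#' Tidy a lexicon
#'
#' @param x A `marker_lexicon`.
#' @param ... Unused.
#' @return The entry table as a plain tibble.
#' @exportS3Method generics::tidy
tidy.marker_lexicon <- function(x, ...) {
  as_tibble(unclass_lexicon(x))
}

#' Glance at a lexicon
#'
#' @param x A `marker_lexicon`.
#' @param ... Unused.
#' @return The one-row tibble of [lexicon_stats()].
#' @exportS3Method generics::glance
glance.marker_lexicon <- function(x, ...) {
  lexicon_stats(x)
}
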