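#' Bibliometric summaries of a corpus and its co-occurrences
#'
#' Summarizes where and when the literature reports candidate biomarker
#' information: publications and distinct journals per year, and per
#' journal the total co-occurrences, distinct disease-gene associations,
#' distinct diseases and distinct biomarker genes extracted from its
#' abstracts.
#'
#' @param docs A document tibble from [read_corpus()].
#' @param cooccs Optional co-occurrence tibble from
#'   [extract_cooccurrences()]; when `NULL` (or empty) all per-journal
#'   association counts are zero.
#' @return An object of class `marker_bibliometrics`: a list with tibbles
#'   `by_year` (`year`, `n_publications`, `n_journals`) and `by_journal`
#'   (`journal`, `n_cooccurrences`, `n_associations`, `n_diseases`,
#'   `n_genes`).
#' @export
bibliometrics <- function(docs, cooccs = NULL) {
  by_year <- docs |>
    filter(!is.na(.data$year)) |>
    group_by(.data$year) |>
    summarise(
      n_publications = n(),
      n_journals = n_distinct(.data$journal),
      .groups = "drop"
    ) |>
    arrange(.data$year)
  journals <- docs |> distinct(.data$journal) |> arrange(.data$journal)
  if (is.null(cooccs) || nrow(cooccs) == 0L) {
    by_journal <- journals |>
      mutate(n_cooccurrences = 0L, n_associations = 0L,
             n_diseases = 0L, n_genes = 0L)
  } else {
    per_journal <- cooccs |>
      left_join(select(docs, "pmid", "journal"), by = "pmid") |>
      group_by(.data$journal) |>
      summarise(
        n_cooccurrences = n(),
        n_associations = n_distinct(paste(.data$disease_id, .data$gene_id)),
        n_diseases = n_distinct(.data$disease_id),
        n_genes = n_distinct(.data$gene_id),
        .groups = "drop"
      )
    by_journal <- journals |>
      left_join(per_journal, by = "journal") |>
      mutate(across(c("n_cooccurrences", "n_associations", "n_diseases", "n_genes"),
                    \(x) tidyr::replace_na(x, 0L)))
  }
  structure(list(by_year = by_year, by_journal = arrange(by_journal, desc(.data$n_cooccurrences), .data$journal)),
            class = "marker_bibliometrics")
}

#' @export
print.marker_bibliometrics <- function(x, ...) {
  cat(sprintf("<marker_bibliometrics> %d year(s), %d journal(s)\n",
              nrow(x$by_year), nrow(x$by_journal)))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.marker_bibliometrics <- function(object, ...) {
  scale <- max(1, max(object$by_year$n_publications)) /
    max(1, max(object$by_year$n_journals))
  ggplot2::ggplot(object$by_year, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$n_publications), fill = "grey55") +
    ggplot2::geom_line(ggplot2::aes(y = .data$n_journals * scale), linewidth = 0.8) +
    ggplot2::scale_y_continuous(
      "Publications",
      sec.axis = ggplot2::sec_axis(~ . / scale, name = "Journals")
    ) +
    ggplot2::labs(x = "Year") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.marker_associations <- function(object, top_n = 20, ...) {
  dat <- head(as_tibble(object), top_n) |>
    mutate(pair = paste(.data$disease_id, .data$gene_id, sep = " × "))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$score,
                                    y = stats::reorder(.data$pair, .data$score))) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "Score", y = NULL,
                  title = sprintf("Top %d disease-biomarker associations", nrow(dat))) +
    ggplot2::theme_minimal()
}
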