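#' Extract sentence-level disease-gene co-occurrences
#'
#' A disease and a gene are candidate associates when they are mentioned in
#' the same sentence. For every sentence the Cartesian product of its
#' distinct disease concepts and distinct gene concepts is emitted, each
#' pair at most once per sentence; an ambiguous mention contributes each of
#' its candidate concepts once.
#'
#' @param mentions A mention tibble from [tag_corpus()] containing both
#'   entity classes.
#' @return A tibble with columns `pmid`, `section`, `sentence_index`,
#'   `disease_id`, `gene_id`.
#' @export
extract_cooccurrences <- function(mentions) {
  empty <- tibble(
    pmid = character(), section = character(), sentence_index = integer(),
    disease_id = character(), gene_id = character()
  )
  if (nrow(mentions) == 0L) return(empty)
  flat <- mentions |>
    select("pmid", "section", "sentence_index", "entity_class", "concept_ids") |>
    tidyr::unnest("concept_ids") |>
    rename(concept_id = "concept_ids") |>
    distinct()
  genes <- flat |>
    filter(.data$entity_class == "GENE") |>
    select("pmid", "section", "sentence_index", gene_id = "concept_id")
  diseases <- flat |>
    filter(.data$entity_class == "DISEASE") |>
    select("pmid", "section", "sentence_index", disease_id = "concept_id")
  if (nrow(genes) == 0L || nrow(diseases) == 0L) return(empty)
  diseases |>
    inner_join(genes, by = c("pmid", "section", "sentence_index"),
               relationship = "many-to-many") |>
    distinct() |>
    select("pmid", "section", "sentence_index", "disease_id", "gene_id") |>
    arrange(.data$pmid, match(.data$section, c("TITLE", "BODY", "CONCLUSIONS")),
            .data$sentence_index, .data$disease_id, .data$gene_id)
}

#' Per-abstract weighted association frequency
#'
#' The within-abstract frequency f of a disease-gene pair counts the
#' sentences of that abstract in which the pair co-occurs, weighting each
#' sentence by its section: a co-occurrence in the title or conclusions
#' carries weight 2 (the default), one in the body weight 1, reflecting
#' that titles and closing statements carry the message of a publication
#' most concisely.
#'
#' @param cooccs A co-occurrence tibble from [extract_cooccurrences()]
#'   (one or several abstracts).
#' @param weight_title_conclusions Weight for TITLE/CONCLUSIONS sentences
#'   (body sentences always weigh 1).
#' @return A tibble with columns `pmid`, `disease_id`, `gene_id`, `f`.
#' @export
abstract_frequency <- function(cooccs, weight_title_conclusions = 2) {
  stopifnot(weight_title_conclusions > 0)
  cooccs |>
    mutate(w = ifelse(.data$section %in% c("TITLE", "CONCLUSIONS"),
                      weight_title_conclusions, 1)) |>
    group_by(.data$pmid, .data$disease_id, .data$gene_id) |>
    summarise(f = sum(.data$w), .groups = "drop")
}

#' Score and rank disease-gene associations
#'
#' Associations are ranked by a section-weighted inverse document frequency
#' score. With `A` the set of abstracts containing at least one
#' co-occurrence, a pair DB is scored
#'
#' \deqn{Score_{DB} = idf(DB, A) \cdot \sum_i af(DB, A_i)}
#'
#' where \eqn{idf(DB, A) = \log_{10}(|A| / |\{a \in A : DB \in a\}|)}
#' down-weights ubiquitous pairs, and the per-abstract frequency
#' \eqn{af(DB, A_i) = f(DB, A_i) / \max\{f(XY, A_i) : XY \in A_i\}}
#' normalizes the weighted sentence count of [abstract_frequency()] by the
#' most frequent pair of the same abstract. Records are sorted by score
#' (descending), ties broken by abstract count (descending) then by
#' disease and gene identifier.
#'
#' @inheritParams abstract_frequency
#' @param idf_base Logarithm base of the idf term.
#' @param n_total Total abstract count `|A|`; defaults to the number of
#'   distinct abstracts in `cooccs`. Supply a larger value to score against
#'   a wider document selection.
#' @return A tibble of class `marker_associations` with columns
#'   `disease_id`, `gene_id`, `n_abstracts`, `idf`, `af_sum`, `score`.
#' @export
score_associations <- function(cooccs, weight_title_conclusions = 2,
                               idf_base = 10, n_total = NULL) {
  if (nrow(cooccs) == 0L) abort("No co-occurrences to score.")
  freq <- abstract_frequency(cooccs, weight_title_conclusions)
  n_total <- n_total %||% n_distinct(freq$pmid)
  af <- freq |>
    group_by(.data$pmid) |>
    mutate(af = .data$f / max(.data$f)) |>
    ungroup()
  out <- af |>
    group_by(.data$disease_id, .data$gene_id) |>
    summarise(
      n_abstracts = n_distinct(.data$pmid),
      af_sum = sum(.data$af),
      .groups = "drop"
    ) |>
    mutate(
      idf = log(n_total / .data$n_abstracts, base = idf_base),
      score = .data$idf * .data$af_sum
    ) |>
    select("disease_id", "gene_id", "n_abstracts", "idf", "af_sum", "score") |>
    arrange(desc(.data$score), desc(.data$n_abstracts),
            .data$disease_id, .data$gene_id)
  structure(out, class = c("marker_associations", class(out)),
            n_total_abstracts = n_total,
            weight_title_conclusions = weight_title_conclusions,
            idf_base = idf_base)
}

#' @export
print.marker_associations <- function(x, ...) {
  cat(sprintf("<marker_associations> %d associations over %d abstracts\n",
              nrow(x), attr(x, "n_total_abstracts")))
  NextMethod()
}

#' Specificity profiles of associations
#'
#' A biomarker studied against a single disease is highly specific; one
#' associated with hundreds of diseases (IL6-like immune genes) is not —
#' and symmetrically for diseases. Returns, for each gene, the number of
#' distinct associated diseases, and for each disease the number of
#' distinct associated genes.
#'
#' @param records An association tibble (`marker_associations` or any table
#'   with `disease_id` and `gene_id` columns).
#' @return A list with tibbles `by_gene` (`gene_id`, `n_diseases`) and
#'   `by_disease` (`disease_id`, `n_genes`), each sorted by count
#'   (descending) then identifier.
#' @export
specificity_profiles <- function(records) {
  records <- as_tibble(records)
  by_gene <- records |>
    group_by(.data$gene_id) |>
    summarise(n_diseases = n_distinct(.data$disease_id), .groups = "drop") |>
    arrange(desc(.data$n_diseases), .data$gene_id)
  by_disease <- records |>
    group_by(.data$disease_id) |>
    summarise(n_genes = n_distinct(.data$gene_id), .groups = "drop") |>
    arrange(desc(.data$n_genes), .data$disease_id)
  list(by_gene = by_gene, by_disease = by_disease)
}

#' Overlap of extracted associations with a reference table
#'
#' Compares the extracted disease-gene pairs with an external association
#' resource (a curated gene-disease database export) and reports the
#' fraction of extracted pairs present in the reference — overall, and per
#' disease class when a class mapping is supplied.
#'
#' @param records An association tibble with `disease_id` and `gene_id`.
#' @param reference A data frame with columns `disease_id` and `gene_id`.
#' @param class_map Optional data frame mapping `disease_id` to
#'   `disease_class`.
#' @return A list with `overall` (one-row tibble: `n_extracted`,
#'   `n_in_reference`, `overlap`) and `by_class` (per-class tibble, or
#'   `NULL` when no `class_map` given). Overlap fractions are in `[0, 1]`.
#' @export
overlap_with_reference <- function(records, reference, class_map = NULL) {
  records <- as_tibble(records)
  reference <- as_tibble(reference)
  if (!all(c("disease_id", "gene_id") %in% names(reference))) {
    abort("`reference` must have columns disease_id and gene_id.")
  }
  pairs <- distinct(records, .data$disease_id, .data$gene_id)
  ref <- distinct(reference, .data$disease_id, .data$gene_id)
  pairs$in_ref <- vctrs_in(pairs, ref)
  overall <- tibble(
    n_extracted = nrow(pairs),
    n_in_reference = sum(pairs$in_ref),
    overlap = if (nrow(pairs)) mean(pairs$in_ref) else NA_real_
  )
  by_class <- NULL
  if (!is.null(class_map)) {
    class_map <- as_tibble(class_map)
    if (!all(c("disease_id", "disease_class") %in% names(class_map))) {
      abort("`class_map` must have columns disease_id and disease_class.")
    }
    by_class <- pairs |>
      inner_join(class_map, by = "disease_id",
                 relationship = "many-to-many") |>
      group_by(.data$disease_class) |>
      summarise(
        n_extracted = n(),
        n_in_reference = sum(.data$in_ref),
        overlap = mean(.data$in_ref),
        .groups = "drop"
      ) |>
      arrange(.data$disease_class)
  }
  list(overall = overall, by_class = by_class)
}

# row-wise membership of (disease_id, gene_id) pairs
vctrs_in <- function(pairs, ref) {
  paste(pairs$disease_id, pairs$gene_id, sep = "\r") %in%
    paste(ref$disease_id, ref$gene_id, sep = "\r")
}

#' Export associations to TSV
#'
#' Optionally joins human-readable names from the lexicons used.
#'
#' @param records A `marker_associations` tibble.
#' @param path Output path.
#' @param gene_lexicon,disease_lexicon Optional lexicons supplying
#'   `gene_symbol` and `disease_name` columns.
#' @return `records`, invisibly.
#' @export
write_associations_tsv <- function(records, path,
                                   gene_lexicon = NULL, disease_lexicon = NULL) {
  out <- as_tibble(records)
  if (!is.null(disease_lexicon)) {
    nm <- distinct(as_tibble(disease_lexicon), .data$concept_id, .data$preferred_name)
    out <- left_join(out, rename(nm, disease_id = "concept_id",
                                 disease_name = "preferred_name"),
                     by = "disease_id")
  }
  if (!is.null(gene_lexicon)) {
    nm <- distinct(as_tibble(gene_lexicon), .data$concept_id, .data$preferred_name)
    out <- left_join(out, rename(nm, gene_id = "concept_id",
                                 gene_symbol = "preferred_name"),
                     by = "gene_id")
  }
  front <- intersect(c("disease_id", "disease_name", "gene_id", "gene_symbol",
                       "n_abstracts", "idf", "af_sum", "score"), names(out))
  readr::write_tsv(out[, front], path, progress = FALSE)
  invisible(records)
}
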