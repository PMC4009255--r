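#' Build a pipeline configuration
#'
#' Collects every input path and tunable of an end-to-end run. File-based
#' word lists default to the lists shipped with the package. The section
#' weight (2 for title/conclusions) and the idf logarithm base (10) default
#' to the published scoring model.
#'
#' @param corpus Path to the corpus file.
#' @param corpus_format `"tsv"`, `"pubmed_xml"` or `"nbib"`.
#' @param gene_lexicon,disease_lexicon Paths to lexicon TSVs
#'   ([write_lexicon_tsv()] format), already merged from their source
#'   vocabularies but not necessarily curated.
#' @param out_dir Output directory (created if absent).
#' @param stopwords,triggers,blocklist Paths to one-term-per-line files;
#'   `NULL` selects the packaged defaults.
#' @param weight_title_conclusions Section weight for title/conclusions
#'   sentences.
#' @param idf_base Logarithm base of the idf.
#' @param curate Whether to run [curate_lexicon()] on the input lexicons.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(corpus, gene_lexicon, disease_lexicon, out_dir,
                            corpus_format = "tsv", stopwords = NULL,
                            triggers = NULL, blocklist = NULL,
                            weight_title_conclusions = 2, idf_base = 10,
                            curate = TRUE) {
  stopifnot(weight_title_conclusions > 0, idf_base > 1)
  cfg <- list(
    corpus = corpus, corpus_format = corpus_format,
    gene_lexicon = gene_lexicon, disease_lexicon = disease_lexicon,
    out_dir = out_dir,
    stopwords = stopwords %||% system.file("extdata", "stopwords.txt",
                                           package = "markermine"),
    triggers = triggers %||% system.file("extdata", "triggers.txt",
                                         package = "markermine"),
    blocklist = blocklist %||% system.file("extdata", "blocklist.txt",
                                           package = "markermine"),
    weight_title_conclusions = weight_title_conclusions,
    idf_base = idf_base,
    curate = curate
  )
  inputs <- c("corpus", "gene_lexicon", "disease_lexicon",
              "stopwords", "triggers", "blocklist")
  for (f in inputs) {
    if (!file.exists(cfg[[f]])) abort(sprintf("Config input `%s` not found: %s", f, cfg[[f]]))
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Path to a YAML/JSON file whose keys match the arguments of
#'   [pipeline_config()]. Relative paths are resolved against the config
#'   file's directory.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base <- dirname(normalizePath(path))
  for (f in c("corpus", "gene_lexicon", "disease_lexicon", "out_dir",
              "stopwords", "triggers", "blocklist")) {
    if (!is.null(raw[[f]]) && !grepl("^/", raw[[f]])) {
      raw[[f]] <- file.path(base, raw[[f]])
    }
  }
  do.call(pipeline_config, raw)
}

#' Run the full extraction pipeline
#'
#' Executes curate-lexicons, read-corpus, tag, biomarker-filter, re-tag
#' with the biomarker-specific dictionaries, extract co-occurrences, score,
#' and report, writing every result as TSV plus a JSON manifest with input
#' checksums, the configuration hash and per-stage record counts. Identical
#' configuration and inputs produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (a list; also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }

  stopwords <- read_term_file(config$stopwords)
  triggers <- read_term_file(config$triggers)
  blocklist <- read_term_file(config$blocklist)

  gene_lex <- stage("build-lexicon", {
    lx <- read_lexicon_tsv(config$gene_lexicon)
    if (config$curate) curate_lexicon(lx, blocklist) else lx
  })
  disease_lex <- stage("build-lexicon", {
    lx <- read_lexicon_tsv(config$disease_lexicon)
    if (config$curate) curate_lexicon(lx, blocklist) else lx
  })

  docs <- stage("read-corpus", read_corpus(config$corpus, config$corpus_format))
  counts <- list(documents = nrow(docs))
  if (nrow(docs) == 0L) {
    return(invisible(write_empty_outputs(config, gene_lex, disease_lex, counts)))
  }
  sents <- stage("segment", corpus_sentences(docs))
  counts$sentences <- nrow(sents)

  gene_idx <- compile_patterns(gene_lex, stopwords)
  disease_idx <- compile_patterns(disease_lex, stopwords)
  mentions_full <- stage("tag", tag_corpus(sents, gene_idx, disease_idx))

  trig_sents <- stage("filter-biomarker", find_trigger_sentences(sents, triggers))
  gene_bm <- filter_lexicon(gene_lex, mentions_full, trig_sents)
  disease_bm <- filter_lexicon(disease_lex, mentions_full, trig_sents)
  counts$trigger_sentences <- nrow(trig_sents)
  counts$biomarker_genes <- n_distinct(gene_bm$concept_id)
  counts$biomarker_diseases <- n_distinct(disease_bm$concept_id)

  mentions <- if (nrow(gene_bm) && nrow(disease_bm)) {
    stage("tag", tag_corpus(sents,
                            compile_patterns(gene_bm, stopwords),
                            compile_patterns(disease_bm, stopwords)))
  } else {
    mentions_full[0L, , drop = FALSE]
  }
  counts$mentions <- nrow(mentions)

  cooccs <- stage("extract", extract_cooccurrences(mentions))
  counts$cooccurrences <- nrow(cooccs)
  counts$abstracts_with_cooccurrence <- n_distinct(cooccs$pmid)

  assoc <- if (nrow(cooccs)) {
    stage("score", score_associations(
      cooccs,
      weight_title_conclusions = config$weight_title_conclusions,
      idf_base = config$idf_base
    ))
  } else {
    NULL
  }
  counts$associations <- if (is.null(assoc)) 0L else nrow(assoc)

  biblio <- stage("report", bibliometrics(docs, cooccs))

  o <- function(f) file.path(config$out_dir, f)
  write_lexicon_tsv(gene_lex, o("gene_lexicon_curated.tsv"))
  write_lexicon_tsv(disease_lex, o("disease_lexicon_curated.tsv"))
  write_lexicon_tsv(gene_bm, o("gene_lexicon_biomarker.tsv"))
  write_lexicon_tsv(disease_bm, o("disease_lexicon_biomarker.tsv"))
  write_mentions_tsv(mentions, o("mentions.tsv"))
  readr::write_tsv(cooccs, o("cooccurrences.tsv"), progress = FALSE)
  if (!is.null(assoc)) {
    write_associations_tsv(assoc, o("associations.tsv"),
                           gene_lexicon = gene_lex, disease_lexicon = disease_lex)
  } else {
    readr::write_tsv(
      tibble(disease_id = character(), gene_id = character(),
             n_abstracts = integer(), idf = double(), af_sum = double(),
             score = double()),
      o("associations.tsv"), progress = FALSE
    )
  }
  readr::write_tsv(biblio$by_year, o("bibliometrics_by_year.tsv"), progress = FALSE)
  readr::write_tsv(biblio$by_journal, o("bibliometrics_by_journal.tsv"), progress = FALSE)

  manifest <- build_manifest(config, counts)
  jsonlite::write_json(manifest, o("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

write_empty_outputs <- function(config, gene_lex, disease_lex, counts) {
  o <- function(f) file.path(config$out_dir, f)
  write_lexicon_tsv(gene_lex, o("gene_lexicon_curated.tsv"))
  write_lexicon_tsv(disease_lex, o("disease_lexicon_curated.tsv"))
  empty_assoc <- tibble(
    disease_id = character(), gene_id = character(), n_abstracts = integer(),
    idf = double(), af_sum = double(), score = double()
  )
  readr::write_tsv(empty_assoc, o("associations.tsv"), progress = FALSE)
  counts <- utils::modifyList(
    list(documents = 0L, sentences = 0L, trigger_sentences = 0L,
         biomarker_genes = 0L, biomarker_diseases = 0L, mentions = 0L,
         cooccurrences = 0L, abstracts_with_cooccurrence = 0L,
         associations = 0L),
    counts
  )
  manifest <- build_manifest(config, counts)
  jsonlite::write_json(manifest, o("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

build_manifest <- function(config, counts) {
  inputs <- c("corpus", "gene_lexicon", "disease_lexicon",
              "stopwords", "triggers", "blocklist")
  checksums <- vapply(inputs, function(f) {
    unname(tools::md5sum(config[[f]]))
  }, character(1))
  list(
    package = "markermine",
    version = as.character(utils::packageVersion("markermine")),
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    input_md5 = as.list(checksums),
    counts = counts
  )
}
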