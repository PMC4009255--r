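#' Simulate gene and disease lexicons with known structure
#'
#' Builds synthetic lexicons whose shape exercises every curation path:
#' acronym-style gene symbols (letter block + digit block), multi-word
#' names with Arabic numerals (Roman-variant cases), a Greek-letter synonym
#' on the first gene, and optional deliberately shared terms for ambiguity
#' tests. Concept stems are invented pseudo-words, disjoint between genes
#' and diseases, so fixture sentences cannot collide with dictionary terms
#' by accident. Construction is fully deterministic.
#'
#' @param n_genes,n_diseases Number of concepts per class (each >= 1).
#' @param shared_terms Number of synonyms shared between consecutive gene
#'   pairs (creates terms with 2 candidate concepts; ambiguity > 1).
#' @return A list with `marker_lexicon` elements `genes` and `diseases`.
#' @export
sim_lexicons <- function(n_genes = 6, n_diseases = 6, shared_terms = 0) {
  stopifnot(n_genes >= 1, n_diseases >= 1, shared_terms >= 0,
            shared_terms <= max(0, n_genes - 1))
  stems <- fixture_stems(n_genes + n_diseases)
  gene_stems <- stems[seq_len(n_genes)]
  disease_stems <- stems[n_genes + seq_len(n_diseases)]

  gene_rows <- purrr::imap(gene_stems, function(stem, i) {
    surfaces <- c(
      sprintf("GMK%d", i),                 # acronym: letter block + digits
      sprintf("%s kinase %d", stem, i)     # long name with numeral
    )
    if (i == 1L) surfaces <- c(surfaces, sprintf("%s-alpha", stem))
    tibble(
      concept_id = sprintf("gene:%d", 1000L + i),
      entity_class = "GENE",
      preferred_name = sprintf("GMK%d", i),
      surface = surfaces
    )
  })
  genes <- bind_rows(gene_rows)
  if (shared_terms > 0L) {
    shared <- purrr::map(seq_len(shared_terms), function(k) {
      tibble(
        concept_id = sprintf("gene:%d", 1000L + c(k, k + 1L)),
        entity_class = "GENE",
        preferred_name = sprintf("GMK%d", c(k, k + 1L)),
        surface = sprintf("SHRD%d", k)
      )
    })
    genes <- bind_rows(genes, bind_rows(shared))
  }

  disease_rows <- purrr::imap(disease_stems, function(stem, j) {
    tibble(
      concept_id = sprintf("disease:C%07d", 5000000L + j),
      entity_class = "DISEASE",
      preferred_name = sprintf("%s disorder type %d", stem, j),
      semantic_types = "T047",
      surface = c(
        sprintf("%s disorder type %d", stem, j),
        sprintf("%s disorder", stem)
      )
    )
  })
  diseases <- bind_rows(disease_rows)

  list(genes = lexicon(genes), diseases = lexicon(diseases))
}

# deterministic pool of pronounceable pseudo-word stems
fixture_stems <- function(n) {
  syl1 <- c("vel", "dan", "quo", "zeph", "mir", "kol", "fex", "tuv", "rax",
            "bem", "cyt", "ulv", "pram", "jol", "wex", "hil", "ovr", "nub")
  syl2 <- c("mora", "trix", "line", "rab", "tase", "dane", "arin", "alon",
            "ide", "olin", "rane", "exa", "era", "onib", "vane", "astin")
  pool <- as.vector(outer(syl1, syl2, paste0))
  if (n > length(pool)) abort("Requested more stems than the fixture pool provides.")
  pool[seq_len(n)]
}

.fixture_fillers <- c(
  "Patients were enrolled and samples were collected.",
  "Results were evaluated and findings are reported.",
  "Additional measurements were performed at follow up."
)
.fixture_titles <- c(
  "A prospective study of clinical outcomes.",
  "An observational cohort evaluation."
)
.fixture_journals <- c(
  "J Synth Med", "Ann Fixture Res", "Clin Test Rep", "Int J Mock Biol",
  "Synth Biomark Q"
)

#' Simulate a corpus of abstracts with planted mentions and ground truth
#'
#' Emits template abstracts (title, body, optional conclusions) embedding
#' dictionary terms at controlled per-abstract rates, together with the
#' ground-truth mention and pair tables, so the full
#' lexicon/NER/relation-extraction pipeline can be validated end to end.
#' For each abstract and each (disease, gene) pair, the pair co-occurs in
#' one sentence with probability `pair_rate` (or the matching cell of a
#' rate matrix); that sentence lands in the title, body or conclusions with
#' probabilities `p_title`, `1 - p_title - p_conclusions`,
#' `p_conclusions`, and carries a biomarker trigger term with probability
#' `trigger_rate`. Default placement probabilities (0.10 / 0.85 / 0.05)
#' follow the section distribution observed in biomarker abstracts.
#' Template sentences are verified not to contain any dictionary term
#' outside the planted slots.
#'
#' @param lexicons A list with `genes` and `diseases` lexicons, as from
#'   [sim_lexicons()].
#' @param n_abstracts Number of abstracts.
#' @param p_title,p_conclusions Section placement probabilities
#'   (`p_title + p_conclusions <= 1`).
#' @param pair_rate Background probability that a given pair appears in a
#'   given abstract; scalar, or a `n_diseases x n_genes` matrix of rates
#'   (rows = diseases, columns = genes, in lexicon order).
#' @param signal_pair Optional `c(disease_id, gene_id)` planted at
#'   `signal_rate` instead of the background rate.
#' @param signal_rate Rate for `signal_pair`; defaults to `10 * pair_rate`.
#' @param trigger_rate Probability that a pair sentence carries a biomarker
#'   trigger term.
#' @param p_lone_gene Probability that an abstract contains one extra
#'   gene-only sentence (mention without co-occurrence).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A list: `documents` (corpus tibble), `truth_mentions`
#'   (`pmid`, `section`, `sentence_index`, `entity_class`, `concept_id`),
#'   `truth_pairs` (`pmid`, `section`, `sentence_index`, `disease_id`,
#'   `gene_id`, `trigger`).
#' @export
sim_corpus <- function(lexicons, n_abstracts = 50, p_title = 0.10,
                       p_conclusions = 0.05, pair_rate = 0.02,
                       signal_pair = NULL, signal_rate = NULL,
                       trigger_rate = 0.5, p_lone_gene = 0.3, seed = 1) {
  stopifnot(p_title >= 0, p_conclusions >= 0, p_title + p_conclusions <= 1,
            trigger_rate >= 0, trigger_rate <= 1, n_abstracts >= 1)
  genes <- plantable_entries(lexicons$genes)
  diseases <- plantable_entries(lexicons$diseases)
  gene_ids <- unique(genes$concept_id)
  disease_ids <- unique(diseases$concept_id)
  rates <- build_rate_matrix(pair_rate, disease_ids, gene_ids,
                             signal_pair, signal_rate)
  verify_templates(c(.fixture_fillers, .fixture_titles),
                   c(lexicons$genes$normalized, lexicons$diseases$normalized))

  withr::with_seed(seed, {
    docs <- vector("list", n_abstracts)
    men <- vector("list", n_abstracts)
    prs <- vector("list", n_abstracts)
    for (i in seq_len(n_abstracts)) {
      pmid <- sprintf("PM%05d", i)
      pairs <- which(matrix(stats::runif(length(rates)), nrow(rates)) < rates,
                     arr.ind = TRUE)
      sect <- character(0)
      txt <- character(0)
      trig <- logical(0)
      d_id <- character(0)
      g_id <- character(0)
      g_surf <- character(0)
      d_surf <- character(0)
      if (nrow(pairs)) {
        for (k in seq_len(nrow(pairs))) {
          did <- disease_ids[pairs[k, 1L]]
          gid <- gene_ids[pairs[k, 2L]]
          gs <- pick_surface(genes, gid)
          ds <- pick_surface(diseases, did)
          has_trigger <- stats::runif(1) < trigger_rate
          sentence <- cap_first(if (has_trigger) {
            sprintf("%s is a promising biomarker for %s.", gs, ds)
          } else {
            sprintf("%s expression was altered in %s.", gs, ds)
          })
          sect <- c(sect, sample(c("TITLE", "BODY", "CONCLUSIONS"), 1L,
                                 prob = c(p_title, 1 - p_title - p_conclusions,
                                          p_conclusions)))
          txt <- c(txt, sentence)
          trig <- c(trig, has_trigger)
          d_id <- c(d_id, did)
          g_id <- c(g_id, gid)
          g_surf <- c(g_surf, gs)
          d_surf <- c(d_surf, ds)
        }
      }
      lone <- stats::runif(1) < p_lone_gene
      lone_gid <- if (lone) sample(gene_ids, 1L) else NA_character_
      lone_txt <- if (lone) {
        sprintf("Levels of %s were measured at baseline.",
                pick_surface(genes, lone_gid))
      } else {
        character(0)
      }

      title_sents <- txt[sect == "TITLE"]
      if (!length(title_sents)) {
        title_sents <- sample(.fixture_titles, 1L)
      }
      body_sents <- c(txt[sect == "BODY"], lone_txt,
                      sample(.fixture_fillers, 2L))
      conc_sents <- txt[sect == "CONCLUSIONS"]

      docs[[i]] <- tibble(
        pmid = pmid,
        year = sample(1990:2013, 1L),
        journal = sample(.fixture_journals, 1L),
        title = paste(title_sents, collapse = " "),
        body = paste(body_sents, collapse = " "),
        conclusions = paste(conc_sents, collapse = " ")
      )

      # sentence indices within each section, in emission order
      sent_index <- integer(length(txt))
      for (s in c("TITLE", "BODY", "CONCLUSIONS")) {
        sent_index[sect == s] <- seq_len(sum(sect == s)) - 1L
      }
      if (length(txt)) {
        prs[[i]] <- tibble(
          pmid = pmid, section = sect, sentence_index = sent_index,
          disease_id = d_id, gene_id = g_id, trigger = trig
        )
        men[[i]] <- bind_rows(
          tibble(pmid = pmid, section = sect, sentence_index = sent_index,
                 entity_class = "GENE", concept_id = g_id),
          tibble(pmid = pmid, section = sect, sentence_index = sent_index,
                 entity_class = "DISEASE", concept_id = d_id)
        )
      }
      if (lone) {
        men[[i]] <- bind_rows(men[[i]], tibble(
          pmid = pmid, section = "BODY",
          sentence_index = sum(sect == "BODY"),
          entity_class = "GENE", concept_id = lone_gid
        ))
      }
    }
    truth_mentions <- distinct(bind_rows(men))
    truth_pairs <- distinct(bind_rows(prs))
    if (nrow(truth_mentions) == 0L) {
      truth_mentions <- tibble(
        pmid = character(), section = character(), sentence_index = integer(),
        entity_class = character(), concept_id = character()
      )
    }
    if (nrow(truth_pairs) == 0L) {
      truth_pairs <- tibble(
        pmid = character(), section = character(), sentence_index = integer(),
        disease_id = character(), gene_id = character(), trigger = logical()
      )
    }
    list(
      documents = bind_rows(docs),
      truth_mentions = truth_mentions,
      truth_pairs = truth_pairs
    )
  })
}

# entries safe to plant: normalized form maps to exactly one concept
plantable_entries <- function(lex) {
  if (nrow(lex) == 0L) abort("Cannot plant from an empty lexicon.")
  shared <- lex |>
    distinct(.data$normalized, .data$concept_id) |>
    count(.data$normalized) |>
    filter(.data$n > 1L)
  out <- lex |> filter(!(.data$normalized %in% shared$normalized))
  if (nrow(out) == 0L) abort("No unambiguous entries available for planting.")
  out
}

pick_surface <- function(entries, id) {
  s <- entries$surface[entries$concept_id == id]
  s[sample.int(length(s), 1L)]
}

build_rate_matrix <- function(pair_rate, disease_ids, gene_ids,
                              signal_pair, signal_rate) {
  if (is.matrix(pair_rate)) {
    stopifnot(nrow(pair_rate) == length(disease_ids),
              ncol(pair_rate) == length(gene_ids))
    rates <- pair_rate
  } else {
    rates <- matrix(pair_rate, length(disease_ids), length(gene_ids))
  }
  if (!is.null(signal_pair)) {
    di <- match(signal_pair[1], disease_ids)
    gi <- match(signal_pair[2], gene_ids)
    if (is.na(di) || is.na(gi)) abort("signal_pair not found in the lexicons.")
    rates[di, gi] <- signal_rate %||% (10 * rates[di, gi])
  }
  stopifnot(all(rates >= 0), all(rates <= 1))
  rates
}

# templates must not contain any dictionary term at token boundaries
verify_templates <- function(templates, normalized_terms) {
  tpl <- normalize_term(templates)
  for (term in unique(normalized_terms)) {
    hit <- stringr::str_detect(tpl, paste0("(^| )", escape_regex(term), "( |$)"))
    if (any(hit)) {
      abort(sprintf("Fixture template collides with dictionary term '%s'.", term))
    }
  }
  invisible(TRUE)
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# abstracts capitalize sentence-initial words; matching is case-folded anyway
cap_first <- function(x) {
  paste0(toupper(substr(x, 1L, 1L)), substr(x, 2L, nchar(x)))
}
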