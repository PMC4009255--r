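# Independent oracles and shared fixtures for the test suite.

# ---- brute-force leftmost-longest matcher -----------------------------------
# Enumerates every token span of `sentence` (already normalized, single-space
# separated) that equals a pattern, then applies greedy leftmost-longest
# selection. Independent of the package's scanning matcher.
bf_match <- function(sentence, patterns) {
  if (!nzchar(sentence)) return(character())
  toks <- strsplit(sentence, " ", fixed = TRUE)[[1]]
  n <- length(toks)
  cand <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      key <- paste(toks[i:j], collapse = " ")
      if (key %in% patterns) {
        cand[[length(cand) + 1L]] <- c(start = i, end = j)
      }
    }
  }
  if (!length(cand)) return(character())
  cand <- do.call(rbind, cand)
  out <- character()
  pos <- 1L
  while (pos <= n) {
    here <- cand[cand[, "start"] == pos, , drop = FALSE]
    if (nrow(here)) {
      best <- here[which.max(here[, "end"]), ]
      out <- c(out, paste(toks[best["start"]:best["end"]], collapse = " "))
      pos <- best[["end"]] + 1L
    } else {
      pos <- pos + 1L
    }
  }
  out
}

# random sentence/pattern instances over a plain lowercase vocabulary
# (normalization is the identity there, isolating the matching logic)
random_ner_instance <- function() {
  vocab <- c("apo", "bri", "cor", "dul", "eme", "fas", "gli", "hap",
             "ixo", "jun", "kel", "lom")
  n_pat <- sample(2:8, 1)
  patterns <- unique(replicate(n_pat, {
    paste(sample(vocab, sample(1:3, 1), replace = TRUE), collapse = " ")
  }))
  sentence <- paste(sample(vocab, sample(3:20, 1), replace = TRUE), collapse = " ")
  list(patterns = patterns, sentence = sentence)
}

# build a marker_index straight from normalized pattern strings
index_from_patterns <- function(patterns, entity_class = "GENE") {
  prefix <- if (entity_class == "GENE") "gene:" else "disease:"
  lex <- lexicon(tibble::tibble(
    concept_id = paste0(prefix, seq_along(patterns)),
    entity_class = entity_class,
    preferred_name = patterns,
    surface = patterns
  ))
  compile_patterns(lex)
}

# ---- brute-force association scorer -----------------------------------------
# Literal loop implementation of the section-weighted idf scoring model,
# computed per abstract and per pair with no shared code with the package.
bf_score <- function(cooccs, weight = 2, base = 10) {
  cooccs <- as.data.frame(cooccs)
  pmids <- unique(cooccs$pmid)
  n_total <- length(pmids)
  pair_key <- paste(cooccs$disease_id, cooccs$gene_id, sep = "|")
  pairs <- unique(pair_key)
  f <- matrix(0, nrow = length(pairs), ncol = n_total,
              dimnames = list(pairs, pmids))
  for (r in seq_len(nrow(cooccs))) {
    w <- if (cooccs$section[r] %in% c("TITLE", "CONCLUSIONS")) weight else 1
    f[pair_key[r], cooccs$pmid[r]] <- f[pair_key[r], cooccs$pmid[r]] + w
  }
  res <- data.frame(pair = pairs, n_abstracts = NA_real_, idf = NA_real_,
                    af_sum = NA_real_, score = NA_real_)
  for (p in seq_along(pairs)) {
    af_sum <- 0
    n_abs <- 0
    for (a in seq_len(n_total)) {
      if (f[p, a] > 0) {
        n_abs <- n_abs + 1
        af_sum <- af_sum + f[p, a] / max(f[, a])
      }
    }
    res$n_abstracts[p] <- n_abs
    res$idf[p] <- log(n_total / n_abs, base = base)
    res$af_sum[p] <- af_sum
    res$score[p] <- res$idf[p] * af_sum
  }
  res$disease_id <- sub("\\|.*$", "", res$pair)
  res$gene_id <- sub("^.*\\|", "", res$pair)
  res[order(res$disease_id, res$gene_id),
      c("disease_id", "gene_id", "n_abstracts", "idf", "af_sum", "score")]
}

# random sentence-level co-occurrence sets over small entity inventories
random_cooccs <- function(max_abstracts = 20, max_entities = 6) {
  n_abs <- sample(2:max_abstracts, 1)
  n_d <- sample(2:max_entities, 1)
  n_g <- sample(2:max_entities, 1)
  rows <- list()
  for (i in seq_len(n_abs)) {
    n_sent <- sample(1:4, 1)
    for (s in seq_len(n_sent)) {
      sec <- sample(c("TITLE", "BODY", "BODY", "CONCLUSIONS"), 1)
      n_pairs <- sample(0:3, 1)
      if (n_pairs == 0) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        pmid = sprintf("PM%03d", i),
        section = sec,
        sentence_index = s - 1L,
        disease_id = sprintf("disease:C%d", sample(n_d, n_pairs, replace = TRUE)),
        gene_id = sprintf("gene:%d", sample(n_g, n_pairs, replace = TRUE))
      )
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(
      pmid = "PM001", section = "BODY", sentence_index = 0L,
      disease_id = "disease:C1", gene_id = "gene:1"
    ))
  }
  dplyr::distinct(dplyr::bind_rows(rows))
}

# ---- worked example: published co-occurrence sentences ----------------------
# Seven abstracts whose sentences (quoted from the cited PMIDs) each contain
# a disease-gene co-occurrence next to a biomarker trigger term, with the
# section each sentence appeared in.
worked_example <- function() {
  filler <- "Supplementary measurements are described."
  docs <- tibble::tibble(
    pmid = c("17726078", "17397492", "19119429", "21740336", "21751783",
             "21732548", "21748260"),
    year = c(2007L, 2007L, 2008L, 2011L, 2011L, 2011L, 2012L),
    journal = rep("Example J", 7L),
    title = c(
      "Anti-Mullerian hormone is a sensitive serum marker for gonadal function in women treated for Hodgkin's lymphoma during childhood.",
      "Urine cytology study.",
      "Neurodevelopmental screening study.",
      "Kidney outcome study.",
      "Top-down quantitative proteomics identified phosphorylation of cardiac troponin I as a candidate biomarker for chronic heart failure.",
      "Immunohistochemistry panel study.",
      "Serum oxidative stress study."
    ),
    body = c(
      filler,
      filler,
      "To investigate levels of brain-derived neurotrophic factor (BDNF) in midpregnancy and neonatal blood specimens as early biologic markers for autism; we conducted a population-based case-control study nested within the cohort of infants born from July 2000 to September 2001 to women who participated in the prenatal screening program in Orange County, CA.",
      "Neutrophil gelatinase-associated lipocalin (NGAL) and netrin-1 have been proposed over the past years as emergent biomarkers for the early and accurate diagnosis and monitoring of acute kidney injury (AKI).",
      filler,
      "MOC-31 is an established immunologic marker to detect adenocarcinomas.",
      "Hence, serum ROM level may be a useful biomarker for staging of lung adenocarcinoma."
    ),
    conclusions = c(
      "",
      "CK20 is an important biomarker that can be used to identify TCC in urine cytology smears.",
      "", "", "", "", ""
    )
  )

  genes <- lexicon(tibble::tibble(
    concept_id = paste0("gene:", c(268, 268, 54474, 627, 627, 3934, 3934,
                                   9423, 7137, 4072, 6094)),
    entity_class = "GENE",
    preferred_name = c("AMH", "AMH", "CK20", "BDNF", "BDNF", "NGAL", "NGAL",
                       "NTN1", "TNNI3", "EPCAM", "ROM"),
    surface = c("Anti-Mullerian hormone", "AMH", "CK20",
                "brain-derived neurotrophic factor", "BDNF",
                "Neutrophil gelatinase-associated lipocalin", "NGAL",
                "netrin-1", "cardiac troponin I", "MOC-31", "ROM")
  ))
  diseases <- lexicon(tibble::tibble(
    concept_id = paste0("disease:", c("C0019829", "C1861305", "C0004352",
                                      "C0022660", "C0022660", "C0264716",
                                      "C0001418", "C0001418", "C0152013")),
    entity_class = "DISEASE",
    preferred_name = c("Hodgkin's lymphoma", "TCC", "Autism",
                       "Acute kidney injury", "Acute kidney injury",
                       "Chronic heart failure", "Adenocarcinoma",
                       "Adenocarcinoma", "Lung adenocarcinoma"),
    semantic_types = "T047",
    surface = c("Hodgkin's lymphoma", "TCC", "autism", "acute kidney injury",
                "AKI", "chronic heart failure", "adenocarcinoma",
                "adenocarcinomas", "lung adenocarcinoma")
  ))

  expected_pairs <- tibble::tibble(
    pmid = c("17726078", "17397492", "19119429", "21740336", "21740336",
             "21751783", "21732548", "21748260"),
    section = c("TITLE", "CONCLUSIONS", "BODY", "BODY", "BODY",
                "TITLE", "BODY", "BODY"),
    disease_id = paste0("disease:", c("C0019829", "C1861305", "C0004352",
                                      "C0022660", "C0022660", "C0264716",
                                      "C0001418", "C0152013")),
    gene_id = paste0("gene:", c(268, 54474, 627, 3934, 9423, 7137, 4072, 6094))
  )
  list(docs = docs, genes = genes, diseases = diseases,
       expected_pairs = expected_pairs)
}

# run the standard extraction stages on a fixture
run_extraction <- function(docs, gene_lex, disease_lex,
                           stopwords = default_stopwords(),
                           triggers = default_triggers(),
                           blocklist = default_blocklist()) {
  cg <- curate_lexicon(gene_lex, blocklist)
  cd <- curate_lexicon(disease_lex, blocklist)
  sents <- corpus_sentences(docs)
  mentions <- tag_corpus(sents, compile_patterns(cg, stopwords),
                         compile_patterns(cd, stopwords))
  trig <- find_trigger_sentences(sents, triggers)
  gene_bm <- filter_lexicon(cg, mentions, trig)
  disease_bm <- filter_lexicon(cd, mentions, trig)
  mentions_bm <- if (nrow(gene_bm) && nrow(disease_bm)) {
    tag_corpus(sents, compile_patterns(gene_bm, stopwords),
               compile_patterns(disease_bm, stopwords))
  } else {
    mentions[0L, , drop = FALSE]
  }
  list(
    sentences = sents, mentions = mentions, trigger_sentences = trig,
    gene_bm = gene_bm, disease_bm = disease_bm, mentions_bm = mentions_bm,
    cooccs = extract_cooccurrences(mentions_bm)
  )
}
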