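toy_lexicon <- function(surfaces, class = "GENE", ids = NULL) {
  prefix <- if (class == "GENE") "gene:" else "disease:C"
  if (is.null(ids)) ids <- paste0(prefix, seq_along(surfaces))
  lexicon(tibble::tibble(
    concept_id = ids, entity_class = class,
    preferred_name = surfaces, surface = surfaces
  ))
}

test_that("lexicon validates identifier namespaces and semantic types", {
  expect_s3_class(toy_lexicon(c("abc", "def")), "marker_lexicon")
  expect_error(
    lexicon(tibble::tibble(concept_id = "disease:C1", entity_class = "GENE",
                           preferred_name = "x", surface = "abc")),
    "namespace"
  )
  expect_error(
    lexicon(tibble::tibble(concept_id = "disease:C1", entity_class = "DISEASE",
                           preferred_name = "x", surface = "abc",
                           semantic_types = "T999")),
    "emantic"
  )
})

test_that("curation enforces the 3-character length floor", {
  lens <- c("a", "ab", "abc", "abcd", "abcde", "abcdef")
  cur <- curate_lexicon(toy_lexicon(lens))
  survivors <- unique(cur$surface[cur$provenance == "SOURCE"])
  expect_identical(min(nchar(survivors)), 3L)
  expect_false(any(c("a", "ab") %in% cur$surface))
})

test_that("curation removes blocklisted generic terms and deduplicates", {
  lex <- toy_lexicon(c("disease", "crohn disease"), class = "DISEASE")
  cur <- curate_lexicon(lex, blocklist = c("disease"))
  expect_false("disease" %in% cur$normalized)
  expect_true("crohn disease" %in% cur$normalized)
  expect_identical(anyDuplicated(paste(cur$normalized, cur$concept_id)), 0L)
  # empty in, empty out
  empty <- lexicon(toy_lexicon("abc")[0L, ])
  expect_identical(nrow(curate_lexicon(empty)), 0L)
})

test_that("curation strips labels, expands variants, never loses source terms", {
  lex <- lexicon(tibble::tibble(
    concept_id = c("disease:C1", "gene:2"),
    entity_class = c("DISEASE", "GENE"),
    preferred_name = c("Gastric neurosis", "IL2"),
    surface = c("[X]Gastric neurosis", "IL2")
  ))
  cur <- curate_lexicon(lex)
  expect_true("gastric neurosis" %in% cur$normalized)
  expect_true(all(c("il2", "il 2") %in% cur$normalized))
  expect_true(all(cur$provenance[cur$surface == "IL 2"] == "GENERATED_VARIANT"))
  # source entries surviving the filters are a subset of the input entries
  n_source_surfaces <- dplyr::n_distinct(cur$surface[cur$provenance == "SOURCE"])
  expect_lte(n_source_surfaces, nrow(lex))
})

test_that("cross-referenced source rows merge into single concepts", {
  t1 <- tibble::tibble(source = "ncbi_gene", source_id = "3934",
                       term = "LCN2", xrefs = "hgnc:6526")
  t2 <- tibble::tibble(source = "hgnc", source_id = "6526",
                       term = "Lipocalin-2", xrefs = "ncbi_gene:3934")
  merged <- merge_sources(list(t1, t2), "GENE", id_source = "ncbi_gene")
  expect_identical(dplyr::n_distinct(merged$concept_id), 1L)
  expect_identical(unique(merged$concept_id), "gene:3934")
  expect_setequal(merged$surface, c("LCN2", "Lipocalin-2"))

  # no cross-references: separate concepts
  t3 <- tibble::tibble(source = "src", source_id = c("1", "2"),
                       term = c("abc", "def"), xrefs = c("", ""))
  expect_identical(dplyr::n_distinct(merge_sources(t3, "GENE")$concept_id), 2L)

  # transitive links a -> b -> c collapse to one concept
  tc <- tibble::tibble(
    source = c("s1", "s2", "s3"), source_id = c("a", "b", "c"),
    term = c("t1", "t2", "t3"),
    xrefs = c("s2:b", "s3:c", "")
  )
  expect_identical(dplyr::n_distinct(merge_sources(tc, "GENE")$concept_id), 1L)
})

test_that("contradictory cross-references union with a warning", {
  tt <- tibble::tibble(
    source = c("s1", "s2", "s2"), source_id = c("a", "b", "c"),
    term = c("t1", "t2", "t3"),
    xrefs = c("s2:b;s2:c", "", "")
  )
  expect_warning(merged <- merge_sources(tt, "GENE"), "single source")
  expect_identical(dplyr::n_distinct(merged$concept_id), 1L)
  expect_setequal(merged$surface, c("t1", "t2", "t3"))
})

test_that("merged concept count equals connected components (union-find oracle)", {
  uf_components <- function(n, edges) {
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    if (nrow(edges)) {
      for (r in seq_len(nrow(edges))) {
        ra <- find(edges[r, 1]); rb <- find(edges[r, 2])
        if (ra != rb) parent[ra] <- rb
      }
    }
    length(unique(vapply(seq_len(n), find, integer(1))))
  }
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    n_edges <- sample(0:n, 1)
    edges <- if (n_edges) {
      cbind(sample(n, n_edges, replace = TRUE), sample(n, n_edges, replace = TRUE))
    } else {
      matrix(integer(), ncol = 2)
    }
    edges <- edges[!duplicated(edges) & edges[, 1] != edges[, 2], , drop = FALSE]
    xrefs <- vapply(seq_len(n), function(i) {
      to <- edges[edges[, 1] == i, 2]
      paste(sprintf("src:%d", to), collapse = ";")
    }, character(1))
    tab <- tibble::tibble(
      source = "src", source_id = as.character(seq_len(n)),
      term = sprintf("term%d", seq_len(n)), xrefs = xrefs
    )
    parent <- seq_len(n)
    merged <- suppressWarnings(merge_sources(tab, "GENE"))
    expect_identical(
      dplyr::n_distinct(merged$concept_id),
      uf_components(n, edges)
    )
  }
})

test_that("ambiguity and variability match hand-enumerated incidences", {
  # 2 concepts, 3 distinct terms, one term shared by both concepts:
  # 4 incidences / 3 terms = 4/3 ambiguity; 4 / 2 concepts = 2.0 variability
  lex <- lexicon(tibble::tibble(
    concept_id = c("gene:1", "gene:1", "gene:2", "gene:2"),
    entity_class = "GENE",
    preferred_name = c("g1", "g1", "g2", "g2"),
    surface = c("shared term", "only one", "shared term", "only two")
  ))
  st <- lexicon_stats(lex)
  expect_equal(st$ambiguity, 4 / 3)
  expect_equal(st$variability, 2.0)
  expect_identical(st$n_concepts, 2L)
  expect_identical(st$n_terms, 3L)

  # a new unambiguous synonym raises variability, leaves ambiguity unchanged
  lex2 <- lexicon(dplyr::bind_rows(
    tibble::as_tibble(lex),
    tibble::tibble(concept_id = "gene:1", entity_class = "GENE",
                   preferred_name = "g1", surface = "brand new synonym")
  ))
  st2 <- lexicon_stats(lex2)
  expect_gt(st2$variability, st$variability)
  expect_equal(st2$ambiguity, (5 / 4))
  expect_error(lexicon_stats(lexicon(tibble::as_tibble(lex)[0L, ])), "empty")
})

test_that("lexicon statistics equal brute-force counts on random toy lexicons", {
  set.seed(41)
  for (rep in 1:15) {
    n_concepts <- sample(2:50, 1)
    n_terms <- sample(2:30, 1)
    terms <- sprintf("term %d", seq_len(n_terms))
    rows <- tibble::tibble(
      concept_id = sprintf("gene:%d", sample(n_concepts, n_concepts * 2, replace = TRUE)),
      term = sample(terms, n_concepts * 2, replace = TRUE)
    ) |> dplyr::distinct()
    lex <- lexicon(tibble::tibble(
      concept_id = rows$concept_id, entity_class = "GENE",
      preferred_name = rows$concept_id, surface = rows$term
    ))
    st <- lexicon_stats(lex)
    inc <- unique(data.frame(t = normalize_term(rows$term), c = rows$concept_id))
    expect_equal(st$ambiguity, nrow(inc) / length(unique(inc$t)))
    expect_equal(st$variability, nrow(inc) / length(unique(inc$c)))
  }
})

test_that("lexicon TSV round trips through disk", {
  lex <- curate_lexicon(toy_lexicon(c("IL2", "TP53", "netrin-1")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon_tsv(lex, path)
  back <- read_lexicon_tsv(path)
  expect_identical(as.data.frame(back), as.data.frame(lex))
})
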