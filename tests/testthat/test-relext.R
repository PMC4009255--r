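mention_row <- function(pmid, section, idx, class, ids) {
  tibble::tibble(
    pmid = pmid, section = section, sentence_index = idx,
    char_start = 0L, char_end = 1L, surface = "x",
    entity_class = class, concept_ids = list(ids),
    ambiguous = length(ids) > 1L
  )
}

test_that("co-occurrences are the per-sentence disease x gene product", {
  we <- worked_example()
  ex <- run_extraction(we$docs, we$genes, we$diseases)
  ngal <- ex$cooccs[ex$cooccs$pmid == "21740336", ]
  expect_identical(nrow(ngal), 2L)
  expect_setequal(ngal$gene_id, c("gene:3934", "gene:9423"))
  expect_identical(unique(ngal$disease_id), "disease:C0022660")

  # genes only: nothing to pair
  m <- mention_row("1", "BODY", 0L, "GENE", "gene:1")
  expect_identical(nrow(extract_cooccurrences(m)), 0L)

  # 2 diseases x 2 genes in one sentence: 4 pairs
  m2 <- dplyr::bind_rows(
    mention_row("1", "BODY", 0L, "GENE", "gene:1"),
    mention_row("1", "BODY", 0L, "GENE", "gene:2"),
    mention_row("1", "BODY", 0L, "DISEASE", "disease:C1"),
    mention_row("1", "BODY", 0L, "DISEASE", "disease:C2")
  )
  expect_identical(nrow(extract_cooccurrences(m2)), 4L)

  # an ambiguous mention contributes each candidate concept once
  m3 <- dplyr::bind_rows(
    mention_row("1", "BODY", 0L, "GENE", c("gene:1", "gene:2")),
    mention_row("1", "BODY", 0L, "DISEASE", "disease:C1")
  )
  expect_identical(nrow(extract_cooccurrences(m3)), 2L)
})

test_that("section weighting doubles title and conclusion frequencies", {
  co <- tibble::tibble(
    pmid = c("a", "b", "c", "c"),
    section = c("TITLE", "BODY", "TITLE", "BODY"),
    sentence_index = 0L,
    disease_id = "disease:C1", gene_id = "gene:1"
  )
  f <- abstract_frequency(co)
  expect_identical(f$f[f$pmid == "a"], 2)   # once in title
  expect_identical(f$f[f$pmid == "b"], 1)   # once in body
  expect_identical(f$f[f$pmid == "c"], 3)   # title + body
  co_c <- dplyr::mutate(co, section = "CONCLUSIONS")
  expect_true(all(abstract_frequency(co_c)$f[1:2] == 2))
  # weight is configurable
  expect_identical(abstract_frequency(co, weight_title_conclusions = 5)$f[1], 5)
})

test_that("idf boundary cases behave as the model dictates", {
  # pair present in every abstract: idf = 0, score = 0
  co <- tibble::tibble(
    pmid = sprintf("PM%d", 1:4), section = "BODY", sentence_index = 0L,
    disease_id = "disease:C1", gene_id = "gene:1"
  )
  a <- score_associations(co)
  expect_equal(a$idf, 0)
  expect_equal(a$score, 0)

  # 10 abstracts, pair in exactly one: idf = log10(10) = 1
  co2 <- dplyr::bind_rows(
    tibble::tibble(pmid = sprintf("PM%02d", 1:10), section = "BODY",
                   sentence_index = 0L,
                   disease_id = "disease:C2", gene_id = "gene:2"),
    tibble::tibble(pmid = "PM01", section = "BODY", sentence_index = 1L,
                   disease_id = "disease:C3", gene_id = "gene:3")
  )
  a2 <- score_associations(co2)
  rare <- a2[a2$disease_id == "disease:C3", ]
  expect_equal(rare$idf, 1.0)
  expect_error(score_associations(co[0L, ]), "No co-occurrences")
})

test_that("scores match the brute-force scorer on random corpora", {
  set.seed(71)
  for (rep in 1:20) {
    co <- random_cooccs()
    got <- dplyr::arrange(tibble::as_tibble(score_associations(co)),
                          disease_id, gene_id)
    want <- bf_score(co)
    expect_equal(got$n_abstracts, as.integer(want$n_abstracts))
    expect_equal(got$idf, want$idf, tolerance = 1e-12)
    expect_equal(got$af_sum, want$af_sum, tolerance = 1e-12)
    expect_equal(got$score, want$score, tolerance = 1e-12)
  }
})

test_that("per-abstract af normalization peaks at exactly 1", {
  set.seed(81)
  for (rep in 1:10) {
    co <- random_cooccs()
    f <- abstract_frequency(co)
    af <- f |>
      dplyr::group_by(pmid) |>
      dplyr::summarise(m = max(f / max(f)))
    expect_true(all(af$m == 1))
    a <- score_associations(co)
    expect_true(all(abs(a$score - a$idf * a$af_sum) < 1e-9))
    expect_true(all(a$n_abstracts >= 1L))
    expect_true(all(a$idf >= 0))
  }
})

test_that("an additional supporting abstract never lowers af_sum", {
  co <- tibble::tibble(
    pmid = c("PM1", "PM2", "PM2"), section = "BODY", sentence_index = c(0L, 0L, 1L),
    disease_id = c("disease:C1", "disease:C1", "disease:C2"),
    gene_id = c("gene:1", "gene:1", "gene:2")
  )
  base <- tibble::as_tibble(score_associations(co))
  extra <- dplyr::bind_rows(co, tibble::tibble(
    pmid = "PM3", section = "BODY", sentence_index = 0L,
    disease_id = "disease:C1", gene_id = "gene:1"
  ))
  more <- tibble::as_tibble(score_associations(extra))
  pick <- function(d) d[d$disease_id == "disease:C1", ]
  expect_gte(pick(more)$af_sum, pick(base)$af_sum)
})

test_that("ranking is deterministic with documented tie-breaks", {
  co <- tibble::tibble(
    pmid = c("PM1", "PM1", "PM2", "PM2"),
    section = "BODY", sentence_index = c(0L, 1L, 0L, 1L),
    disease_id = c("disease:C2", "disease:C1", "disease:C2", "disease:C1"),
    gene_id = "gene:1"
  )
  a <- score_associations(co)
  # identical scores and abstract counts: lexicographic by disease then gene
  expect_identical(a$disease_id, c("disease:C1", "disease:C2"))
})

test_that("specificity profiles count distinct partners", {
  rec <- tibble::tibble(
    disease_id = c("disease:C1", "disease:C2", "disease:C3", "disease:C1"),
    gene_id = c("gene:1", "gene:1", "gene:1", "gene:2")
  )
  prof <- specificity_profiles(rec)
  expect_identical(prof$by_gene$n_diseases[prof$by_gene$gene_id == "gene:1"], 3L)
  expect_identical(prof$by_disease$n_genes[prof$by_disease$disease_id == "disease:C1"], 2L)
  empty <- specificity_profiles(rec[0L, ])
  expect_identical(nrow(empty$by_gene), 0L)
})

test_that("reference overlap reports overall and per-class fractions", {
  rec <- tibble::tibble(
    disease_id = c("disease:C1", "disease:C2"),
    gene_id = c("gene:1", "gene:2")
  )
  expect_equal(overlap_with_reference(rec, rec)$overall$overlap, 1)
  disjoint <- tibble::tibble(disease_id = "disease:C9", gene_id = "gene:9")
  expect_equal(overlap_with_reference(rec, disjoint)$overall$overlap, 0)
  half <- overlap_with_reference(rec, rec[1, ])
  expect_equal(half$overall$overlap, 0.5)

  cls <- tibble::tibble(disease_id = c("disease:C1", "disease:C2"),
                        disease_class = c("C04", "C10"))
  oc <- overlap_with_reference(rec, rec[1, ], class_map = cls)
  expect_equal(oc$by_class$overlap[oc$by_class$disease_class == "C04"], 1)
  expect_equal(oc$by_class$overlap[oc$by_class$disease_class == "C10"], 0)
  expect_error(overlap_with_reference(rec, tibble::tibble(x = 1)), "disease_id")
})
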