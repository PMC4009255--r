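# markermine

`markermine` builds disease–biomarker knowledge bases from literature
abstracts. It is aimed at biomedical text-mining practitioners and curators
who need to turn a corpus of abstracts (PubMed XML, MEDLINE nbib, or a plain
TSV export) plus gene/disease vocabularies into a ranked table of candidate
disease–gene biomarker associations, with every entity normalized to a
standard identifier (NCBI Gene ids for genes/proteins, UMLS CUIs for
diseases).

The pipeline is knowledge-driven rather than statistical:

1. **Lexicon construction and curation** — source vocabularies are
   integrated by cross-reference closure into unique concepts; terms are
   curated with rule-based filters (minimum length 3, diacritic folding,
   lowercasing, punctuation removal, bracketed-label stripping, a
   generic-term blocklist) and extended with surface variants (acronym
   separators `IL2 / IL 2 / IL-2 / IL(2)`, Arabic↔Roman numerals, Greek
   names↔glyphs). Dictionary quality is tracked with two statistics:
   *ambiguity* (mean concepts per distinct term) and *variability* (mean
   distinct terms per concept).
2. **Dictionary NER** — each sentence is normalized with the same pipeline
   as the dictionary and scanned left to right; at every token boundary the
   longest matching term wins, and each mention is normalized to its
   concept identifier(s).
3. **Biomarker trigger filtering** — only concepts co-mentioned in a
   sentence with a biomarker trigger term ("biomarker", "serum marker",
   ...; seeded from the MeSH *Biological Markers* entry terms) are kept,
   yielding biomarker-specific gene and disease dictionaries.
4. **Relation extraction and scoring** — a disease D and gene B are
   candidate associates when mentioned in the same sentence. With A the set
   of abstracts containing at least one co-occurrence, associations are
   ranked by a section-weighted inverse-document-frequency score

   ```
   Score_DB = idf(DB, A) * Σ_i af(DB, A_i)
   idf(DB, A) = log10( |A| / |{a ∈ A : DB ∈ a}| )
   af(DB, A_i) = f(DB, A_i) / max{ f(XY, A_i) : XY ∈ A_i }
   ```

   where `f(DB, A_i)` counts the sentences of abstract `A_i` containing the
   pair, weighted 2 in the title or conclusions and 1 in the body.

A synthetic fixture generator (`sim_lexicons()`, `sim_corpus()`) emits
template corpora with full ground truth, so the whole pipeline is testable
without licensed vocabulary or literature downloads.

## Worked example

```r
library(markermine)

lex <- sim_lexicons(n_genes = 4, n_diseases = 4)
fx  <- sim_corpus(lex, n_abstracts = 40,
                  signal_pair = c("disease:C5000001", "gene:1001"), seed = 7)

genes    <- curate_lexicon(lex$genes, default_blocklist())
diseases <- curate_lexicon(lex$diseases, default_blocklist())
sents    <- corpus_sentences(fx$documents)
mentions <- tag_corpus(sents, compile_patterns(genes, default_stopwords()),
                       compile_patterns(diseases, default_stopwords()))
trig     <- find_trigger_sentences(sents, default_triggers())
genes_bm    <- filter_lexicon(genes, mentions, trig)
diseases_bm <- filter_lexicon(diseases, mentions, trig)
mentions_bm <- tag_corpus(sents, compile_patterns(genes_bm, default_stopwords()),
                          compile_patterns(diseases_bm, default_stopwords()))
assoc <- score_associations(extract_cooccurrences(mentions_bm))
assoc
#> <marker_associations> 6 associations over 10 abstracts
#> # A tibble: 6 × 6
#>   disease_id       gene_id   n_abstracts   idf af_sum score
#> * <chr>            <chr>           <int> <dbl>  <dbl> <dbl>
#> 1 disease:C5000001 gene:1001           6 0.222    5.5  1.22
#> 2 disease:C5000004 gene:1002           2 0.699    1.5  1.05
#> 3 disease:C5000001 gene:1004           1 1        1    1
#> 4 disease:C5000003 gene:1001           1 1        1    1
#> 5 disease:C5000003 gene:1002           1 1        1    1
#> 6 disease:C5000004 gene:1004           1 1        1    1
```

The pair planted at ten times the background co-mention rate
(`disease:C5000001` × `gene:1001`) is supported by six of the ten
co-occurrence-bearing abstracts, so its idf is low (log10(10/6) ≈ 0.22) but
its accumulated normalized frequency (`af_sum` = 5.5) puts it first; the
background pairs each rest on a single abstract. `tidy()` and `glance()`
return the ranked table with ranks and the run summary:

```r
glance(assoc)
#> # A tibble: 1 × 5
#>   n_associations n_genes n_diseases n_abstracts top_score
#>            <int>   <int>      <int>       <int>     <dbl>
#> 1              6       3          3          10      1.22
```

`run_pipeline(pipeline_config(...))` performs all of the above from files
on disk and writes lexicons, mentions, co-occurrences, the association
table, bibliometric summaries and a JSON manifest;
`inst/scripts/markermine.R` is a thin command-line wrapper (`run` and
`fixtures` subcommands). For real corpora, the intended document selection
is a PubMed query restricting to abstracts annotated with the MeSH heading
"Biological Markers" (English, humans, with abstract text); the package
starts from the downloaded records.

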