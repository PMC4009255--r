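---
title: "Mining disease-biomarker associations from abstracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining disease-biomarker associations from abstracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markermine)
library(dplyr)
```

## The problem and the model

Biomarker findings are scattered across millions of abstracts in
heterogeneous wording: the same gene appears as `IL2`, `IL-2`, `IL 2` or
`interleukin 2`, and the same disease as `Sjögren-Larsson syndrome` or
`Sjogren-Larsson syndrome`. `markermine` implements a knowledge-driven
pipeline that (i) organizes that terminology into dictionaries of uniquely
identified concepts, (ii) recognizes and normalizes gene and disease
mentions in sentences, (iii) keeps only entities that the literature itself
labels as biomarker-related, and (iv) ranks candidate disease-gene
associations by a frequency model over the corpus.

The association model is a section-weighted variant of inverse document
frequency. Let $A$ be the set of abstracts containing at least one
disease-gene co-occurrence. For a disease-gene pair $DB$:

$$\mathrm{Score}_{DB} = \mathrm{idf}(DB, A)\cdot\sum_{i=1}^{|A|} \mathrm{af}(DB, A_i),
\qquad
\mathrm{idf}(DB, A) = \log_{10}\frac{|A|}{|\{a \in A : DB \in a\}|},$$

$$\mathrm{af}(DB, A_i) = \frac{f(DB, A_i)}{\max\{f(XY, A_i) : XY \in A_i\}},$$

where $f(DB, A_i)$ counts the sentences of abstract $A_i$ in which the pair
co-occurs, each sentence weighted by its section. The weight reflects a
structural fact about abstracts: the title and the conclusions state the
take-home message, while the body carries background and hypothesis, so a
title or conclusions co-occurrence counts double (the weight and the idf
base are arguments of `score_associations()` and `pipeline_config()`, with
defaults 2 and 10). The idf factor damps ubiquitous pairs: a pair present
in every abstract of $A$ scores exactly zero; a pair in one abstract out of
ten has idf 1. `af` normalizes within each abstract by its most frequent
pair, so each abstract contributes at most 1 per pair and prolific
abstracts do not dominate.

Two modelling choices deserve note. First, $f$ counts *sentences*
containing the pair, not mention-pair multiplicities within a sentence; a
sentence that repeats a gene twice next to one disease still counts once,
which avoids quadratic inflation from repeated mentions. The weighting is
per sentence, so a pair present in two title sentences contributes
$2 + 2$. Second, $|A|$ is the number of abstracts with at least one
co-occurrence, not the full document selection; the corpus the model
describes is the co-occurrence-bearing one. `score_associations(n_total =)`
accepts a larger selection count if the wider convention is wanted.

## Dictionary curation

A lexicon is a tidy table: one row per (concept, term entry), with
namespaced identifiers (`gene:<NCBI Gene id>`, `disease:<UMLS CUI>`).
`merge_sources()` integrates several source vocabularies by cross-reference
closure — rows connected through cross-references (directly or
transitively) collapse into one concept with the union of terms. When one
source contributes two distinct identifiers to a component the references
are contradictory; the union is still taken, with a warning.

`curate_lexicon()` applies the curation rules in a fixed order:

1. bracketed affix labels (`[X]...`, `... [Disease/Finding]`) are removed;
2. terms shorter than three characters are dropped — the threshold applies
   to the label-stripped *source* surface, before variant generation,
   because the rule targets over-short source acronyms, not generated
   separator variants;
3. surface variants are generated: acronym separator forms for gene
   symbols, Roman forms for standalone Arabic numerals, Greek
   name/glyph interconversion in both directions;
4. everything is normalized — diacritics folded, lowercased, punctuation
   replaced by spaces (each punctuation character becomes one space, then
   whitespace collapses, so `hnf-3-gamma` keeps its three tokens);
5. entries whose normalized form is on the generic-term blocklist
   (`disease`, `syndrome`, ...) are removed, and duplicate
   (normalized, concept) pairs collapse.

Roman conversion is limited to standalone tokens valued 1–30: digits
embedded in symbols (`CK20`) and large numbers (years, identifiers) are
left alone. Diacritic folding uses full Unicode Latin-to-ASCII
transliteration rather than a fixed character table, so the stated
examples (`à ö ç û`) and the rest of the Latin diacritic range fold
uniformly; Greek glyphs are letters, not symbols, and survive
normalization, which is what makes the glyph variants matchable.

`lexicon_stats()` reports ambiguity (mean concepts per distinct normalized
term) and variability (mean distinct normalized terms per concept), both
computed over the distinct term-concept incidence list. A good curation
pass raises variability while leaving ambiguity near 1. Ambiguity is
averaged over distinct terms, not term occurrences; with per-corpus
occurrence data unavailable at dictionary-build time, the distinct-term
mean is the definition that depends only on the dictionary.

## Recognition and filtering

`compile_patterns()` turns the distinct normalized terms into a hash over
token sequences (patterns equal to a stop word, or shorter than three
characters, are excluded). `tag_sentence()` normalizes the sentence with an
offset map back to the original text and scans left to right: at each
token boundary the longest matching pattern wins and scanning resumes
after it, so mentions of one entity class never overlap and
`acute lymphoblastic leukemia` shadows `leukemia`. Gene and disease
dictionaries are matched independently, so cross-class overlaps are
allowed. Surface variability is handled entirely by the curation-time
variant generation plus normalization — matching itself is exact, never
edit-distance, because approximate matching on three-letter gene acronyms
would multiply ambiguity. A term shared by several concepts yields one
mention carrying all candidate identifiers, flagged ambiguous; downstream
pairing counts each candidate concept once per sentence.

`find_trigger_sentences()` marks sentences containing a biomarker trigger
term at token boundaries, and `filter_lexicon()` keeps exactly the concepts
with at least one mention in a trigger sentence — the rationale being that
entities named next to "marker"-type words are very likely biomarkers. One
trigger co-mention anywhere in the corpus suffices (no minimum count), and
the trigger list ships as an editable file seeded with MeSH
"Biological Markers" entry-term variants. The pipeline then *re-tags* with
the filtered dictionaries rather than subsetting the first mention set:
with a smaller dictionary, a removed long term no longer shadows a shorter
retained one, so re-tagging is the faithful semantics.

## Corpus handling

Readers accept PubMed XML, MEDLINE nbib and a plain TSV fixture format.
Conclusions are located through structured-abstract labels only
(`CONCLUSION`, `CONCLUSIONS`, `INTERPRETATION`, from XML attributes or
inline `LABEL:` markers); unstructured abstracts are treated as body-only.
This is deterministic and testable, at the cost of missing conclusions
expressed without labels — a positional last-sentences heuristic was
considered and rejected because it misfiles body text unpredictably.
Sentence splitting is rule-based (terminal punctuation followed by a
sentence-initial shape, with an abbreviation guard list), with 0-based
half-open offsets per section that reconstruct the section text exactly;
a statistical splitter would segment slightly better but not
reproducibly across environments.

## The fixture generator

`sim_lexicons()` and `sim_corpus()` define the synthetic study conditions
used throughout the tests. The lexicons use invented pseudo-word stems,
disjoint between genes and diseases and absent from the sentence templates
(the generator verifies this before emitting), so recognition on fixtures
has no accidental matches by construction. The corpus plants each
disease-gene pair in an abstract with a background probability of 0.02 per
pair per abstract; planted sentences land in title/body/conclusions with
probabilities 0.10/0.85/0.05, matching the section distribution reported
for biomarker abstracts; half of the pair sentences carry a biomarker
trigger term (`trigger_rate = 0.5`, a neutral default exercising both
filter outcomes); and the default corpus size is 50 abstracts. The
planted-signal check plants one pair at ten times the background rate and
requires it to rank first. Fixtures emulate *placement*, not prose: real
abstracts bring spelling noise, abbreviation definitions, anaphora and
negation that templates do not, so passing fixture tests demonstrates the
mechanics of matching, weighting and ranking — not end-to-end recall or
precision on real literature.

## Numerical and degenerate-input behaviour

Scores factor exactly as `idf * af_sum` (checked to 1e-9 accumulation
tolerance); within every abstract the maximum `af` is exactly 1. Ranking
ties break by abstract count (descending), then disease and gene
identifier, making output byte-reproducible. Empty inputs are explicit:
scoring an empty co-occurrence set and computing statistics of an empty
lexicon are errors, while an empty corpus flows through `run_pipeline()`
to zero-row outputs and a manifest. Documents without abstract text are
skipped with a reported count.

Test and validation problem sizes are chosen to probe the combinatorics
rather than scale: matcher equivalence against a brute-force oracle uses
hundreds of random sentences over vocabularies of up to 8 patterns and 20
tokens; scoring equivalence uses dozens of random corpora of up to 20
abstracts and 6 entities per class; the planted-signal check uses 20
corpora of 50 abstracts.

## Known limitations

Sentence-level co-occurrence asserts relatedness, not direction or
certainty — a negated co-occurrence still counts, so a fraction of
extracted pairs are false positives; syntactic filtering is out of scope.
Corpus-scale dictionary statistics and association counts depend on the
vocabulary and literature snapshots used and are not reproducible from
fixtures. Abbreviation-definition detection and coreference are not
implemented; a gene defined in one sentence and abbreviated in the next is
only found where dictionary variants cover the abbreviation.
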