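#' Read a corpus of abstracts
#'
#' Supported formats:
#' * `tsv` — a delimited fixture/export format with header columns
#'   `pmid`, `year`, `journal`, `title`, `body`, `conclusions`;
#' * `pubmed_xml` — a `PubmedArticleSet` document; structured-abstract
#'   `AbstractText` labels are used to separate conclusions from body;
#' * `nbib` — MEDLINE nbib records (`PMID-`, `TI  -`, `AB  -`, `JT  -`,
#'   `DP  -` fields); inline structured labels such as "CONCLUSIONS:" are
#'   detected in the abstract text.
#'
#' Records without any abstract text are skipped; the number skipped is
#' reported via a message.
#'
#' @param path Path to the corpus file.
#' @param format One of `"tsv"`, `"pubmed_xml"`, `"nbib"`.
#' @return A tibble with one row per document: `pmid`, `year`, `journal`,
#'   `title`, `body`, `conclusions`.
#' @export
read_corpus <- function(path, format = c("tsv", "pubmed_xml", "nbib")) {
  format <- match.arg(format)
  docs <- switch(format,
    tsv = read_corpus_tsv(path),
    pubmed_xml = read_corpus_pubmed_xml(path),
    nbib = read_corpus_nbib(path)
  )
  empty <- !nzchar(paste0(docs$body, docs$conclusions))
  if (any(empty)) {
    inform(sprintf("Skipped %d record(s) without abstract text.", sum(empty)))
    docs <- docs[!empty, , drop = FALSE]
  }
  if (anyDuplicated(docs$pmid)) abort("Duplicate pmid in corpus.")
  if (any(!nzchar(docs$title))) abort("Documents must have a non-empty title.")
  bad_year <- !is.na(docs$year) & (docs$year < 1900L | docs$year > 2100L)
  if (any(bad_year)) abort("Document year outside 1900-2100.")
  docs
}

read_corpus_tsv <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      pmid = readr::col_character(),
      year = readr::col_integer(),
      .default = readr::col_character()
    ),
    na = character(),
    progress = FALSE
  ) |>
    mutate(across(c("journal", "title", "body", "conclusions"),
                  \(x) tidyr::replace_na(x, "")))
}

#' Write a corpus to the TSV fixture format
#'
#' @param docs A document tibble as returned by [read_corpus()].
#' @param path Output path.
#' @return `docs`, invisibly.
#' @export
write_corpus_tsv <- function(docs, path) {
  readr::write_tsv(docs, path, progress = FALSE)
  invisible(docs)
}

read_corpus_pubmed_xml <- function(path) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) abort(paste0("Malformed PubMed XML: ", conditionMessage(e)))
  )
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  rows <- lapply(arts, function(art) {
    pmid <- xml2::xml_text(xml2::xml_find_first(art, ".//MedlineCitation/PMID"))
    if (is.na(pmid) || !nzchar(pmid)) {
      abort("Malformed PubMed XML record: missing PMID.")
    }
    title <- xml2::xml_text(xml2::xml_find_first(art, ".//Article/ArticleTitle"))
    if (is.na(title)) {
      abort(paste0("Malformed PubMed XML record ", pmid, ": missing ArticleTitle."))
    }
    journal <- xml2::xml_text(xml2::xml_find_first(art, ".//Journal/Title"))
    year <- xml2::xml_text(xml2::xml_find_first(art, ".//JournalIssue/PubDate/Year"))
    segs <- xml2::xml_find_all(art, ".//Article/Abstract/AbstractText")
    seg_text <- xml2::xml_text(segs)
    seg_label <- xml2::xml_attr(segs, "Label")
    seg_label[is.na(seg_label)] <- xml2::xml_attr(segs, "NlmCategory")[is.na(seg_label)]
    parts <- segment_abstract(title, seg_text, labels = seg_label)
    tibble(
      pmid = pmid,
      year = suppressWarnings(as.integer(year)),
      journal = ifelse(is.na(journal), "", journal),
      title = trimws(title),
      body = parts$body,
      conclusions = parts$conclusions
    )
  })
  bind_rows(rows)
}

read_corpus_nbib <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  # continuation lines start with spaces; fold them into the preceding field
  rec_list <- list()
  fields <- list()
  key <- NULL
  flush_record <- function(fields) {
    if (!length(fields)) return(NULL)
    getf <- function(k) {
      v <- fields[[k]]
      if (is.null(v)) "" else paste(v, collapse = " ")
    }
    pmid <- getf("PMID")
    if (!nzchar(pmid)) abort("Malformed nbib record: missing PMID field.")
    dp <- getf("DP")
    year <- suppressWarnings(as.integer(substr(dp, 1L, 4L)))
    ab <- getf("AB")
    parts <- segment_abstract(getf("TI"), ab)
    tibble(
      pmid = pmid, year = year, journal = getf("JT"),
      title = getf("TI"), body = parts$body, conclusions = parts$conclusions
    )
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) {
      rec <- flush_record(fields)
      if (!is.null(rec)) rec_list[[length(rec_list) + 1L]] <- rec
      fields <- list()
      key <- NULL
    } else if (grepl("^[A-Z]{2,4}\\s*- ", ln)) {
      key <- trimws(sub("\\s*- .*$", "", ln))
      val <- sub("^[A-Z]{2,4}\\s*- ", "", ln)
      fields[[key]] <- c(fields[[key]], trimws(val))
    } else if (grepl("^\\s+", ln) && !is.null(key)) {
      n <- length(fields[[key]])
      fields[[key]][n] <- paste(fields[[key]][n], trimws(ln))
    }
  }
  rec <- flush_record(fields)
  if (!is.null(rec)) rec_list[[length(rec_list) + 1L]] <- rec
  bind_rows(rec_list)
}

.conclusion_labels <- c("CONCLUSION", "CONCLUSIONS", "INTERPRETATION")

#' Separate an abstract into body and conclusions
#'
#' Abstracts are split into three parts — title, body, conclusions — because
#' the title and the closing section state the message of a publication more
#' concisely than the rest. Conclusions are located through
#' structured-abstract labels: segments labelled CONCLUSION(S) or
#' INTERPRETATION go to `conclusions`, everything else to `body`. For plain
#' text, inline `LABEL:` markers are detected; an unstructured abstract is
#' all body.
#'
#' @param title The document title (returned unchanged).
#' @param abstract Either a single string, or a character vector of
#'   structured-abstract segments.
#' @param labels Optional character vector of segment labels parallel to
#'   `abstract` (from structured XML); `NA` for unlabelled segments.
#' @return A tibble with columns `title`, `body`, `conclusions`.
#' @export
segment_abstract <- function(title, abstract, labels = NULL) {
  abstract[is.na(abstract)] <- ""
  if (is.null(labels) && length(abstract) == 1L) {
    parts <- split_inline_labels(abstract)
    abstract <- parts$text
    labels <- parts$label
  }
  if (is.null(labels)) labels <- rep(NA_character_, length(abstract))
  is_conc <- !is.na(labels) & toupper(trimws(labels)) %in% .conclusion_labels
  tibble(
    title = trimws(title),
    body = str_squish(paste(abstract[!is_conc], collapse = " ")),
    conclusions = str_squish(paste(abstract[is_conc], collapse = " "))
  )
}

# Split "BACKGROUND: ... METHODS: ... CONCLUSIONS: ..." style abstracts into
# labelled segments; returns the whole text unlabelled when no marker found.
split_inline_labels <- function(text) {
  m <- gregexpr("(?<=^|[.?!] )([A-Z][A-Z /&]{3,40}):\\s", text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(list(text = text, label = NA_character_))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  labels <- character(0)
  segs <- character(0)
  if (starts[1] > 1L) {
    labels <- NA_character_
    segs <- substr(text, 1L, starts[1] - 1L)
  }
  for (k in seq_along(starts)) {
    lab <- sub(":\\s*$", "", substr(text, starts[k], starts[k] + lens[k] - 1L))
    seg_start <- starts[k] + lens[k]
    seg_end <- if (k < length(starts)) starts[k + 1L] - 1L else nchar(text)
    labels <- c(labels, trimws(lab))
    segs <- c(segs, substr(text, seg_start, seg_end))
  }
  list(text = trimws(segs), label = labels)
}

.abbreviations <- c(
  "i.e.", "e.g.", "cf.", "ca.", "vs.", "al.", "fig.", "figs.", "no.",
  "dr.", "st.", "mr.", "mrs.", "approx.", "etc.", "resp.", "spp.", "subsp."
)

#' Split section text into sentences
#'
#' Rule-based splitting: a sentence ends at `.`, `!` or `?` followed by
#' whitespace and an uppercase letter, digit or opening quote/parenthesis,
#' unless the terminating token is a known abbreviation ("i.e.", "e.g.",
#' "Fig.", "et al.", ...) or a single initial. Offsets are 0-based,
#' half-open, relative to the section text, and every non-whitespace
#' character is covered by exactly one sentence span.
#'
#' @param text A single section string.
#' @return A tibble with columns `index` (0-based), `text`, `char_start`,
#'   `char_end`.
#' @export
split_sentences <- function(text) {
  empty <- tibble(index = integer(), text = character(),
                  char_start = integer(), char_end = integer())
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  breaks <- integer(0)  # position of last char of each sentence
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (!ch %in% c(".", "!", "?")) next
    nxt <- if (i < n) chars[i + 1L] else ""
    if (nzchar(nxt) && !grepl("^\\s$", nxt)) next
    # find the next non-space character; require sentence-initial shape
    j <- i + 1L
    while (j <= n && grepl("^\\s$", chars[j])) j <- j + 1L
    if (j <= n && !grepl("^[A-Z0-9\"'(\\[]$", chars[j])) next
    if (ch == ".") {
      # token ending at the period
      k <- i
      while (k > 1L && !grepl("^\\s$", chars[k - 1L])) k <- k - 1L
      token <- tolower(paste(chars[k:i], collapse = ""))
      if (token %in% .abbreviations) next
    }
    breaks <- c(breaks, i)
  }
  if (!length(breaks) || breaks[length(breaks)] < n) breaks <- c(breaks, n)
  starts <- c(1L, head(breaks, -1L) + 1L)
  spans <- purrr::map2(starts, breaks, function(s, e) {
    while (s <= e && grepl("^\\s$", chars[s])) s <- s + 1L
    while (e >= s && grepl("^\\s$", chars[e])) e <- e - 1L
    c(s, e)
  })
  spans <- spans[purrr::map_lgl(spans, \(sp) sp[1] <= sp[2])]
  if (!length(spans)) return(empty)
  tibble(
    index = seq_along(spans) - 1L,
    text = purrr::map_chr(spans, \(sp) substr(text, sp[1], sp[2])),
    char_start = purrr::map_int(spans, \(sp) sp[1] - 1L),
    char_end = purrr::map_int(spans, \(sp) sp[2])
  )
}

#' Sentence-segment every document of a corpus
#'
#' Applies [split_sentences()] to the title, body and conclusions of each
#' document.
#'
#' @param docs A document tibble as returned by [read_corpus()].
#' @return A tibble with columns `pmid`, `section` (`TITLE`, `BODY`,
#'   `CONCLUSIONS`), `index`, `text`, `char_start`, `char_end`.
#' @export
corpus_sentences <- function(docs) {
  if (nrow(docs) == 0L) {
    return(tibble(
      pmid = character(), section = character(), index = integer(),
      text = character(), char_start = integer(), char_end = integer()
    ))
  }
  sections <- tibble(
    pmid = rep(docs$pmid, 3L),
    section = rep(c("TITLE", "BODY", "CONCLUSIONS"), each = nrow(docs)),
    section_text = c(docs$title, docs$body, docs$conclusions)
  )
  sections |>
    mutate(sentences = purrr::map(.data$section_text, split_sentences)) |>
    select(-"section_text") |>
    tidyr::unnest("sentences") |>
    arrange(match(.data$pmid, docs$pmid), match(.data$section, c("TITLE", "BODY", "CONCLUSIONS")),
            .data$index)
}
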