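#' Construct a text document
#'
#' The unit of a corpus: an identifier plus raw text (one abstract, typically).
#'
#' @param doc_id Unique identifier within a corpus.
#' @param text Raw text.
#' @return A `text_document` object.
#' @export
text_document <- function(doc_id, text) {
  structure(list(doc_id = as.character(doc_id), text = as.character(text)),
            class = "text_document")
}

#' Preprocessing configuration
#'
#' Controls the classical normalization steps applied to raw text before
#' embedding training: lowercasing and punctuation removal are always on;
#' lemmatization, numeric-token removal and dictionary synonym substitution
#' are switchable.
#'
#' @param lemmatize Apply the rule-based lemmatizer.
#' @param substitute_synonyms Replace synonym phrases by preferred terms
#'   (requires a synonym table in [preprocess_corpus()]).
#' @param drop_numeric Remove purely numeric tokens. Alphanumeric tokens such
#'   as gene symbols ("brca1") are always kept.
#' @param min_token_length Minimum token length to keep (>= 1).
#' @return A `preprocess_config` object.
#' @export
preprocess_config <- function(lemmatize = TRUE, substitute_synonyms = TRUE,
                              drop_numeric = TRUE, min_token_length = 1L) {
  if (min_token_length < 1L) en_stop("parameter", "min_token_length must be >= 1")
  structure(list(lemmatize = isTRUE(lemmatize),
                 substitute_synonyms = isTRUE(substitute_synonyms),
                 drop_numeric = isTRUE(drop_numeric),
                 min_token_length = as.integer(min_token_length)),
            class = "preprocess_config")
}

# lowercase, strip punctuation (underscore kept: it joins multi-word concepts),
# split on whitespace
.tokenize_raw <- function(text) {
  x <- tolower(text)
  x <- gsub("[^a-z0-9_]+", " ", x)
  toks <- strsplit(trimws(x), " +")[[1L]]
  toks[nzchar(toks)]
}

#' Normalize raw text into a token sequence
#'
#' Applies lowercasing, punctuation removal, optional removal of purely
#' numeric tokens and optional lemmatization.
#'
#' @param doc A [text_document()] or a character scalar.
#' @param config A [preprocess_config()].
#' @return A `token_sequence`: list with `doc_id` and `tokens`.
#' @export
normalize_text <- function(doc, config = preprocess_config()) {
  if (is.character(doc)) doc <- text_document("doc1", doc)
  stopifnot(inherits(doc, "text_document"))
  if (!all(validUTF8(doc$text)))
    en_stop("decoding", "document '%s' is not valid UTF-8", doc$doc_id)
  toks <- .tokenize_raw(doc$text)
  if (config$drop_numeric) toks <- toks[!grepl("^[0-9]+$", toks)]
  if (config$min_token_length > 1L)
    toks <- toks[nchar(toks) >= config$min_token_length]
  if (config$lemmatize) toks <- lemmatize_tokens(toks)
  structure(list(doc_id = doc$doc_id, tokens = toks), class = "token_sequence")
}

# normalize a dictionary phrase with the same surface rules (no lemmatization)
.normalize_phrase <- function(phrase) {
  paste(.tokenize_raw(phrase), collapse = " ")
}

.entity_types <- c("gene", "disease", "drug", "other")

#' Build a synonym table
#'
#' Maps synonym phrases (possibly multi-word) to preferred terms with an
#' entity type, emulating the merge of HUGO-, MeSH- and DrugBank-style
#' dictionaries. Phrases are normalized with the same surface rules as
#' [normalize_text()] (no lemmatization); matching at substitution time is
#' attempted on the surface form first and on the lemmatized form second.
#'
#' @param entries A data.frame with columns `preferred_term`, `synonym`,
#'   `entity_type`.
#' @return A `synonym_table` object.
#' @export
synonym_table <- function(entries) {
  need <- c("preferred_term", "synonym", "entity_type")
  if (!all(need %in% names(entries)))
    en_stop("validation", "synonym table needs columns: %s", paste(need, collapse = ", "))
  bad <- setdiff(unique(entries$entity_type), .entity_types)
  if (length(bad))
    en_stop("validation", "unknown entity_type(s): %s", paste(bad, collapse = ", "))
  entries$preferred_term <- vapply(entries$preferred_term, .normalize_phrase, "")
  entries$synonym <- vapply(entries$synonym, .normalize_phrase, "")
  entries <- entries[nzchar(entries$synonym) & nzchar(entries$preferred_term), , drop = FALSE]
  entries <- unique(entries[c("preferred_term", "synonym", "entity_type")])
  # one synonym phrase must map to exactly one preferred term
  dup <- split(seq_len(nrow(entries)), entries$synonym)
  amb <- dup[vapply(dup, function(i) length(unique(entries$preferred_term[i])) > 1L, NA)]
  if (length(amb))
    en_stop("ambiguity",
            "synonym(s) mapping to multiple preferred terms: %s (rows %s)",
            paste(names(amb), collapse = "; "),
            paste(unlist(amb), collapse = ","))
  surface <- new.env(parent = emptyenv())
  lemma <- new.env(parent = emptyenv())
  max_len <- 1L
  for (i in seq_len(nrow(entries))) {
    ph <- entries$synonym[i]
    assign(ph, entries$preferred_term[i], envir = surface)
    lf <- paste(lemmatize_tokens(strsplit(ph, " ", fixed = TRUE)[[1L]]), collapse = " ")
    if (!exists(lf, envir = lemma, inherits = FALSE))
      assign(lf, entries$preferred_term[i], envir = lemma)
    max_len <- max(max_len, length(strsplit(ph, " ", fixed = TRUE)[[1L]]))
  }
  structure(list(entries = entries, surface = surface, lemma = lemma,
                 max_phrase_len = max_len),
            class = "synonym_table")
}

#' Load a synonym table from a TSV file
#'
#' @param path TSV file with header `preferred_term<TAB>synonym<TAB>entity_type`.
#' @return A `synonym_table`.
#' @export
load_synonym_table <- function(path) {
  if (!file.exists(path)) en_stop("validation", "file not found: %s", path)
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   colClasses = "character", stringsAsFactors = FALSE)
  synonym_table(df)
}

#' Number of synonym entries
#' @param x A `synonym_table`.
#' @export
length.synonym_table <- function(x) nrow(x$entries)

#' Substitute synonym phrases by preferred terms
#'
#' Greedy longest-match left-to-right over the token sequence; every maximal
#' match of a synonym phrase is replaced by its preferred term, with internal
#' spaces of multi-word preferred terms replaced by underscores. Surface
#' phrases take priority over lemmatized phrases.
#'
#' @param tokens A `token_sequence` (already normalized) or character vector.
#' @param table A [synonym_table()].
#' @return A `token_sequence` of the same document.
#' @export
substitute_synonyms <- function(tokens, table) {
  doc_id <- "doc1"
  if (inherits(tokens, "token_sequence")) {
    doc_id <- tokens$doc_id
    toks <- tokens$tokens
  } else {
    toks <- as.character(tokens)
  }
  stopifnot(inherits(table, "synonym_table"))
  n <- length(toks)
  if (n == 0L || length(table) == 0L)
    return(structure(list(doc_id = doc_id, tokens = toks), class = "token_sequence"))
  out <- character(0L)
  i <- 1L
  maxl <- table$max_phrase_len
  while (i <= n) {
    hit <- NULL
    for (L in seq(min(maxl, n - i + 1L), 1L)) {
      ph <- paste(toks[i:(i + L - 1L)], collapse = " ")
      pref <- get0(ph, envir = table$surface, inherits = FALSE)
      if (is.null(pref)) pref <- get0(ph, envir = table$lemma, inherits = FALSE)
      if (!is.null(pref)) {
        hit <- list(pref = pref, len = L)
        break
      }
    }
    if (is.null(hit)) {
      out <- c(out, toks[i])
      i <- i + 1L
    } else {
      out <- c(out, gsub(" ", "_", hit$pref, fixed = TRUE))
      i <- i + hit$len
    }
  }
  structure(list(doc_id = doc_id, tokens = out), class = "token_sequence")
}

#' Preprocess a corpus
#'
#' Runs [normalize_text()] on every document and, when enabled in the config,
#' [substitute_synonyms()] afterwards. Order of documents is preserved. With
#' substitution disabled the output equals per-document normalization alone
#' (the "no synonym replacement" embedding variant).
#'
#' @param documents List of [text_document()]s, or a character vector
#'   (names, if any, become doc ids).
#' @param config A [preprocess_config()].
#' @param table A [synonym_table()]; required when substitution is enabled.
#' @return List of `token_sequence` objects.
#' @export
preprocess_corpus <- function(documents, config = preprocess_config(), table = NULL) {
  if (is.character(documents)) {
    ids <- names(documents) %||% sprintf("doc%d", seq_along(documents))
    documents <- Map(text_document, ids, documents)
  }
  if (config$substitute_synonyms && is.null(table))
    en_stop("validation", "synonym substitution enabled but no synonym table supplied")
  lapply(documents, function(doc) {
    ts <- tryCatch(normalize_text(doc, config), error = function(e) {
      en_stop("preprocess", "document '%s': %s", doc$doc_id, conditionMessage(e))
    })
    if (config$substitute_synonyms) ts <- substitute_synonyms(ts, table)
    ts
  })
}

#' Read a plain-text corpus (one document per line)
#'
#' @param path Text file, optionally gzip-compressed (by extension).
#' @return Named character vector of documents.
#' @export
read_corpus <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE, encoding = "UTF-8")
  names(lines) <- sprintf("doc%d", seq_along(lines))
  lines
}

#' Write token sequences, one space-joined line per document
#'
#' @param token_seqs List of `token_sequence` objects.
#' @param path Output file.
#' @export
write_tokens <- function(token_seqs, path) {
  writeLines(vapply(token_seqs, function(ts) paste(ts$tokens, collapse = " "), ""),
             path)
  invisible(path)
}
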