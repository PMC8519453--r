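#' Embedding training configuration
#'
#' Hyperparameters for skip-gram training with negative sampling. The
#' defaults follow the study configuration: 300 dimensions, context window 5,
#' minimum count 5. Negative-sample count, epochs and learning-rate schedule
#' are conventional word2vec defaults.
#'
#' @param dimension Vector dimensionality (>= 1).
#' @param window Context window size (>= 1); the effective window is drawn
#'   uniformly in `1..window` per position, as in classic word2vec.
#' @param min_count Minimum corpus frequency for a token to enter the
#'   vocabulary (>= 1).
#' @param negative_samples Negative samples per positive pair.
#' @param epochs Training passes over the corpus.
#' @param learning_rate,min_learning_rate Linear learning-rate decay range.
#' @param subsample Frequent-token subsampling threshold (0 disables).
#' @param seed Integer seed for all training randomness.
#' @param deterministic_mode Single-threaded, bit-reproducible training. The
#'   trainer is always single-threaded; the flag is recorded on the result.
#' @return An `embedding_config` object.
#' @export
embedding_config <- function(dimension = 300L, window = 5L, min_count = 5L,
                             negative_samples = 5L, epochs = 5L,
                             learning_rate = 0.025, min_learning_rate = 1e-4,
                             subsample = 1e-3, seed = 1L,
                             deterministic_mode = TRUE) {
  if (dimension < 1L || window < 1L || min_count < 1L)
    en_stop("parameter", "dimension, window and min_count must all be >= 1")
  structure(list(dimension = as.integer(dimension), window = as.integer(window),
                 min_count = as.integer(min_count),
                 negative_samples = as.integer(negative_samples),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 min_learning_rate = min_learning_rate, subsample = subsample,
                 seed = as.integer(seed),
                 deterministic_mode = isTRUE(deterministic_mode)),
            class = "embedding_config")
}

#' Construct an embedding from a vector matrix
#'
#' @param vectors Numeric matrix, one row per term; rownames are the
#'   vocabulary.
#' @param types Optional named character vector mapping terms to entity types
#'   (`gene`, `disease`, `drug`, `other`).
#' @return An `embedding` object.
#' @export
embedding <- function(vectors, types = NULL) {
  if (is.null(rownames(vectors))) en_stop("validation", "vectors need rownames")
  if (anyDuplicated(rownames(vectors)))
    en_stop("validation", "duplicate terms in vocabulary")
  if (!all(is.finite(vectors))) en_stop("validation", "non-finite vector entries")
  if (!is.null(types)) {
    bad <- setdiff(unique(types), .entity_types)
    if (length(bad)) en_stop("validation", "unknown entity type(s): %s",
                             paste(bad, collapse = ", "))
  }
  structure(list(vocab = rownames(vectors), vectors = vectors, types = types),
            class = "embedding")
}

#' @export
#' @method print embedding
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding> %d terms x %d dimensions%s\n", nrow(x$vectors),
              ncol(x$vectors),
              if (is.null(x$types)) "" else sprintf(", %d typed terms", length(x$types))))
  invisible(x)
}

#' Train a skip-gram embedding
#'
#' Trains word2vec-style vectors (skip-gram with negative sampling) on a
#' preprocessed corpus. Training is single-threaded and bit-reproducible
#' given the config seed.
#'
#' @param corpus List of `token_sequence` objects or character vectors.
#' @param config An [embedding_config()].
#' @param types Optional named character vector of entity-type labels copied
#'   onto the embedding (restricted to the trained vocabulary).
#' @return An `embedding`.
#' @export
train_embedding <- function(corpus, config = embedding_config(), types = NULL) {
  toks <- lapply(corpus, function(x) if (inherits(x, "token_sequence")) x$tokens else as.character(x))
  if (length(toks) == 0L || sum(lengths(toks)) == 0L)
    en_stop("training", "empty corpus")
  counts <- table(unlist(toks, use.names = FALSE))
  counts <- counts[counts >= config$min_count]
  if (length(counts) == 0L)
    en_stop("training", "vocabulary empty after min_count = %d filtering",
            config$min_count)
  # vocabulary ordered by decreasing frequency, ties lexicographic
  ord <- order(-as.integer(counts), names(counts))
  vocab <- names(counts)[ord]
  freq <- as.integer(counts)[ord]
  ids <- seq_along(vocab)
  names(ids) <- vocab
  sentences <- lapply(toks, function(tk) {
    v <- unname(ids[tk])
    as.integer(v[!is.na(v)] - 1L)
  })
  sentences <- sentences[lengths(sentences) > 0L]
  mat <- .sgns_train(sentences, as.integer(freq), config$dimension,
                     config$window, config$negative_samples, config$epochs,
                     config$learning_rate, config$min_learning_rate,
                     config$subsample, config$seed)
  rownames(mat) <- vocab
  if (!is.null(types)) types <- types[intersect(names(types), vocab)]
  emb <- embedding(mat, types = types)
  emb$config <- config
  emb
}

.vec_of <- function(emb, term) {
  i <- match(term, emb$vocab)
  if (is.na(i)) en_stop("lookup", "term not in vocabulary: '%s'", term)
  emb$vectors[i, ]
}

#' Cosine similarity between two terms
#'
#' @param emb An `embedding`.
#' @param term_a,term_b Vocabulary terms.
#' @return Cosine similarity in `[-1, 1]`.
#' @export
cosine <- function(emb, term_a, term_b) {
  u <- .vec_of(emb, term_a)
  v <- .vec_of(emb, term_b)
  as.numeric(sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2))))
}

# unit-normalized vector matrix (rows)
.unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

#' Nearest neighbors of a term by cosine similarity
#'
#' @param emb An `embedding`.
#' @param term Query term (excluded from its own neighbors).
#' @param k Number of neighbors (>= 0).
#' @param type_filter Optional entity type; restricts candidates to terms
#'   carrying that type label.
#' @return A `neighbor_result`: list with `term` and a data.frame `neighbors`
#'   (`term`, `similarity`) in non-increasing order, ties broken
#'   lexicographically.
#' @export
nearest_neighbors <- function(emb, term, k = 10L, type_filter = NULL) {
  if (k < 0L) en_stop("parameter", "k must be >= 0")
  u <- .vec_of(emb, term)
  un <- .unit_rows(emb$vectors)
  sims <- as.numeric(un %*% (u / sqrt(sum(u^2))))
  names(sims) <- emb$vocab
  sims <- sims[names(sims) != term]
  if (!is.null(type_filter)) {
    if (is.null(emb$types)) en_stop("parameter", "embedding carries no type labels")
    keep <- names(emb$types)[emb$types == type_filter]
    sims <- sims[names(sims) %in% keep]
  }
  ord <- order(-sims, names(sims))
  top <- head(ord, k)
  structure(list(term = term,
                 neighbors = data.frame(term = names(sims)[top],
                                        similarity = unname(sims[top]),
                                        stringsAsFactors = FALSE)),
            class = "neighbor_result")
}

#' Neighbor stability across embeddings
#'
#' Computes the neighbors of a term that are common to the top-k lists of
#' several embeddings (e.g. trained on corpora of increasing size), together
#' with the trajectory of their cosine similarities. Neighbors are ordered by
#' decreasing similarity in the first embedding.
#'
#' @param embeddings List of >= 2 `embedding` objects.
#' @param term Query term; must be present in every embedding.
#' @param k Neighborhood size per embedding.
#' @return List with `common` (character vector) and `trajectory` (data.frame
#'   with one similarity column per embedding).
#' @export
neighbor_stability <- function(embeddings, term, k = 10L) {
  if (length(embeddings) < 2L) en_stop("parameter", "need at least 2 embeddings")
  missing_in <- which(vapply(embeddings, function(e) !(term %in% e$vocab), NA))
  if (length(missing_in))
    en_stop("lookup", "term '%s' missing from embedding(s): %s", term,
            paste(missing_in, collapse = ", "))
  tops <- lapply(embeddings, function(e) nearest_neighbors(e, term, k)$neighbors)
  common <- Reduce(intersect, lapply(tops, `[[`, "term"))
  if (length(common) == 0L)
    return(list(common = character(0L),
                trajectory = data.frame(neighbor = character(0L))))
  sims <- vapply(embeddings, function(e)
    vapply(common, function(nb) cosine(e, term, nb), 0), numeric(length(common)))
  sims <- matrix(sims, nrow = length(common),
                 dimnames = list(NULL, sprintf("embedding%d", seq_along(embeddings))))
  ord <- order(-sims[, 1L], common)
  traj <- data.frame(neighbor = common[ord], sims[ord, , drop = FALSE],
                     stringsAsFactors = FALSE)
  rownames(traj) <- NULL
  list(common = common[ord], trajectory = traj)
}

#' Write an embedding in word2vec text format
#'
#' First line is `<vocab_size> <dimension>`, then one term and its vector per
#' line. Type labels, if present, go to a sidecar TSV `term<TAB>entity_type`.
#'
#' @param emb An `embedding`.
#' @param path Output file.
#' @param types_path Optional sidecar path for type labels.
#' @export
write_embedding <- function(emb, path, types_path = NULL) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(emb$vectors), ncol(emb$vectors)), con)
  lines <- vapply(seq_len(nrow(emb$vectors)), function(i)
    paste(emb$vocab[i], paste(sprintf("%.9g", emb$vectors[i, ]), collapse = " ")),
    "")
  writeLines(lines, con)
  if (!is.null(types_path) && !is.null(emb$types))
    writeLines(paste(names(emb$types), emb$types, sep = "\t"), types_path)
  invisible(path)
}

#' Read an embedding in word2vec text format
#'
#' @param path Embedding file written by [write_embedding()] or any
#'   word2vec-text-format file.
#' @param types_path Optional sidecar TSV `term<TAB>entity_type`.
#' @return An `embedding`.
#' @export
read_embedding <- function(path, types_path = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(lines[1L], " ", fixed = TRUE)[[1L]])
  if (length(hdr) != 2L || anyNA(hdr))
    en_stop("parse", "malformed word2vec header in %s", path)
  body <- strsplit(lines[-1L], " ", fixed = TRUE)
  vocab <- vapply(body, `[[`, "", 1L)
  mat <- t(vapply(body, function(x) as.numeric(x[-1L]), numeric(hdr[2L])))
  rownames(mat) <- vocab
  types <- NULL
  if (!is.null(types_path) && file.exists(types_path)) {
    td <- read.delim(types_path, header = FALSE, sep = "\t",
                     colClasses = "character")
    types <- stats::setNames(td[[2L]], td[[1L]])
  }
  embedding(mat, types = types)
}
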