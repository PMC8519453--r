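# Independent oracles used to cross-check the implementation.

# union-find connected components
uf_components <- function(vertices, edges) {
  parent <- stats::setNames(vertices, vertices)
  find <- function(v) {
    while (parent[[v]] != v) {
      parent[[v]] <<- parent[[parent[[v]]]]
      v <- parent[[v]]
    }
    v
  }
  if (NROW(edges) > 0L)
    for (i in seq_len(nrow(edges))) {
      ra <- find(edges$from[i])
      rb <- find(edges$to[i])
      if (ra != rb) parent[[ra]] <- rb
    }
  roots <- vapply(vertices, find, "")
  unname(lapply(split(vertices, roots), sort))
}

# brute-force AUC: all positive-negative pairs, ties count one half
bf_auc <- function(truth, scores) {
  pos <- scores[truth == 1L]
  neg <- scores[truth == 0L]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  100 * mean(cmp)
}

# quartiles by explicit linear interpolation on the sorted values
sort_quartiles <- function(v) {
  s <- sort(v)
  n <- length(s)
  one <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }
  c(q1 = one(0.25), median = one(0.5), q3 = one(0.75))
}

# plain cosine between two numeric vectors
vec_cos <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))

# tiny embedding with fixed random vectors
toy_embedding <- function(n = 10L, dim = 6L, seed = 1L, types = NULL) {
  set.seed(seed)
  V <- matrix(rnorm(n * dim), n, dim,
              dimnames = list(sprintf("t%02d", seq_len(n)), NULL))
  embedding(V, types = types)
}

# random similarity_network on n vertices
toy_network <- function(n = 20L, p = 0.15, seed = 1L, weighted = FALSE) {
  set.seed(seed)
  v <- sprintf("v%02d", seq_len(n))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(idx)) < p
  edges <- data.frame(from = v[idx[keep, 1L]], to = v[idx[keep, 2L]],
                      weight = stats::runif(sum(keep)))
  similarity_network(v, edges, weighted = weighted)
}

# small connected graph as a similarity_network (ring + chords)
connected_toy_network <- function(n = 16L, seed = 3L) {
  set.seed(seed)
  v <- sprintf("g%02d", seq_len(n))
  ring <- data.frame(from = v, to = v[c(2:n, 1L)])
  extra <- data.frame(from = sample(v, n %/% 2L), to = sample(v, n %/% 2L))
  similarity_network(v, rbind(ring, extra), weighted = FALSE)
}

# desk-scale corpus settings shared by pipeline-level tests
small_corpus_spec <- function(seed, ...) {
  corpus_spec(n_documents = 1200L, vocab_background = 250L,
              doc_length_mean = 20, seed = seed, ...)
}

desk_embed_config <- function(seed, dim = 50L) {
  embedding_config(dimension = dim, epochs = 15L, min_count = 5L, seed = seed)
}
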