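make_tiny_corpus <- function() {
  # "alpha beta" co-occur in every doc; "gamma" appears with fillers
  c(rep(list(c("alpha", "beta", "w1", "w2")), 8L),
    rep(list(c("gamma", "w3", "w1", "w2")), 8L))
}

test_that("training yields vectors of the configured dimension and filters by min_count", {
  corp <- make_tiny_corpus()
  emb <- train_embedding(corp, embedding_config(dimension = 300L, window = 5L,
                                                min_count = 5L, epochs = 1L,
                                                seed = 1L))
  expect_true(all(vapply(seq_along(emb$vocab),
                         function(i) length(emb$vectors[i, ]), 0L) == 300L))
  # every vocabulary token occurs >= min_count times
  counts <- table(unlist(corp))
  expect_setequal(emb$vocab, names(counts)[counts >= 5L])

  # a token appearing 4 times is dropped at min_count 5
  corp2 <- c(corp, rep(list(c("rare")), 4L))
  emb2 <- train_embedding(corp2, embedding_config(dimension = 10L, epochs = 1L,
                                                  min_count = 5L, seed = 1L))
  expect_false("rare" %in% emb2$vocab)

  expect_error(train_embedding(list(), embedding_config()),
               class = "embednet_training_error")
  expect_error(train_embedding(list(c("once")), embedding_config(min_count = 5L)),
               class = "embednet_training_error")
})

test_that("training is bit-reproducible under a fixed seed", {
  corp <- make_tiny_corpus()
  cfg <- embedding_config(dimension = 16L, epochs = 3L, min_count = 2L, seed = 7L)
  e1 <- train_embedding(corp, cfg)
  e2 <- train_embedding(corp, cfg)
  expect_identical(e1$vectors, e2$vectors)
  cfg2 <- cfg
  cfg2$seed <- 8L
  e3 <- train_embedding(corp, cfg2)
  expect_false(identical(e1$vectors, e3$vectors))
})

test_that("cosine matches closed forms and its invariants", {
  V <- rbind(a = c(1, 0), b = c(0, 1), c = c(1, 1))
  emb <- embedding(V)
  expect_equal(cosine(emb, "a", "a"), 1.0)
  expect_equal(cosine(emb, "a", "b"), 0.0)
  expect_equal(round(cosine(emb, "a", "c"), 4L), 0.7071)
  expect_error(cosine(emb, "a", "zzz"), "zzz",
               class = "embednet_lookup_error")

  emb2 <- toy_embedding(12L, 7L, seed = 2L)
  for (pair in list(c(1L, 2L), c(3L, 9L), c(5L, 12L))) {
    ta <- emb2$vocab[pair[1L]]
    tb <- emb2$vocab[pair[2L]]
    expect_lt(abs(cosine(emb2, ta, tb) - cosine(emb2, tb, ta)), 1e-12)
  }
  # scale invariance
  emb3 <- emb2
  emb3$vectors[3L, ] <- 17.5 * emb3$vectors[3L, ]
  t3 <- emb2$vocab[3L]
  expect_equal(cosine(emb3, t3, emb2$vocab[8L]), cosine(emb2, t3, emb2$vocab[8L]),
               tolerance = 1e-12)
})

test_that("nearest neighbors match an exhaustive all-pairs oracle", {
  V <- rbind(a = c(1, 0), b = c(0.9, 0.1), c = c(0, 1), d = c(-1, 0))
  emb <- embedding(V, types = c(a = "gene", b = "gene", c = "disease", d = "gene"))
  expect_equal(nrow(nearest_neighbors(emb, "a", 0L)$neighbors), 0L)

  nn <- nearest_neighbors(emb, "a", 3L)
  oracle <- sort(sapply(setdiff(rownames(V), "a"),
                        function(t) vec_cos(V["a", ], V[t, ])), decreasing = TRUE)
  expect_equal(nn$neighbors$term, names(oracle))
  expect_equal(nn$neighbors$similarity, unname(oracle), tolerance = 1e-12)
  expect_true(all(diff(nn$neighbors$similarity) <= 0))
  expect_false("a" %in% nn$neighbors$term)

  gn <- nearest_neighbors(emb, "a", 3L, type_filter = "gene")
  expect_setequal(gn$neighbors$term, c("b", "d"))

  # larger random oracle
  emb2 <- toy_embedding(15L, 5L, seed = 3L)
  q <- emb2$vocab[1L]
  nn2 <- nearest_neighbors(emb2, q, 14L)
  oracle2 <- sapply(emb2$vocab[-1L], function(t)
    vec_cos(emb2$vectors[q, ], emb2$vectors[t, ]))
  oracle2 <- oracle2[order(-oracle2, names(oracle2))]
  expect_equal(nn2$neighbors$term, names(oracle2))
})

test_that("neighbor stability intersects top-k sets across embeddings", {
  emb <- toy_embedding(12L, 6L, seed = 4L)
  st <- neighbor_stability(list(emb, emb, emb, emb), emb$vocab[1L], 5L)
  expect_setequal(st$common,
                  nearest_neighbors(emb, emb$vocab[1L], 5L)$neighbors$term)
  expect_equal(ncol(st$trajectory), 5L)  # neighbor + 4 similarity columns
  # trajectory ordered by the first embedding's similarity
  expect_true(all(diff(st$trajectory$embedding1) <= 0))

  # disjoint neighborhoods produce an empty intersection
  V1 <- rbind(q = c(1, 0), a = c(1, 0.1), b = c(1, 0.2), c = c(-1, 0), d = c(-1, 0.1))
  V2 <- rbind(q = c(1, 0), a = c(-1, 0), b = c(-1, 0.2), c = c(1, 0.1), d = c(1, 0.2))
  st2 <- neighbor_stability(list(embedding(V1), embedding(V2)), "q", 2L)
  expect_length(st2$common, 0L)

  expect_error(neighbor_stability(list(emb), "t01", 3L),
               class = "embednet_parameter_error")
  expect_error(neighbor_stability(list(emb, toy_embedding(3L)), "t09", 3L),
               class = "embednet_lookup_error")
})

test_that("word2vec text format round-trips with type sidecar", {
  emb <- toy_embedding(8L, 5L, seed = 6L,
                       types = stats::setNames(rep(c("gene", "drug"), 4L),
                                               sprintf("t%02d", 1:8)))
  f <- withr::local_tempfile(fileext = ".vec")
  ft <- withr::local_tempfile(fileext = ".tsv")
  write_embedding(emb, f, types_path = ft)
  hdr <- readLines(f, n = 1L)
  expect_equal(hdr, "8 5")
  back <- read_embedding(f, types_path = ft)
  expect_equal(back$vocab, emb$vocab)
  expect_equal(back$vectors, emb$vectors, tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(back$types, emb$types)
})

test_that("planted co-occurring pairs score above unrelated pairs across seeds", {
  wins <- 0L
  n_runs <- 20L
  for (s in seq_len(n_runs)) {
    gen <- generate_corpus(corpus_spec(n_documents = 600L, n_groups = 5L,
                                       group_size = 6L, synonym_prob = 0,
                                       vocab_background = 150L,
                                       doc_length_mean = 15, seed = s))
    toks <- lapply(strsplit(unname(gen$documents), " ", fixed = TRUE), identity)
    emb <- train_embedding(toks, embedding_config(dimension = 30L, epochs = 10L,
                                                  min_count = 5L, seed = s))
    g1 <- intersect(gen$truth$groups[[1L]], emb$vocab)
    g2 <- intersect(gen$truth$groups[[2L]], emb$vocab)
    if (length(g1) >= 2L && length(g2) >= 1L) {
      planted <- cosine(emb, g1[1L], g1[2L])
      unrelated <- cosine(emb, g1[1L], g2[1L])
      wins <- wins + (planted > unrelated)
    } else {
      wins <- wins + 1L  # degenerate vocabulary; cannot lose
    }
  }
  expect_gte(wins / n_runs, 0.95)
})
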