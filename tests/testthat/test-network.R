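test_that("thresholded similarity networks match a brute-force pair filter", {
  emb <- toy_embedding(4L, 3L, seed = 2L)
  terms <- emb$vocab
  expect_equal(nrow(build_similarity_network(emb, terms, 1.5)$edges), 0L)
  full <- build_similarity_network(emb, terms, -1)
  expect_equal(nrow(full$edges), 6L)
  expect_equal(length(full$vertices), 4L)

  emb20 <- toy_embedding(20L, 6L, seed = 3L)
  net <- build_similarity_network(emb20, emb20$vocab, 0.5)
  oracle <- character(0L)
  for (i in 1:19) for (j in (i + 1L):20) {
    cs <- vec_cos(emb20$vectors[i, ], emb20$vectors[j, ])
    if (cs >= 0.5)
      oracle <- c(oracle, paste(emb20$vocab[i], emb20$vocab[j]))
  }
  got <- paste(net$edges$from, net$edges$to)
  expect_setequal(got, oracle)
  expect_true(all(net$edges$weight >= 0.5))

  expect_error(build_similarity_network(emb20, c(emb20$vocab, "nope"), 0.5),
               "nope", class = "embednet_lookup_error")
})

test_that("component decomposition matches a union-find oracle", {
  path5 <- similarity_network(letters[1:5],
                              data.frame(from = letters[1:4], to = letters[2:5]))
  dc <- decompose_network(path5)
  expect_length(dc$components, 1L)
  expect_equal(dc$sizes, 5L)

  two <- similarity_network(c("a", "b", "c", "d"),
                            data.frame(from = c("a", "c"), to = c("b", "d")))
  dc2 <- decompose_network(two)
  expect_length(dc2$components, 2L)
  expect_equal(dc2$main, c("a", "b"))  # size tie broken by smallest member

  for (s in 1:50) {
    net <- toy_network(n = 30L, p = 0.06, seed = s)
    got <- decompose_network(net)$components
    oracle <- uf_components(net$vertices, net$edges)
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(oracle, paste, collapse = ","))
  }
})

test_that("threshold search finds the largest threshold reaching the target size", {
  emb <- toy_embedding(15L, 4L, seed = 9L)
  terms <- emb$vocab
  # exhaustive oracle over all observed weights
  un <- emb$vectors / sqrt(rowSums(emb$vectors^2))
  S <- tcrossprod(un)
  weights <- sort(unique(S[upper.tri(S)]), decreasing = TRUE)
  main_at <- function(t) {
    net <- build_similarity_network(emb, terms, t)
    length(decompose_network(net)$main)
  }
  for (target in c(5L, 10L, 15L)) {
    sizes <- vapply(weights, main_at, 0L)
    if (any(sizes >= target)) {
      expected_t <- weights[which(sizes >= target)[1L]]
      got <- threshold_for_size(emb, terms, target)
      expect_equal(got$threshold, expected_t, tolerance = 1e-12)
      expect_gte(got$achieved, target)
    }
  }
  # target of all vertices on a minimum-weight-connected graph
  res <- threshold_for_size(emb, terms, 1L)
  expect_equal(res$threshold, weights[1L], tolerance = 1e-12)
})

test_that("main-component size is monotone non-increasing in the threshold", {
  for (s in 1:50) {
    emb <- toy_embedding(12L, 3L, seed = 100L + s)
    sizes <- vapply(seq(-1, 1, by = 0.25), function(t)
      length(decompose_network(build_similarity_network(emb, emb$vocab, t))$main),
      0L)
    expect_true(all(diff(sizes) <= 0L))
  }
})

test_that("control networks honor their modes and seeds", {
  # k = 0: empty graph
  z <- make_control_network(10L, control_spec("k_out_random", k = 0L, seed = 1L))
  expect_equal(nrow(z$edges), 0L)
  expect_error(make_control_network(5L, control_spec("k_out_random", k = 5L)),
               class = "embednet_parameter_error")

  k8 <- make_control_network(400L, control_spec("k_out_random", k = 8L, seed = 2L))
  deg <- igraph::degree(as_igraph(k8))
  expect_true(all(deg >= 8L - 1L))  # collapsed duplicate draws only
  expect_lt(mean(deg < 8L), 0.01)
  k8b <- make_control_network(400L, control_spec("k_out_random", k = 8L, seed = 2L))
  expect_identical(k8$edges, k8b$edges)

  ref <- toy_network(25L, p = 0.2, seed = 4L, weighted = TRUE)
  pm <- make_control_network(ref, control_spec("permute_vertices", seed = 3L))
  expect_setequal(pm$vertices, ref$vertices)
  expect_equal(sort(unname(igraph::degree(as_igraph(pm)))),
               sort(unname(igraph::degree(as_igraph(ref)))))
  expect_equal(nrow(pm$edges), nrow(ref$edges))

  rw <- make_control_network(ref, control_spec("random_weights",
                                               weight_range = c(0.65, 1),
                                               seed = 5L))
  expect_setequal(paste(rw$edges$from, rw$edges$to),
                  paste(ref$edges$from, ref$edges$to))
  expect_true(all(rw$edges$weight >= 0.65 & rw$edges$weight <= 1))
  rw2 <- make_control_network(ref, control_spec("random_weights",
                                                weight_range = c(0.65, 1),
                                                seed = 5L))
  expect_identical(rw$edges, rw2$edges)
})

test_that("weighted edge import deduplicates, thresholds and reports bad lines", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t0.2", "b\tc\t0.4", "c\td\t0.9"), f)
  expect_equal(nrow(import_weighted_edges(f, 0.1)$edges), 3L)
  expect_equal(nrow(import_weighted_edges(f, 0.95)$edges), 0L)

  writeLines(c("a\tb\t0.7", "b\ta\t0.9", "b\tc\t0.85"), f)
  net <- import_weighted_edges(f, 0.8)
  ab <- net$edges[net$edges$from == "a", ]
  expect_equal(ab$weight, 0.9)
  expect_equal(nrow(net$edges), 2L)

  writeLines(c("a\tb\t0.7", "broken line"), f)
  expect_error(import_weighted_edges(f, 0), "line 2",
               class = "embednet_parse_error")
  writeLines(c("a\tb\tnotanumber"), f)
  expect_error(import_weighted_edges(f, 0), class = "embednet_parse_error")
})

test_that("network files round-trip and main_component restricts correctly", {
  net <- toy_network(15L, p = 0.2, seed = 6L, weighted = TRUE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, f)
  back <- import_weighted_edges(f, -Inf)
  expect_setequal(paste(back$edges$from, back$edges$to),
                  paste(net$edges$from, net$edges$to))
  mc <- main_component(net)
  expect_equal(sort(mc$vertices), sort(decompose_network(net)$main))
  expect_true(all(mc$edges$from %in% mc$vertices))
  # weighted and unweighted exports share the same topology
  unw <- similarity_network(net$vertices, net$edges, weighted = FALSE)
  expect_equal(paste(unw$edges$from, unw$edges$to),
               paste(net$edges$from, net$edges$to))
})
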