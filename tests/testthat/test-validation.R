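test_that("group summaries follow the size filter and quartile convention", {
  # 12 identical vectors: every pairwise cosine is 1
  V <- matrix(rep(c(1, 2, 3), each = 12L), 12L,
              dimnames = list(sprintf("g%02d", 1:12), NULL))
  emb <- embedding(V)
  summ <- group_similarity_summary(emb, list(entity_group("same", rownames(V))),
                                   min_size = 10L, max_size = 3000L)
  expect_equal(summ$x, 12L)
  expect_equal(c(summ$q1, summ$median, summ$q3), c(1, 1, 1))

  # a 5-member group is excluded under the (10, 3000) gene filter
  emb2 <- toy_embedding(20L, 6L, seed = 1L)
  small <- entity_group("small", emb2$vocab[1:5])
  expect_warning(
    out <- group_similarity_summary(emb2, list(small), 10L, 3000L),
    "no groups")
  expect_equal(nrow(out), 0L)

  # 3-member group: median equals the middle of the three pair cosines
  V3 <- rbind(a = c(1, 0), b = c(1, 0.5), c = c(0, 1))
  emb3 <- embedding(V3)
  pair_cos <- c(vec_cos(V3["a", ], V3["b", ]), vec_cos(V3["a", ], V3["c", ]),
                vec_cos(V3["b", ], V3["c", ]))
  s3 <- group_similarity_summary(emb3, list(entity_group("t", rownames(V3))),
                                 min_size = 2L, max_size = 10L)
  expect_equal(s3$median, sort(pair_cos)[2L], tolerance = 1e-12)

  expect_error(group_similarity_summary(emb3, list(), min_size = 1L),
               class = "embednet_parameter_error")
})

test_that("group quartiles match a sort-based oracle on groups up to 50 members", {
  emb <- toy_embedding(60L, 8L, seed = 11L)
  set.seed(12)
  for (size in c(5L, 17L, 36L, 50L)) {
    members <- sample(emb$vocab, size)
    summ <- group_similarity_summary(emb, list(entity_group("g", members)),
                                     min_size = 2L, max_size = 100L)
    V <- emb$vectors[members, ]
    cos_all <- c()
    for (i in seq_len(size - 1L))
      for (j in (i + 1L):size)
        cos_all <- c(cos_all, vec_cos(V[i, ], V[j, ]))
    o <- sort_quartiles(cos_all)
    expect_equal(c(summ$q1, summ$median, summ$q3),
                 unname(o), tolerance = 1e-12)
  }
})

test_that("random pair sampling is uniform over the admissible universe", {
  expect_equal(nrow(sample_random_pairs(letters[1:5], 0L)), 0L)

  terms <- c("a", "b", "c")
  all3 <- data.frame(a = c("a", "a", "b"), b = c("b", "c", "c"))
  expect_error(sample_random_pairs(terms, 1L, excluded_pairs = all3, seed = 1L),
               class = "embednet_sampling_error")

  terms10 <- sprintf("x%02d", 1:10)
  smp <- sample_random_pairs(terms10, 20L, seed = 5L)
  expect_equal(nrow(smp), 20L)
  key <- paste(pmin(smp$a, smp$b), pmax(smp$a, smp$b))
  expect_false(any(duplicated(key)))
  universe <- apply(t(combn(terms10, 2L)), 1L, paste, collapse = " ")
  expect_true(all(key %in% universe))
  expect_false(any(smp$a == smp$b))

  expect_identical(sample_random_pairs(terms10, 20L, seed = 5L), smp)
  excl <- smp[1:10, ]
  smp2 <- sample_random_pairs(terms10, 20L, excluded_pairs = excl, seed = 6L)
  key2 <- paste(pmin(smp2$a, smp2$b), pmax(smp2$a, smp2$b))
  expect_length(intersect(key2, paste(pmin(excl$a, excl$b), pmax(excl$a, excl$b))), 0L)
})

test_that("the decay curve is recovered from noiseless and noisy medians", {
  x <- seq(10L, 100L, by = 10L)
  a_true <- 0.5
  b_true <- 0.2
  summ <- data.frame(x = x, median = 1 / (x^a_true + b_true))
  fit <- fit_decay(summ)
  expect_lt(abs(fit$a - a_true), 1e-6)
  expect_lt(abs(fit$b - b_true), 1e-6)
  expect_true(fit$converged)

  # constant medians: a -> 0 and b -> 1/m - 1
  m <- 0.4
  cfit <- fit_decay(data.frame(x = x, median = m))
  expect_lt(cfit$a, 0.01)
  expect_equal(cfit$b, 1 / m - 1, tolerance = 1e-3)

  # noisy recovery across 20 seeds
  errs <- sapply(1:20, function(s) {
    set.seed(s)
    nf <- fit_decay(data.frame(x = x, median = 1 / (x^a_true + b_true) +
                                 rnorm(length(x), sd = 0.01)))
    abs(nf$a - a_true)
  })
  expect_true(all(errs < 0.1))

  expect_error(fit_decay(data.frame(x = c(5, 5, 5), median = c(0.1, 0.2, 0.3))),
               class = "embednet_fit_error")
  # monotone decreasing fitted curve for a > 0, b > -1
  expect_true(all(diff(decay_predict(fit, 1:200)) < 0))
})

test_that("the loess trend reproduces lines, constants and a frozen reference", {
  x <- seq_len(10L)
  lin <- data.frame(x = x, median = 0.5 - 0.03 * x)
  lt <- loess_trend(lin)
  expect_equal(lt$fitted, 0.5 - 0.03 * lt$x, tolerance = 1e-6)

  ct <- loess_trend(data.frame(x = x, median = rep(0.31, 10L)))
  expect_equal(ct$fitted, rep(0.31, 10L), tolerance = 1e-9)

  expect_error(loess_trend(lin, span = 0), class = "embednet_parameter_error")
  expect_error(loess_trend(lin, span = 1.2), class = "embednet_parameter_error")
  expect_error(loess_trend(lin[1:4, ]), class = "embednet_parameter_error")

  # frozen fixture computed with an independent tricube local-linear oracle
  fx <- c(4, 7, 9, 12, 15, 18, 22, 26, 31, 37, 44, 52)
  fy <- c(0.405001, 0.274568, 0.262697, 0.190913, 0.195958, 0.167658,
          0.134492, 0.155816, 0.112714, 0.115765, 0.095156, 0.100865)
  expected <- c(0.344645779558, 0.303124707973, 0.276515358042, 0.237909064412,
                0.20141870592, 0.174417306414, 0.154638900031, 0.14063761452,
                0.127005059227, 0.115524453002, 0.104532324909, 0.092234429829)
  out <- loess_trend(data.frame(x = fx, median = fy), span = 0.75)
  expect_equal(out$fitted, expected, tolerance = 1e-6)
})

test_that("paired comparison separates duplicated from orthogonal constructions", {
  # positives duplicate a reference direction, the rest are orthogonal
  V <- matrix(0, 8L, 6L,
              dimnames = list(c(paste0("p", 1:4), paste0("n", 1:4)), NULL))
  V[1:4, 1L] <- 1                      # positives share one direction
  V[cbind(5:8, 2:5)] <- 1              # negatives mutually orthogonal
  emb <- embedding(V)
  pos <- data.frame(a = c("p1", "p2", "p1", "p2"), b = c("p2", "p3", "p4", "p4"))
  res <- paired_similarity_comparison(emb, pos, 3L, seed = 2L,
                                      terms = c("n1", "n2", "n3", "n4"))
  expect_equal(res$summary$median[res$summary$arm == "positive"], 1.0)
  expect_lte(abs(res$summary$median[res$summary$arm == "random"]), 1e-12)
  expect_equal(nrow(res$positive), 3L)
  expect_equal(nrow(res$random), 3L)

  expect_error(paired_similarity_comparison(emb, pos, 100L, seed = 1L),
               class = "embednet_sampling_error")
})

test_that("drug pairs stratify by brute-force shared-target counts", {
  targets <- list(d1 = c("g1", "g2"), d2 = c("g3", "g4"),
                  d3 = c("g1", "g2", "g3", "g4", "g5", "g6", "g7"),
                  d4 = c("g1", "g2", "g3", "g4", "g5", "g6", "g8"),
                  d5 = c("g9"))
  emb <- toy_embedding(5L, 4L, seed = 8L)
  emb$vocab <- names(targets)
  rownames(emb$vectors) <- names(targets)
  res <- drug_shared_target_analysis(emb, targets, n = 100L, seed = 1L)
  # oracle: exhaustive intersections
  for (i in seq_len(nrow(res$pairs))) {
    o <- length(intersect(targets[[res$pairs$a[i]]], targets[[res$pairs$b[i]]]))
    expect_equal(res$pairs$shared[i], o)
  }
  # disjoint target sets land in stratum 1 (no shared genes)
  r12 <- res$pairs[res$pairs$a == "d1" & res$pairs$b == "d2", ]
  expect_equal(r12$stratum, 1L)
  # d3-d4 share 6 genes -> stratum 3 (6..9)
  r34 <- res$pairs[res$pairs$a == "d3" & res$pairs$b == "d4", ]
  expect_equal(r34$stratum, 3L)
  expect_equal(res$requested_n, 100L)
  expect_error(drug_shared_target_analysis(emb, targets, group_bounds = c(5, 5, 9)),
               class = "embednet_parameter_error")
})
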