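# dense Chebyshev evaluation oracle: sum_k theta_k T_k(L) x with explicit
# dense polynomial matrices
dense_cheb <- function(L, X, K, W) {
  L <- as.matrix(L)
  n <- nrow(L)
  Tk <- vector("list", K)
  Tk[[1L]] <- diag(n)
  if (K >= 2L) Tk[[2L]] <- L
  if (K >= 3L) for (k in 3:K) Tk[[k]] <- 2 * L %*% Tk[[k - 1L]] - Tk[[k - 2L]]
  Fin <- ncol(X)
  out <- 0
  for (k in seq_len(K)) {
    Wk <- W[((k - 1L) * Fin + 1L):(k * Fin), , drop = FALSE]
    out <- out + Tk[[k]] %*% X %*% Wk
  }
  out
}

# rescaled Laplacian of a path graph as a plain sparse matrix
path_laplacian <- function(n) {
  net <- similarity_network(sprintf("v%02d", 1:n),
                            data.frame(from = sprintf("v%02d", 1:(n - 1)),
                                       to = sprintf("v%02d", 2:n)))
  build_graph_operator(net, levels = 1L)
}

test_that("graph operator Laplacians have the expected spectrum", {
  # single edge: normalized Laplacian eigenvalues {0, 2}
  e2 <- similarity_network(c("a", "b"), data.frame(from = "a", to = "b"))
  op2 <- build_graph_operator(e2, levels = 1L)
  L_unscaled <- (as.matrix(op2$L[[1L]]) + diag(op2$sizes[1L])) * op2$lmax[1L] / 2
  ev <- sort(eigen(L_unscaled[1:2, 1:2], symmetric = TRUE)$values)
  expect_equal(ev, c(0, 2), tolerance = 1e-9)

  # 30-vertex random graph: eigenvalues of the normalized Laplacian in [0, 2]
  net <- main_component(toy_network(30L, p = 0.12, seed = 21L))
  op <- build_graph_operator(net, levels = 2L)
  n0 <- op$sizes[1L]
  Lu <- (as.matrix(op$L[[1L]]) + diag(n0)) * op$lmax[1L] / 2
  ev <- eigen(Lu, symmetric = TRUE)$values
  expect_true(all(ev >= -1e-9 & ev <= 2 + 1e-9))

  # each pooling level halves the padded vertex count exactly
  expect_equal(op$sizes[1L], 2L * op$sizes[2L])
  expect_equal(op$sizes[2L], 2L * op$sizes[3L])

  disc <- similarity_network(c("a", "b", "c", "d"),
                             data.frame(from = c("a", "c"), to = c("b", "d")))
  expect_error(build_graph_operator(disc), class = "embednet_structure_error")
})

test_that("chebyshev convolution matches dense polynomial evaluation", {
  # K = 1 is a pointwise scaling by theta_0
  op <- path_laplacian(6L)
  x <- rnorm(op$sizes[1L])
  expect_equal(as.numeric(chebyshev_conv(x, op, 1L, 0.37)), 0.37 * x,
               tolerance = 1e-12)

  # K = 2 on a 5-vertex toy graph equals theta0 x + theta1 L x
  net5 <- main_component(toy_network(5L, p = 0.7, seed = 2L))
  op5 <- build_graph_operator(net5, levels = 1L)
  L5 <- as.matrix(op5$L[[1L]])
  x5 <- rnorm(nrow(L5))
  th <- c(0.4, -1.2)
  expect_equal(as.numeric(chebyshev_conv(x5, op5, 2L, th)),
               as.numeric(th[1L] * x5 + th[2L] * L5 %*% x5), tolerance = 1e-10)

  # random graphs of 5..30 vertices, multi-channel, vs dense oracle
  set.seed(10)
  for (n in c(5L, 12L, 30L)) {
    net <- main_component(toy_network(n, p = 0.4, seed = n))
    op <- build_graph_operator(net, levels = 1L)
    np <- op$sizes[1L]
    K <- 4L
    Fin <- 2L
    Fout <- 3L
    X <- matrix(rnorm(np * Fin), np)
    W <- matrix(rnorm(K * Fin * Fout), K * Fin)
    expect_equal(unname(chebyshev_conv(X, op, K, W)),
                 unname(dense_cheb(op$L[[1L]], X, K, W)), tolerance = 1e-9)
  }

  expect_error(chebyshev_conv(matrix(rnorm(10L), 5L), path_laplacian(5L)$L[[1L]],
                              3L, matrix(rnorm(4L), 2L)),
               class = "embednet_shape_error")
})

test_that("order-K filters are localized to K-1 hops", {
  n <- 13L
  op <- path_laplacian(n)
  # identify the path vertices inside the padded ordering
  slot_of <- match(seq_len(n), op$input_map)
  K <- 4L
  w <- c(0.3, -0.5, 0.8, 0.2)
  base <- numeric(op$sizes[1L])
  y0 <- chebyshev_conv(base, op, K, w)
  mid <- 7L
  pert <- base
  pert[slot_of[mid]] <- 1
  y1 <- chebyshev_conv(pert, op, K, w)
  changed <- which(abs(y1 - y0) > 1e-12)
  hops <- abs(seq_len(n) - mid)
  expect_true(all(changed %in% slot_of[hops <= K - 1L]))
  # vertices exactly K-1 hops away do change (the bound is tight on a path)
  expect_true(slot_of[mid + K - 1L] %in% changed)
})

test_that("padding vertices never influence real outputs", {
  net <- main_component(toy_network(11L, p = 0.3, seed = 5L))
  op <- build_graph_operator(net, levels = 2L)
  fake <- which(is.na(op$input_map))
  expect_gt(length(fake), 0L)  # 11 real vertices cannot fill an even padding
  w <- rnorm(3L)
  x <- numeric(op$sizes[1L])
  x[fake[1L]] <- 5
  y <- chebyshev_conv(x, op, 3L, w)
  real <- which(!is.na(op$input_map))
  expect_true(all(abs(y[real]) < 1e-12))
})

test_that("the classifier overfits separable data and is seed-deterministic", {
  net <- connected_toy_network(16L)
  set.seed(20)
  n <- 40L
  y <- rep(c(0L, 1L), each = n / 2L)
  X <- matrix(rnorm(n * 16L), n, dimnames = list(sprintf("s%02d", 1:n),
                                                 net$vertices))
  X[y == 1L, 1:4] <- X[y == 1L, 1:4] + 3
  labs <- stats::setNames(y, rownames(X))
  ds <- suppressMessages(align_to_graph(X, net, labs))
  op <- build_graph_operator(ds$network, levels = 2L)
  arch <- gcnn_architecture(fc = c(64L, 32L))
  cfg <- train_config(epochs = 100L, seed = 3L, dropout = 0.2,
                      batch_size = 16L)
  model <- train_gcnn(ds, op, arch, cfg)
  m <- compute_metrics(ds$y, predict(model, ds))
  expect_equal(m[["accuracy"]], 100)

  model2 <- train_gcnn(ds, op, arch, cfg)
  expect_equal(model$history[length(model$history)],
               model2$history[length(model2$history)], tolerance = 1e-6)

  # architecture echo
  txt <- paste(format(model), collapse = " ")
  expect_match(txt, "32 filters")
  expect_match(txt, "64 -> 32")

  one_class <- ds
  one_class$y[] <- 1L
  expect_error(train_gcnn(one_class, op, arch, cfg),
               class = "embednet_training_error")
})

test_that("the default architecture echoes the study layer sizes", {
  a <- gcnn_architecture()
  expect_equal(a$n_filters, c(32L, 32L))
  expect_equal(a$cheb_order, 7L)
  expect_equal(a$pool_size, 2L)
  expect_equal(a$fc, c(512L, 128L))
  fake_model <- structure(list(arch = a, config = train_config(),
                               history = 0.5, converged = TRUE),
                          class = "gcnn_model")
  txt <- paste(format(fake_model), collapse = " ")
  expect_match(txt, "2 convolutional layers x 32 filters")
  expect_match(txt, "512 -> 128 -> 2")
})

test_that("metrics match brute-force counting and hand confusion matrices", {
  expect_equal(unname(compute_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))),
               c(100, 100, 100))
  m <- compute_metrics(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
  expect_equal(m[["auc"]], 75)
  expect_equal(m[["accuracy"]], 75)
  expect_equal(m[["f1_weighted"]], 73.33, tolerance = 1e-3)

  set.seed(99)
  for (i in 1:100) {
    n <- sample(6:25, 1L)
    truth <- c(0L, 1L, sample(0:1, n - 2L, replace = TRUE))
    scores <- round(runif(n), 2L)  # rounding forces ties
    expect_equal(compute_metrics(truth, scores)[["auc"]], bf_auc(truth, scores),
                 tolerance = 1e-9)
  }

  set.seed(7)
  big_truth <- sample(0:1, 10000L, replace = TRUE)
  big_scores <- runif(10000L)
  expect_lt(abs(compute_metrics(big_truth, big_scores)[["auc"]] - 50), 2)

  expect_error(compute_metrics(c(1, 1), c(0.5, 0.6)),
               class = "embednet_metric_error")
  expect_error(compute_metrics(c(0, 1), c(0.5)),
               class = "embednet_shape_error")
})

test_that("cross-validation partitions are stratified and leak-free features ace it", {
  net <- connected_toy_network(16L)
  set.seed(41)
  n <- 60L
  y <- rep(c(0L, 1L), each = n / 2L)
  X <- matrix(rnorm(n * 16L), n, dimnames = list(sprintf("s%02d", 1:n),
                                                 net$vertices))
  X[, 1L] <- y * 10  # the label leaks into one feature
  labs <- stats::setNames(y, rownames(X))
  ds <- suppressMessages(align_to_graph(X, net, labs))
  op <- build_graph_operator(ds$network, levels = 2L)
  cfg <- train_config(epochs = 30L, folds = 5L, seed = 2L, dropout = 0.2,
                      batch_size = 16L)
  res <- cross_validate(ds, op, gcnn_architecture(fc = c(32L, 16L)), cfg)

  fa <- res$fold_assignment
  expect_setequal(unique(fa), 1:5)            # folds partition the samples
  expect_equal(length(fa), n)
  for (f in 1:5) expect_equal(sum(y[fa == f]), 6L)  # stratified: 6 of each class

  expect_equal(res$summary$mean[res$summary$metric == "auc"], 100)
  expect_equal(res$summary$sem[res$summary$metric == "auc"], 0)

  # SEM matches direct recomputation from the per-fold values
  for (mt in c("auc", "accuracy", "f1_weighted")) {
    v <- res$folds[[mt]]
    expect_equal(res$summary$sem[res$summary$metric == mt],
                 sd(v) / sqrt(length(v)), tolerance = 1e-12)
  }

  small <- ds
  small$y[] <- c(rep(0L, 3L), rep(1L, n - 3L))
  expect_error(cross_validate(small, op, gcnn_architecture(), cfg),
               class = "embednet_partition_error")
})
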