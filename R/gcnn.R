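# Spectral graph-convolutional classifier with Chebyshev polynomial filters,
# greedy heavy-edge graph coarsening for fixed-size max pooling, and a manual
# forward/backward implementation trained with Adam. Dense linear algebra goes
# through BLAS; Laplacian polynomials use a compiled sparse-dense product.
# Activations are held as (vertices, batch, channels) arrays so that both the
# polynomial recurrence and the filter GEMM see them as copy-free reshapes.

#' Graph-CNN architecture
#'
#' The study architecture: two convolutional layers of 32 Chebyshev filters
#' each, max pooling of size 2 after both, and fully connected layers of 512
#' and 128 units before a 2-class softmax. Filters of order `K` aggregate
#' over `K - 1` hops.
#'
#' @param n_filters Filters per convolutional layer.
#' @param cheb_order Chebyshev order `K` (>= 1).
#' @param fc Fully-connected layer widths.
#' @param n_classes Output classes.
#' @return A `gcnn_architecture`.
#' @export
gcnn_architecture <- function(n_filters = c(32L, 32L), cheb_order = 7L,
                              fc = c(512L, 128L), n_classes = 2L) {
  if (cheb_order < 1L) en_stop("parameter", "cheb_order must be >= 1")
  if (any(fc < 1L) || any(n_filters < 1L))
    en_stop("parameter", "layer widths must be positive")
  if (length(n_filters) != 2L)
    en_stop("parameter", "the architecture has exactly 2 convolutional layers")
  structure(list(n_filters = as.integer(n_filters),
                 cheb_order = as.integer(cheb_order),
                 pool_size = 2L, fc = as.integer(fc),
                 n_classes = as.integer(n_classes)),
            class = "gcnn_architecture")
}

#' Training configuration for the graph CNN
#'
#' @param epochs Training passes per fit (the study grid uses 25/40/100).
#' @param folds Cross-validation folds (>= 2).
#' @param seed Integer seed controlling fold assignment, initialization,
#'   batch order and dropout.
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param dropout Dropout probability on fully connected activations.
#' @param weight_decay L2 penalty coefficient on weight matrices.
#' @return A `train_config`.
#' @export
train_config <- function(epochs = 25L, folds = 10L, seed = 1L,
                         learning_rate = 1e-3, batch_size = 32L,
                         dropout = 0.5, weight_decay = 0) {
  if (folds < 2L) en_stop("parameter", "folds must be >= 2")
  if (epochs < 1L) en_stop("parameter", "epochs must be >= 1")
  structure(list(epochs = as.integer(epochs), folds = as.integer(folds),
                 seed = as.integer(seed), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), dropout = dropout,
                 weight_decay = weight_decay),
            class = "train_config")
}

# ---- coarsening -----------------------------------------------------------

# one level of greedy matching; vertices visited by ascending weighted degree,
# each picks the unmatched neighbor maximizing w_ij * (1/d_i + 1/d_j)
.heavy_edge_matching <- function(W) {
  n <- nrow(W)
  d <- Matrix::colSums(W)
  sm <- Matrix::summary(W)
  sm <- sm[sm$i != sm$j & sm$x > 0, , drop = FALSE]
  nb <- split(data.frame(j = sm$j, x = sm$x), factor(sm$i, levels = seq_len(n)))
  matched <- logical(n)
  cluster <- integer(n)
  cid <- 0L
  for (i in order(d, seq_len(n))) {
    if (matched[i]) next
    cid <- cid + 1L
    cluster[i] <- cid
    matched[i] <- TRUE
    cand <- nb[[i]]
    if (!is.null(cand) && nrow(cand)) {
      cand <- cand[!matched[cand$j], , drop = FALSE]
      if (nrow(cand)) {
        val <- cand$x * (1 / d[i] + 1 / d[cand$j])
        best <- cand$j[order(-val, cand$j)][1L]
        cluster[best] <- cid
        matched[best] <- TRUE
      }
    }
  }
  cluster
}

# collapse W by cluster assignment; self-loops dropped
.coarsen_adjacency <- function(W, cluster) {
  n <- nrow(W)
  S <- Matrix::sparseMatrix(i = seq_len(n), j = cluster, x = 1,
                            dims = c(n, max(cluster)))
  Wc <- Matrix::t(S) %*% W %*% S
  Matrix::diag(Wc) <- 0
  Matrix::drop0(Wc)
}

# padded symmetric-normalized rescaled Laplacian; `ord` maps padded slot ->
# vertex index (NA = fake). Fake vertices are isolated; their Laplacian row is
# the identity row, so zero-valued features stay zero under any polynomial.
.padded_laplacian <- function(W, ord) {
  np <- length(ord)
  pos <- match(seq_len(nrow(W)), ord)
  sm <- Matrix::summary(Matrix::drop0(W))
  sm <- sm[sm$i != sm$j, , drop = FALSE]
  Wp <- Matrix::sparseMatrix(i = pos[sm$i], j = pos[sm$j], x = sm$x,
                             dims = c(np, np))
  d <- Matrix::colSums(Wp)
  dis <- ifelse(d > 0, 1 / sqrt(d), 0)
  Dm <- Matrix::Diagonal(np, dis)
  L <- Matrix::Diagonal(np) - Dm %*% Wp %*% Dm
  lmax <- .lmax_power(L)
  Lhat <- (2 / lmax) * L - Matrix::Diagonal(np)
  list(L = methods::as(Lhat, "CsparseMatrix"), lmax = lmax)
}

# largest eigenvalue of a symmetric PSD sparse matrix by power iteration
.lmax_power <- function(L, iters = 80L) {
  n <- nrow(L)
  v <- 1 + 1e-3 * seq_len(n) / n
  v <- v / sqrt(sum(v^2))
  nw <- 1
  for (it in seq_len(iters)) {
    w <- as.numeric(L %*% v)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) return(1)
    v <- w / nw
  }
  max(nw, 1e-6)
}

#' Build the graph operator for spectral convolution
#'
#' Computes the rescaled symmetric-normalized Laplacian of a connected prior
#' network, a greedy-matching coarsening hierarchy with padding ("fake")
#' vertices so each pooling step halves the vertex count exactly, and the
#' permutation aligning input features to the padded level-0 ordering. Fake
#' vertices carry zero features and no edges, so they never influence real
#' outputs.
#'
#' @param network A connected `similarity_network` (use [main_component()]
#'   first if needed).
#' @param levels Number of coarsening levels (= number of pooling layers).
#' @return A `graph_operator`.
#' @export
build_graph_operator <- function(network, levels = 2L) {
  comp <- decompose_network(network)
  if (length(comp$components) > 1L)
    en_stop("structure",
            "network is disconnected (%d components); extract the main component first",
            length(comp$components))
  vertices <- network$vertices
  n <- length(vertices)
  vid <- match(network$edges$from, vertices)
  wid <- match(network$edges$to, vertices)
  w <- if (network$weighted) abs(network$edges$weight) else rep(1, length(vid))
  W <- Matrix::sparseMatrix(i = c(vid, wid), j = c(wid, vid), x = c(w, w),
                            dims = c(n, n))
  graphs <- list(W)
  parents <- vector("list", levels)
  for (l in seq_len(levels)) {
    cluster <- .heavy_edge_matching(graphs[[l]])
    parents[[l]] <- cluster
    graphs[[l + 1L]] <- .coarsen_adjacency(graphs[[l]], cluster)
  }
  # padded orderings, coarsest to finest; NA marks a fake slot
  ords <- vector("list", levels + 1L)
  ords[[levels + 1L]] <- seq_len(nrow(graphs[[levels + 1L]]))
  for (l in seq(levels, 1L)) {
    by_parent <- split(seq_along(parents[[l]]), parents[[l]])
    out <- integer(0L)
    for (p in ords[[l + 1L]]) {
      ch <- if (is.na(p)) integer(0L) else sort(by_parent[[as.character(p)]] %||% integer(0L))
      ch <- c(ch, rep(NA_integer_, 2L - length(ch)))
      out <- c(out, ch)
    }
    ords[[l]] <- out
  }
  laps <- lapply(seq_len(levels), function(l)
    .padded_laplacian(graphs[[l]], ords[[l]]))
  structure(list(vertices = vertices, levels = as.integer(levels),
                 sizes = vapply(ords, length, integer(1L)),
                 L = lapply(laps, `[[`, "L"),
                 lmax = vapply(laps, `[[`, "lmax", FUN.VALUE = 0),
                 input_map = ords[[1L]]),
            class = "graph_operator")
}

#' @export
#' @method print graph_operator
print.graph_operator <- function(x, ...) {
  cat(sprintf("<graph_operator> %d vertices, %d levels, padded sizes %s\n",
              length(x$vertices), x$levels,
              paste(x$sizes, collapse = " -> ")))
  invisible(x)
}

# map samples x vertices features into the padded level-0 ordering
.align_features <- function(op, X) {
  if (!is.null(colnames(X))) {
    miss <- setdiff(op$vertices, colnames(X))
    if (length(miss))
      en_stop("alignment", "features missing for vertices: %s",
              paste(head(miss, 5L), collapse = ", "))
    X <- X[, op$vertices, drop = FALSE]
  } else if (ncol(X) != length(op$vertices)) {
    en_stop("alignment", "feature count %d != vertex count %d", ncol(X),
            length(op$vertices))
  }
  Xp <- matrix(0, nrow(X), op$sizes[1L])
  real <- which(!is.na(op$input_map))
  Xp[, real] <- X[, op$input_map[real]]
  rownames(Xp) <- rownames(X)
  Xp
}

# ---- Chebyshev polynomial application ------------------------------------

# L %*% X with a fast path for dgCMatrix
.Lmult <- function(L, X) {
  if (inherits(L, "dgCMatrix")) .sp_dense_prod(L, X) else as.matrix(L %*% X)
}

# alpha * L %*% X + Y1 - Y2 with a fused kernel for dgCMatrix
.Laffine <- function(L, X, alpha = 1, Y1 = NULL, Y2 = NULL) {
  if (inherits(L, "dgCMatrix")) return(.sp_affine(L, X, alpha, Y1, Y2))
  out <- alpha * as.matrix(L %*% X)
  if (!is.null(Y1)) out <- out + Y1
  if (!is.null(Y2)) out <- out - Y2
  out
}

# list of T_k(L) X for k = 0..K-1 (recurrence T_k = 2 L T_{k-1} - T_{k-2})
.cheb_stack <- function(L, X, K) {
  out <- vector("list", K)
  out[[1L]] <- X
  if (K >= 2L) out[[2L]] <- .Laffine(L, X)
  if (K >= 3L) for (k in 3:K)
    out[[k]] <- .Laffine(L, out[[k - 1L]], 2, Y2 = out[[k - 2L]])
  out
}

# sum_k T_k(L) G[[k+1]] via the Clenshaw reverse recurrence
.clenshaw_sum <- function(L, G) {
  K <- length(G)
  if (K == 1L) return(G[[1L]])
  bkp1 <- NULL
  bkp2 <- NULL
  for (k in seq(K - 1L, 1L)) {
    bk <- if (is.null(bkp1)) G[[k + 1L]]
          else .Laffine(L, bkp1, 2, G[[k + 1L]], bkp2)
    bkp2 <- bkp1
    bkp1 <- bk
  }
  .Laffine(L, bkp1, 1, G[[1L]], bkp2)
}

#' Chebyshev spectral graph convolution
#'
#' Computes `sum_k theta_k T_k(L) x` for `k = 0..K-1`, where `T_k` is the
#' Chebyshev polynomial of the rescaled graph Laplacian. An order-`K` filter
#' is localized to `K - 1` hops.
#'
#' @param features Per-vertex signal: a numeric vector or an
#'   `n x channels` matrix in the operator's vertex order.
#' @param operator A `graph_operator` (its level-1 Laplacian is used) or a
#'   Laplacian matrix directly.
#' @param K Chebyshev order.
#' @param weights Filter coefficients: a length-`K` vector (single channel)
#'   or a `(K * channels_in) x channels_out` matrix with rows ordered by
#'   polynomial order then input channel.
#' @return Matrix of per-vertex output signals (`n x channels_out`).
#' @export
chebyshev_conv <- function(features, operator, K, weights) {
  L <- if (inherits(operator, "graph_operator")) operator$L[[1L]] else operator
  X <- if (is.null(dim(features))) matrix(as.numeric(features), ncol = 1L)
       else as.matrix(features)
  if (nrow(X) != nrow(L))
    en_stop("shape", "features have %d rows but the Laplacian is %d x %d",
            nrow(X), nrow(L), ncol(L))
  Fin <- ncol(X)
  Wm <- if (is.null(dim(weights))) matrix(as.numeric(weights), ncol = 1L)
        else as.matrix(weights)
  if (nrow(Wm) != K * Fin)
    en_stop("shape", "weights have %d rows; expected K * channels_in = %d",
            nrow(Wm), K * Fin)
  S <- .cheb_stack(L, X, K)
  A <- do.call(cbind, S)  # n x (K * Fin), order: k block then input channel
  A %*% Wm
}

# ---- layer forward/backward ----------------------------------------------

# batched conv: Xarr is (n, B, Fin); returns Yarr (n, B, Fout) plus the
# cached GEMM design matrix. The compiled kernel builds the Chebyshev stack
# directly inside the design matrix and calls BLAS for the filter product;
# the (n, B*Fin) and ((n*B), Fin) views of each block share one buffer in
# column-major layout.
.conv_forward <- function(Xarr, L, W, b) .conv_fwd(L, Xarr, W, b)

.conv_backward <- function(dYarr, cache, L, W) .conv_bwd(L, dYarr, cache$A, W)

.glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -s, s), nin, nout)
}

.init_params <- function(arch, op, seed) {
  K <- arch$cheb_order
  F1 <- arch$n_filters[1L]
  F2 <- arch$n_filters[2L]
  flat <- (op$sizes[1L] / 4L) * F2
  with_seed(seed, list(
    conv1_W = .glorot(K, F1), conv1_b = numeric(F1),
    conv2_W = .glorot(K * F1, F2), conv2_b = numeric(F2),
    fc1_W = .glorot(flat, arch$fc[1L]), fc1_b = numeric(arch$fc[1L]),
    fc2_W = .glorot(arch$fc[1L], arch$fc[2L]), fc2_b = numeric(arch$fc[2L]),
    out_W = .glorot(arch$fc[2L], arch$n_classes),
    out_b = numeric(arch$n_classes)))
}

# forward pass; X is samples x padded-vertices. With `train = TRUE` dropout
# masks are drawn and caches kept for backprop.
.gcnn_forward <- function(params, op, arch, X, dropout = 0, train = FALSE) {
  B <- nrow(X)
  n0 <- op$sizes[1L]
  Xarr <- t(X)
  dim(Xarr) <- c(n0, B, 1L)
  c1 <- .conv_forward(Xarr, op$L[[1L]], params$conv1_W, params$conv1_b)
  p1 <- .relu_pool_fwd(c1$out)
  c2 <- .conv_forward(p1$out, op$L[[2L]], params$conv2_W, params$conv2_b)
  p2 <- .relu_pool_fwd(c2$out)
  n2 <- dim(p2$out)[1L]
  F2 <- dim(p2$out)[3L]
  H0 <- aperm(p2$out, c(2L, 1L, 3L))  # (B, n2, F2)
  dim(H0) <- c(B, n2 * F2)
  Z1 <- H0 %*% params$fc1_W + rep(params$fc1_b, each = B)
  A1 <- Z1; mf1 <- A1 > 0; A1[!mf1] <- 0
  d1 <- NULL
  if (train && dropout > 0) {
    d1 <- matrix(rbinom(length(A1), 1L, 1 - dropout), nrow(A1)) / (1 - dropout)
    A1 <- A1 * d1
  }
  Z2 <- A1 %*% params$fc2_W + rep(params$fc2_b, each = B)
  A2 <- Z2; mf2 <- A2 > 0; A2[!mf2] <- 0
  d2 <- NULL
  if (train && dropout > 0) {
    d2 <- matrix(rbinom(length(A2), 1L, 1 - dropout), nrow(A2)) / (1 - dropout)
    A2 <- A2 * d2
  }
  Z <- A2 %*% params$out_W + rep(params$out_b, each = B)
  Zs <- Z - apply(Z, 1L, max)
  P <- exp(Zs) / rowSums(exp(Zs))
  out <- list(prob = P)
  if (train)
    out <- c(out, list(c1 = c1, p1 = p1, c2 = c2, p2 = p2,
                       H0 = H0, mf1 = mf1, A1 = A1, d1 = d1, mf2 = mf2,
                       A2 = A2, d2 = d2, B = B, n2 = n2, F2 = F2))
  out
}

.gcnn_backward <- function(params, op, fw, y) {
  B <- fw$B
  Y1 <- matrix(0, B, ncol(fw$prob))
  Y1[cbind(seq_len(B), y + 1L)] <- 1
  dZ <- (fw$prob - Y1) / B
  g <- list()
  g$out_W <- crossprod(fw$A2, dZ)
  g$out_b <- colSums(dZ)
  dA2 <- tcrossprod(dZ, params$out_W)
  if (!is.null(fw$d2)) dA2 <- dA2 * fw$d2
  dZ2 <- dA2; dZ2[!fw$mf2] <- 0
  g$fc2_W <- crossprod(fw$A1, dZ2)
  g$fc2_b <- colSums(dZ2)
  dA1 <- tcrossprod(dZ2, params$fc2_W)
  if (!is.null(fw$d1)) dA1 <- dA1 * fw$d1
  dZ1 <- dA1; dZ1[!fw$mf1] <- 0
  g$fc1_W <- crossprod(fw$H0, dZ1)
  g$fc1_b <- colSums(dZ1)
  dH0 <- tcrossprod(dZ1, params$fc1_W)
  dim(dH0) <- c(B, fw$n2, fw$F2)
  dp2 <- aperm(dH0, c(2L, 1L, 3L))
  dr2 <- .relu_pool_bwd(dp2, fw$p2$top, fw$p2$pos)
  b2 <- .conv_backward(dr2, fw$c2, op$L[[2L]], params$conv2_W)
  g$conv2_W <- b2$dW
  g$conv2_b <- b2$db
  dr1 <- .relu_pool_bwd(b2$dX, fw$p1$top, fw$p1$pos)
  b1 <- .conv_backward(dr1, fw$c1, op$L[[1L]], params$conv1_W)
  g$conv1_W <- b1$dW
  g$conv1_b <- b1$db
  g
}

#' Train the graph-convolutional classifier
#'
#' Mini-batch training of the Chebyshev graph CNN on a graph-aligned
#' dataset with softmax cross-entropy and Adam. Deterministic given the
#' config seed.
#'
#' @param dataset A `graph_aligned_dataset` (see [align_to_graph()]) whose
#'   genes match the operator's vertices.
#' @param operator A `graph_operator` built on the dataset's network.
#' @param arch A [gcnn_architecture()].
#' @param config A [train_config()].
#' @return A `gcnn_model`.
#' @export
train_gcnn <- function(dataset, operator, arch = gcnn_architecture(),
                       config = train_config()) {
  X <- .align_features(operator, dataset$x)
  y <- as.integer(dataset$y)
  if (length(unique(y)) < 2L)
    en_stop("training", "training data contain a single class")
  params <- .init_params(arch, operator, config$seed)
  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- lapply(params, function(p) p * 0)
  nsamp <- nrow(X)
  history <- numeric(config$epochs)
  step <- 0L
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      idx <- sample.int(nsamp)
      losses <- numeric(0L)
      for (s in seq(1L, nsamp, by = config$batch_size)) {
        take <- idx[s:min(s + config$batch_size - 1L, nsamp)]
        if (length(take) < 2L) next
        fw <- .gcnn_forward(params, operator, arch, X[take, , drop = FALSE],
                            dropout = config$dropout, train = TRUE)
        p <- fw$prob[cbind(seq_along(take), y[take] + 1L)]
        losses <- c(losses, -mean(log(pmax(p, 1e-12))))
        g <- .gcnn_backward(params, operator, fw, y[take])
        step <- step + 1L
        for (nm in names(params))
          .adam_update(params[[nm]], g[[nm]], adam_m[[nm]], adam_v[[nm]],
                       step, config$learning_rate, 0.9, 0.999, 1e-8,
                       if (grepl("_W$", nm)) config$weight_decay else 0)
      }
      history[ep] <- mean(losses)
    }
  })
  tail_loss <- mean(history[max(1L, config$epochs - 2L):config$epochs])
  converged <- is.finite(tail_loss) && (config$epochs == 1L || tail_loss <= history[1L])
  structure(list(params = params, arch = arch, config = config,
                 operator = operator, history = history,
                 converged = converged),
            class = "gcnn_model")
}

#' @export
#' @method print gcnn_model
print.gcnn_model <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
#' @method format gcnn_model
format.gcnn_model <- function(x, ...) {
  a <- x$arch
  c(sprintf("<gcnn_model> %d convolutional layers x %d filters (Chebyshev order %d)",
            2L, a$n_filters[1L], a$cheb_order),
    sprintf("  max pooling of size %d after each convolution", a$pool_size),
    sprintf("  fully connected %s -> %d classes",
            paste(a$fc, collapse = " -> "), a$n_classes),
    sprintf("  trained %d epochs, final loss %.4f%s", x$config$epochs,
            x$history[length(x$history)],
            if (x$converged) "" else " (convergence failure)"))
}

#' Predict class-1 probabilities
#'
#' @param object A `gcnn_model`.
#' @param newdata Samples x genes matrix (columns matching the operator's
#'   vertices) or a `graph_aligned_dataset`.
#' @param ... Unused.
#' @return Numeric vector of class-1 probabilities.
#' @export
predict.gcnn_model <- function(object, newdata, ...) {
  if (inherits(newdata, "graph_aligned_dataset")) newdata <- newdata$x
  X <- .align_features(object$operator, newdata)
  fw <- .gcnn_forward(object$params, object$operator, object$arch, X,
                      dropout = 0, train = FALSE)
  stats::setNames(fw$prob[, 2L], rownames(newdata))
}

#' Classification metrics
#'
#' AUC (probability that a random positive outranks a random negative, ties
#' counting one half), accuracy and support-weighted F1 at the cutoff. All
#' returned in percent.
#'
#' @param truth 0/1 labels.
#' @param scores Class-1 probabilities or scores.
#' @param cutoff Classification cutoff for accuracy/F1.
#' @return Named numeric vector `auc`, `accuracy`, `f1_weighted` (percent).
#' @export
compute_metrics <- function(truth, scores, cutoff = 0.5) {
  truth <- as.integer(truth)
  if (length(truth) != length(scores))
    en_stop("shape", "truth and scores differ in length")
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L)
    en_stop("metric", "AUC undefined: only one class present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- as.integer(scores >= cutoff)
  acc <- mean(pred == truth)
  f1 <- vapply(c(0L, 1L), function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (2 * tp + fp + fn == 0L) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 0)
  support <- c(n0, n1) / length(truth)
  c(auc = 100 * auc, accuracy = 100 * acc,
    f1_weighted = 100 * sum(f1 * support))
}

#' Cross-validated evaluation of the graph CNN
#'
#' Stratified k-fold cross-validation: the model is trained on k-1 folds and
#' evaluated on the held-out fold; AUC, accuracy and weighted F1 are averaged
#' over folds with the standard error of the mean. Convergence failures are
#' recorded per fold, never silently averaged away.
#'
#' @param dataset A `graph_aligned_dataset`.
#' @param operator A `graph_operator` built on the dataset's network.
#' @param arch A [gcnn_architecture()].
#' @param config A [train_config()] (`folds`, `seed` control the split).
#' @return An `evaluation_result`: list with `folds` (per-fold metrics and
#'   convergence flags) and `summary` (mean and SEM per metric, percent).
#' @export
cross_validate <- function(dataset, operator, arch = gcnn_architecture(),
                           config = train_config()) {
  y <- as.integer(dataset$y)
  nfold <- config$folds
  if (min(table(y)) < nfold)
    en_stop("partition", "smallest class (%d samples) cannot stratify %d folds",
            min(table(y)), nfold)
  assign_fold <- integer(length(y))
  with_seed(config$seed, {
    for (cl in c(0L, 1L)) {
      ix <- sample(which(y == cl))
      assign_fold[ix] <- rep_len(seq_len(nfold), length(ix))
    }
  })
  rows <- vector("list", nfold)
  for (f in seq_len(nfold)) {
    test <- assign_fold == f
    tr_data <- structure(list(x = dataset$x[!test, , drop = FALSE],
                              y = dataset$y[!test], genes = dataset$genes,
                              network = dataset$network),
                         class = "graph_aligned_dataset")
    cfg <- config
    cfg$seed <- config$seed + f
    model <- train_gcnn(tr_data, operator, arch, cfg)
    scores <- predict(model, dataset$x[test, , drop = FALSE])
    m <- compute_metrics(y[test], scores)
    rows[[f]] <- data.frame(fold = f, auc = m[["auc"]],
                            accuracy = m[["accuracy"]],
                            f1_weighted = m[["f1_weighted"]],
                            converged = model$converged)
  }
  folds <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(c("auc", "accuracy", "f1_weighted"), function(mt)
    data.frame(metric = mt, mean = mean(folds[[mt]]),
               sem = sd(folds[[mt]]) / sqrt(nfold))))
  structure(list(folds = folds, summary = summ, fold_assignment = assign_fold),
            class = "evaluation_result")
}

#' @export
#' @method print evaluation_result
print.evaluation_result <- function(x, ...) {
  cat("<evaluation_result> ", nrow(x$folds), "-fold cross-validation\n", sep = "")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-12s %6.2f +- %.2f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sem[i]))
  nf <- sum(!x$folds$converged)
  if (nf > 0L) cat(sprintf("  (%d fold(s) reported convergence failure)\n", nf))
  invisible(x)
}
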