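#' Construct a similarity network
#'
#' An undirected weighted term graph. Edges are canonicalized (no self-loops,
#' no duplicates; duplicate input pairs keep the maximum weight).
#'
#' @param vertices Character vector of vertex names (may include isolated
#'   vertices).
#' @param edges Data.frame with columns `from`, `to` and optionally `weight`
#'   (defaults to 1).
#' @param threshold Threshold used to build the network, if any.
#' @param weighted Whether edge weights are meaningful (`FALSE` for purely
#'   topological networks; weights are stored as 1).
#' @return A `similarity_network`.
#' @export
similarity_network <- function(vertices, edges = NULL, threshold = NA_real_,
                               weighted = TRUE) {
  vertices <- unique(as.character(vertices))
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- data.frame(from = character(0L), to = character(0L),
                        weight = numeric(0L))
  } else {
    from <- as.character(edges[[1L]])
    to <- as.character(edges[[2L]])
    weight <- if (ncol(edges) >= 3L) as.numeric(edges[[3L]]) else rep(1, length(from))
    keep <- from != to
    from <- from[keep]; to <- to[keep]; weight <- weight[keep]
    a <- pmin(from, to)
    b <- pmax(from, to)
    key <- paste(a, b, sep = "\r")
    if (anyDuplicated(key)) {
      w <- tapply(weight, key, max)
      ab <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
      a <- ab[, 1L]; b <- ab[, 2L]; weight <- unname(w)
    }
    if (!weighted) weight <- rep(1, length(a))
    edges <- data.frame(from = a, to = b, weight = weight,
                        stringsAsFactors = FALSE)
    rownames(edges) <- NULL
    miss <- setdiff(unique(c(a, b)), vertices)
    if (length(miss))
      en_stop("validation", "edge endpoints missing from vertex set: %s",
              paste(head(miss, 5L), collapse = ", "))
  }
  structure(list(vertices = vertices, edges = edges,
                 threshold = threshold, weighted = isTRUE(weighted)),
            class = "similarity_network")
}

#' @export
#' @method print similarity_network
print.similarity_network <- function(x, ...) {
  cat(sprintf("<similarity_network> %d vertices, %d edges (%s%s)\n",
              length(x$vertices), nrow(x$edges),
              if (x$weighted) "weighted" else "unweighted",
              if (is.na(x$threshold)) "" else sprintf(", threshold %g", x$threshold)))
  invisible(x)
}

#' Convert a similarity network to an igraph graph
#' @param net A `similarity_network`.
#' @return An igraph graph with a `weight` edge attribute.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$vertices))
}

#' Build a thresholded cosine-similarity network
#'
#' Edge `(u, v)` is present iff `cosine(u, v) >= t` (closed bound), weighted
#' by the cosine similarity.
#'
#' @param emb An `embedding`.
#' @param terms Vertex terms; must all be in the vocabulary. When the
#'   embedding is typed, pass e.g. the gene-typed terms to build a gene-gene
#'   network.
#' @param t Cosine threshold.
#' @return A `similarity_network` over `terms`.
#' @export
build_similarity_network <- function(emb, terms, t) {
  terms <- unique(as.character(terms))
  missing <- setdiff(terms, emb$vocab)
  if (length(missing))
    en_stop("lookup", "terms not in vocabulary: %s",
            paste(head(missing, 10L), collapse = ", "))
  un <- .unit_rows(emb$vectors[match(terms, emb$vocab), , drop = FALSE])
  n <- length(terms)
  from <- list(); to <- list(); w <- list()
  chunk <- 512L
  starts <- seq(1L, n, by = chunk)
  for (s in starts) {
    e <- min(s + chunk - 1L, n)
    sims <- un[s:e, , drop = FALSE] %*% t(un)
    for (r in seq_len(e - s + 1L)) {
      i <- s + r - 1L
      if (i >= n) next
      js <- which(sims[r, (i + 1L):n] >= t) + i
      if (length(js)) {
        from[[length(from) + 1L]] <- rep(terms[i], length(js))
        to[[length(to) + 1L]] <- terms[js]
        w[[length(w) + 1L]] <- sims[r, js]
      }
    }
  }
  edges <- data.frame(from = unlist(from) %||% character(0L),
                      to = unlist(to) %||% character(0L),
                      weight = as.numeric(unlist(w) %||% numeric(0L)),
                      stringsAsFactors = FALSE)
  similarity_network(terms, edges, threshold = t, weighted = TRUE)
}

#' Connected-component decomposition
#'
#' Components are ordered by decreasing size; ties are broken by the
#' lexicographically smallest member. The first component is the main
#' component.
#'
#' @param net A `similarity_network`.
#' @return A `component_decomposition`: list with `components` (list of
#'   vertex-name vectors), `sizes` and `main`.
#' @export
decompose_network <- function(net) {
  g <- as_igraph(net)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- lapply(members, sort)
  sizes <- lengths(members)
  smallest <- vapply(members, `[[`, "", 1L)
  ord <- order(-sizes, smallest)
  members <- unname(members[ord])
  structure(list(components = members, sizes = unname(sizes[ord]),
                 main = members[[1L]]),
            class = "component_decomposition")
}

#' Extract the main connected component as a subnetwork
#' @param net A `similarity_network`.
#' @return A `similarity_network` restricted to the main component.
#' @export
main_component <- function(net) {
  main <- decompose_network(net)$main
  keep <- net$edges$from %in% main & net$edges$to %in% main
  similarity_network(main, net$edges[keep, , drop = FALSE],
                     threshold = net$threshold, weighted = net$weighted)
}

# main-component size of the graph over `terms` with edges of weight >= t
.main_size_at <- function(pairs, terms, t) {
  keep <- pairs$weight >= t
  if (!any(keep)) return(1L)
  g <- igraph::graph_from_data_frame(pairs[keep, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = terms))
  max(igraph::components(g)$csize)
}

#' Find the largest threshold reaching a target main-component size
#'
#' Scans the observed pairwise cosine weights (by bisection; the
#' main-component size is non-increasing in the threshold) for the largest
#' threshold whose main component has at least `target_vertices` vertices.
#' This reproduces the study's practice of picking score thresholds to match
#' vertex counts across network sources.
#'
#' @param emb An `embedding`.
#' @param terms Vertex terms.
#' @param target_vertices Desired main-component size (1..`length(terms)`).
#' @return List with `threshold` and `achieved` (main-component size at that
#'   threshold).
#' @export
threshold_for_size <- function(emb, terms, target_vertices) {
  terms <- unique(as.character(terms))
  if (target_vertices < 1L || target_vertices > length(terms))
    en_stop("parameter", "target_vertices must be in 1..%d", length(terms))
  missing <- setdiff(terms, emb$vocab)
  if (length(missing))
    en_stop("lookup", "terms not in vocabulary: %s",
            paste(head(missing, 10L), collapse = ", "))
  un <- .unit_rows(emb$vectors[match(terms, emb$vocab), , drop = FALSE])
  s <- tcrossprod(un)
  idx <- which(upper.tri(s), arr.ind = TRUE)
  pairs <- data.frame(from = terms[idx[, 1L]], to = terms[idx[, 2L]],
                      weight = s[upper.tri(s)], stringsAsFactors = FALSE)
  cand <- sort(unique(pairs$weight), decreasing = TRUE)  # high -> low
  best <- .main_size_at(pairs, terms, cand[length(cand)])
  if (best < target_vertices)
    en_stop("search",
            "target %d unreachable: best achievable main component has %d vertices",
            target_vertices, best)
  lo <- 1L  # highest threshold index known... searching smallest index satisfying
  hi <- length(cand)
  # find smallest index (largest threshold) with main size >= target
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (.main_size_at(pairs, terms, cand[mid]) >= target_vertices) hi <- mid
    else lo <- mid + 1L
  }
  list(threshold = cand[lo],
       achieved = .main_size_at(pairs, terms, cand[lo]))
}

#' Specification of a control network
#'
#' @param mode One of `k_out_random` (each vertex draws `k` partners
#'   uniformly, with repetition, collapsed to a simple undirected graph),
#'   `permute_vertices` (identical topology, labels permuted) or
#'   `random_weights` (identical topology, weights uniform in
#'   `weight_range`).
#' @param k Partners per vertex (`k_out_random`).
#' @param weight_range Interval for `random_weights`.
#' @param seed Integer seed.
#' @return A `control_spec`.
#' @export
control_spec <- function(mode = c("k_out_random", "permute_vertices",
                                  "random_weights"),
                         k = 8L, weight_range = c(0.65, 1), seed = 1L) {
  mode <- match.arg(mode)
  if (k < 0L) en_stop("parameter", "k must be >= 0")
  if (weight_range[1L] > weight_range[2L])
    en_stop("parameter", "weight_range must satisfy lo <= hi")
  structure(list(mode = mode, k = as.integer(k),
                 weight_range = as.numeric(weight_range),
                 seed = as.integer(seed)),
            class = "control_spec")
}

#' Build a control network
#'
#' Three randomized controls used to probe how much of a prior network's
#' value lies in its specific biology versus its topology or weights.
#'
#' @param reference A `similarity_network`, or (for `k_out_random`) a vertex
#'   count.
#' @param spec A [control_spec()].
#' @return A `similarity_network`.
#' @export
make_control_network <- function(reference, spec) {
  stopifnot(inherits(spec, "control_spec"))
  if (spec$mode == "k_out_random") {
    if (inherits(reference, "similarity_network")) {
      vertices <- reference$vertices
    } else {
      n <- as.integer(reference)
      vertices <- sprintf("v%0*d", nchar(n), seq_len(n))
    }
    n <- length(vertices)
    if (spec$k >= n)
      en_stop("parameter", "k (%d) must be smaller than the vertex count (%d)",
              spec$k, n)
    edges <- with_seed(spec$seed, {
      if (spec$k == 0L) {
        data.frame(from = character(0L), to = character(0L))
      } else {
        # each vertex draws k partners among the others, repetition allowed
        draws <- matrix(sample.int(n - 1L, n * spec$k, replace = TRUE),
                        nrow = n)
        i <- rep(seq_len(n), spec$k)
        j <- as.vector(draws)
        j <- j + (j >= i)  # skip self
        data.frame(from = vertices[pmin(i, j)], to = vertices[pmax(i, j)],
                   stringsAsFactors = FALSE)
      }
    })
    return(similarity_network(vertices, edges, weighted = FALSE))
  }
  if (!inherits(reference, "similarity_network"))
    en_stop("parameter", "mode '%s' needs a reference network", spec$mode)
  if (spec$mode == "permute_vertices") {
    relabel <- with_seed(spec$seed,
                         stats::setNames(sample(reference$vertices),
                                         reference$vertices))
    edges <- data.frame(from = unname(relabel[reference$edges$from]),
                        to = unname(relabel[reference$edges$to]),
                        weight = reference$edges$weight,
                        stringsAsFactors = FALSE)
    return(similarity_network(reference$vertices, edges,
                              threshold = reference$threshold,
                              weighted = reference$weighted))
  }
  # random_weights
  w <- with_seed(spec$seed,
                 runif(nrow(reference$edges), spec$weight_range[1L],
                       spec$weight_range[2L]))
  edges <- data.frame(from = reference$edges$from, to = reference$edges$to,
                      weight = w, stringsAsFactors = FALSE)
  similarity_network(reference$vertices, edges,
                     threshold = reference$threshold, weighted = TRUE)
}

#' Import a weighted edge list with thresholding
#'
#' Reads a TSV edge list (`term_a<TAB>term_b<TAB>weight`), drops self-loops,
#' keeps the maximum weight of duplicate pairs and retains edges with weight
#' `>= t` (a STRING-style score import).
#'
#' @param path TSV file without header.
#' @param t Weight threshold.
#' @return A `similarity_network` over the endpoints of retained edges.
#' @export
import_weighted_edges <- function(path, t = -Inf) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    en_stop("parse", "malformed edge line %d: '%s'", bad[1L], lines[bad[1L]])
  w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(w)) {
    bad <- which(is.na(w))[1L]
    en_stop("parse", "non-numeric weight on line %d: '%s'", bad, lines[bad])
  }
  df <- data.frame(from = vapply(parts, `[[`, "", 1L),
                   to = vapply(parts, `[[`, "", 2L),
                   weight = w, stringsAsFactors = FALSE)
  df <- df[df$from != df$to, , drop = FALSE]
  # dedupe by max weight before thresholding
  key <- pair_key(df$from, df$to)
  mx <- tapply(df$weight, key, max)
  df <- df[!duplicated(key), , drop = FALSE]
  df$weight <- unname(mx[pair_key(df$from, df$to)])
  df <- df[df$weight >= t, , drop = FALSE]
  similarity_network(unique(c(df$from, df$to)), df, threshold = t,
                     weighted = TRUE)
}

#' Write a network as a TSV edge list
#' @param net A `similarity_network`.
#' @param path Output file.
#' @param vertices_path Optional sidecar listing all vertices (including
#'   isolated ones).
#' @export
write_network <- function(net, path, vertices_path = NULL) {
  writeLines(sprintf("%s\t%s\t%.9g", net$edges$from, net$edges$to,
                     net$edges$weight), path)
  if (!is.null(vertices_path)) writeLines(net$vertices, vertices_path)
  invisible(path)
}

#' Degree statistics of a network
#'
#' Mean, median and standard deviation of the degree distribution (isolated
#' vertices included).
#'
#' @param net A `similarity_network`.
#' @return Named numeric vector `mean`, `median`, `sd`.
#' @export
degree_stats <- function(net) {
  deg <- igraph::degree(as_igraph(net))
  c(mean = mean(deg), median = median(deg), sd = sd(deg))
}
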