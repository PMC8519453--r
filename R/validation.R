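#' Construct an entity group
#'
#' A named set of terms (e.g. a pathway's genes or a disease-ontology
#' group's diseases) used to validate embedding similarities.
#'
#' @param group_id Identifier.
#' @param members Character vector of member terms.
#' @param entity_type Entity type of the members.
#' @return An `entity_group`.
#' @export
entity_group <- function(group_id, members, entity_type = "gene") {
  structure(list(group_id = as.character(group_id),
                 members = unique(as.character(members)),
                 entity_type = entity_type),
            class = "entity_group")
}

#' Read groups from a GMT file
#'
#' GMT format: `group_id<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path GMT file.
#' @param entity_type Entity type assigned to all groups in the file.
#' @return List of `entity_group`s.
#' @export
load_gmt <- function(path, entity_type = "gene") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      en_stop("parse", "GMT line with fewer than 3 fields: '%s'", ln)
    entity_group(parts[1L], parts[-(1:2)], entity_type)
  })
}

#' Write groups to a GMT file
#' @param groups List of `entity_group`s.
#' @param path Output file.
#' @export
write_gmt <- function(groups, path) {
  writeLines(vapply(groups, function(g)
    paste(c(g$group_id, g$entity_type, g$members), collapse = "\t"), ""), path)
  invisible(path)
}

# quartiles with the linear-interpolation convention (stats::quantile type 7)
.quartiles <- function(x) {
  q <- unname(quantile(x, probs = c(0.25, 0.5, 0.75), type = 7))
  c(q1 = q[1L], median = q[2L], q3 = q[3L])
}

# all pairwise cosines among `terms` (must be in the embedding)
.pairwise_cosines <- function(emb, terms) {
  un <- .unit_rows(emb$vectors[match(terms, emb$vocab), , drop = FALSE])
  s <- tcrossprod(un)
  s[upper.tri(s)]
}

#' Within-group cosine-similarity quartiles
#'
#' For every group whose count of embedding-present members `x` satisfies
#' `min_size <= x <= max_size`, computes lower quartile, median and upper
#' quartile over all `x(x-1)/2` pairwise cosine similarities. Groups with
#' fewer than 2 present members are excluded silently.
#'
#' @param emb An `embedding`.
#' @param groups List of `entity_group`s.
#' @param min_size,max_size Bounds on the embedding-present group size
#'   (study defaults: genes 10..3000, diseases 6..999).
#' @return A `group_summary` data.frame: `group_id`, `x`, `q1`, `median`, `q3`.
#' @export
group_similarity_summary <- function(emb, groups, min_size = 10L,
                                     max_size = 3000L) {
  if (min_size < 2L) en_stop("parameter", "min_size must be >= 2")
  rows <- lapply(groups, function(g) {
    present <- intersect(g$members, emb$vocab)
    x <- length(present)
    if (x < 2L || x < min_size || x > max_size) return(NULL)
    q <- .quartiles(.pairwise_cosines(emb, present))
    data.frame(group_id = g$group_id, x = x, q1 = q[["q1"]],
               median = q[["median"]], q3 = q[["q3"]],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, NA)]
  if (length(rows) == 0L) {
    warning("no groups survived the size filter")
    return(data.frame(group_id = character(0L), x = integer(0L),
                      q1 = numeric(0L), median = numeric(0L), q3 = numeric(0L)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sample random unordered term pairs
#'
#' Draws `n` distinct unordered pairs uniformly without replacement from all
#' pairs of `terms`, excluding `excluded_pairs`.
#'
#' @param terms Character vector of terms.
#' @param n Number of pairs.
#' @param excluded_pairs Optional two-column data.frame (or matrix) of pairs
#'   to exclude.
#' @param seed Integer seed.
#' @return Data.frame with columns `a`, `b`.
#' @export
sample_random_pairs <- function(terms, n, excluded_pairs = NULL, seed = 1L) {
  terms <- unique(as.character(terms))
  m <- length(terms)
  if (n == 0L) return(data.frame(a = character(0L), b = character(0L)))
  total <- m * (m - 1) / 2
  excl <- character(0L)
  if (!is.null(excluded_pairs) && NROW(excluded_pairs) > 0L) {
    ea <- as.character(excluded_pairs[[1L]])
    eb <- as.character(excluded_pairs[[2L]])
    keep <- ea %in% terms & eb %in% terms & ea != eb
    excl <- unique(pair_key(ea[keep], eb[keep]))
  }
  admissible <- total - length(excl)
  if (admissible < n)
    en_stop("sampling",
            "cannot draw %d pairs: only %d admissible (deficit %d)",
            n, admissible, n - admissible)
  with_seed(seed, {
    got <- character(0L)
    out_a <- character(0L)
    out_b <- character(0L)
    guard <- 0L
    while (length(out_a) < n) {
      guard <- guard + 1L
      if (guard > 10000L) en_stop("sampling", "pair sampling did not terminate")
      todo <- n - length(out_a)
      batch <- max(2L * todo, 32L)
      i <- sample.int(m, batch, replace = TRUE)
      j <- sample.int(m, batch, replace = TRUE)
      ok <- i != j
      a <- terms[pmin(i[ok], j[ok])]
      b <- terms[pmax(i[ok], j[ok])]
      key <- pair_key(a, b)
      new <- !(key %in% excl) & !(key %in% got) & !duplicated(key)
      take <- which(new)[seq_len(min(todo, sum(new)))]
      got <- c(got, key[take])
      out_a <- c(out_a, a[take])
      out_b <- c(out_b, b[take])
    }
    data.frame(a = out_a, b = out_b, stringsAsFactors = FALSE)
  })
}

#' Fit the group-size decay curve
#'
#' Fits `f(x) = (x^a + b)^-1` to group medians as a function of group size
#' by nonlinear least squares (initialized at `a = 1, b = 0`, with `a >= 0`;
#' multi-start over `a` in 0.1/0.5/1/2 on failure).
#'
#' @param summaries A `group_summary` data.frame from
#'   [group_similarity_summary()] (columns `x` and `median`).
#' @return A `decay_fit`: list with `a`, `b`, `rss`, `converged`, `start`.
#' @export
fit_decay <- function(summaries) {
  df <- data.frame(x = as.numeric(summaries$x), y = as.numeric(summaries$median))
  if (length(unique(df$x)) < 3L)
    en_stop("fit", "need >= 3 summaries with distinct sizes")
  starts <- list(c(a = 1, b = 0), c(a = 0.1, b = 0), c(a = 0.5, b = 0),
                 c(a = 2, b = 0))
  best <- NULL
  last_err <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ 1 / (x^a + b), data = df, start = as.list(st),
                        lower = c(a = 0, b = -0.999),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      last_err <- fit
      next
    }
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(fit)
      best <- list(a = unname(cf["a"]), b = unname(cf["b"]), rss = rss,
                   converged = fit$convInfo$isConv %||% TRUE, start = st)
    }
  }
  if (is.null(best))
    en_stop("fit", "decay fit failed to converge from all starts (last: %s)",
            conditionMessage(last_err))
  structure(best, class = "decay_fit")
}

#' Evaluate a fitted decay curve
#' @param fit A `decay_fit`.
#' @param x Group sizes.
#' @export
decay_predict <- function(fit, x) 1 / (x^fit$a + fit$b)

#' Loess trend of group medians
#'
#' Local linear regression (degree 1, tricube weights) of group medians
#' against group size, evaluated at the observed sizes. Used where the
#' parametric decay curve is not appropriate (the disease-ontology panel).
#'
#' @param summaries A `group_summary` data.frame.
#' @param span Smoothing span in `(0, 1]`.
#' @return Data.frame `x`, `fitted`, ordered by `x`.
#' @export
loess_trend <- function(summaries, span = 0.75) {
  if (!is.numeric(span) || span <= 0 || span > 1)
    en_stop("parameter", "span must be in (0, 1]")
  df <- data.frame(x = as.numeric(summaries$x), y = as.numeric(summaries$median))
  if (nrow(df) < 5L) en_stop("parameter", "need >= 5 points for a loess trend")
  fit <- loess(y ~ x, data = df, span = span, degree = 1, family = "gaussian",
               control = loess.control(surface = "direct"))
  out <- data.frame(x = df$x, fitted = as.numeric(predict(fit, df)))
  out[order(out$x), , drop = FALSE]
}

#' Compare cosine similarities of known pairs against random pairs
#'
#' Samples `n` positive pairs (e.g. known protein-protein interactions) and
#' `n` random pairs excluding all positives, and summarizes the two cosine
#' distributions.
#'
#' @param emb An `embedding`.
#' @param positive_pairs Two-column data.frame of known pairs.
#' @param n Pairs per arm.
#' @param seed Integer seed.
#' @param terms Universe for the random arm; defaults to gene-typed terms if
#'   the embedding is typed, otherwise to the full vocabulary.
#' @return A `paired_similarity_sample`: list with `positive`, `random`
#'   (data.frames `a,b,cosine`) and `summary` (quartiles per arm).
#' @export
paired_similarity_comparison <- function(emb, positive_pairs, n, seed = 1L,
                                         terms = NULL) {
  pa <- as.character(positive_pairs[[1L]])
  pb <- as.character(positive_pairs[[2L]])
  keep <- pa %in% emb$vocab & pb %in% emb$vocab & pa != pb
  pa <- pa[keep]
  pb <- pb[keep]
  key <- pair_key(pa, pb)
  dup <- duplicated(key)
  pa <- pa[!dup]; pb <- pb[!dup]
  if (length(pa) < n)
    en_stop("sampling", "only %d positive pairs available, %d requested",
            length(pa), n)
  if (is.null(terms)) {
    terms <- if (!is.null(emb$types)) names(emb$types)[emb$types == "gene"] else emb$vocab
    terms <- intersect(terms, emb$vocab)
  }
  pos_idx <- with_seed(seed, sample.int(length(pa), n))
  pos <- data.frame(a = pa[pos_idx], b = pb[pos_idx], stringsAsFactors = FALSE)
  rnd <- sample_random_pairs(terms, n,
                             excluded_pairs = data.frame(a = pa, b = pb),
                             seed = seed + 1L)
  cos_of <- function(df) {
    un <- .unit_rows(emb$vectors[match(unique(c(df$a, df$b)), emb$vocab), , drop = FALSE])
    rownames(un) <- unique(c(df$a, df$b))
    rowSums(un[df$a, , drop = FALSE] * un[df$b, , drop = FALSE])
  }
  pos$cosine <- as.numeric(cos_of(pos))
  rnd$cosine <- as.numeric(cos_of(rnd))
  sm <- rbind(
    data.frame(arm = "positive", n = nrow(pos), t(.quartiles(pos$cosine))),
    data.frame(arm = "random", n = nrow(rnd), t(.quartiles(rnd$cosine))))
  structure(list(positive = pos, random = rnd, summary = sm, requested_n = n),
            class = "paired_similarity_sample")
}

#' Load PPI pairs from a TSV file (`gene_a<TAB>gene_b`)
#' @param path TSV file, no header.
#' @export
load_ppi_pairs <- function(path) {
  df <- read.delim(path, header = FALSE, sep = "\t", colClasses = "character")
  names(df)[1:2] <- c("a", "b")
  df[1:2]
}

#' Load drug-target assignments from a TSV file (`drug<TAB>gene`)
#' @param path TSV file, no header.
#' @return Named list mapping each drug to its target gene set.
#' @export
load_drug_targets <- function(path) {
  df <- read.delim(path, header = FALSE, sep = "\t", colClasses = "character")
  split(df[[2L]], df[[1L]])
}

#' Drug-pair similarity by shared-target stratum
#'
#' Assigns drug pairs to strata by the number of target genes the two drugs
#' share (study strata: none, 1..5, 6..9), samples up to `n` pairs per
#' stratum, and summarizes cosine similarities per stratum.
#'
#' @param emb An `embedding`.
#' @param targets Named list mapping drugs to target gene sets (see
#'   [load_drug_targets()]).
#' @param group_bounds Strictly increasing shared-count bounds; the default
#'   `c(0, 5, 9)` yields strata `0`, `1..5` and `6..9`.
#' @param n Maximum sampled pairs per stratum.
#' @param seed Integer seed.
#' @return List with `pairs` (all strata-assigned pairs) and `summary`
#'   (per-stratum counts and cosine quartiles).
#' @export
drug_shared_target_analysis <- function(emb, targets, group_bounds = c(0, 5, 9),
                                        n = 50000L, seed = 1L) {
  if (any(diff(group_bounds) <= 0))
    en_stop("parameter", "group_bounds must be strictly increasing")
  drugs <- names(targets)
  absent <- setdiff(drugs, emb$vocab)
  if (length(absent) == length(drugs))
    en_stop("lookup", "no drugs present in the embedding")
  drugs <- intersect(drugs, emb$vocab)
  m <- length(drugs)
  if (m < 2L) en_stop("sampling", "need >= 2 embedding-present drugs")
  idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  a <- drugs[idx[, 1L]]
  b <- drugs[idx[, 2L]]
  shared <- mapply(function(x, y) length(intersect(targets[[x]], targets[[y]])),
                   a, b, USE.NAMES = FALSE)
  stratum <- rep(NA_integer_, length(shared))
  stratum[shared <= group_bounds[1L]] <- 1L
  for (g in seq_along(group_bounds)[-1L])
    stratum[shared > group_bounds[g - 1L] & shared <= group_bounds[g]] <- g
  pairs <- data.frame(a = a, b = b, shared = shared, stratum = stratum,
                      stringsAsFactors = FALSE)
  un <- .unit_rows(emb$vectors[match(drugs, emb$vocab), , drop = FALSE])
  rownames(un) <- drugs
  pairs$cosine <- rowSums(un[pairs$a, , drop = FALSE] * un[pairs$b, , drop = FALSE])
  sm <- lapply(seq_along(group_bounds), function(g) {
    sub <- pairs[!is.na(pairs$stratum) & pairs$stratum == g, , drop = FALSE]
    if (nrow(sub) == 0L)
      return(data.frame(stratum = g, n_pairs = 0L, n_sampled = 0L,
                        q1 = NA_real_, median = NA_real_, q3 = NA_real_))
    take <- if (nrow(sub) > n)
      with_seed(seed + g, sample.int(nrow(sub), n)) else seq_len(nrow(sub))
    q <- .quartiles(sub$cosine[take])
    data.frame(stratum = g, n_pairs = nrow(sub), n_sampled = length(take),
               q1 = q[["q1"]], median = q[["median"]], q3 = q[["q3"]])
  })
  list(pairs = pairs, summary = do.call(rbind, sm), requested_n = n)
}
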