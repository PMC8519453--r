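# Synthetic-data generators. They emulate, at desk scale, the statistical
# structure the analysis assumes: a literature corpus in which functionally
# related entities co-occur in the same documents (with synonym variants), a
# knowledgebase consistent with the planted groups, and expression cohorts
# whose class signal is smooth on a supplied prior network.

#' Specification of a synthetic corpus
#'
#' Documents are token streams: each document is "about" one planted entity
#' group, whose member genes appear at the within-group rate while all other
#' entities appear at the background rate, mixed with Zipf-distributed filler
#' vocabulary. Each entity occurrence is emitted as one of its synonym
#' variants with probability `synonym_prob`. Each group also owns diseases
#' and drugs that co-occur with it; drug target sets are nested subsets of
#' the group's genes so that drug pairs realize distinct shared-target
#' strata.
#'
#' @param n_documents Number of documents.
#' @param n_groups Number of planted groups.
#' @param group_size Genes per group.
#' @param within_rate Per-document inclusion probability of each focal-group
#'   gene.
#' @param background_rate Per-document inclusion probability of every other
#'   entity.
#' @param diseases_per_group,drugs_per_group Entities attached to each group.
#' @param disease_rate,drug_rate Inclusion probabilities of the focal group's
#'   diseases/drugs.
#' @param synonyms_per_entity Synonym variants per entity.
#' @param synonym_prob Probability an occurrence is emitted as a synonym.
#' @param vocab_background Filler vocabulary size.
#' @param doc_length_mean Mean filler tokens per document (Poisson).
#' @param n_genes Total gene pool; must be >= `n_groups * group_size`.
#' @param seed Integer seed.
#' @return A `corpus_spec`.
#' @export
corpus_spec <- function(n_documents = 2000L, n_groups = 10L, group_size = 10L,
                        within_rate = 0.3, background_rate = 0.01,
                        diseases_per_group = 3L, drugs_per_group = 3L,
                        disease_rate = 0.3, drug_rate = 0.15,
                        synonyms_per_entity = 2L, synonym_prob = 0.5,
                        vocab_background = 300L, doc_length_mean = 25,
                        n_genes = NULL, seed = 1L) {
  rates <- c(within_rate, background_rate, disease_rate, drug_rate, synonym_prob)
  if (any(rates < 0 | rates > 1))
    en_stop("spec", "all rates must lie in [0, 1]")
  if (within_rate <= background_rate)
    en_stop("spec", "within_rate must exceed background_rate for planted signal")
  n_genes <- as.integer(n_genes %||% (n_groups * group_size))
  if (n_genes < n_groups * group_size)
    en_stop("spec", "gene pool (%d) smaller than groups need (%d)",
            n_genes, n_groups * group_size)
  structure(list(n_documents = as.integer(n_documents),
                 n_groups = as.integer(n_groups),
                 group_size = as.integer(group_size),
                 within_rate = within_rate, background_rate = background_rate,
                 diseases_per_group = as.integer(diseases_per_group),
                 drugs_per_group = as.integer(drugs_per_group),
                 disease_rate = disease_rate, drug_rate = drug_rate,
                 synonyms_per_entity = as.integer(synonyms_per_entity),
                 synonym_prob = synonym_prob,
                 vocab_background = as.integer(vocab_background),
                 doc_length_mean = doc_length_mean,
                 n_genes = n_genes, seed = as.integer(seed)),
            class = "corpus_spec")
}

# entity catalog: names, group memberships, synonyms, drug targets
.corpus_entities <- function(spec) {
  genes <- sprintf("gene%03d", seq_len(spec$n_genes))
  groups <- lapply(seq_len(spec$n_groups), function(g)
    genes[((g - 1L) * spec$group_size + 1L):(g * spec$group_size)])
  names(groups) <- sprintf("group%02d", seq_len(spec$n_groups))
  diseases <- lapply(seq_len(spec$n_groups), function(g)
    sprintf("malady%02d%s", g, letters[seq_len(spec$diseases_per_group)]))
  drugs <- lapply(seq_len(spec$n_groups), function(g)
    sprintf("remedium%02d%s", g, letters[seq_len(spec$drugs_per_group)]))
  # drug target sets: nested subsets of the group's genes, so same-group
  # drug pairs share many targets and cross-group pairs share none
  drug_targets <- list()
  for (g in seq_len(spec$n_groups)) {
    gg <- groups[[g]]
    sizes <- c(9L, 6L, 5L, 8L, 7L)
    for (d in seq_len(spec$drugs_per_group)) {
      sz <- min(sizes[(d - 1L) %% length(sizes) + 1L], length(gg))
      off <- if (d >= 3L) min(4L, length(gg) - sz) else 0L
      drug_targets[[drugs[[g]][d]]] <- gg[(1L + off):(off + sz)]
    }
  }
  all_entities <- c(genes, unlist(diseases), unlist(drugs))
  types <- c(rep("gene", length(genes)),
             rep("disease", length(unlist(diseases))),
             rep("drug", length(unlist(drugs))))
  names(types) <- all_entities
  # synonym variants; the second disease variant is a two-word phrase to
  # exercise multi-word dictionary matching
  syn_rows <- list()
  synonyms <- list()
  for (ent in all_entities) {
    v <- character(0L)
    if (spec$synonyms_per_entity >= 1L) v <- c(v, paste0(ent, "x"))
    if (spec$synonyms_per_entity >= 2L) {
      v <- c(v, if (types[[ent]] == "disease")
        paste(paste0(ent, "w"), "disorder") else paste0(ent, "z"))
    }
    if (spec$synonyms_per_entity >= 3L)
      v <- c(v, paste0(ent, letters[3:spec$synonyms_per_entity], "alt"))
    synonyms[[ent]] <- v
    for (s in v)
      syn_rows[[length(syn_rows) + 1L]] <- data.frame(
        preferred_term = ent, synonym = s, entity_type = types[[ent]],
        stringsAsFactors = FALSE)
  }
  list(genes = genes, groups = groups, diseases = diseases, drugs = drugs,
       drug_targets = drug_targets, types = types, synonyms = synonyms,
       synonym_df = do.call(rbind, syn_rows))
}

#' Generate a synthetic corpus with planted co-occurrence structure
#'
#' @param spec A [corpus_spec()].
#' @return List with `documents` (named character vector, one document per
#'   element) and `truth` (planted group memberships, entity types, synonym
#'   table and drug-target assignments).
#' @export
generate_corpus <- function(spec = corpus_spec()) {
  stopifnot(inherits(spec, "corpus_spec"))
  ents <- .corpus_entities(spec)
  fillers <- sprintf("word%04d", seq_len(spec$vocab_background))
  zipf <- (1 / seq_len(spec$vocab_background))
  zipf <- zipf / sum(zipf)
  n_ent <- length(ents$types)
  ent_names <- names(ents$types)
  docs <- with_seed(spec$seed, {
    vapply(seq_len(spec$n_documents), function(d) {
      g <- sample.int(spec$n_groups, 1L)
      present <- runif(n_ent) < spec$background_rate
      focal_genes <- ents$groups[[g]]
      present[match(focal_genes, ent_names)] <-
        runif(length(focal_genes)) < spec$within_rate
      focal_dis <- ents$diseases[[g]]
      present[match(focal_dis, ent_names)] <-
        runif(length(focal_dis)) < spec$disease_rate
      focal_drug <- ents$drugs[[g]]
      present[match(focal_drug, ent_names)] <-
        runif(length(focal_drug)) < spec$drug_rate
      units <- lapply(ent_names[present], function(ent) {
        if (spec$synonym_prob > 0 && length(ents$synonyms[[ent]]) > 0L &&
            runif(1L) < spec$synonym_prob) {
          sample(ents$synonyms[[ent]], 1L)
        } else ent
      })
      nfill <- rpois(1L, spec$doc_length_mean)
      if (nfill > 0L)
        units <- c(units, as.list(sample(fillers, nfill, replace = TRUE,
                                         prob = zipf)))
      paste(unlist(lapply(sample(units), strsplit, " ", fixed = TRUE)),
            collapse = " ")
    }, "")
  })
  names(docs) <- sprintf("doc%d", seq_along(docs))
  truth <- list(groups = ents$groups, diseases = ents$diseases,
                drugs = ents$drugs, drug_targets = ents$drug_targets,
                types = ents$types, synonym_df = ents$synonym_df,
                spec = spec)
  list(documents = docs, truth = truth)
}

#' Emit knowledgebase files consistent with a planted corpus
#'
#' Writes GMT group files for gene groups and disease groups, a PPI pair
#' list containing exactly the within-group gene pairs, a drug-target TSV and
#' the synonym table TSV.
#'
#' @param truth The `truth` component returned by [generate_corpus()].
#' @param dir Output directory (created if missing).
#' @return Named list of file paths plus the in-memory objects (`groups`,
#'   `ppi`, `drug_targets`, `synonyms`).
#' @export
generate_knowledgebase <- function(truth, dir = tempfile("kb")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gene_groups <- Map(function(id, members) entity_group(id, members, "gene"),
                     names(truth$groups), truth$groups)
  disease_groups <- Map(function(i, members)
    entity_group(sprintf("disease_group%02d", i), members, "disease"),
    seq_along(truth$diseases), truth$diseases)
  ppi <- do.call(rbind, lapply(truth$groups, function(gg) {
    idx <- which(upper.tri(matrix(0, length(gg), length(gg))), arr.ind = TRUE)
    data.frame(a = gg[idx[, 1L]], b = gg[idx[, 2L]], stringsAsFactors = FALSE)
  }))
  rownames(ppi) <- NULL
  paths <- list(
    gene_groups = file.path(dir, "gene_groups.gmt"),
    disease_groups = file.path(dir, "disease_groups.gmt"),
    ppi = file.path(dir, "ppi.tsv"),
    drug_targets = file.path(dir, "drug_targets.tsv"),
    synonyms = file.path(dir, "synonyms.tsv"))
  write_gmt(gene_groups, paths$gene_groups)
  write_gmt(disease_groups, paths$disease_groups)
  writeLines(paste(ppi$a, ppi$b, sep = "\t"), paths$ppi)
  dt <- truth$drug_targets
  writeLines(unlist(Map(function(d, gs) paste(d, gs, sep = "\t"),
                        names(dt), dt)),
             paths$drug_targets)
  utils::write.table(truth$synonym_df, paths$synonyms, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  c(paths, list(groups = unname(gene_groups),
                disease_groups = unname(disease_groups), ppi = ppi,
                drug_targets = dt, synonyms = truth$synonym_df))
}

#' Generate a connected scale-free prior network
#'
#' A preferential-attachment graph, the conventional stand-in for the
#' degree structure of curated protein-protein interaction networks; always
#' connected, which the graph-convolution formulation requires.
#'
#' @param n_vertices Number of vertices.
#' @param edges_per_vertex Attachment edges per new vertex.
#' @param seed Integer seed.
#' @return An unweighted `similarity_network`.
#' @export
simulate_prior_network <- function(n_vertices = 500L, edges_per_vertex = 3L,
                                   seed = 1L) {
  g <- with_seed(seed,
                 igraph::sample_pa(n_vertices, m = edges_per_vertex,
                                   directed = FALSE))
  names <- sprintf("gene%04d", seq_len(n_vertices))
  el <- igraph::as_edgelist(g, names = FALSE)
  similarity_network(names,
                     data.frame(from = names[el[, 1L]], to = names[el[, 2L]],
                                stringsAsFactors = FALSE),
                     weighted = FALSE)
}

#' Specification of a synthetic expression cohort
#'
#' Class 0 samples are baseline Gaussian per gene; class 1 samples receive a
#' mean shift on a connected signal subnetwork, attenuated exponentially
#' with hop distance from the subnetwork's seed vertex (so the class signal
#' is smooth on the graph). The matrix is then quantile normalized across
#' samples and shifted to a non-negative range. The default class sizes
#' emulate the study's 40:60 imbalance at n = 300.
#'
#' @param network Prior `similarity_network` (connected).
#' @param n_class0,n_class1 Samples per class (default 180 / 120).
#' @param signal_size Vertices in the signal subnetwork.
#' @param effect Mean shift (in noise-sd units) at the signal seed vertex.
#' @param noise_sd Per-gene Gaussian noise standard deviation.
#' @param decay_rate Exponential attenuation per hop.
#' @param quantile_normalize Apply quantile normalization across samples.
#' @param seed Integer seed.
#' @return An `expression_spec`.
#' @export
expression_spec <- function(network, n_class0 = 180L, n_class1 = 120L,
                            signal_size = 30L, effect = 2, noise_sd = 1,
                            decay_rate = 0.5, quantile_normalize = TRUE,
                            seed = 1L) {
  if (effect < 0) en_stop("spec", "effect size must be >= 0")
  if (signal_size > length(network$vertices))
    en_stop("spec", "signal subnetwork larger than the network")
  structure(list(network = network, n_class0 = as.integer(n_class0),
                 n_class1 = as.integer(n_class1),
                 signal_size = as.integer(signal_size), effect = effect,
                 noise_sd = noise_sd, decay_rate = decay_rate,
                 quantile_normalize = isTRUE(quantile_normalize),
                 seed = as.integer(seed)),
            class = "expression_spec")
}

#' Generate a graph-smooth synthetic expression cohort
#'
#' @param spec An [expression_spec()].
#' @return List with `matrix` (samples x genes), `labels` (named 0/1
#'   vector), `signal_genes` and `effect_profile` (per-gene mean shift).
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "expression_spec"))
  net <- spec$network
  if (length(decompose_network(net)$components) > 1L)
    en_stop("spec", "prior network must be connected")
  g <- as_igraph(net)
  genes <- net$vertices
  n_genes <- length(genes)
  n <- spec$n_class0 + spec$n_class1
  with_seed(spec$seed, {
    seed_vertex <- sample(genes, 1L)
    dists <- igraph::distances(g, v = seed_vertex)[1L, ]
    ord <- order(dists, names(dists))
    signal <- names(dists)[ord][seq_len(spec$signal_size)]
    shift <- numeric(n_genes)
    names(shift) <- genes
    shift[signal] <- spec$effect * spec$noise_sd *
      exp(-spec$decay_rate * dists[signal])
    baseline <- rnorm(n_genes, mean = 7, sd = 1)
    X <- matrix(rnorm(n * n_genes, sd = spec$noise_sd), n, n_genes)
    X <- sweep(X, 2L, baseline, `+`)
    y <- c(rep(0L, spec$n_class0), rep(1L, spec$n_class1))
    X[y == 1L, ] <- sweep(X[y == 1L, , drop = FALSE], 2L, shift, `+`)
    perm <- sample.int(n)
    X <- X[perm, , drop = FALSE]
    y <- y[perm]
    rownames(X) <- sprintf("sample%03d", seq_len(n))
    colnames(X) <- genes
    names(y) <- rownames(X)
    if (spec$quantile_normalize) {
      dn <- dimnames(X)
      X <- t(limma::normalizeQuantiles(t(X)))
      dimnames(X) <- dn
    }
    X <- nonnegative_shift(X)
    list(matrix = X, labels = y, signal_genes = signal,
         effect_profile = shift, seed_vertex = seed_vertex)
  })
}
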