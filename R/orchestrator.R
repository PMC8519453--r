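# Single entry point wiring the pipeline stages: simulate -> preprocess ->
# embed -> validate -> network -> expression -> graph-CNN cross-validation.
# One global seed deterministically derives per-stage seeds (seed + stage
# index) so a config re-run reproduces every artifact.

.stage_registry <- function() {
  list(
    simulate_corpus = function(params, state, seed, dir) {
      params$seed <- params$seed %||% seed
      spec <- do.call(corpus_spec, params)
      gen <- generate_corpus(spec)
      state$corpus <- gen$documents
      state$truth <- gen$truth
      state$synonyms <- synonym_table(gen$truth$synonym_df)
      corpus_path <- file.path(dir, "corpus.txt")
      writeLines(unname(gen$documents), corpus_path)
      list(state = state, outputs = corpus_path)
    },
    simulate_knowledgebase = function(params, state, seed, dir) {
      if (is.null(state$truth))
        en_stop("dependency", "simulate_knowledgebase needs simulate_corpus upstream")
      kb <- generate_knowledgebase(state$truth, file.path(dir, "kb"))
      state$kb <- kb
      list(state = state,
           outputs = unlist(kb[c("gene_groups", "disease_groups", "ppi",
                                 "drug_targets", "synonyms")]))
    },
    preprocess = function(params, state, seed, dir) {
      if (is.null(state$corpus))
        en_stop("dependency", "preprocess needs a corpus upstream")
      variant <- params$variant %||% "v1"
      cfg <- preprocess_config(
        lemmatize = params$lemmatize %||% FALSE,
        substitute_synonyms = params$substitute_synonyms %||% TRUE)
      toks <- preprocess_corpus(state$corpus, cfg, state$synonyms)
      state$tokens[[variant]] <- toks
      path <- file.path(dir, sprintf("tokens_%s.txt", variant))
      write_tokens(toks, path)
      list(state = state, outputs = path)
    },
    train_embedding = function(params, state, seed, dir) {
      variant <- params$variant %||% "v1"
      toks <- state$tokens[[variant]]
      if (is.null(toks))
        en_stop("dependency", "train_embedding needs preprocessed tokens '%s'",
                variant)
      cfg <- embedding_config(
        dimension = params$dimension %||% 50L,
        window = params$window %||% 5L,
        min_count = params$min_count %||% 5L,
        epochs = params$epochs %||% 5L,
        seed = params$seed %||% seed)
      emb <- train_embedding(toks, cfg, types = state$truth$types)
      state$embeddings[[variant]] <- emb
      path <- file.path(dir, sprintf("embedding_%s.vec", variant))
      write_embedding(emb, path,
                      types_path = file.path(dir, sprintf("types_%s.tsv", variant)))
      list(state = state, outputs = path)
    },
    validate = function(params, state, seed, dir) {
      variant <- params$variant %||% "v1"
      emb <- state$embeddings[[variant]]
      if (is.null(emb))
        en_stop("dependency", "validate needs embedding '%s'", variant)
      groups <- Map(entity_group, names(state$truth$groups),
                    state$truth$groups)
      summ <- group_similarity_summary(emb, groups,
                                       min_size = params$min_size %||% 5L,
                                       max_size = params$max_size %||% 3000L)
      path <- file.path(dir, sprintf("group_summary_%s.csv", variant))
      write.csv(summ, path, row.names = FALSE)
      state$validation[[variant]] <- summ
      list(state = state, outputs = path)
    },
    build_network = function(params, state, seed, dir) {
      variant <- params$variant %||% "v1"
      emb <- state$embeddings[[variant]]
      if (is.null(emb))
        en_stop("dependency", "build_network needs embedding '%s'", variant)
      terms <- if (!is.null(emb$types))
        intersect(names(emb$types)[emb$types == "gene"], emb$vocab)
      else emb$vocab
      net <- build_similarity_network(emb, terms,
                                      t = params$threshold %||% 0.65)
      net <- main_component(net)
      state$network <- net
      path <- file.path(dir, sprintf("network_%s.tsv", variant))
      write_network(net, path)
      list(state = state, outputs = path)
    },
    simulate_expression = function(params, state, seed, dir) {
      net <- state$network %||%
        simulate_prior_network(params$n_vertices %||% 500L,
                               seed = params$seed %||% seed)
      spec <- expression_spec(
        net,
        n_class0 = params$n_class0 %||% 180L,
        n_class1 = params$n_class1 %||% 120L,
        signal_size = min(params$signal_size %||% 30L,
                          length(net$vertices)),
        effect = params$effect %||% 2,
        seed = params$seed %||% seed)
      gen <- generate_expression(spec)
      state$expression <- gen
      state$network <- net
      mpath <- file.path(dir, "expression.tsv")
      lpath <- file.path(dir, "labels.tsv")
      write_expression(gen$matrix, mpath)
      writeLines(paste(names(gen$labels), gen$labels, sep = "\t"), lpath)
      list(state = state, outputs = c(mpath, lpath))
    },
    gcnn_cv = function(params, state, seed, dir) {
      if (is.null(state$expression) || is.null(state$network))
        en_stop("dependency", "gcnn_cv needs expression data and a network upstream")
      ds <- align_to_graph(state$expression$matrix, state$network,
                           state$expression$labels)
      op <- build_graph_operator(ds$network, levels = 2L)
      cfg <- train_config(epochs = params$epochs %||% 25L,
                          folds = params$folds %||% 10L,
                          seed = params$seed %||% seed)
      res <- cross_validate(ds, op, gcnn_architecture(), cfg)
      state$evaluation <- res
      fpath <- file.path(dir, "cv_folds.csv")
      spath <- file.path(dir, "cv_summary.csv")
      write.csv(res$folds, fpath, row.names = FALSE)
      write.csv(res$summary, spath, row.names = FALSE)
      list(state = state, outputs = c(fpath, spath))
    })
}

#' Run the pipeline
#'
#' Executes a configured sequence of stages, threading intermediate objects
#' through and writing every artifact under the output directory. A failure
#' in one stage aborts the run with the stage named in the error.
#'
#' @param config A list with elements `stages` (list of
#'   `list(name = , params = )`), `seed` (global seed; per-stage seeds are
#'   `seed + stage index`) and `out_dir`; or the path of a YAML file with
#'   that structure.
#' @return Invisibly, a list with `manifest` (per-stage name, seed, outputs,
#'   elapsed seconds) and `state` (in-memory results, e.g. embeddings and
#'   the evaluation).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages %||% list()
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% tempfile("pipeline")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  registry <- .stage_registry()
  state <- new.env(parent = emptyenv())
  state$tokens <- list()
  state$embeddings <- list()
  state$validation <- list()
  manifest <- list()
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    name <- st$name %||% st[[1L]]
    if (!name %in% names(registry))
      en_stop("config", "unknown stage name: '%s'", name)
    stage_seed <- seed + i
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      registry[[name]](st$params %||% list(), state, stage_seed, out_dir),
      error = function(e) {
        en_stop("stage", "stage %d ('%s') failed: %s", i, name,
                conditionMessage(e))
      })
    state <- res$state
    manifest[[i]] <- list(stage = name, index = i, seed = stage_seed,
                          outputs = as.character(res$outputs %||% character(0L)),
                          elapsed = round(proc.time()[["elapsed"]] - t0, 3L))
    message(sprintf("stage %d/%d '%s' done (%.1fs)", i, length(stages), name,
                    manifest[[i]]$elapsed))
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, state = state,
                 manifest_path = manifest_path))
}
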