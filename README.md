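# embednet

Biomedical word-embedding networks as priors for graph-convolutional
classification.

## The problem

Most of what is known about gene function is written down as free text. A
word-embedding model trained on a large literature corpus places terms that
occur in similar contexts close together, so the cosine similarity between
two gene vectors becomes a cheap, database-free proxy for functional
relatedness. `embednet` implements the full analysis chain that turns this
idea into a testable pipeline:

1. **Corpus preprocessing** — lowercasing, punctuation/numeral removal,
   rule-based lemmatization, and dictionary-based substitution of synonymous
   biomedical terms by their preferred terms (so `p73` and `tp73` share one
   vector, and `mood disorder` becomes the single token `mood_disorders`).
2. **Embedding training** — skip-gram with negative sampling (word2vec),
   single-threaded and bit-reproducible, with the study configuration of
   300 dimensions, context window 5 and minimum count 5.
3. **Knowledgebase validation** — within-group cosine quartiles for
   pathway/process/disease groups against random pairs, a decay-curve fit
   `f(x) = (x^a + b)^-1` of group-size versus median similarity, a Loess
   alternative, paired comparisons for known protein-protein interactions,
   and drug-pair strata by shared-target counts (0, ≤5, ≤9).
4. **Network extraction** — thresholded cosine-similarity gene-gene networks
   (edge iff `cos(u,v) ≥ t`, default `t = 0.65`), main-component extraction,
   threshold search for a target vertex count, weighted-edge import, and
   three control networks (k-out random, permuted vertices, random weights).
5. **Graph-CNN evaluation** — a spectral graph-convolutional classifier with
   Chebyshev filters (order `K = 7`, receptive field 6 hops), greedy
   heavy-edge coarsening with fake-vertex padding for size-2 max pooling,
   architecture 2×32 filters → FC 512 → 128 → 2, trained with Adam under
   stratified 10-fold cross-validation reporting AUC, accuracy and weighted
   F1 (percent, mean ± SEM).
6. **Synthetic data** — generators for a corpus with planted co-occurrence
   groups and synonym variants, a matching knowledgebase (GMT/PPI/drug-target
   files), and quantile-normalized expression cohorts whose class signal is
   smooth on a supplied prior network, so the whole chain is testable at desk
   scale without any downloads.

The classifier treats an expression profile as a signal on the vertices of a
prior network; a Chebyshev filter of order `K` computes
`y = Σ_{k=0}^{K-1} θ_k T_k(L̃) x` with `T_0 = I`, `T_1 = L̃`,
`T_k = 2L̃T_{k-1} − T_{k-2}`, where `L̃` is the rescaled symmetric-normalized
graph Laplacian `2L/λ_max − I`.

## Worked example

```r
library(embednet)

# plant a corpus with 10 co-occurrence groups of 10 genes
gen  <- generate_corpus(corpus_spec(seed = 1))
tab  <- synonym_table(gen$truth$synonym_df)
toks <- preprocess_corpus(gen$documents, preprocess_config(), tab)
emb  <- train_embedding(toks,
                        embedding_config(dimension = 50, epochs = 15, seed = 1),
                        types = gen$truth$types)

cosine(emb, "gene001", "gene002")   # same planted group
#> [1] 0.9373085
cosine(emb, "gene001", "gene055")   # different groups
#> [1] 0.2204573

groups <- Map(entity_group, names(gen$truth$groups), gen$truth$groups)
head(group_similarity_summary(emb, groups, min_size = 5, max_size = 3000), 3)
#>   group_id  x        q1    median        q3
#> 1  group01 10 0.8983796 0.9173645 0.9365950
#> 2  group02 10 0.9129854 0.9242628 0.9380057
#> 3  group03 10 0.8922334 0.9117470 0.9288393
```

Within-group cosines (~0.92) sit far above unrelated pairs (~0.22), the
pattern the validation module quantifies. Building the gene-gene network and
evaluating it as a prior:

```r
net <- main_component(build_similarity_network(emb, names(which(emb$types == "gene")), 0.65))
prior <- simulate_prior_network(500, 3, seed = 11)
expr  <- generate_expression(expression_spec(prior, effect = 2, seed = 1))
ds    <- align_to_graph(expr$matrix, prior, expr$labels)
op    <- build_graph_operator(ds$network, levels = 2)
cross_validate(ds, op, gcnn_architecture(),
               train_config(epochs = 25, folds = 10, seed = 1))
#> <evaluation_result> 10-fold cross-validation
#>   auc           96.99 +- 1.46
#>   accuracy      89.67 +- 2.30
#>   f1_weighted   89.62 +- 2.30
```

With `effect = 0` the same protocol returns AUC ≈ 54.6%, confirming the
classifier finds nothing when no signal is planted.

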