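---
title: "From literature co-occurrence to graph-structured classification: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From literature co-occurrence to graph-structured classification: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`embednet` chains four models: a text-normalization and concept-mapping
stage, a skip-gram word embedding, a knowledgebase-anchored validation of
the embedding geometry, and a spectral graph-convolutional classifier that
consumes embedding-derived networks as structural priors. This vignette
explains each model, its assumptions, the tunable parameters, and the
design decisions taken where the methodology leaves room.

## 1. Preprocessing and synonym substitution

Raw documents are lowercased, stripped of punctuation (underscores are kept,
because they join multi-word concepts into single tokens), purged of purely
numeric tokens (alphanumerics such as `brca1` always survive), and
optionally lemmatized. Substitution then replaces every maximal match of a
dictionary synonym phrase with its preferred term, greedy longest-match
left-to-right, emitting multi-word preferred terms with underscores
(`mood disorders` → `mood_disorders`).

Design choices, all in `preprocess_config()` / `synonym_table()`:

* **Lemmatizer.** No lemmatizer was prescribed, so the package ships a
  rule-based one: an irregular-form table (be/have forms, mouse/mice,
  Latin/Greek plurals common in biomedicine) plus conservative suffix rules
  (`-ies→y`, `-ed`, `-ing`, plural `-s`). It is deterministic and never
  touches tokens containing digits or underscores. Its outputs are frozen in
  the test fixtures; swapping in a different lemmatizer would only require
  re-freezing those.
* **Matching order.** Surface phrases are matched before lemmatized phrases,
  and longer phrases before shorter ones, so specific multi-word concepts
  beat their sub-words deterministically.
* **Ambiguity.** A synonym mapping to two different preferred terms across
  source dictionaries is rejected at load time with the offending rows
  listed. Resolving silently would make validation results depend on row
  order.
* **Context unit.** Documents (abstracts) are the training unit; no sentence
  splitting is performed. Only the embedding window limits context.

## 2. Skip-gram embedding

`train_embedding()` implements skip-gram with negative sampling: a linearly
decaying learning rate (0.025 → 1e-4), dynamic window (the effective window
is drawn uniformly in `1..window` per position), optional frequent-token
subsampling (threshold 1e-3), and a unigram^0.75 negative-sampling table
(5 negatives). The study configuration — 300 dimensions, window 5, minimum
count 5 — is the default. Training is single-threaded on purpose:
multi-threaded word2vec interleaves updates non-deterministically, and every
result in this package is bit-reproducible from a seed.

**Desk-scale configuration.** The package's synthetic corpora are about
three orders of magnitude smaller than a literature corpus, so pipeline-level
analyses here use 50 dimensions and 15 epochs: with ~80 occurrences per
planted entity, 5 epochs leaves vectors near their common initialization
(every cosine ≈ 0.99, a known small-corpus anisotropy regime), while 15
epochs resolves the geometry (within-group median ≈ 0.91 vs. random ≈ 0.29
at the default generator settings). Dimension and epochs remain free
parameters of `embedding_config()`.

## 3. Validating embedding geometry against knowledgebases

`group_similarity_summary()` computes, per group, the quartiles of all
`x(x−1)/2` pairwise cosines over the embedding-present members, filtered to
a size range (defaults: genes 10–3000, diseases 6–999). Quartiles use the
linear-interpolation convention (`stats::quantile` type 7) so oracle tests
can be exact. The size-similarity trend is summarized two ways:

* `fit_decay()` fits `f(x) = (x^a + b)^{-1}` by nonlinear least squares
  (Levenberg–Marquardt via `minpack.lm`), initialized at `(a, b) = (1, 0)`
  with `a ≥ 0`, multi-starting over `a ∈ {0.1, 0.5, 1, 2}` and keeping the
  best residual sum of squares. `f` is monotone decreasing for `a > 0`,
  `b > −1`, capturing that smaller groups are functionally tighter.
* `loess_trend()` (degree-1 local regression, tricube weights, default span
  0.75, exact "direct" surface) for panels where the parametric form is not
  appropriate.

`paired_similarity_comparison()` contrasts known interacting pairs with
random pairs excluding all positives; `drug_shared_target_analysis()`
stratifies drug pairs by shared-target count (0, 1–5, 6–9). Random-pair
sampling is uniform without replacement, rejection-sampled in batches under
a fixed seed, and fails loudly with the exact deficit when the admissible
universe is too small.

## 4. Networks and controls

`build_similarity_network()` includes an edge iff `cos(u, v) ≥ t` (a closed
bound, so the study threshold 0.65 includes equality), with the cosine as
the edge weight. `threshold_for_size()` bisects the observed weights for the
largest threshold whose main component still reaches a target vertex count —
the device used to make networks from different sources comparable. The main
component is required downstream because spectral convolution assumes a
connected graph; ties between equal-size components break on the
lexicographically smallest member.

Three controls isolate what a prior contributes:

* **k-out random** (`k_out_random`): each vertex draws `k = 8` partners
  uniformly with repetition; duplicate and reciprocal draws collapse into a
  simple undirected graph. The degree distribution then concentrates just
  below `2k` (mean ≈ 15.99, median 16, sd ≈ 2.8 at 6888 vertices), which the
  acceptance script recomputes.
* **permuted vertices**: identical topology, labels permuted — destroys the
  biology, keeps the structure.
* **random weights**: identical topology, weights uniform on `[0.65, 1]`.

## 5. The graph-convolutional classifier

`build_graph_operator()` computes the symmetric normalized Laplacian
`L = I − D^{−1/2} A D^{−1/2}` of the prior network, estimates `λ_max` by
power iteration, and rescales to `L̃ = 2L/λ_max − I` so Chebyshev polynomials
are evaluated on `[−1, 1]`. Pooling needs a vertex hierarchy: greedy
heavy-edge matching (each vertex, visited in ascending degree order, pairs
with the unmatched neighbor maximizing `w_ij(1/d_i + 1/d_j)`) halves the
graph per level; unmatched vertices receive disconnected "fake" siblings so
every level has exactly half the slots of the previous one. Fake vertices
carry zero features and no edges; because an isolated vertex's Laplacian row
is the identity row, every polynomial in `L̃` maps zero to zero there, so
padding provably never leaks into real outputs (asserted by test).

The classifier itself is the study architecture: two convolutional layers
of 32 Chebyshev filters of order `K = 7` (a 6-hop receptive field per
layer), size-2 max pooling after each, then fully connected layers of 512
and 128 units and a 2-class softmax. The convolution computes
`Σ_k θ_k T_k(L̃) x` with the three-term recurrence forward and the Clenshaw
reverse recurrence for the input gradient. Forward and backward passes are
written out explicitly — the fixed architecture makes manual gradients
practical — with the hot paths (sparse polynomial application, the filter
GEMMs, Adam) in compiled code against BLAS.

Choices the methodology left open, and what was done:

* **"7 hops"** is read as per-layer order `K = 7` (configurable).
* **Optimizer**: Adam, learning rate 1e-3, batch size 32, dropout 0.5 on the
  fully connected activations, no weight decay by default. None of these are
  part of the published protocol; all are logged in `train_config()`.
* **Cross-validation** is stratified by class, protecting the 40:60
  imbalance the expression generator emulates; the published protocol states
  only "10-fold".
* **Epochs**: fixed per run across all folds; 25 by default (the smallest
  value in the study's grid of 25/40/100).
* **Convergence reporting**: a fold whose tail training loss is not finite
  or not below its first epoch is flagged `converged = FALSE` in the fold
  table — mirroring the observation that badly matched random-weight priors
  can fail to converge — and is never silently dropped from the averages.
* **Metrics**: AUC is the Mann–Whitney probability with ties counting ½;
  F1-weighted is the support-weighted mean of per-class F1 at cutoff 0.5;
  SEM is the across-fold standard deviation over √folds. All in percent.

## 6. What the synthetic generators emulate — and what they do not

`generate_corpus()` plants co-occurrence at the document level: each
document is "about" one group whose member genes appear at `within_rate`
(0.3) while every other entity appears at `background_rate` (0.01), mixed
with Zipf-distributed filler vocabulary (Poisson length, mean 25). At the
defaults (2000 documents, 10 groups of 10 genes) the within-group
co-document rate exceeds background by more than tenfold, which the window-5
skip-gram converts into the planted cosine structure. Each occurrence is
emitted as a synonym variant with probability `synonym_prob` (default 0.5);
disease entities get one multi-word variant to exercise phrase matching.
Diseases and drugs attach to groups, and drug target sets are nested subsets
of the group's genes so all three shared-target strata are realized.

`generate_expression()` gives class-1 samples a mean shift on a connected
signal subnetwork (BFS ball around a seed vertex), attenuated as
`exp(−0.5 · hops)` so the prior network genuinely carries information about
where the signal lives; the matrix is then quantile normalized across
samples (via `limma`) and shifted to a non-negative range, matching the
preparation the classifier expects. Class sizes default to 180:120,
emulating the study's 40:60 imbalance at n = 300. The default prior for
evaluation experiments is a 500-vertex preferential-attachment graph — the
standard stand-in for protein-interaction degree structure — which is always
connected.

What passing tests on these data do **not** show: real abstracts have
syntax, polysemy, section structure and citation phrasing that document-level
co-occurrence ignores; real expression cohorts carry batch effects,
platform-specific noise and correlated gene modules beyond a single planted
subnetwork. The generators validate the machinery and its directional
claims, not the published effect sizes, which depend on the 16M-abstract
corpus and the clinical cohorts.

**The substitution contrast needs converged embeddings.** Turning synonym
substitution off halves every concept's token frequency (occurrences split
across variants). At small epoch counts the lower-frequency arm retains more
common-direction anisotropy, which *inflates* all its cosines and masks the
substitution benefit; the within-group advantage of substitution emerges
once both arms are trained to convergence. The substitution-direction check
therefore trains both arms for 50 epochs before comparing — an analysis
requirement, not a generator setting.

## 7. Numerical notes and limitations

* Determinism everywhere: every stochastic step (generation, training
  order, dropout, initialization, sampling, fold assignment) derives from an
  explicit seed, and the RNG state of the caller is always restored.
* Problem sizes in the test suite are chosen for a single CPU: corpora of
  ~2000 documents, embeddings of 30–50 dimensions, priors of ≤500 vertices,
  10-fold cross-validation at 25 epochs. These are stated as the package's
  desk-scale study conditions; all scale up by configuration only.
* `fit_decay` can sit at the `a = 0` boundary for constant medians (then
  `b = 1/m − 1`); the multi-start reports the best RSS fit and its
  convergence status rather than failing.
* The k-out control collapses multi-edges, so its mean degree is slightly
  below `2k`; at `n ≫ k` fewer than 1% of vertices fall below degree `k`.
* Known limitations: dictionary matching only (no entity disambiguation or
  abbreviation expansion); the rule lemmatizer is intentionally small; no
  GPU path; contextual (transformer) embeddings and the upstream microarray
  normalization chain are out of scope.
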