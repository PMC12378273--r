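---
title: "Methods: density-based topic modeling for short texts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: density-based topic modeling for short texts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its model and of the design
choices that were genuinely open: what each stage computes, the
assumptions it rests on, which parameters matter and why their defaults
are what they are, what the synthetic generator does and does not emulate,
and the package's known limitations.

## The pipeline

`run_pipeline()` chains seven stages. Each is exposed as an ordinary
function, so any stage can be run, inspected or replaced in isolation.

**1. Preprocessing** (`clean_corpus()`). URLs (strings starting
`http(s)://` or `www`) and emoji (a fixed, documented set of Unicode
code-point ranges: U+1F300–U+1FAFF, U+1F1E6–U+1F1FF, U+2600–U+27BF,
U+2B00–U+2BFF, U+FE0F, U+200D) are removed; text is lowercased and split
on non-word characters, preserving underscores so user handles like
`@user_name` survive as a single token. Tokens in a pinned English
stopword list are dropped, and a suffix-`s` singularizer folds plural
forms (`portraits` → `portrait`; words ending `ss` and words of at most
three characters are exempt). HTML entities are deliberately *not*
decoded — `&amp;` becomes the token `amp` — because entity decoding is a
data-source property, not a modeling one; the cleaning function is
idempotent either way. Near-duplicate posts (retweet-like copies) are
removed by exact hash matching first, then by cosine similarity of
document embeddings at threshold ε = 0.95; the earliest copy in input
order is kept.

**2. Embedding** (`embed_documents()`). A document is the arithmetic mean
of its token vectors. Token vectors come from a pluggable backend. The
default `"hash"` backend derives a deterministic unit vector per term from
a seeded hash, at 128 dimensions: enough that distinct terms are
near-orthogonal in expectation, so shared vocabulary — and only shared
vocabulary — creates document similarity. This makes the whole pipeline
self-contained and exactly reproducible. The `"precomputed"` backend
accepts vectors from any external encoder (e.g. a sentence-transformer)
for production use; transformer embeddings additionally encode word-order
and contextual similarity that hash vectors cannot, so absolute metric
values differ between backends even though every downstream contract is
identical. Documents left empty by cleaning are dropped with a warning
rather than zero-embedded, since zero vectors poison cosine similarity.
Hash-backend embeddings are unit-norm by construction; precomputed vectors
are used as supplied, without renormalization.

**3. Reduction** (`reduce_embeddings()`). High-dimensional document
vectors are projected with a spectral embedding of a k-nearest-neighbour
graph (default `n_neighbors = 30`, cosine distance). Affinities use the
locally-calibrated kernel `exp(−(d − ρ_i)/σ_i)`, where ρ_i is the
distance to the nearest neighbour and σ_i is tuned by bisection so each
point spreads ~log2(k) of affinity mass over its neighbourhood; the graph
is symmetrized by probabilistic union (`W + Wᵀ − W∘Wᵀ`) and kept connected
by flooring its minimum-spanning-tree edges at a small affinity (10⁻³).
Coordinates are the leading non-trivial eigenvectors of the normalized
adjacency, scaled by their eigenvalues raised to a diffusion exponent
(default 8). The exponent is the knob that contracts within-cluster
directions relative to between-cluster ones — the role the attractive
forces of a stochastic-neighbour layout play — and values in 4–16 behave
near-identically on separated data. Two properties follow that the
package exploits: the embedding is fully deterministic (no optimization,
no random initialization), and the eigenbasis is *nested*, so one
decomposition serves every candidate dimensionality in the sweep.

**4. Dimension selection** (`select_dimension()`). For each candidate
`d ∈ [2, 40]` the reduced points are clustered (hyperparameters held fixed
across the sweep) and scored by the mean silhouette of the non-noise
points; noise is excluded because the silhouette is defined only for
labelled points, and a sweep where everything is noise or a single cluster
scores the sentinel −1. The chosen `d` maximizes the score, ties breaking
toward the smaller dimension; if every candidate is undefined the
selection falls back to dimensionality 5, the conventional fixed setting.
One choice here deserves emphasis: the silhouette is computed in the
**original** embedding space (under the reduction metric), not in each
candidate's own reduced space. With a nested eigenbasis, a
lower-dimensional projection is always more compact in its own coordinates
— on the default synthetic corpus, the 2-dimensional projection merges
five topics into three yet scores 0.852 in its own space against 0.826
for the correct five-cluster solution at d ≥ 4 — so scoring each
candidate in its own space systematically selects degenerate
low-dimensional clusterings. Scoring all candidates in the one space they
share makes the numbers comparable and the selection meaningful. The
reported silhouette *metric* (`silhouette_score()` in the evaluation
suite) keeps the conventional reduced-space definition.

**5. Clustering** (`fit_clusters()`). Hierarchical density-based
clustering over mutual reachability distances
`d_mreach(i, j) = max(core(i), core(j), d(i, j))`, where `core(x)` is the
distance to the k-th nearest neighbour (`k = min_samples`, defaulting to
`min_cluster_size` since nothing else pins it). The hierarchy is the
single-linkage dendrogram of the mutual-reachability matrix (equivalent to
the minimum-spanning-tree construction); it is condensed at
`min_cluster_size` (default 100): a side of a split smaller than the
minimum sheds its points from the current cluster at λ = 1/distance,
while a split into two large sides creates two child clusters. Cluster
stability is accumulated in the per-point form
`S(C) = Σ_p (λ_p − λ_birth(C))` — the printed edge-sum form of the
stability functional is ambiguous about what is summed, and the per-point
form is the one with an unambiguous operational meaning; per-cluster
λ_birth/λ_death are reported alongside. The flat clustering selects the
most stable antichain (excess-of-mass: a parent is kept when its stability
is at least the summed stability of its children), the root is never a
cluster, and unclaimed points are noise (−1). Outlier scores are each
member's core distance divided by its cluster's mean core distance, so
scores average exactly 1 within a cluster and values well above 1 flag
probable outliers.

**6. Topic representation** (`ctfidf()`, `pdr_weights()`,
`topic_keywords()`). Class-based TF-IDF with natural log (configurable to
log10); noise documents are excluded from topic term counts but still
count toward N and document frequencies, so rescued corpora and raw
corpora share one IDF scale. The popularity regularizer ranks terms by
raw corpus term frequency (ties broken lexicographically), multiplies the
top decile by `e^(−α·rank)` and dictionary terms by 1.5 (decay first when
a term is both). Two switches acknowledge a genuine ambiguity in the
decay's direction: as printed, the most frequent term (rank 1) receives
the *mildest* penalty `e^(−α)` while mid-decile terms are annihilated,
which arguably inverts the stated goal of suppressing top terms. The
default (`rank_direction = "as_printed"`, `rank_scope = "decile_only"`)
honours the printed form; `"inverted"` reverses ranks within the scope so
the most frequent term is penalized hardest. Both paths are tested.
Dictionary matching is by unigram token equality; multiword entries
("mental health") match by either component token in the default unigram
vocabulary. Keywords are the top 2k candidates re-ranked by greedy MMR
(λ = 0.5, a neutral default since no value is prescribed) with term
similarity taken as cosine between token vectors and the query as the
weight-weighted candidate centroid; without token vectors (precomputed
backend) the plain weight ranking is returned.

**7. Probabilistic reassignment** (`soft_assign()`,
`reassign_outliers()`). Document-topic distances are measured to topic
*centroids* — the only topic-level representative the hard clustering
provides — in the reduced space under cosine distance (both configurable).
A softmax over negative distances (temperature 1, computed with
max-subtraction) gives each document a probability row summing to 1.
Only noise documents are touched: one whose winning probability strictly
exceeds the threshold (default 0.15) takes the argmax topic, ties going to
the lowest topic index for determinism. Reassignment equals
nearest-centroid assignment whenever the winner clears the threshold, and
the outlier rate can only fall. Keywords are computed before reassignment
by default (`recompute_keywords` re-derives them afterwards), so the
keyword tables describe the high-confidence cores of topics.

## Evaluation metrics

All metrics are implemented in the package and each is cross-checked in
the test suite against an independent brute-force reference on small
corpora.

- **NPMI** (in [−1, 1]): per topic, the mean over top-k word pairs of
  `log(p_ij/(p_i p_j)) / (−log p_ij)` with document-level occurrence
  probabilities; the corpus-wide value is the mean over topics. A pair
  that never co-occurs scores exactly −1 (the vanishing-smoothing limit;
  ε = 10⁻¹² guards all other logs); pairs involving a word absent from
  the corpus are skipped and surface in a coverage diagnostic.
- **Topic diversity**: distinct words across all top-k lists divided by
  total slots; T identical lists score exactly 1/T.
- **Perplexity**: this pipeline is not generative, so the likelihood-based
  notion does not transfer; the package defines perplexity explicitly as
  `exp(−mean log P(d, assigned topic))` over non-noise documents, which
  lies in [1, M] for row-stochastic rows under argmax assignment — 1 for
  one-hot certainty, M for uniform indifference.
- **Lexical diversity**: no canonical formula exists for within-topic
  keyword uniqueness at the document level; the package's reading — each
  member document contributes its top-m terms (document term frequency
  weighted by the topic's term weights, m = 3 by default for 8–20-token
  documents), and the topic scores distinct/total — is the one the keyword
  regularizer can actually move, and is labelled an interpretation.
- **Centroid cosine**: mean cosine of documents to their topic centroid.
  When the regularizer is active, document vectors are re-pooled as
  weight-weighted token means first; through plain mean-pooled embeddings
  the regularizer could not affect this metric at all.
- **Silhouette** and **outlier rate** as defined above.

## The synthetic generator

`generate_corpus()` emulates the statistical skeleton of a short-text
corpus: T topics (default 5) of 200 documents each, 8–20 tokens per
document, a generic vocabulary of 50 filler terms sampled with Zipf
exponent 0.7 making up ~35% of tokens, disjoint 40-term topic blocks
(partially shared when `separation < 1`), 5% planted outlier documents
drawing topical tokens uniformly across all blocks, and domain-dictionary
terms planted one per topic block so the dictionary boost is measurable.
The Zipf exponent is deliberately flatter than the raw-text value of ~1
because stopword removal strips the extreme head of the real frequency
curve before topic modeling ever sees it; with these defaults the generic
terms dominate the corpus-frequency top decile by construction, which is
what the regularizer's decay targets. `generate_embeddings()` provides
the geometric analogue: isotropic Gaussian blobs at the vertices of a
regular simplex with pairwise center distance `separation · σ`, plus
uniform box outliers.

What the generator does *not* emulate: grammar and word order (irrelevant
to the hash backend), emoji/URL noise beyond what preprocessing tests
inject explicitly, multilinguality, author/thread structure, bursty
near-duplicates, and the heavy topic-size imbalance of real streams.
Passing tests therefore demonstrate the pipeline's correctness and its
behaviour under controlled separation and noise — not performance claims
about any particular real corpus.

## Numerical choices and degenerate inputs

- Bisection for the local bandwidth runs 64 iterations from
  [10⁻⁶, 4·max gap + 1]; λ values cap heights at 10⁻¹² to survive
  duplicate points.
- Eigenvector signs are canonicalized (largest-magnitude component made
  positive) so runs are bit-reproducible.
- Frequency-rank ties break lexicographically; argmax ties in softmax
  rows take the lowest topic index; equal silhouette scores take the
  smaller dimension.
- Empty documents are dropped (embedding), empty topics yield zero weight
  rows with a warning (c-TF-IDF), all-noise clusterings short-circuit the
  representation and reassignment stages, a corpus smaller than
  `min_cluster_size` is all noise with a warning, and zero-norm vectors
  under cosine fall back to Euclidean per entry.
- The softmax uses max-subtraction; winning probabilities are floored at
  10⁻¹² inside the perplexity log.

## Problem sizes

The test suite and the acceptance script run the full pipeline on the
1000-document default corpus (about 10 s on one CPU, most of it the
39-candidate dimension sweep), property checks on 150–400-point geometric
fixtures, and oracle comparisons on ≤ 50-document corpora where literal
two-loop references are exact. These sizes were chosen so the whole suite
gives dense coverage in well under a minute of compute per module; the
pipeline itself is O(N²) in documents (dense distance matrices, dense
eigendecomposition) and is comfortable to tens of thousands of documents,
beyond which the reduction and clustering stages would want sparse
neighbour search and truncated eigensolvers.

## Known limitations

- The O(N²) memory of dense distance matrices is the binding constraint
  at scale, as noted above.
- The hash backend measures lexical overlap only; synonymy and context
  require the precomputed backend with a real encoder.
- Silhouette-guided dimension selection inherits silhouette's bias toward
  few, well-separated clusters; on corpora whose topics genuinely overlap
  it can prefer coarser structure.
- The printed rank-decay direction (mildest penalty at rank 1) is kept as
  the default for fidelity even though its intent is arguable; users who
  want the aggressive reading must opt into `rank_direction = "inverted"`.
- Reassignment is single-pass: term weights are not refit after outliers
  are rescued unless `recompute_keywords` is set, and no EM-style
  iteration is attempted.
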