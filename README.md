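# shorttopics

Topic modeling for short, noisy social-media texts — tweets and tweet-like
documents of roughly 5–30 tokens — aimed at public-health text mining
(infodemiology): surfacing what a population is discussing about, say,
adolescent health, from large streams of short posts. Conventional topic
models struggle on such corpora: bag-of-words likelihoods are starved by
document brevity, ubiquitous generic terms ("health", "teen") wash out
topic-specific vocabulary, and density-based clustering discards a large
fraction of documents as noise.

`shorttopics` implements an embedding-cluster-represent pipeline with three
optimizations targeted at those failure modes:

1. **Silhouette-tuned dimensionality** — documents are embedded as
   mean-pooled token vectors `v_T = (1/n) Σ v_i`, then projected with a
   spectral embedding of a locally-calibrated k-nearest-neighbour graph.
   The output dimensionality `d` is not fixed: every candidate in
   `d ∈ [2, 40]` is clustered and scored, and the `d` maximizing the mean
   silhouette `S(d) = mean[(b − a) / max(a, b)]` of the clustered points is
   selected.
2. **Popularity-deviation regularization of keywords** — topics are
   represented by class-based TF-IDF,
   `w(t, c) = TF(t, c)/ΣTF(·, c) × log(N/df(t))`, with an exponential
   rank-decay penalty `w(t) ← w(t)·e^(−α·rank(t))` (α = 0.05) applied to
   the top frequency decile and a ×1.5 boost for terms of a domain
   dictionary (an adolescent-health vocabulary ships as the default).
   Keywords are re-ranked by maximal marginal relevance
   `MMR(w) = λ·Sim(w, q) − (1−λ)·max_{s∈S} Sim(w, s)`.
3. **Probabilistic outlier reassignment** — density clustering labels
   low-density documents as noise (−1). Every document receives a
   row-stochastic topic distribution
   `P(t_j | d_i) = exp(−d_ij) / Σ_k exp(−d_ik)` over distances to topic
   centroids; a noise document whose winning probability exceeds 0.15 is
   reassigned to that topic, shrinking the outlier rate without touching
   confident assignments.

The clustering itself is hierarchical density-based clustering over
**mutual reachability distances**
`d_mreach(x_i, x_j) = max(core(x_i), core(x_j), d(x_i, x_j))`, with
condensed-tree stability selection and core-distance outlier scores —
implemented in the package, with the published formulas as the tested
contract. A full evaluation suite (NPMI coherence, topic diversity,
assigned-topic perplexity, lexical diversity, centroid cosine, silhouette,
outlier rate) and a seeded planted-topic corpus generator make every stage
testable without any pretrained model or external data.

## Worked example

```r
library(shorttopics)

corpus <- generate_corpus(synthetic_spec(seed = 1))  # 5 topics x 200 docs
run <- run_pipeline(corpus, run_config(seed = 1))
print(run)
#> <pipeline_run> 1000 documents, 5 topics, OR 12.90% -> 0.00%

run$ddeo$chosen_dim
#> [1] 13

print(run$metrics)
#> <metrics_report>
#>   npmi               0.32925
#>   td                 1
#>   perplexity         2.2083
#>   ...
```

Reading the output: the pipeline found the 5 planted topics; density
clustering initially labelled 12.9% of documents as noise, and the
reassignment stage rescued all of them (each noise document's winning
topic probability cleared the 0.15 threshold). The dimension sweep chose a
13-dimensional reduced space. NPMI of 0.33 means the top-10 keywords of
each topic strongly co-occur in documents; topic diversity 1.0 means no
keyword is shared between topics; perplexity 2.2 (bounded by the topic
count, 5) reflects moderately confident topic distributions. Against the
generator's gold labels the recovered partition has adjusted Rand index
0.92 (`mclust::adjustedRandIndex(run$final_labels, gold)`).

Real corpora enter the same way as CSV (`id,text[,timestamp]`) or JSONL:

```r
run <- run_pipeline("tweets.csv", run_config(seed = 1), out_dir = "run1")
```

which writes `labels.tsv`, `keywords.tsv`, `doc_topic.tsv`,
`metrics.json` and a reproducibility manifest. A command-line front-end
with `simulate` / `fit` / `evaluate` / `sweep` subcommands is installed at
`system.file("cli", "shorttopics.R", package = "shorttopics")`.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "shorttopics",
                               load_package = "installed")'
```

The suite cross-checks every metric and weighting formula against literal
brute-force reference implementations, pins closed-form anchor values, and
exercises the pipeline end-to-end on planted-topic corpora.

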