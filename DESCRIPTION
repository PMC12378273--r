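Package: shorttopics
Title: Density-Based Topic Modeling for Short Social-Media Texts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An optimized topic-modeling pipeline for short, noisy texts such
    as health-related tweets. Documents are embedded as mean-pooled token
    vectors, reduced with a nearest-neighbour-graph spectral embedding whose
    output dimensionality is chosen by silhouette maximization, and clustered
    with hierarchical density-based clustering over mutual reachability
    distances. Topic keywords are extracted with class-based TF-IDF,
    regularized by an exponential rank-decay penalty on high-frequency terms
    plus a domain-dictionary boost, and re-ranked by maximal marginal
    relevance. Noise documents are rescued through a row-stochastic
    document-topic probability matrix built from a softmax over
    document-to-centroid distances. Includes a full evaluation suite (NPMI
    coherence, topic diversity, perplexity, lexical diversity, centroid
    cosine, silhouette, outlier rate) and a seeded generator of planted-topic
    synthetic corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    optparse,
    yaml
Config/testthat/edition: 3
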