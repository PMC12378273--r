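## Seeded generators of planted-topic short-text corpora and Gaussian
## mixture embedding fixtures, so every pipeline stage is testable without
## external data. Topical documents mix Zipf-distributed generic filler
## terms with their topic's term block; planted outlier documents draw
## their topical tokens uniformly across all blocks (gold label -1).

#' Specification of a synthetic planted-topic corpus
#'
#' @param n_topics Number of planted topics (default 5).
#' @param docs_per_topic Documents per topic (default 200).
#' @param vocab_generic Number of generic filler terms (default 50),
#'   sampled with Zipf weights; sized against `generic_mix` so generic
#'   terms dominate the corpus-frequency top decile, as high-frequency
#'   generic vocabulary does in real short-text corpora.
#' @param vocab_per_topic Topic-block size in terms (default 40).
#' @param zipf_exponent Zipf exponent for generic-term sampling (default
#'   0.7: flatter than raw Zipf because stopword removal strips the extreme
#'   head of the real frequency curve before topic modeling sees it).
#' @param doc_length Integer range `c(min, max)` of tokens per document
#'   (default `c(8, 20)`, within the 5-30 band typical of tweets).
#' @param generic_mix Expected fraction of generic tokens per document
#'   (default 0.35).
#' @param outlier_fraction Fraction of documents planted as outliers
#'   (default 0.05).
#' @param separation Topic-term disjointness in `[0, 1]`: probability that
#'   a topical token comes from the document's own block rather than the
#'   union of all blocks (default 1, fully disjoint).
#' @param dictionary_terms Domain-dictionary terms planted into topic
#'   blocks (default: packaged adolescent-health unigrams), at most one per
#'   topic block.
#' @param seed Integer seed; the corpus is a pure function of the spec.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_topics = 5, docs_per_topic = 200,
                           vocab_generic = 50, vocab_per_topic = 40,
                           zipf_exponent = 0.7, doc_length = c(8, 20),
                           generic_mix = 0.35, outlier_fraction = 0.05,
                           separation = 1,
                           dictionary_terms = NULL, seed = 1) {
  stopifnot(is_count(n_topics), is_count(docs_per_topic),
            is_count(vocab_generic), is_count(vocab_per_topic),
            length(doc_length) == 2, doc_length[1] >= 1,
            doc_length[2] >= doc_length[1],
            generic_mix >= 0, generic_mix <= 1,
            outlier_fraction >= 0, outlier_fraction <= 1,
            separation >= 0, separation <= 1)
  if (is.null(dictionary_terms)) {
    dict <- load_dictionary()
    dictionary_terms <- dict[!grepl("[^[:alnum:]_-]", dict)]
  }
  structure(list(n_topics = as.integer(n_topics),
                 docs_per_topic = as.integer(docs_per_topic),
                 vocab_generic = as.integer(vocab_generic),
                 vocab_per_topic = as.integer(vocab_per_topic),
                 zipf_exponent = zipf_exponent,
                 doc_length = as.integer(doc_length),
                 generic_mix = generic_mix,
                 outlier_fraction = outlier_fraction,
                 separation = separation,
                 dictionary_terms = tolower(dictionary_terms),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a planted-topic short-text corpus
#'
#' @param spec A [synthetic_spec()].
#' @return Object of class `synthetic_corpus`: list with `docs` (data frame
#'   `id`, `text`), `gold_labels` (named integer vector, planted topic or
#'   -1 for planted outliers, 0-based) and `dictionary_terms` (the planted
#'   domain terms per topic).
#' @export
generate_corpus <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$seed, {
    generic <- sprintf("filler%03d", seq_len(spec$vocab_generic))
    zipf_w <- 1 / seq_len(spec$vocab_generic)^spec$zipf_exponent

    blocks <- vector("list", spec$n_topics)
    planted <- character(spec$n_topics)
    dict_pool <- sample(spec$dictionary_terms)
    for (t in seq_len(spec$n_topics)) {
      base <- sprintf("topic%d_term%03d", t,
                      seq_len(spec$vocab_per_topic))
      if (t <= length(dict_pool)) {
        planted[t] <- dict_pool[t]
        base[1] <- dict_pool[t]
      }
      blocks[[t]] <- base
    }
    all_topical <- unlist(blocks, use.names = FALSE)

    n_docs <- spec$n_topics * spec$docs_per_topic
    n_out <- round(spec$outlier_fraction * n_docs)
    gold <- c(rep(seq_len(spec$n_topics) - 1L, each = spec$docs_per_topic))
    if (n_out > 0) {
      out_idx <- sample(n_docs, n_out)
      gold[out_idx] <- -1L
    }

    texts <- character(n_docs)
    for (i in seq_len(n_docs)) {
      len <- sample(seq(spec$doc_length[1], spec$doc_length[2]), 1)
      n_gen <- stats::rbinom(1, len, spec$generic_mix)
      n_top <- len - n_gen
      gen_toks <- if (n_gen > 0) {
        sample(generic, n_gen, replace = TRUE, prob = zipf_w)
      } else character(0)
      top_toks <- if (n_top > 0) {
        if (gold[i] == -1L) {
          sample(all_topical, n_top, replace = TRUE)
        } else {
          own <- stats::runif(n_top) < spec$separation
          toks <- character(n_top)
          if (any(own)) toks[own] <- sample(blocks[[gold[i] + 1L]],
                                            sum(own), replace = TRUE)
          if (any(!own)) toks[!own] <- sample(all_topical, sum(!own),
                                              replace = TRUE)
          toks
        }
      } else character(0)
      texts[i] <- paste(sample(c(gen_toks, top_toks)), collapse = " ")
    }

    ids <- sprintf("doc%05d", seq_len(n_docs))
    names(gold) <- ids
    structure(list(docs = data.frame(id = ids, text = texts,
                                     stringsAsFactors = FALSE),
                   gold_labels = gold,
                   dictionary_terms = planted[nzchar(planted)],
                   blocks = blocks, generic_terms = generic),
              class = "synthetic_corpus")
  })
}

#' Generate Gaussian-mixture embedding fixtures with planted labels
#'
#' Cluster centers sit at the vertices of a regular simplex scaled so the
#' pairwise center distance is `separation` (in units of the unit
#' within-cluster standard deviation); outliers are uniform in the bounding
#' box of the data and carry gold label -1.
#'
#' @param n_clusters Number of Gaussian blobs.
#' @param n_points Total points including outliers.
#' @param dim Dimensionality (>= 2; the simplex needs
#'   `dim >= n_clusters - 1`).
#' @param separation Pairwise center distance in within-cluster sigmas.
#' @param outlier_fraction Fraction of points planted as outliers.
#' @param seed Integer seed.
#' @return List with `embedding` (an [embedding_matrix()]) and
#'   `gold_labels` (integer vector, 0-based, -1 = outlier).
#' @export
generate_embeddings <- function(n_clusters, n_points, dim, separation,
                                outlier_fraction = 0, seed = 1) {
  stopifnot(is_count(n_clusters), is_count(n_points), is_count(dim),
            dim >= 2, separation >= 0,
            outlier_fraction >= 0, outlier_fraction < 1)
  if (n_points < n_clusters) stop("need at least one point per cluster")
  with_local_seed(seed, {
    centers <- simplex_centers(n_clusters, dim) * separation
    n_out <- round(outlier_fraction * n_points)
    n_in <- n_points - n_out
    lab <- rep(seq_len(n_clusters) - 1L, length.out = n_in)
    X <- centers[lab + 1L, , drop = FALSE] +
      matrix(stats::rnorm(n_in * dim), n_in, dim)
    if (n_out > 0) {
      lo <- apply(X, 2, min); hi <- apply(X, 2, max)
      O <- sapply(seq_len(dim), function(j) {
        stats::runif(n_out, lo[j], hi[j])
      })
      O <- matrix(O, n_out, dim)
      X <- rbind(X, O)
      lab <- c(lab, rep(-1L, n_out))
    }
    perm <- sample(n_points)
    X <- X[perm, , drop = FALSE]
    lab <- lab[perm]
    ids <- sprintf("pt%05d", seq_len(n_points))
    list(embedding = embedding_matrix(ids, X),
         gold_labels = stats::setNames(lab, ids))
  })
}

## Vertices of a regular simplex with unit pairwise distance, centered at
## the origin, embedded in `dim` dimensions (requires dim >= k - 1; falls
## back to scaled random directions otherwise).
simplex_centers <- function(k, dim) {
  if (k == 1) return(matrix(0, 1, dim))
  if (dim >= k - 1) {
    X <- diag(k) - 1 / k            # centered vertices e_i, rows
    sv <- svd(X)
    coords <- (sv$u %*% diag(sv$d))[, seq_len(k - 1), drop = FALSE]
    coords <- coords / sqrt(2)      # pairwise distance of e_i, e_j
    C <- matrix(0, k, dim)
    C[, seq_len(k - 1)] <- coords
    return(C)
  }
  C <- matrix(stats::rnorm(k * dim), k, dim)
  d <- pairwise_distances(C)
  C / mean(d[upper.tri(d)])
}
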