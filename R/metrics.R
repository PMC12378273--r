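## Evaluation suite: silhouette, outlier rate, NPMI coherence, topic
## diversity, assigned-topic perplexity, lexical diversity and
## document-to-centroid cosine similarity.

#' Mean silhouette coefficient over non-noise points
#'
#' For each labelled point, `s = (b - a) / max(a, b)` where `a` is the mean
#' distance to the other members of its cluster and `b` the smallest mean
#' distance to another cluster; the score is the mean over points. Noise
#' points (-1) are excluded. Singleton-cluster points score 0.
#'
#' @param points An [embedding_matrix()] or numeric matrix.
#' @param labels Integer labels aligned with rows (-1 = noise).
#' @param metric Distance metric, default `"euclidean"`.
#' @return Mean silhouette in `[-1, 1]`, or `NA` (with attribute `reason`)
#'   when fewer than two clusters exist.
#' @export
silhouette_score <- function(points, labels,
                             metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  X <- as_point_matrix(points)
  keep <- labels >= 0
  X <- X[keep, , drop = FALSE]
  labels <- labels[keep]
  cl <- sort(unique(labels))
  if (length(cl) < 2) {
    return(structure(NA_real_, reason = "undefined: fewer than two clusters"))
  }
  D <- pairwise_distances(X, metric = metric)
  n <- nrow(X)
  s <- numeric(n)
  sizes <- table(factor(labels, levels = cl))
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    n_own <- sum(own)
    if (n_own == 1) { s[i] <- 0; next }
    a <- sum(D[i, own]) / (n_own - 1)
    b <- Inf
    for (c2 in cl) {
      if (c2 == labels[i]) next
      b <- min(b, mean(D[i, labels == c2]))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Normalized pointwise mutual information coherence
#'
#' For each topic's top-`k` word list, NPMI is averaged over unordered word
#' pairs using document-level occurrence probabilities:
#' `npmi = log(p_ij / (p_i p_j)) / (-log p_ij)`. Pairs that never co-occur
#' score exactly -1 (the vanishing-smoothing limit); pairs with a word
#' absent from the corpus are skipped and counted in the `coverage`
#' attribute. The result is the mean over topics, in `[-1, 1]`.
#'
#' @param topics List of character vectors (top-k words per topic).
#' @param docs A `clean_corpus` data frame (the reference corpus).
#' @param eps Smoothing floor for probabilities inside logs; default 1e-12.
#' @return Mean NPMI with attribute `coverage` (fraction of evaluable
#'   pairs).
#' @export
npmi <- function(topics, docs, eps = 1e-12) {
  stopifnot(is.list(topics), length(topics) >= 1, nrow(docs) >= 1)
  n <- nrow(docs)
  doc_sets <- lapply(docs$tokens, unique)
  words <- unique(unlist(topics, use.names = FALSE))
  occ <- matrix(FALSE, n, length(words), dimnames = list(NULL, words))
  for (i in seq_len(n)) {
    w <- intersect(doc_sets[[i]], words)
    if (length(w)) occ[i, w] <- TRUE
  }
  counts <- colSums(occ)

  pair_npmi <- function(w1, w2) {
    c1 <- counts[[w1]]; c2 <- counts[[w2]]
    if (c1 == 0 || c2 == 0) return(NA_real_)   # not evaluable
    cj <- sum(occ[, w1] & occ[, w2])
    if (cj == 0) return(-1)
    p1 <- c1 / n; p2 <- c2 / n; pj <- cj / n
    pmi <- log(max(pj, eps)) - log(max(p1, eps)) - log(max(p2, eps))
    val <- pmi / (-log(max(pj, eps)))
    if (!is.finite(val)) 1 else min(max(val, -1), 1)
  }

  total_pairs <- 0; skipped <- 0
  topic_scores <- vapply(topics, function(ws) {
    ws <- unique(ws)
    if (length(ws) < 2) return(NA_real_)
    vals <- c()
    for (i in seq_len(length(ws) - 1)) {
      for (j in seq(i + 1, length(ws))) {
        total_pairs <<- total_pairs + 1
        v <- pair_npmi(ws[i], ws[j])
        if (is.na(v)) skipped <<- skipped + 1 else vals <- c(vals, v)
      }
    }
    if (length(vals)) mean(vals) else NA_real_
  }, numeric(1))

  res <- mean(topic_scores, na.rm = TRUE)
  attr(res, "coverage") <- if (total_pairs > 0) {
    1 - skipped / total_pairs
  } else NA_real_
  res
}

#' Topic diversity
#'
#' Fraction of distinct words across all topics' top-`k` lists:
#' `|distinct| / (k * T)` with `k` taken as the longest list. In `(0, 1]`;
#' `T` identical lists score `1/T`.
#'
#' @param topics List of character vectors (top-k words per topic).
#' @return Topic diversity score.
#' @export
topic_diversity <- function(topics) {
  stopifnot(is.list(topics), length(topics) >= 1)
  slots <- sum(lengths(topics))
  if (slots == 0) stop("empty keyword lists")
  length(unique(unlist(topics, use.names = FALSE))) / slots
}

#' Assigned-topic perplexity
#'
#' `exp(-(1/N') * sum_i log P(d_i, label(d_i)))` over the `N'` non-noise
#' documents. For valid probability rows this lies in `[1, M]` when labels
#' agree with the row argmax: 1 for one-hot rows, `M` for uniform rows.
#' Winning probabilities are floored at 1e-12.
#'
#' @param P A `doc_topic_matrix`.
#' @param labels Integer labels aligned with `P` rows (-1 = noise,
#'   excluded).
#' @return Perplexity (>= 1 for row-stochastic input).
#' @export
perplexity_score <- function(P, labels) {
  stopifnot(inherits(P, "doc_topic_matrix"),
            length(labels) == nrow(P$P))
  keep <- which(labels >= 0)
  if (length(keep) == 0) stop("no labelled documents")
  col <- match(as.character(labels[keep]), P$topics)
  if (anyNA(col)) stop("labels reference topics missing from P")
  p <- P$P[cbind(keep, col)]
  exp(-mean(log(pmax(p, 1e-12))))
}

#' Within-topic lexical diversity of member documents' top terms
#'
#' For each topic, each member document contributes its `per_doc_top_m`
#' highest-scoring terms (document term frequency weighted by the topic's
#' term weights); the topic's score is distinct/total over the concatenated
#' slots, and the result is the mean over topics with members. In `(0, 1]`.
#'
#' @param docs A `clean_corpus` data frame.
#' @param labels Integer topic labels aligned with `docs`.
#' @param tw Optional `term_weights` used to score terms within documents;
#'   without it, terms are scored by document frequency alone.
#' @param per_doc_top_m Terms contributed per document (default 3).
#' @return Mean lexical diversity over topics.
#' @export
lexical_diversity <- function(docs, labels, tw = NULL, per_doc_top_m = 3) {
  stopifnot(nrow(docs) == length(labels))
  topics <- sort(unique(labels[labels >= 0]))
  if (length(topics) == 0) stop("need at least one topic")
  scores <- numeric(0)
  for (t in topics) {
    members <- which(labels == t)
    if (length(members) == 0) next
    wrow <- if (!is.null(tw) && as.character(t) %in% rownames(tw$weights)) {
      tw$weights[as.character(t), ]
    } else NULL
    slots <- unlist(lapply(members, function(i) {
      tk <- docs$tokens[[i]]
      if (length(tk) == 0) return(character(0))
      tab <- table(tk)
      sc <- as.numeric(tab)
      if (!is.null(wrow)) {
        sc <- sc * ifelse(names(tab) %in% names(wrow), wrow[names(tab)], 0)
      }
      names(tab)[order(-sc, names(tab))][seq_len(min(per_doc_top_m,
                                                     length(tab)))]
    }), use.names = FALSE)
    if (length(slots)) scores <- c(scores, length(unique(slots)) /
                                     length(slots))
  }
  mean(scores)
}

#' Mean cosine between documents and their topic centroid
#'
#' @param vectors An [embedding_matrix()] or matrix of document vectors.
#' @param labels Integer topic labels aligned with rows (-1 = noise,
#'   excluded). Zero-norm vectors are excluded with a message.
#' @return Mean cosine similarity in `[-1, 1]`.
#' @export
centroid_cosine <- function(vectors, labels) {
  X <- as_point_matrix(vectors)
  stopifnot(nrow(X) == length(labels))
  topics <- sort(unique(labels[labels >= 0]))
  if (length(topics) == 0) stop("need at least one non-noise cluster")
  vals <- numeric(0)
  for (t in topics) {
    M <- X[labels == t, , drop = FALSE]
    ctr <- colMeans(M)
    nz <- sqrt(rowSums(M^2)) > 0
    if (any(!nz)) message(sum(!nz), " zero-norm vector(s) excluded")
    if (sqrt(sum(ctr^2)) == 0 || !any(nz)) next
    vals <- c(vals, drop(cosine_similarity(M[nz, , drop = FALSE],
                                           matrix(ctr, 1))))
  }
  mean(vals)
}

#' Full metrics report for a fitted run
#'
#' @param docs A `clean_corpus` data frame.
#' @param labels Final topic labels aligned with `docs`.
#' @param reduced An [embedding_matrix()] of reduced vectors (for the
#'   silhouette).
#' @param vectors An [embedding_matrix()] of document vectors (for centroid
#'   cosine).
#' @param keywords A `topic_keywords` list.
#' @param P Optional `doc_topic_matrix` (for perplexity).
#' @param tw Optional `term_weights` (for lexical diversity).
#' @param top_k Words per topic used by NPMI/TD (default 10).
#' @param per_doc_top_m Terms per document for lexical diversity.
#' @return List of class `metrics_report`; values are numbers, or `NA` with
#'   a reason attribute where undefined.
#' @export
evaluate_metrics <- function(docs, labels, reduced, vectors, keywords,
                             P = NULL, tw = NULL, top_k = 10,
                             per_doc_top_m = 3) {
  word_lists <- lapply(keywords, function(df) {
    utils::head(as.character(df$term), top_k)
  })
  word_lists <- word_lists[lengths(word_lists) > 0]
  orate <- outlier_rate(labels)
  rep <- list(
    npmi = as.numeric(npmi(word_lists, docs)),
    td = topic_diversity(word_lists),
    perplexity = if (!is.null(P)) perplexity_score(P, labels) else NA_real_,
    lexical_diversity = lexical_diversity(docs, labels, tw,
                                          per_doc_top_m = per_doc_top_m),
    centroid_cosine = centroid_cosine(vectors, labels),
    silhouette = as.numeric(silhouette_score(reduced, labels)),
    outlier_rate = orate$rate,
    n_outliers = orate$n_outliers,
    n_docs = orate$n,
    n_topics = length(word_lists),
    top_k = top_k)
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  for (k in names(x)) {
    cat(sprintf("  %-18s %s\n", k, format(x[[k]], digits = 5)))
  }
  invisible(x)
}
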