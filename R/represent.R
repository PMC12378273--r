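## Topic keyword extraction. Class-based TF-IDF scores every term per topic;
## a popularity-deviation regularizer applies an exponential rank-decay
## penalty to the top frequency decile and a fixed multiplicative boost to
## domain-dictionary terms; maximal marginal relevance re-ranks the top
## candidates to trade relevance against redundancy.

#' Class-based TF-IDF term weights
#'
#' For term `w` and topic `t`:
#' `weight(w, t) = TF(w, t) / sum_i TF(w_i, t) * log(N / df(w))`
#' where `TF(w, t)` counts occurrences of `w` in documents of topic `t`,
#' `N` is the total number of documents and `df(w)` the number of documents
#' containing `w`. Noise-labelled documents (-1) are excluded from topic
#' term counts but still counted in `N` and in document frequencies. A term
#' present in every document gets weight 0 in every topic.
#'
#' @param docs A `clean_corpus` data frame.
#' @param labels Integer vector of topic labels aligned with `docs`
#'   (-1 = noise).
#' @param log_base Base of the IDF logarithm; default `exp(1)` (natural
#'   log), `10` also supported.
#' @return Object of class `term_weights`: list with `topics`, `vocabulary`,
#'   `weights` (topics x vocabulary matrix), `doc_freq`, `corpus_tf` (raw
#'   corpus term counts), `tf` (per-topic term counts) and `n_docs`.
#' @export
ctfidf <- function(docs, labels, log_base = exp(1)) {
  stopifnot(is.data.frame(docs), length(labels) == nrow(docs))
  topics <- sort(unique(labels[labels >= 0]))
  if (length(topics) == 0) stop("need at least one non-noise topic")
  vocab <- sort(unique(unlist(docs$tokens, use.names = FALSE)))
  if (length(vocab) == 0) stop("empty vocabulary")
  n_docs <- nrow(docs)

  doc_freq <- stats::setNames(integer(length(vocab)), vocab)
  corpus_tf <- stats::setNames(integer(length(vocab)), vocab)
  for (tk in docs$tokens) {
    tab <- table(tk)
    corpus_tf[names(tab)] <- corpus_tf[names(tab)] + as.integer(tab)
    u <- unique(tk)
    doc_freq[u] <- doc_freq[u] + 1L
  }

  tf <- matrix(0, length(topics), length(vocab),
               dimnames = list(topics, vocab))
  for (ti in seq_along(topics)) {
    toks <- unlist(docs$tokens[labels == topics[ti]], use.names = FALSE)
    if (length(toks) == 0) {
      warning("topic ", topics[ti], " has no tokens; zero weight row")
      next
    }
    tab <- table(toks)
    tf[ti, names(tab)] <- as.integer(tab)
  }

  idf <- log(n_docs / pmax(doc_freq, 1)) / log(log_base)
  row_tot <- rowSums(tf)
  weights <- (tf / ifelse(row_tot > 0, row_tot, 1)) *
    matrix(idf, nrow(tf), ncol(tf), byrow = TRUE)

  structure(list(topics = topics, vocabulary = vocab, weights = weights,
                 doc_freq = doc_freq, corpus_tf = corpus_tf, tf = tf,
                 n_docs = n_docs),
            class = "term_weights")
}

#' Configuration for the popularity-deviation regularizer
#'
#' @param alpha Exponential decay rate applied per frequency rank
#'   (default 0.05).
#' @param decile Fraction of the vocabulary, by corpus frequency, subject to
#'   the decay (default 0.10, i.e. the top decile).
#' @param boost Multiplier for domain-dictionary terms (default 1.5).
#' @param dictionary Character vector of dictionary terms; defaults to the
#'   packaged adolescent-health vocabulary.
#' @param rank_scope `"decile_only"` (default): decay only terms inside the
#'   top decile; `"all"`: decay every term by its rank.
#' @param rank_direction `"as_printed"` (default): the exponent is the raw
#'   frequency rank, so the most frequent term (rank 1) receives the mildest
#'   decay `e^(-alpha)`; `"inverted"`: ranks are reversed within the scope so
#'   the most frequent term is penalized hardest.
#' @return Object of class `pdr_config`.
#' @export
pdr_config <- function(alpha = 0.05, decile = 0.10, boost = 1.5,
                       dictionary = load_dictionary(),
                       rank_scope = c("decile_only", "all"),
                       rank_direction = c("as_printed", "inverted")) {
  rank_scope <- match.arg(rank_scope)
  rank_direction <- match.arg(rank_direction)
  stopifnot(alpha >= 0, decile > 0, decile <= 1, boost >= 1)
  structure(list(alpha = alpha, decile = decile, boost = boost,
                 dictionary = tolower(dictionary), rank_scope = rank_scope,
                 rank_direction = rank_direction),
            class = "pdr_config")
}

## Terms a dictionary entry matches in a unigram vocabulary: unigram entries
## by equality; multiword entries by either component token.
dictionary_matches <- function(dictionary, vocabulary) {
  parts <- unlist(strsplit(dictionary, "[^[:alnum:]_]+"), use.names = FALSE)
  unique(vocabulary[vocabulary %in% tolower(parts[nzchar(parts)])])
}

#' Popularity-deviation regularization of term weights
#'
#' Terms in the top `decile` of the corpus frequency ranking are multiplied
#' by `exp(-alpha * rank)` (ranking ties broken lexicographically);
#' dictionary terms are multiplied by `boost`, applied after the decay when
#' a term is both. All other weights are unchanged.
#'
#' @param tw A `term_weights` object from [ctfidf()].
#' @param cfg A [pdr_config()].
#' @return A `term_weights` object with regularized `weights` plus fields
#'   `multipliers` (per-term), `decile_terms`, `dictionary_terms`, and
#'   `diagnostics` (mean decile multiplier as `reduction_ratio`, mean
#'   dictionary multiplier as `boosting_rate`).
#' @export
pdr_weights <- function(tw, cfg = pdr_config()) {
  stopifnot(inherits(tw, "term_weights"), inherits(cfg, "pdr_config"))
  vocab <- tw$vocabulary
  V <- length(vocab)
  ord <- order(-tw$corpus_tf, vocab)
  rank <- integer(V); rank[ord] <- seq_len(V)  # rank 1 = most frequent

  n_scope <- if (cfg$rank_scope == "decile_only") {
    ceiling(cfg$decile * V)
  } else V
  in_scope <- rank <= n_scope
  r_eff <- if (cfg$rank_direction == "as_printed") rank
           else n_scope - rank + 1L

  mult <- rep(1, V)
  mult[in_scope] <- exp(-cfg$alpha * r_eff[in_scope])

  dict_terms <- dictionary_matches(cfg$dictionary, vocab)
  is_dict <- vocab %in% dict_terms
  mult[is_dict] <- mult[is_dict] * cfg$boost

  out <- tw
  out$weights <- tw$weights * matrix(mult, nrow(tw$weights), V, byrow = TRUE)
  out$multipliers <- stats::setNames(mult, vocab)
  out$decile_terms <- vocab[rank <= ceiling(cfg$decile * V)]
  out$dictionary_terms <- dict_terms
  out$diagnostics <- list(
    reduction_ratio = if (any(in_scope)) mean(exp(-cfg$alpha * r_eff[in_scope]))
                      else NA_real_,
    boosting_rate = if (any(is_dict)) mean(mult[is_dict]) else NA_real_)
  out
}

#' Greedy maximal marginal relevance selection
#'
#' Iteratively picks the candidate maximizing
#' `lambda * relevance(w) - (1 - lambda) * max_{s in selected} sim(w, s)`;
#' the first pick is the most relevant candidate.
#'
#' @param candidates Data frame with columns `term` and `relevance`, ranked
#'   or not.
#' @param sim Term-term similarity matrix with dimnames covering the
#'   candidate terms.
#' @param lambda Trade-off in `[0, 1]`; 1 reduces to top-k by relevance.
#' @param k Number of terms to select.
#' @return Character vector of selected terms (no repeats). If
#'   `k > nrow(candidates)`, all candidates are returned with a warning.
#' @export
mmr_select <- function(candidates, sim, lambda = 0.5, k = 10) {
  stopifnot(is.data.frame(candidates),
            all(c("term", "relevance") %in% names(candidates)),
            lambda >= 0, lambda <= 1, k >= 1)
  terms <- as.character(candidates$term)
  rel <- candidates$relevance
  if (k > length(terms)) {
    warning("k exceeds number of candidates; returning all")
    k <- length(terms)
  }
  selected <- character(0)
  avail <- seq_along(terms)
  for (step in seq_len(k)) {
    if (length(selected) == 0) {
      pick <- avail[which.max(rel[avail])]
    } else {
      red <- vapply(avail, function(i) {
        max(sim[terms[i], selected])
      }, numeric(1))
      score <- lambda * rel[avail] - (1 - lambda) * red
      pick <- avail[which.max(score)]
    }
    selected <- c(selected, terms[pick])
    avail <- setdiff(avail, pick)
  }
  selected
}

#' Ranked keyword lists for every topic
#'
#' Takes the top `2 * top_k` terms of each topic by (regularized) weight as
#' candidates and re-ranks them with [mmr_select()]. Term similarity is the
#' cosine between token embedding vectors; the query is the weight-weighted
#' centroid of the candidate term vectors. When token vectors are
#' unavailable, MMR is skipped and the plain weight ranking is returned.
#'
#' @param tw A `term_weights` object (after [pdr_weights()] if the
#'   regularizer is active).
#' @param token_vecs Optional matrix of token vectors (rownames = terms),
#'   e.g. from the hash embedding backend.
#' @param top_k Keywords per topic (default 10).
#' @param mmr_lambda MMR trade-off (default 0.5); ignored without token
#'   vectors.
#' @return List of per-topic data frames `(term, weight)` of `top_k` rows,
#'   named by topic id; class `topic_keywords`.
#' @export
topic_keywords <- function(tw, token_vecs = NULL, top_k = 10,
                           mmr_lambda = 0.5) {
  stopifnot(inherits(tw, "term_weights"))
  out <- vector("list", length(tw$topics))
  names(out) <- tw$topics
  for (ti in seq_along(tw$topics)) {
    w <- tw$weights[ti, ]
    ord <- order(-w, tw$vocabulary)
    cand_n <- min(2 * top_k, sum(w > 0))
    if (cand_n == 0) {
      out[[ti]] <- data.frame(term = character(0), weight = numeric(0))
      next
    }
    cand <- tw$vocabulary[ord[seq_len(cand_n)]]
    cw <- w[ord[seq_len(cand_n)]]
    if (!is.null(token_vecs) && all(cand %in% rownames(token_vecs)) &&
        cand_n > 1) {
      V <- token_vecs[cand, , drop = FALSE]
      q <- colSums(V * cw) / sum(cw)
      relevance <- drop(cosine_similarity(V, matrix(q, 1)))
      sim <- cosine_similarity(V)
      dimnames(sim) <- list(cand, cand)
      sel <- mmr_select(data.frame(term = cand, relevance = relevance),
                        sim, lambda = mmr_lambda, k = min(top_k, cand_n))
    } else {
      sel <- cand[seq_len(min(top_k, cand_n))]
    }
    out[[ti]] <- data.frame(term = sel, weight = w[sel],
                            row.names = NULL)
  }
  class(out) <- "topic_keywords"
  out
}

#' @export
print.topic_keywords <- function(x, n = 5, ...) {
  for (t in names(x)) {
    cat("topic ", t, ": ",
        paste(utils::head(x[[t]]$term, n), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

## Flatten topic keyword lists into the TSV schema used by run artifacts.
keywords_table <- function(kw, tw = NULL) {
  rows <- lapply(names(kw), function(t) {
    df <- kw[[t]]
    if (nrow(df) == 0) return(NULL)
    data.frame(topic_id = t, rank = seq_len(nrow(df)), term = df$term,
               weight = df$weight, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
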