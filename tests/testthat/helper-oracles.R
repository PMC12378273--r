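# Independent naive reference implementations used to cross-check the
# package's metric and weighting code. These are deliberately literal
# two-loop translations of the definitions and share no code with R/.

oracle_silhouette <- function(X, labels, metric = "euclidean") {
  keep <- labels >= 0
  X <- as.matrix(X)[keep, , drop = FALSE]
  labels <- labels[keep]
  cl <- unique(labels)
  if (length(cl) < 2) return(NA_real_)
  n <- nrow(X)
  dfun <- function(i, j) {
    if (metric == "euclidean") sqrt(sum((X[i, ] - X[j, ])^2))
    else 1 - sum(X[i, ] * X[j, ]) /
      (sqrt(sum(X[i, ]^2)) * sqrt(sum(X[j, ]^2)))
  }
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) dfun(i, j), 0))
    b <- Inf
    for (c2 in setdiff(cl, labels[i])) {
      others <- which(labels == c2)
      b <- min(b, mean(vapply(others, function(j) dfun(i, j), 0)))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

oracle_mreach <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  core <- vapply(seq_len(n), function(i) sort(D[i, -i])[k], 0)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) M[i, j] <- max(core[i], core[j], D[i, j])
  }
  M
}

oracle_ctfidf <- function(docs, labels) {
  topics <- sort(unique(labels[labels >= 0]))
  vocab <- sort(unique(unlist(docs$tokens)))
  N <- nrow(docs)
  W <- matrix(0, length(topics), length(vocab),
              dimnames = list(topics, vocab))
  for (ti in seq_along(topics)) {
    toks <- unlist(docs$tokens[labels == topics[ti]])
    tot <- length(toks)
    for (vi in seq_along(vocab)) {
      w <- vocab[vi]
      tf <- sum(toks == w)
      df <- sum(vapply(docs$tokens, function(tk) w %in% tk, TRUE))
      if (tot > 0 && df > 0) {
        W[ti, vi] <- tf / tot * log(N / df)
      }
    }
  }
  W
}

oracle_npmi <- function(word_lists, docs) {
  n <- nrow(docs)
  sets <- lapply(docs$tokens, unique)
  has <- function(w) vapply(sets, function(s) w %in% s, TRUE)
  per_topic <- vapply(word_lists, function(ws) {
    ws <- unique(ws)
    vals <- c()
    for (i in seq_len(length(ws) - 1)) for (j in seq(i + 1, length(ws))) {
      ci <- sum(has(ws[i])); cj <- sum(has(ws[j]))
      if (ci == 0 || cj == 0) next
      cij <- sum(has(ws[i]) & has(ws[j]))
      v <- if (cij == 0) -1 else {
        pmi <- log((cij / n) / ((ci / n) * (cj / n)))
        if (cij == n) 1 else pmi / (-log(cij / n))
      }
      vals <- c(vals, v)
    }
    if (length(vals)) mean(vals) else NA_real_
  }, 0)
  mean(per_topic, na.rm = TRUE)
}

oracle_td <- function(word_lists) {
  length(unique(unlist(word_lists))) / sum(lengths(word_lists))
}

oracle_perplexity <- function(P, labels) {
  keep <- which(labels >= 0)
  lp <- vapply(keep, function(i) {
    log(max(P$P[i, match(as.character(labels[i]), P$topics)], 1e-12))
  }, 0)
  exp(-mean(lp))
}

oracle_lexdiv <- function(docs, labels, tw, m) {
  topics <- sort(unique(labels[labels >= 0]))
  scores <- c()
  for (t in topics) {
    slots <- c()
    for (i in which(labels == t)) {
      tk <- docs$tokens[[i]]
      if (!length(tk)) next
      tab <- table(tk)
      sc <- as.numeric(tab)
      if (!is.null(tw)) {
        wr <- tw$weights[as.character(t), ]
        sc <- sc * ifelse(names(tab) %in% names(wr), wr[names(tab)], 0)
      }
      slots <- c(slots,
                 names(tab)[order(-sc, names(tab))][seq_len(min(m,
                                                               length(tab)))])
    }
    if (length(slots)) scores <- c(scores,
                                   length(unique(slots)) / length(slots))
  }
  mean(scores)
}

oracle_centroid_cosine <- function(X, labels) {
  X <- as.matrix(X)
  vals <- c()
  for (t in sort(unique(labels[labels >= 0]))) {
    M <- X[labels == t, , drop = FALSE]
    ctr <- colMeans(M)
    for (i in seq_len(nrow(M))) {
      vals <- c(vals, sum(M[i, ] * ctr) /
                  (sqrt(sum(M[i, ]^2)) * sqrt(sum(ctr^2))))
    }
  }
  mean(vals)
}
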