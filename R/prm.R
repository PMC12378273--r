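## Probabilistic reassignment of noise documents. Every document gets a
## row-stochastic probability distribution over topics from a softmax over
## negative document-to-centroid distances; noise documents whose winning
## probability strictly clears a threshold are reassigned to that topic.

#' Configuration for probabilistic reassignment
#'
#' @param threshold Minimum winning probability for a noise document to be
#'   reassigned; strict inequality; default 0.15.
#' @param distance Document-to-centroid distance: `"cosine"` (default) or
#'   `"euclidean"`.
#' @param space Which vectors to use: `"reduced"` (default) or `"original"`.
#' @return Object of class `prm_config`.
#' @export
prm_config <- function(threshold = 0.15,
                       distance = c("cosine", "euclidean"),
                       space = c("reduced", "original")) {
  distance <- match.arg(distance)
  space <- match.arg(space)
  stopifnot(threshold >= 0, threshold < 1)
  structure(list(threshold = threshold, distance = distance, space = space),
            class = "prm_config")
}

#' Distances from every document to every topic centroid
#'
#' A topic's centroid is the mean of its member vectors. Under cosine the
#' distance is `1 - cos`; a zero-norm vector (document or centroid) falls
#' back to the Euclidean distance for that entry, with a message.
#'
#' @param points An [embedding_matrix()] aligned with `result`.
#' @param result A `cluster_result` providing topic memberships.
#' @param cfg A [prm_config()].
#' @return N x M nonnegative matrix, columns named by topic label.
#' @export
topic_distances <- function(points, result, cfg = prm_config()) {
  X <- as_point_matrix(points)
  labels <- result$labels
  stopifnot(nrow(X) == length(labels))
  topics <- sort(unique(labels[labels >= 0]))
  if (length(topics) == 0) stop("no topics to compute distances to")
  C <- t(vapply(topics, function(t) {
    colMeans(X[labels == t, , drop = FALSE])
  }, numeric(ncol(X))))

  if (cfg$distance == "euclidean") {
    D <- pairwise_distances(X, C, metric = "euclidean")
  } else {
    D <- 1 - cosine_similarity(X, C)
    zr <- sqrt(rowSums(X^2)) == 0
    zc <- sqrt(rowSums(C^2)) == 0
    if (any(zr) || any(zc)) {
      message("zero-norm vector(s) under cosine; using euclidean fallback ",
              "for affected entries")
      E <- pairwise_distances(X, C, metric = "euclidean")
      D[zr, ] <- E[zr, , drop = FALSE]
      D[, zc] <- E[, zc, drop = FALSE]
    }
  }
  dimnames(D) <- list(rownames(X), topics)
  pmax(D, 0)
}

#' Row-stochastic document-topic probabilities
#'
#' `P(t_j | d_i) = exp(-d_ij) / sum_k exp(-d_ik)`, computed with
#' max-subtraction for numerical stability; every row sums to 1.
#'
#' @param distances Finite N x M matrix of document-to-topic distances.
#' @return Object of class `doc_topic_matrix`: list with `ids`, `topics`
#'   and `P` (N x M row-stochastic matrix).
#' @export
soft_assign <- function(distances) {
  distances <- as.matrix(distances)
  if (ncol(distances) == 0) stop("no topics to assign")
  if (!all(is.finite(distances))) stop("distances must be finite")
  Z <- -distances
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  P <- E / rowSums(E)
  structure(list(ids = rownames(distances) %||%
                   as.character(seq_len(nrow(distances))),
                 topics = colnames(distances) %||%
                   as.character(seq_len(ncol(distances)) - 1L),
                 P = P),
            class = "doc_topic_matrix")
}

#' @export
print.doc_topic_matrix <- function(x, ...) {
  cat("<doc_topic_matrix> ", length(x$ids), " documents x ",
      length(x$topics), " topics\n", sep = "")
  invisible(x)
}

#' Reassign noise documents above the probability threshold
#'
#' Only documents labelled -1 are touched: a noise document whose maximum
#' topic probability strictly exceeds the threshold receives the argmax
#' topic (ties go to the lowest topic index); others stay noise. Non-noise
#' labels never change, so the outlier count never increases.
#'
#' @param result A `cluster_result`.
#' @param P A `doc_topic_matrix` aligned with `result` (same order).
#' @param cfg A [prm_config()].
#' @return A `cluster_result` with updated labels and an attribute
#'   `"reassignment_report"`: data frame
#'   `(id, old_label, new_label, winning_probability)` for the touched
#'   documents.
#' @export
reassign_outliers <- function(result, P, cfg = prm_config()) {
  stopifnot(inherits(result, "cluster_result"),
            inherits(P, "doc_topic_matrix"))
  labels <- result$labels
  if (length(labels) != nrow(P$P)) stop("P not aligned with result")
  topic_ids <- as.integer(P$topics)
  out <- result
  noise <- which(labels == -1L)
  rows <- data.frame(id = character(0), old_label = integer(0),
                     new_label = integer(0),
                     winning_probability = numeric(0))
  if (length(noise)) {
    win <- apply(P$P[noise, , drop = FALSE], 1, which.max)
    wp <- P$P[cbind(noise, win)]
    hit <- wp > cfg$threshold
    new_lab <- labels
    new_lab[noise[hit]] <- topic_ids[win[hit]]
    rows <- data.frame(id = names(labels)[noise],
                       old_label = -1L,
                       new_label = new_lab[noise],
                       winning_probability = wp,
                       stringsAsFactors = FALSE)
    out$labels <- new_lab
    out$outlier_scores <- outlier_scores(out)
  }
  attr(out, "reassignment_report") <- rows
  out
}
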