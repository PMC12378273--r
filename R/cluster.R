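## Hierarchical density-based clustering over mutual reachability distances.
## The hierarchy is the single-linkage dendrogram of the mutual reachability
## matrix (equivalent to the minimum spanning tree construction); it is
## condensed by the minimum cluster size, cluster stability is accumulated
## in the per-point form sum_p (lambda_p - lambda_birth), and the flat
## clustering is the excess-of-mass selection of most-stable clusters.
## Points in no selected cluster carry the noise label -1.

#' Configuration for density clustering
#'
#' @param min_cluster_size Smallest group of documents accepted as a
#'   cluster (default 100).
#' @param min_samples Neighbourhood size `k` used for core distances;
#'   defaults to `min_cluster_size`.
#' @param metric Distance metric in the reduced space, `"euclidean"`
#'   (default) or `"cosine"`.
#' @return Object of class `clustering_config`.
#' @export
clustering_config <- function(min_cluster_size = 100,
                              min_samples = min_cluster_size,
                              metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  if (!is_count(min_cluster_size) || min_cluster_size < 2) {
    stop("min_cluster_size must be >= 2")
  }
  if (!is_count(min_samples)) stop("min_samples must be >= 1")
  structure(list(min_cluster_size = as.integer(min_cluster_size),
                 min_samples = as.integer(min_samples), metric = metric),
            class = "clustering_config")
}

as_point_matrix <- function(points) {
  if (inherits(points, "embedding_matrix")) points$vectors
  else as.matrix(points)
}

## Distance from each point to its k-th nearest neighbour (self excluded;
## expects the diagonal of D set to Inf).
core_distances <- function(D, k) {
  apply(D, 1, function(r) sort(r, partial = k)[k])
}

#' Mutual reachability distance matrix
#'
#' `d_mreach(i, j) = max(core(i), core(j), d(i, j))` where `core(x)` is the
#' distance from `x` to its `k`-th nearest neighbour (`k = min_samples`).
#' Symmetric and pointwise no smaller than the base distance.
#'
#' @param points An [embedding_matrix()] or numeric matrix of row vectors.
#' @param cfg A [clustering_config()]; `min_samples` must be below the
#'   number of points.
#' @return N x N symmetric matrix with attribute `"core_distances"`.
#' @export
mutual_reachability <- function(points, cfg = clustering_config()) {
  X <- as_point_matrix(points)
  n <- nrow(X)
  if (n < 2) stop("need at least two points")
  k <- cfg$min_samples
  if (k >= n) stop("min_samples (", k, ") must be below the number of points")
  D <- pairwise_distances(X, metric = cfg$metric)
  diag(D) <- Inf
  core <- core_distances(D, k)
  diag(D) <- 0
  M <- pmax(D, outer(core, rep(1, n)), outer(rep(1, n), core))
  diag(M) <- 0
  attr(M, "core_distances") <- core
  M
}

#' Density-based clustering with noise labels
#'
#' Builds the mutual-reachability hierarchy, condenses it at
#' `min_cluster_size`, selects the most stable clusters, and labels every
#' document with a cluster index (0-based) or -1 for noise. Deterministic
#' for a fixed input order.
#'
#' @inheritParams mutual_reachability
#' @return Object of class `cluster_result`: list with `labels` (named
#'   integer vector, -1 = noise), `core_distances`, `outlier_scores` (ratio
#'   of a member's core distance to its cluster's mean core distance; `NA`
#'   for noise), and `stabilities` (data frame `cluster`, `stability`,
#'   `lambda_birth`, `lambda_death`, `size`).
#' @export
fit_clusters <- function(points, cfg = clustering_config()) {
  X <- as_point_matrix(points)
  n <- nrow(X)
  ids <- rownames(X) %||% as.character(seq_len(n))
  mcs <- cfg$min_cluster_size

  if (n < mcs) {
    warning("fewer points (", n, ") than min_cluster_size (", mcs,
            "); labelling everything noise")
    core <- if (cfg$min_samples < n && n >= 2) {
      D <- pairwise_distances(X, metric = cfg$metric)
      diag(D) <- Inf
      core_distances(D, cfg$min_samples)
    } else rep(NA_real_, n)
    return(new_cluster_result(ids, rep(-1L, n), core,
                              data.frame(cluster = integer(0),
                                         stability = numeric(0),
                                         lambda_birth = numeric(0),
                                         lambda_death = numeric(0),
                                         size = integer(0))))
  }

  M <- mutual_reachability(points, cfg)
  core <- attr(M, "core_distances")
  hc <- stats::hclust(stats::as.dist(M), method = "single")
  condensed <- condense_tree(hc, n, mcs)
  sel <- select_eom(condensed)
  labels <- label_points(condensed, sel, n)
  names(labels) <- ids

  keep <- condensed$cluster_id %in% which(sel | !is.na(condensed$parent))
  stab <- data.frame(cluster = condensed$cluster_id,
                     stability = condensed$stability,
                     lambda_birth = condensed$lambda_birth,
                     lambda_death = condensed$lambda_death,
                     size = condensed$size)
  stab$selected <- sel

  new_cluster_result(ids, labels, core, stab)
}

new_cluster_result <- function(ids, labels, core, stabilities) {
  names(labels) <- ids
  names(core) <- ids
  res <- structure(list(labels = labels, core_distances = core,
                        outlier_scores = NULL, stabilities = stabilities),
                   class = "cluster_result")
  res$outlier_scores <- outlier_scores(res)
  res
}

#' @export
print.cluster_result <- function(x, ...) {
  m <- length(unique(x$labels[x$labels >= 0]))
  cat("<cluster_result> ", length(x$labels), " points, ", m, " clusters, ",
      sum(x$labels == -1), " noise\n", sep = "")
  invisible(x)
}

## --- condensed tree ---------------------------------------------------

## Walk the single-linkage dendrogram top-down. A child subtree smaller
## than min_cluster_size sheds its points from the current cluster at the
## current lambda = 1/height; a split into two large subtrees creates two
## child clusters. Returns parallel vectors describing clusters plus the
## per-point fall-out records.
condense_tree <- function(hc, n, mcs) {
  merge <- hc$merge
  height <- hc$height
  nm <- nrow(merge)
  size <- integer(nm)
  for (m in seq_len(nm)) {
    l <- merge[m, 1]; r <- merge[m, 2]
    size[m] <- (if (l < 0) 1L else size[l]) + (if (r < 0) 1L else size[r])
  }

  subtree_leaves <- function(node) {
    if (node < 0) return(-node)
    out <- integer(0)
    stack <- node
    while (length(stack)) {
      nd <- stack[length(stack)]; stack <- stack[-length(stack)]
      l <- merge[nd, 1]; r <- merge[nd, 2]
      if (l < 0) out <- c(out, -l) else stack <- c(stack, l)
      if (r < 0) out <- c(out, -r) else stack <- c(stack, r)
    }
    out
  }

  K <- 0L
  parent <- integer(0); lambda_birth <- numeric(0)
  stability <- numeric(0); lambda_death <- numeric(0)
  csize <- integer(0)
  children <- list()
  pt_cluster <- integer(n); pt_lambda <- numeric(n)

  new_cluster <- function(par, birth, sz) {
    K <<- K + 1L
    parent[K] <<- par; lambda_birth[K] <<- birth
    stability[K] <<- 0; lambda_death[K] <<- NA_real_
    csize[K] <<- sz
    children[[K]] <<- integer(0)
    if (!is.na(par)) children[[par]] <<- c(children[[par]], K)
    K
  }

  root_node <- nm
  root <- new_cluster(NA_integer_, 1 / max(height[nm], 1e-12), n)
  stack_nodes <- root_node
  stack_clusters <- root

  while (length(stack_nodes)) {
    node <- stack_nodes[length(stack_nodes)]
    c_id <- stack_clusters[length(stack_clusters)]
    stack_nodes <- stack_nodes[-length(stack_nodes)]
    stack_clusters <- stack_clusters[-length(stack_clusters)]

    lam <- 1 / max(height[node], 1e-12)
    l <- merge[node, 1]; r <- merge[node, 2]
    sl <- if (l < 0) 1L else size[l]
    sr <- if (r < 0) 1L else size[r]

    if (sl >= mcs && sr >= mcs) {
      # true split: the current cluster dies, two children are born
      stability[c_id] <- stability[c_id] +
        (sl + sr) * (lam - lambda_birth[c_id])
      lambda_death[c_id] <- lam
      cl <- new_cluster(c_id, lam, sl)
      cr <- new_cluster(c_id, lam, sr)
      stack_nodes <- c(stack_nodes, l, r)
      stack_clusters <- c(stack_clusters, cl, cr)
    } else if (sl >= mcs || sr >= mcs) {
      big <- if (sl >= mcs) l else r
      small <- if (sl >= mcs) r else l
      pts <- subtree_leaves(small)
      pt_cluster[pts] <- c_id; pt_lambda[pts] <- lam
      stability[c_id] <- stability[c_id] +
        length(pts) * (lam - lambda_birth[c_id])
      stack_nodes <- c(stack_nodes, big)       # big side is internal
      stack_clusters <- c(stack_clusters, c_id)
    } else {
      # cluster dwindles below min size: everything sheds here
      pts <- c(subtree_leaves(l), subtree_leaves(r))
      pt_cluster[pts] <- c_id; pt_lambda[pts] <- lam
      stability[c_id] <- stability[c_id] +
        length(pts) * (lam - lambda_birth[c_id])
      lambda_death[c_id] <- lam
    }
  }

  list(cluster_id = seq_len(K), parent = parent,
       lambda_birth = lambda_birth, lambda_death = lambda_death,
       stability = stability, size = csize, children = children,
       pt_cluster = pt_cluster, pt_lambda = pt_lambda, root = root)
}

## Excess-of-mass selection: bottom-up, a cluster is selected when its own
## stability is at least the summed (selected) stability of its children;
## the root is never a cluster.
select_eom <- function(ct) {
  K <- length(ct$cluster_id)
  selected <- logical(K)
  sel_stab <- numeric(K)
  for (c_id in rev(seq_len(K))) {
    ch <- ct$children[[c_id]]
    if (length(ch) == 0) {
      selected[c_id] <- c_id != ct$root
      sel_stab[c_id] <- ct$stability[c_id]
    } else {
      cs <- sum(sel_stab[ch])
      if (c_id != ct$root && ct$stability[c_id] >= cs) {
        selected[c_id] <- TRUE
        sel_stab[c_id] <- ct$stability[c_id]
      } else {
        sel_stab[c_id] <- cs
      }
    }
  }
  # prune: deselect descendants of selected clusters
  stack <- ct$root
  shadow <- logical(K)
  order_visit <- integer(0)
  while (length(stack)) {
    c_id <- stack[length(stack)]; stack <- stack[-length(stack)]
    order_visit <- c(order_visit, c_id)
    for (ch in ct$children[[c_id]]) {
      shadow[ch] <- shadow[c_id] || selected[c_id]
      stack <- c(stack, ch)
    }
  }
  selected & !shadow
}

label_points <- function(ct, selected, n) {
  # map each condensed cluster to the selected ancestor-or-self, if any
  K <- length(ct$cluster_id)
  sel_ids <- which(selected)
  label_of <- rep(NA_integer_, K)
  flat <- stats::setNames(seq_along(sel_ids) - 1L, sel_ids)
  for (c_id in seq_len(K)) {
    cur <- c_id
    while (!is.na(cur)) {
      if (selected[cur]) { label_of[c_id] <- flat[[as.character(cur)]]; break }
      cur <- ct$parent[cur]
    }
  }
  labels <- rep(-1L, n)
  has <- ct$pt_cluster > 0
  labels[has] <- ifelse(is.na(label_of[ct$pt_cluster[has]]), -1L,
                        label_of[ct$pt_cluster[has]])
  labels
}

#' Core-distance outlier scores
#'
#' A cluster member's score is its core distance divided by the mean core
#' distance of its cluster, so scores average exactly 1 within each cluster
#' and larger values flag likely outliers. Noise points receive `NA`.
#'
#' @param result A `cluster_result`.
#' @return Named numeric vector of scores aligned with `result$labels`.
#' @export
outlier_scores <- function(result) {
  stopifnot(inherits(result, "cluster_result"))
  labels <- result$labels
  core <- result$core_distances
  scores <- rep(NA_real_, length(labels))
  for (cl in unique(labels[labels >= 0])) {
    idx <- which(labels == cl)
    m <- mean(core[idx])
    scores[idx] <- if (m > 0) core[idx] / m else 1
  }
  names(scores) <- names(labels)
  scores
}

#' Fraction of documents labelled noise
#'
#' @param labels Integer label vector (-1 = noise).
#' @return List with `rate` (fraction in `[0, 1]`), `n_outliers` and `n`.
#' @export
outlier_rate <- function(labels) {
  stopifnot(length(labels) > 0)
  n_out <- sum(labels == -1)
  list(rate = n_out / length(labels), n_outliers = n_out, n = length(labels))
}
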