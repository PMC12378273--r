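## Manifold dimensionality reduction. Document vectors are projected with a
## spectral embedding of a locally-calibrated k-nearest-neighbour graph:
## affinities use the familiar exp(-(d - rho)/sigma) kernel with a per-point
## bandwidth sigma tuned so each point distributes ~log2(k) of mass over its
## neighbourhood, the graph is symmetrized by probabilistic union and kept
## connected through its minimum spanning tree, and coordinates are the
## leading non-trivial eigenvectors of the normalized adjacency. Because the
## eigenbasis is nested, a single decomposition serves every candidate
## dimensionality in the silhouette sweep.

#' Configuration for dimensionality reduction
#'
#' @param n_neighbors Neighbourhood size of the kNN graph (default 30).
#' @param metric Distance in the input space: `"cosine"` (default) or
#'   `"euclidean"`.
#' @param seed Integer seed (used only when silhouette subsampling kicks in;
#'   the embedding itself is deterministic).
#' @param candidate_dims Integer vector of output dimensionalities to score
#'   in [select_dimension()]; default `2:40`.
#' @param diffusion_time Nonnegative integer exponent applied to the graph
#'   eigenvalues (diffusion-map scaling, default 8). Larger values contract
#'   within-cluster directions relative to between-cluster ones, mimicking
#'   the cluster-tightening behaviour of stochastic neighbour layouts.
#' @return Object of class `reduction_config`.
#' @export
reduction_config <- function(n_neighbors = 30, metric = c("cosine", "euclidean"),
                             seed = 1, candidate_dims = 2:40,
                             diffusion_time = 8) {
  metric <- match.arg(metric)
  stopifnot(is.numeric(diffusion_time), length(diffusion_time) == 1,
            diffusion_time >= 0, diffusion_time == floor(diffusion_time))
  candidate_dims <- sort(unique(as.integer(candidate_dims)))
  if (length(candidate_dims) == 0) stop("candidate_dims must be non-empty")
  if (any(candidate_dims < 2)) stop("candidate dimensions must be >= 2")
  if (!is_count(n_neighbors) || n_neighbors < 2) {
    stop("n_neighbors must be >= 2")
  }
  structure(list(n_neighbors = as.integer(n_neighbors), metric = metric,
                 seed = as.integer(seed), candidate_dims = candidate_dims,
                 diffusion_time = diffusion_time),
            class = "reduction_config")
}

#' Reduce document vectors to a fixed dimensionality
#'
#' @param vectors An [embedding_matrix()].
#' @param dim Target dimensionality (at least 2).
#' @param cfg A [reduction_config()].
#' @return An [embedding_matrix()] of shape N x `dim`. Deterministic for a
#'   fixed configuration.
#' @export
reduce_embeddings <- function(vectors, dim, cfg = reduction_config()) {
  stopifnot(inherits(vectors, "embedding_matrix"))
  if (!is_count(dim) || dim < 2) stop("dim must be >= 2")
  basis <- spectral_basis(vectors, dim, cfg)
  embedding_matrix(vectors$ids, basis[, seq_len(dim), drop = FALSE])
}

## Leading `max_dim` non-trivial spectral coordinates of the kNN graph.
spectral_basis <- function(vectors, max_dim, cfg) {
  X <- vectors$vectors
  n <- nrow(X)
  k <- cfg$n_neighbors
  if (n <= k) {
    stop("need more documents (", n, ") than n_neighbors (", k,
         "); lower n_neighbors in the reduction config")
  }
  if (max_dim >= n - 1) stop("target dimensionality too large for corpus size")

  D <- pairwise_distances(X, metric = cfg$metric)
  diag(D) <- Inf
  W <- matrix(0, n, n)
  target <- log2(k)
  for (i in seq_len(n)) {
    ord <- order(D[i, ])[seq_len(k)]
    dists <- D[i, ord]
    rho <- min(dists)
    gaps <- pmax(dists - rho, 0)
    # binary search for the local bandwidth
    lo <- 1e-6; hi <- max(max(gaps), 1e-6) * 4 + 1
    for (it in 1:64) {
      mid <- (lo + hi) / 2
      s <- sum(exp(-gaps / mid))
      if (s > target) hi <- mid else lo <- mid
    }
    W[i, ord] <- exp(-gaps / ((lo + hi) / 2))
  }
  W <- W + t(W) - W * t(W)          # probabilistic union
  mst <- mst_edges(D)                # keep the graph connected
  floor_w <- 1e-3
  W[mst] <- pmax(W[mst], floor_w)
  W[mst[, c(2, 1)]] <- pmax(W[mst[, c(2, 1)]], floor_w)

  dg <- pmax(rowSums(W), 1e-12)
  S <- W / sqrt(outer(dg, dg))
  eg <- eigen(S, symmetric = TRUE)
  # drop the trivial leading eigenvector; canonicalize signs for determinism
  U <- eg$vectors[, 1 + seq_len(max_dim), drop = FALSE]
  lam <- pmax(eg$values[1 + seq_len(max_dim)], 0)
  U <- U %*% diag(lam^cfg$diffusion_time, nrow = length(lam))
  for (j in seq_len(ncol(U))) {
    p <- which.max(abs(U[, j]))
    if (U[p, j] < 0) U[, j] <- -U[, j]
  }
  U * sqrt(n)
}

## Minimum spanning tree of a dense distance matrix (Prim). Returns a
## two-column index matrix of edges.
mst_edges <- function(D) {
  n <- nrow(D)
  in_tree <- logical(n)
  best <- rep(Inf, n)
  parent <- integer(n)
  in_tree[1] <- TRUE
  d1 <- D[1, ]; d1[1] <- Inf
  upd <- d1 < best
  best[upd] <- d1[upd]; parent[upd] <- 1L
  edges <- matrix(0L, n - 1, 2)
  for (e in seq_len(n - 1)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    edges[e, ] <- c(parent[v], v)
    in_tree[v] <- TRUE
    dv <- D[v, ]
    upd <- !in_tree & dv < best
    best[upd] <- dv[upd]; parent[upd] <- v
  }
  edges
}

#' Pick the dimension that maximizes a silhouette score table
#'
#' @param scores Named numeric vector mapping dimension to silhouette value.
#' @return The dimension (integer) attaining the maximum score; exact ties
#'   are broken toward the smallest dimension.
#' @export
choose_dimension <- function(scores) {
  stopifnot(length(scores) > 0, !is.null(names(scores)))
  dims <- as.integer(names(scores))
  best <- max(scores)
  min(dims[scores == best])
}

#' Silhouette-guided selection of the reduced dimensionality
#'
#' For each candidate dimensionality the documents are reduced and clustered
#' with [fit_clusters()]; the candidate is scored by the mean silhouette of
#' the non-noise points computed in the ORIGINAL embedding space under the
#' reduction metric, so that scores are comparable across candidates (a
#' lower-dimensional projection always looks more compact in its own space,
#' which would bias the selection toward degenerate merged clusterings).
#' Dimensions where the silhouette is undefined (fewer than two clusters, or
#' everything noise) receive the sentinel score -1. The dimension attaining
#' the maximum score is selected; ties break toward the smallest dimension.
#' If every candidate is undefined, the selection falls back to
#' dimensionality 5 with a warning.
#'
#' @param vectors An [embedding_matrix()] of full-dimensional document
#'   vectors.
#' @param cfg A [reduction_config()]; `cfg$candidate_dims` is the sweep grid.
#' @param cluster_cfg A [clustering_config()] held fixed across the sweep.
#' @param subsample_above Silhouette is computed on a seeded subsample when
#'   the corpus exceeds this many points (default 20000).
#' @return Object of class `ddeo_result`: list with `scores` (named numeric,
#'   one entry per candidate), `chosen_dim`, `reduced` (the embedding at the
#'   chosen dimension) and `table` (data frame `dimension`, `silhouette`,
#'   `n_clusters`, `outlier_rate`).
#' @export
select_dimension <- function(vectors, cfg = reduction_config(),
                             cluster_cfg = clustering_config(),
                             subsample_above = 20000) {
  dims <- cfg$candidate_dims
  basis <- spectral_basis(vectors, max(c(dims, 5L)), cfg)
  n <- length(vectors$ids)
  scores <- stats::setNames(rep(-1, length(dims)), dims)
  nclus <- integer(length(dims))
  orate <- numeric(length(dims))
  for (i in seq_along(dims)) {
    d <- dims[i]
    em <- embedding_matrix(vectors$ids, basis[, seq_len(d), drop = FALSE])
    res <- suppressWarnings(fit_clusters(em, cluster_cfg))
    labs <- res$labels
    nclus[i] <- length(unique(labs[labs >= 0]))
    orate[i] <- mean(labs == -1)
    if (nclus[i] >= 2) {
      keep <- labs >= 0
      pts <- vectors$vectors[keep, , drop = FALSE]
      lk <- labs[keep]
      if (nrow(pts) > subsample_above) {
        sel <- with_local_seed(cfg$seed,
                               sample(nrow(pts), subsample_above))
        pts <- pts[sel, , drop = FALSE]; lk <- lk[sel]
      }
      s <- silhouette_score(pts, lk, metric = cfg$metric)
      if (!is.na(s)) scores[i] <- s
    }
  }
  if (all(scores == -1)) {
    warning("silhouette undefined at every candidate dimension; ",
            "falling back to dimensionality 5")
    chosen <- 5L
  } else {
    chosen <- choose_dimension(scores)
  }
  structure(list(
    scores = scores, chosen_dim = chosen,
    reduced = embedding_matrix(vectors$ids,
                               basis[, seq_len(chosen), drop = FALSE]),
    table = data.frame(dimension = dims, silhouette = unname(scores),
                       n_clusters = nclus, outlier_rate = orate)),
    class = "ddeo_result")
}

#' @export
print.ddeo_result <- function(x, ...) {
  cat("<ddeo_result> chosen dimension:", x$chosen_dim,
      "(silhouette", round(max(x$scores), 4), ")\n")
  invisible(x)
}
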