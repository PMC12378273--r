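#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run expr under a private RNG state so library calls never disturb the
## caller's stream. `seed` must be a single integer < 2^31.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Deterministic 31-bit hash of a string (polynomial rolling hash).
string_hash <- function(x) {
  codes <- utf8ToInt(enc2utf8(x))
  h <- 0
  m <- 2147483647  # 2^31 - 1
  for (c in codes) h <- (h * 31 + c) %% m
  h
}

## Cosine similarity between rows of a and rows of b (matrices).
cosine_similarity <- function(a, b = a) {
  a <- as.matrix(a); b <- as.matrix(b)
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  s <- tcrossprod(a, b) / outer(pmax(na, 1e-300), pmax(nb, 1e-300))
  pmin(pmax(s, -1), 1)
}

## Dense pairwise distance matrix between rows of a and rows of b.
pairwise_distances <- function(a, b = NULL, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  a <- as.matrix(a)
  if (metric == "euclidean") {
    if (is.null(b)) return(unname(as.matrix(stats::dist(a))))
    b <- as.matrix(b)
    d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
      outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
    sqrt(pmax(d2, 0))
  } else {
    1 - cosine_similarity(a, if (is.null(b)) a else b)
  }
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x == floor(x) && x > 0
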