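## Document embedding: each document vector is the arithmetic mean of its
## token vectors. Token vectors come from a pluggable backend; the default
## "hash" backend derives a deterministic unit vector from each term string,
## so the whole pipeline runs without any pretrained model. A "precomputed"
## backend accepts externally computed document vectors (e.g. from a
## sentence-transformer) for production use.

#' Construct an embedding matrix
#'
#' @param ids Character vector of document ids.
#' @param vectors Numeric matrix, one row per id; all entries finite and at
#'   least two columns.
#' @return Object of class `embedding_matrix`: list with `ids`, `vectors`
#'   (rownames set to ids) and `dim`.
#' @export
embedding_matrix <- function(ids, vectors) {
  vectors <- as.matrix(vectors)
  ids <- as.character(ids)
  if (nrow(vectors) != length(ids)) stop("one row per id required")
  if (ncol(vectors) < 2) stop("embedding dimension must be >= 2")
  if (!all(is.finite(vectors))) stop("all embedding entries must be finite")
  rownames(vectors) <- ids
  structure(list(ids = ids, vectors = vectors, dim = ncol(vectors)),
            class = "embedding_matrix")
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat("<embedding_matrix> ", length(x$ids), " documents x ", x$dim,
      " dimensions\n", sep = "")
  invisible(x)
}

#' Specify an embedding backend
#'
#' @param backend `"hash"` (deterministic hash-projection token vectors,
#'   mean-pooled; needs no model files) or `"precomputed"` (document vectors
#'   supplied in `vectors`).
#' @param dim Dimensionality for the hash backend (default 128).
#' @param seed Integer seed for the hash backend.
#' @param vectors For `backend = "precomputed"`: an [embedding_matrix()]
#'   whose ids cover the corpus.
#' @param model_name Informational label recorded in run manifests (for the
#'   precomputed backend, the name of the model that produced the vectors).
#' @return Object of class `embedder_spec`.
#' @export
embedder_spec <- function(backend = c("hash", "precomputed"), dim = 128,
                          seed = 1, vectors = NULL,
                          model_name = "paraphrase-multilingual-MiniLM-L12-v2") {
  backend <- match.arg(backend)
  if (backend == "hash") {
    if (!is_count(dim) || dim < 2) stop("hash backend requires dim >= 2")
    if (!is.numeric(seed) || length(seed) != 1) {
      stop("hash backend requires a scalar seed")
    }
  }
  if (backend == "precomputed" && !inherits(vectors, "embedding_matrix")) {
    stop("precomputed backend requires an embedding_matrix in `vectors`")
  }
  structure(list(backend = backend, dim = as.integer(dim),
                 seed = as.integer(seed), vectors = vectors,
                 model_name = model_name),
            class = "embedder_spec")
}

#' Deterministic hash-projection vector for one term
#'
#' Maps a term string to a unit-norm vector by seeding a private RNG with a
#' hash of the term combined with `seed`. Identical term and seed always
#' give the identical vector; different seeds decorrelate; distinct terms
#' are near-orthogonal in expectation at moderate `dim`.
#'
#' @param term Character scalar.
#' @param dim Output dimensionality, at least 2.
#' @param seed Integer seed shared across a corpus.
#' @return Numeric unit vector of length `dim`.
#' @export
hash_embed_token <- function(term, dim, seed) {
  if (!is_count(dim) || dim < 2) stop("dim must be >= 2")
  h <- (string_hash(term) + as.numeric(seed) * 2654435761) %% 2147483647
  v <- with_local_seed(as.integer(h), stats::rnorm(dim))
  v / sqrt(sum(v^2))
}

#' Embed cleaned documents
#'
#' Each document's vector is the arithmetic mean of its token vectors under
#' the chosen backend. Documents whose token list is empty are excluded with
#' a warning (zero vectors would break cosine similarity downstream).
#'
#' @param docs A `clean_corpus` data frame.
#' @param spec An [embedder_spec()].
#' @return An [embedding_matrix()] with one row per embedded document.
#' @export
embed_documents <- function(docs, spec = embedder_spec()) {
  stopifnot(is.data.frame(docs), inherits(spec, "embedder_spec"))
  empty <- lengths(docs$tokens) == 0
  if (any(empty)) {
    warning(sum(empty), " document(s) with no tokens excluded from embedding")
    docs <- docs[!empty, , drop = FALSE]
  }
  if (nrow(docs) == 0) stop("no documents to embed")

  if (spec$backend == "precomputed") {
    idx <- match(docs$id, spec$vectors$ids)
    if (anyNA(idx)) stop("precomputed vectors missing for some document ids")
    return(embedding_matrix(docs$id,
                            spec$vectors$vectors[idx, , drop = FALSE]))
  }

  vocab <- unique(unlist(docs$tokens, use.names = FALSE))
  tokvec <- token_vectors(vocab, spec$dim, spec$seed)
  V <- t(vapply(docs$tokens, function(tk) {
    colMeans(tokvec[tk, , drop = FALSE])
  }, numeric(spec$dim)))
  embedding_matrix(docs$id, V)
}

## Matrix of hash token vectors for a vocabulary (rownames = terms).
token_vectors <- function(vocab, dim, seed) {
  V <- t(vapply(vocab, hash_embed_token, numeric(dim),
                dim = dim, seed = seed))
  rownames(V) <- vocab
  V
}
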