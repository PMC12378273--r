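## Text cleaning for short social-media documents: URL and emoji stripping,
## lowercasing, tokenization on non-word characters, stopword removal and an
## optional suffix-s singularizer.

# URLs: any whitespace-delimited string starting "http://", "https://" or
# "www"; removed before tokenization.
.url_pattern <- "(?i)(?:\\b|^)(?:https?://|www\\.?)\\S*"

# Emoji: a fixed set of Unicode code-point ranges — emoticons, symbols &
# pictographs and their supplements (U+1F300-U+1FAFF), regional-indicator
# flags (U+1F1E6-U+1F1FF), miscellaneous symbols and dingbats
# (U+2600-U+27BF), symbols/arrows block (U+2B00-U+2BFF), the variation
# selector U+FE0F and zero-width joiner U+200D.
.emoji_pattern <- paste0(
  "(*UTF)[\\x{1F300}-\\x{1FAFF}\\x{1F1E6}-\\x{1F1FF}",
  "\\x{2600}-\\x{27BF}\\x{2B00}-\\x{2BFF}\\x{FE0F}\\x{200D}]"
)

#' Load the packaged English stopword list
#'
#' @param path Optional path to a custom stopword file (one term per line,
#'   `#` comments). Defaults to the list shipped with the package.
#' @return Character vector of stopword terms.
#' @export
load_stopwords <- function(path = NULL) {
  path <- path %||% system.file("extdata", "stopwords_en.txt",
                                package = "shorttopics")
  read_term_file(path)
}

#' Load a domain-term dictionary
#'
#' Reads a term file (one term per line, `#` comments). The packaged default
#' is an adolescent-health vocabulary used by the keyword regularizer's
#' dictionary boost.
#'
#' @param path Optional path to a dictionary file; defaults to the packaged
#'   adolescent-health vocabulary.
#' @return Character vector of dictionary terms (may include multiword
#'   entries).
#' @export
load_dictionary <- function(path = NULL) {
  path <- path %||% system.file("extdata", "adolescent_health.txt",
                                package = "shorttopics")
  read_term_file(path)
}

read_term_file <- function(path) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("term file not found: ", path)
  }
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  tolower(lines)
}

#' Clean one raw text into a token sequence
#'
#' Applies, in order: URL removal, emoji removal, lowercasing, splitting on
#' non-word characters (underscores are preserved, so handles like
#' `@user_name` become the token `user_name`), stopword removal, and an
#' optional suffix-`s` singularizer (`portraits` -> `portrait`; terms ending
#' in `ss` and terms of three or fewer characters are left alone). HTML
#' entities are not decoded: `&amp;` yields the token `amp`. The operation is
#' deterministic and idempotent on its own output.
#'
#' @param text A single character string (may be empty).
#' @param stopwords Character vector of stopwords; must be non-empty.
#' @param singularize Strip a plural `-s` suffix? Default `TRUE`.
#' @return Character vector of surviving tokens, in their original order.
#' @export
#' @examples
#' clean_text("Check the sleep!!", load_stopwords())
clean_text <- function(text, stopwords = load_stopwords(),
                       singularize = TRUE) {
  stopifnot(length(text) == 1, is.character(text))
  if (length(stopwords) == 0) stop("stopword set must be non-empty")
  if (is.na(text) || !nzchar(text)) return(character(0))
  x <- enc2utf8(text)
  x <- gsub(.url_pattern, " ", x, perl = TRUE)
  x <- gsub(.emoji_pattern, " ", x, perl = TRUE)
  x <- tolower(x)
  toks <- strsplit(x, "[^[:alnum:]_]+", perl = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  toks <- toks[!toks %in% stopwords]
  if (singularize) {
    plural <- nchar(toks) > 3 & endsWith(toks, "s") & !endsWith(toks, "ss")
    toks[plural] <- substr(toks[plural], 1, nchar(toks[plural]) - 1)
    toks <- toks[!toks %in% stopwords]
  }
  toks
}

#' Clean a corpus of raw documents
#'
#' @param corpus Data frame with columns `id` and `text` (optionally
#'   `timestamp`), as returned by [read_corpus()] or [generate_corpus()].
#' @inheritParams clean_text
#' @param drop_empty Drop documents whose token list is empty after
#'   cleaning? Default `TRUE` (with a message when any are dropped).
#' @return Data frame with columns `id`, `tokens` (list column) and
#'   `text_norm` (space-joined tokens), class `clean_corpus`.
#' @export
clean_corpus <- function(corpus, stopwords = load_stopwords(),
                         singularize = TRUE, drop_empty = TRUE) {
  stopifnot(is.data.frame(corpus), all(c("id", "text") %in% names(corpus)))
  if (anyDuplicated(corpus$id)) stop("document ids must be unique")
  tokens <- lapply(corpus$text, clean_text, stopwords = stopwords,
                   singularize = singularize)
  out <- data.frame(id = as.character(corpus$id), stringsAsFactors = FALSE)
  out$tokens <- tokens
  out$text_norm <- vapply(tokens, paste, "", collapse = " ")
  if (drop_empty) {
    empty <- lengths(out$tokens) == 0
    if (any(empty)) {
      message(sum(empty), " document(s) empty after cleaning; dropped")
      out <- out[!empty, , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  class(out) <- c("clean_corpus", "data.frame")
  out
}

#' Near-duplicate removal by hash matching and embedding cosine similarity
#'
#' Exact duplicates (identical normalized text) are removed first by hash
#' matching; remaining documents are compared by cosine similarity of their
#' embedding vectors and a later document is dropped when its similarity to
#' an already-retained one reaches `epsilon`. The earliest document (input
#' order) of each duplicate group is retained; a retained pair therefore has
#' similarity below `epsilon` or was never compared under the enabled
#' strategies. Idempotent.
#'
#' @param docs A `clean_corpus` data frame.
#' @param vectors Optional [embedding_matrix()] aligned with `docs` by id;
#'   required when `use_embedding = TRUE`.
#' @param epsilon Cosine-similarity threshold in `[0, 1]`; default 0.95.
#' @param use_hash Apply exact normalized-text matching? Default `TRUE`.
#' @param use_embedding Apply embedding cosine matching? Default `TRUE` when
#'   `vectors` is supplied.
#' @return `docs` restricted to retained rows, with attribute
#'   `"dedup_report"`: a data frame `(dropped_id, kept_id, similarity)`.
#' @export
deduplicate <- function(docs, vectors = NULL, epsilon = 0.95,
                        use_hash = TRUE, use_embedding = !is.null(vectors)) {
  stopifnot(is.data.frame(docs), epsilon >= 0, epsilon <= 1)
  report <- data.frame(dropped_id = character(0), kept_id = character(0),
                       similarity = numeric(0), stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(docs))

  if (use_hash && nrow(docs) > 1) {
    first <- match(docs$text_norm, docs$text_norm)
    dup <- which(first != seq_len(nrow(docs)))
    if (length(dup)) {
      keep[dup] <- FALSE
      report <- rbind(report, data.frame(
        dropped_id = docs$id[dup], kept_id = docs$id[first[dup]],
        similarity = 1, stringsAsFactors = FALSE))
    }
  }

  if (use_embedding) {
    if (is.null(vectors)) stop("embedding dedup requested but no vectors given")
    idx <- match(docs$id, vectors$ids)
    if (anyNA(idx)) stop("ids in docs and vectors do not align")
    V <- vectors$vectors[idx, , drop = FALSE]
    kept_rows <- integer(0)
    for (i in which(keep)) {
      if (length(kept_rows)) {
        sims <- drop(cosine_similarity(V[i, , drop = FALSE],
                                       V[kept_rows, , drop = FALSE]))
        j <- which(sims >= epsilon)
        if (length(j)) {
          keep[i] <- FALSE
          jk <- kept_rows[j[which.max(sims[j])]]
          report <- rbind(report, data.frame(
            dropped_id = docs$id[i], kept_id = docs$id[jk],
            similarity = max(sims[j]), stringsAsFactors = FALSE))
          next
        }
      }
      kept_rows <- c(kept_rows, i)
    }
  }

  out <- docs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dedup_report") <- report
  class(out) <- c("clean_corpus", "data.frame")
  out
}
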