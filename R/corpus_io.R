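## Corpus and artifact I/O. Corpora are plain data frames with columns
## id, text[, timestamp]; accepted formats are CSV and JSONL (one object
## per line with the same keys).

#' Read a corpus of raw documents
#'
#' @param path Path to a `.csv` file (columns `id,text[,timestamp]`) or a
#'   `.jsonl`/`.json` file (one JSON object per line, same keys).
#' @param format `"auto"` (by extension), `"csv"` or `"jsonl"`.
#' @return Data frame with character columns `id`, `text` and, if present,
#'   `timestamp`.
#' @export
read_corpus <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("jsonl", "json", "ndjson")) "jsonl" else "csv"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, function(l) jsonlite::fromJSON(l))
    df <- do.call(rbind, lapply(rows, function(r) {
      data.frame(id = as.character(r$id), text = as.character(r$text),
                 timestamp = as.character(r$timestamp %||% NA),
                 stringsAsFactors = FALSE)
    }))
  }
  if (!all(c("id", "text") %in% names(df))) {
    stop("corpus must have columns 'id' and 'text'")
  }
  if (anyDuplicated(df$id)) stop("document ids must be unique")
  df
}

#' Write a cleaned corpus as JSONL
#'
#' One object per line with keys `id`, `tokens`, `text_norm`.
#'
#' @param docs A `clean_corpus` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clean_jsonl <- function(docs, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(docs))) {
    writeLines(jsonlite::toJSON(list(
      id = docs$id[i], tokens = docs$tokens[[i]],
      text_norm = docs$text_norm[i]), auto_unbox = TRUE), con)
  }
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
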