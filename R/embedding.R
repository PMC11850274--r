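# Post and word embeddings. The production path is a pluggable sentence
# encoder; the package ships a deterministic hash fallback so the whole
# pipeline runs offline with no model download. Under the fallback a post is
# embedded as the renormalised mean of seeded unit-norm token hash vectors,
# so bag-of-words composition is preserved; a word is embedded by hashing
# the token itself at the word-embedding width.

#' Encoder specification
#'
#' @param kind `"hash-fallback"` (deterministic offline encoder) or
#'   `"paper-encoder"` (a pretrained sentence encoder adapter; requires the
#'   model to be available and errors otherwise).
#' @param d_e Post-embedding width (default 384, the sentence-encoder
#'   width).
#' @param d_w Word-embedding width (default 300, the width the injection
#'   layer consumes).
#' @param seed Integer seed fully determining the hash fallback.
#' @return An object of class `encoder_spec`.
#' @export
encoder_spec <- function(kind = c("hash-fallback", "paper-encoder"),
                         d_e = 384L, d_w = 300L, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(d_e >= 1, d_w >= 1)
  structure(list(kind = kind, d_e = as.integer(d_e), d_w = as.integer(d_w),
                 seed = as.integer(seed)),
            class = "encoder_spec")
}

#' @export
print.encoder_spec <- function(x, ...) {
  cat(sprintf("<encoder_spec %s: d_e=%d d_w=%d seed=%d>\n", x$kind, x$d_e,
              x$d_w, x$seed))
  invisible(x)
}

#' Deterministic hash embedding of a text
#'
#' Maps a string to a unit-norm vector that depends only on `(text, d,
#' seed)`; distinct texts collide with negligible probability. Reproducible
#' across platforms and sessions (no R RNG involved).
#'
#' @param text A single string.
#' @param d Embedding width.
#' @param seed Integer seed.
#' @return Numeric vector of length `d` with Euclidean norm 1.
#' @export
hash_embed <- function(text, d, seed = 1L) {
  stopifnot(length(text) == 1, d >= 1)
  cpp_hash_embed(as.character(text), as.integer(d), as.numeric(seed))
}

#' Embed a sequence of posts
#'
#' Returns one embedding row per post, in post order. Identical texts give
#' identical rows under either encoder kind.
#'
#' @param posts Character vector of post texts, or a data frame with a
#'   `text` column.
#' @param spec An [encoder_spec()].
#' @return Numeric matrix of `length(posts)` rows and `spec$d_e` columns.
#' @export
embed_posts <- function(posts, spec = encoder_spec()) {
  if (is.data.frame(posts)) posts <- posts$text
  if (length(posts) == 0) stopf("cannot embed an empty post list")
  if (spec$kind == "paper-encoder")
    stopf(paste("the pretrained sentence encoder is not available in this",
                "installation; use encoder_spec(kind = 'hash-fallback')"))
  cpp_embed_texts(as.character(posts), spec$d_e, as.numeric(spec$seed),
                  token_mean = TRUE)
}

#' Word embedder for a given encoder spec
#'
#' @param spec An [encoder_spec()].
#' @return A function mapping a character vector of words to a matrix with
#'   one `spec$d_w`-wide row per word.
#' @export
word_embedder <- function(spec = encoder_spec()) {
  if (spec$kind == "paper-encoder")
    stopf(paste("the pretrained sentence encoder is not available in this",
                "installation; use encoder_spec(kind = 'hash-fallback')"))
  force(spec)
  function(words) {
    cpp_embed_texts(as.character(words), spec$d_w, as.numeric(spec$seed),
                    token_mean = FALSE)
  }
}

#' Keep a user's k most recent posts
#'
#' Sorts by timestamp ascending and keeps the last `k`; returns all posts in
#' chronological order when fewer than `k` exist.
#'
#' @param posts Data frame with a `timestamp` column (Date or coercible).
#' @param k Number of most recent posts to keep (>= 1).
#' @return The trailing rows, chronologically ordered.
#' @export
truncate_last_k <- function(posts, k = 100L) {
  stopifnot(k >= 1)
  if (nrow(posts) == 0) stopf("empty post list")
  posts <- posts[order(as.Date(posts$timestamp)), , drop = FALSE]
  tail(posts, k)
}

#' Read a corpus from JSONL
#'
#' One JSON object per line with fields `user_id`, `text`, `timestamp`
#' (ISO date) and `is_original`.
#'
#' @param path JSONL path.
#' @return Tibble with those four columns (`timestamp` as Date).
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stopf("corpus file '%s' is empty", path)
  rows <- lapply(lines, jsonlite::fromJSON)
  tibble::tibble(
    user_id = vapply(rows, `[[`, "", "user_id"),
    text = vapply(rows, `[[`, "", "text"),
    timestamp = as.Date(vapply(rows, `[[`, "", "timestamp")),
    is_original = vapply(rows, `[[`, TRUE, "is_original")
  )
}

#' Write a corpus as JSONL
#' @param posts Tibble with `user_id`, `text`, `timestamp`, `is_original`.
#' @param path Output path.
#' @export
write_corpus_jsonl <- function(posts, path) {
  lines <- vapply(seq_len(nrow(posts)), function(i) {
    jsonlite::toJSON(list(user_id = posts$user_id[i], text = posts$text[i],
                          timestamp = format(as.Date(posts$timestamp[i])),
                          is_original = posts$is_original[i]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
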