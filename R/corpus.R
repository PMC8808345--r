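#' Construct an annotated post
#'
#' An annotated post bundles a post id, its normalized text, the token
#' sequence (recomputed with the canonical tokenizer), and gold entity
#' spans with offsets on the normalized text. Span invariants (offsets in
#' range, surface equal to the covered text, no overlap) are validated.
#'
#' @param id Post identifier (non-empty string).
#' @param text Normalized post text.
#' @param spans Span data frame (`start`, `end`, `label`, optionally
#'   `text`), 0-based half-open offsets on `text`.
#' @return An object of class `annotated_post`.
#' @export
annotated_post <- function(id, text, spans = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- enc2utf8(text)
  spans <- as_span_df(spans)
  n <- nchar(text, type = "chars")
  if (nrow(spans) > 0L) {
    if (any(spans$start < 0L | spans$end > n | spans$start >= spans$end)) {
      stop(sprintf("post %s: span offsets out of range", id))
    }
    covered <- substr0(text, spans$start, spans$end)
    have_text <- !is.na(spans$text)
    if (any(have_text & spans$text != covered)) {
      stop(sprintf("post %s: span text does not match covered text", id))
    }
    spans$text <- covered
    check_no_overlap(spans)
    spans <- spans[order(spans$start), , drop = FALSE]
    rownames(spans) <- NULL
  }
  structure(list(id = id, text = text, tokens = tokenize(text),
                 spans = spans),
            class = "annotated_post")
}

#' Annotate a raw post
#'
#' Convenience constructor that normalizes raw text with [normalize_post()],
#' projects raw-text spans through the offset map, and builds an
#' [annotated_post()]. Spans falling entirely inside removed text (for
#' example inside a hashtag) are dropped with a warning.
#'
#' @param id Post identifier.
#' @param text Raw post text (hashtags, emoji allowed).
#' @param spans_raw Optional span data frame with offsets on the raw text.
#' @return An `annotated_post` on the normalized text.
#' @export
annotate_post <- function(id, text, spans_raw = NULL) {
  nr <- normalize_post(text)
  pr <- project_spans(as_span_df(spans_raw), nr$map, nr$text)
  annotated_post(id, nr$text, pr$spans)
}

#' @export
print.annotated_post <- function(x, ...) {
  cat(sprintf("<annotated_post %s> %d tokens, %d spans\n  %s\n",
              x$id, nrow(x$tokens), nrow(x$spans),
              if (nchar(x$text) > 70) paste0(substr(x$text, 1, 67), "...")
              else x$text))
  invisible(x)
}

#' Construct a corpus of annotated posts
#'
#' @param posts List of `annotated_post` objects with unique ids.
#' @return An object of class `ner_corpus` (a list of posts).
#' @export
ner_corpus <- function(posts) {
  stopifnot(is.list(posts),
            all(vapply(posts, inherits, TRUE, "annotated_post")))
  ids <- vapply(posts, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate post ids in corpus")
  structure(posts, names = ids, class = "ner_corpus")
}

#' @export
`[.ner_corpus` <- function(x, i) {
  structure(unclass(x)[i], class = "ner_corpus")
}

#' @export
print.ner_corpus <- function(x, ...) {
  st <- corpus_statistics(x)
  cat(sprintf(
    "<ner_corpus> %d posts, %d tokens, %d brand / %d flavor mentions\n",
    st$posts, st$tokens, st$brand_mentions, st$flavor_mentions))
  invisible(x)
}

# gather all spans of a corpus into one data frame (with post id column)
corpus_spans <- function(corpus) {
  dfs <- lapply(corpus, function(p) {
    if (nrow(p$spans) == 0L) return(NULL)
    cbind(post_id = p$id, p$spans, stringsAsFactors = FALSE)
  })
  dfs <- dfs[!vapply(dfs, is.null, TRUE)]
  if (length(dfs) == 0L) {
    return(cbind(post_id = character(0), as_span_df(NULL)))
  }
  out <- do.call(rbind, dfs)
  rownames(out) <- NULL
  out
}

#' Read a corpus from JSONL stand-off format
#'
#' One JSON object per line: `{"id", "text", "spans": [{"start", "end",
#' "label", "text"}]}` with offsets on the normalized text. All
#' `annotated_post` invariants are validated on read.
#'
#' @param path Path to a JSONL file.
#' @return A `ner_corpus`.
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  posts <- lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln)
    spans <- obj$spans
    if (is.null(spans) || length(spans) == 0L) spans <- NULL
    annotated_post(as.character(obj$id), obj$text, spans)
  })
  ner_corpus(posts)
}

#' Write a corpus to JSONL stand-off format
#'
#' @param corpus A `ner_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (p in corpus) {
    spans <- p$spans[, c("start", "end", "label", "text"), drop = FALSE]
    line <- jsonlite::toJSON(
      list(id = p$id, text = p$text, spans = spans),
      auto_unbox = TRUE, digits = NA)
    writeLines(line, con, useBytes = TRUE)
  }
  invisible(path)
}

#' Export a corpus in CoNLL two-column format
#'
#' Writes `token<TAB>tag` lines, posts separated by blank lines, using the
#' requested tag encoding of the gold spans.
#'
#' @param corpus A `ner_corpus`.
#' @param path Output path.
#' @param scheme Tag encoding scheme.
#' @return `path`, invisibly.
#' @export
write_conll <- function(corpus, path, scheme = "IO") {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (p in corpus) {
    tags <- encode_tags(p$tokens, p$spans, scheme)
    if (nrow(p$tokens) > 0L) {
      writeLines(paste(p$tokens$surface, tags, sep = "\t"), con,
                 useBytes = TRUE)
    }
    writeLines("", con, useBytes = TRUE)
  }
  invisible(path)
}
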