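#' Construct a labeled lexicon
#'
#' A lexicon is a flat list of known surface forms (brand or flavor names)
#' carrying a single entity label and a provenance name, the input to the
#' dictionary look-up baseline.
#'
#' @param entries Character vector of surface forms; trimmed, must be
#'   non-empty with no empty strings.
#' @param label Entity label for every entry (e.g. `"BRAND"`).
#' @param name Provenance tag (e.g. `"nielsen-like"`).
#' @return An object of class `ner_lexicon`.
#' @export
lexicon <- function(entries, label, name = "lexicon") {
  stopifnot(is.character(entries), is.character(label), length(label) == 1L)
  entries <- trimws(entries)
  if (length(entries) == 0L || any(!nzchar(entries))) {
    stop("lexicon entries must be non-empty strings")
  }
  structure(list(entries = unique(entries), label = label, name = name),
            class = "ner_lexicon")
}

#' @export
print.ner_lexicon <- function(x, ...) {
  cat(sprintf("<ner_lexicon %s> %d %s entries\n", x$name,
              length(x$entries), x$label))
  invisible(x)
}

#' Read lexicons from TSV
#'
#' Format: optional `# name: <tag>` comment header, then
#' `surface<TAB>label` lines. Entries are grouped by label.
#'
#' @param path Path to a TSV file.
#' @return A named list of `ner_lexicon`, one per label present.
#' @export
read_lexicon_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  name <- "lexicon"
  hdr <- grep("^#\\s*name:", lines, value = TRUE)
  if (length(hdr) > 0L) name <- trimws(sub("^#\\s*name:", "", hdr[1L]))
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  surf <- vapply(parts, `[`, "", 1L)
  lab <- vapply(parts, `[`, "", 2L)
  if (anyNA(lab)) stop("malformed lexicon TSV: expected surface<TAB>label")
  labs <- unique(lab)
  out <- lapply(labs, function(l) lexicon(surf[lab == l], l, name))
  stats::setNames(out, labs)
}

#' Write lexicons to TSV
#'
#' @param lexicons A `ner_lexicon` or list of them.
#' @param path Output path.
#' @param name Provenance name written as a `# name:` header.
#' @return `path`, invisibly.
#' @export
write_lexicon_tsv <- function(lexicons, path, name = NULL) {
  if (inherits(lexicons, "ner_lexicon")) lexicons <- list(lexicons)
  if (is.null(name)) name <- lexicons[[1L]]$name
  lines <- c(paste0("# name: ", name),
             unlist(lapply(lexicons, function(l) {
               paste(l$entries, l$label, sep = "\t")
             })))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Compile a lexicon for token-boundary matching
#'
#' Entries are passed through the same normalization pipeline as post text
#' (lower-cased, [normalize_post()], [tokenize()]) and stored as token
#' sequences; duplicates that normalize identically collapse to one
#' pattern.
#'
#' @param lex A `ner_lexicon`.
#' @return An object of class `compiled_matcher`.
#' @examples
#' compile_lexicon(lexicon(c("Puff Bar", "JUUL", "juul"), "BRAND"))
#' @export
compile_lexicon <- function(lex) {
  stopifnot(inherits(lex, "ner_lexicon"))
  toks <- lapply(lex$entries, function(e) {
    tokenize(normalize_post(tolower(e))$text)$surface
  })
  if (any(lengths(toks) == 0L)) {
    stop("lexicon entry normalizes to nothing")
  }
  keys <- vapply(toks, paste, "", collapse = "\x1f")
  keep <- !duplicated(keys)
  toks <- toks[keep]
  keys <- keys[keep]
  index <- new.env(parent = emptyenv(), size = length(keys))
  for (k in keys) assign(k, TRUE, envir = index)
  structure(list(patterns = toks, keys = keys, index = index,
                 raw = tolower(unique(trimws(lex$entries))),
                 max_len = max(lengths(toks)), label = lex$label,
                 name = lex$name),
            class = "compiled_matcher")
}

#' @export
print.compiled_matcher <- function(x, ...) {
  cat(sprintf("<compiled_matcher %s> %d %s patterns (max %d tokens)\n",
              x$name, length(x$patterns), x$label, x$max_len))
  invisible(x)
}

#' Dictionary look-up tagging
#'
#' Flags every occurrence of a lexicon entry in the token sequence as a
#' predicted entity span — the recall-favoring baseline. In `"token"` mode
#' (default) matches are case-insensitive and anchored at token boundaries,
#' so `"pop"` does not match inside `"lollipop"`; overlapping candidates
#' are resolved longest-match-first, then leftmost, and the output spans
#' never overlap. In `"substring"` mode entries are matched anywhere in the
#' raw text (case-insensitive), with the same overlap resolution.
#'
#' @param tokens Token data frame from [tokenize()].
#' @param matcher A `compiled_matcher`.
#' @param mode `"token"` (default) or `"substring"`.
#' @param text Optional text the tokens index into (used for surfaces and
#'   required for `"substring"` mode).
#' @return Span data frame (`start`, `end`, `label`, `text`).
#' @export
gazetteer_tag <- function(tokens, matcher, mode = c("token", "substring"),
                          text = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(matcher, "compiled_matcher"))
  if (mode == "substring") {
    if (is.null(text)) stop("substring mode requires the post text")
    return(gazetteer_tag_substring(text, matcher))
  }
  n <- nrow(tokens)
  if (n == 0L) return(as_span_df(NULL))
  low <- tolower(tokens$surface)
  out_first <- integer(0); out_last <- integer(0)
  i <- 1L
  while (i <= n) {
    hit_len <- 0L
    for (len in seq(min(matcher$max_len, n - i + 1L), 1L)) {
      key <- paste(low[i:(i + len - 1L)], collapse = "\x1f")
      if (exists(key, envir = matcher$index, inherits = FALSE)) {
        hit_len <- len
        break
      }
    }
    if (hit_len > 0L) {
      out_first <- c(out_first, i)
      out_last <- c(out_last, i + hit_len - 1L)
      i <- i + hit_len
    } else {
      i <- i + 1L
    }
  }
  if (length(out_first) == 0L) return(as_span_df(NULL))
  start <- tokens$start[out_first]
  end <- tokens$end[out_last]
  surf <- if (!is.null(text)) substr0(text, start, end) else
    vapply(seq_along(out_first), function(j) {
      reconstruct_surface(tokens[out_first[j]:out_last[j], , drop = FALSE])
    }, "")
  data.frame(start = start, end = end, label = matcher$label, text = surf,
             stringsAsFactors = FALSE)
}

gazetteer_tag_substring <- function(text, matcher) {
  low <- tolower(enc2utf8(text))
  cand <- list()
  for (e in matcher$raw) {
    m <- gregexpr(e, low, fixed = TRUE)[[1]]
    if (m[1] == -1L) next
    st <- as.integer(m) - 1L
    cand[[length(cand) + 1L]] <-
      data.frame(start = st, end = st + attr(m, "match.length"))
  }
  if (length(cand) == 0L) return(as_span_df(NULL))
  cand <- do.call(rbind, cand)
  # longest match first, then leftmost
  cand <- cand[order(-(cand$end - cand$start), cand$start), , drop = FALSE]
  chosen <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    if (nrow(chosen) == 0L ||
        all(cand$end[i] <= chosen$start | cand$start[i] >= chosen$end)) {
      chosen <- rbind(chosen, cand[i, ])
    }
  }
  chosen <- chosen[order(chosen$start), , drop = FALSE]
  data.frame(start = chosen$start, end = chosen$end, label = matcher$label,
             text = substr0(text, chosen$start, chosen$end),
             stringsAsFactors = FALSE)
}

#' Gazetteer baseline as a tagger
#'
#' Wraps one or more lexicons as a tagger usable with [cross_validate()].
#' "Fitting" ignores the training folds (the dictionary is fixed);
#' prediction runs [gazetteer_tag()] for every lexicon and resolves
#' cross-lexicon overlaps longest-match-first, then leftmost.
#'
#' @param lexicons A `ner_lexicon` or list of them.
#' @param mode Matching mode passed to [gazetteer_tag()].
#' @return An object of class `gazetteer_tagger`.
#' @export
gazetteer_tagger <- function(lexicons, mode = "token") {
  if (inherits(lexicons, "ner_lexicon")) lexicons <- list(lexicons)
  matchers <- lapply(lexicons, compile_lexicon)
  structure(list(matchers = matchers, mode = mode),
            class = c("gazetteer_tagger", "ner_tagger"))
}

#' @rdname fit_tagger
#' @export
fit_tagger.gazetteer_tagger <- function(tagger, corpus, ...) tagger

#' @rdname predict_spans
#' @export
predict_spans.gazetteer_tagger <- function(object, post, ...) {
  preds <- lapply(object$matchers, function(m) {
    gazetteer_tag(post$tokens, m, mode = object$mode, text = post$text)
  })
  preds <- do.call(rbind, preds)
  if (nrow(preds) <= 1L) return(preds)
  preds <- preds[order(-(preds$end - preds$start), preds$start), ,
                 drop = FALSE]
  chosen <- preds[0, ]
  for (i in seq_len(nrow(preds))) {
    if (nrow(chosen) == 0L ||
        all(preds$end[i] <= chosen$start | preds$start[i] >= chosen$end)) {
      chosen <- rbind(chosen, preds[i, ])
    }
  }
  chosen <- chosen[order(chosen$start), , drop = FALSE]
  rownames(chosen) <- NULL
  chosen
}

#' Cross-validated benchmark of a dictionary look-up
#'
#' Evaluates [gazetteer_tag()] predictions against gold spans under the
#' same k-fold partition used for the learned taggers, reporting per-fold
#' entity-level precision/recall/F1 with mean and SD. Because the
#' dictionary needs no training, folds only define the evaluation
#' partitions.
#'
#' @param corpus A `ner_corpus` with gold spans.
#' @param lexicons A `ner_lexicon` or list of them.
#' @param k Number of folds.
#' @param seed Fold-assignment seed.
#' @param mode Matching mode (see [gazetteer_tag()]).
#' @param match_mode `"exact"` or `"partial"` span matching.
#' @return A `cv_report` (see [cross_validate()]).
#' @export
benchmark_lexicon <- function(corpus, lexicons, k = 5L, seed = 1L,
                              mode = "token", match_mode = "exact") {
  cross_validate(corpus, gazetteer_tagger(lexicons, mode = mode),
                 k = k, seed = seed, mode = match_mode)
}
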