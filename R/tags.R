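#' Tag set for an encoding scheme
#'
#' Returns the ordered tag vocabulary for a scheme and set of entity types.
#' The order is fixed (outside tag first, then types in the given order)
#' and is also the tie-breaking order used by Viterbi decoding.
#'
#' @param scheme One of `"IO"`, `"IOB"`, `"BILOU"`.
#' @param types Character vector of entity type names.
#' @return Character vector of tags, starting with `"O"`.
#' @examples
#' tag_set("IO")
#' @export
tag_set <- function(scheme = c("IO", "IOB", "BILOU"),
                    types = c("BRAND", "FLAVOR")) {
  scheme <- match.arg(scheme)
  pref <- switch(scheme, IO = "I", IOB = c("B", "I"),
                 BILOU = c("B", "I", "L", "U"))
  c("O", as.vector(t(outer(types, pref, function(ty, p) paste0(p, "-", ty)))))
}

scheme_prefixes <- function(scheme) {
  switch(scheme, IO = "I", IOB = c("B", "I"), BILOU = c("B", "I", "L", "U"),
         stop("unknown scheme: ", scheme))
}

split_tag <- function(tags) {
  pre <- ifelse(tags == "O", "O", sub("-.*$", "", tags))
  typ <- ifelse(tags == "O", NA_character_, sub("^[A-Z]+-", "", tags))
  list(prefix = pre, type = typ)
}

validate_tags <- function(tags, scheme) {
  ok <- tags == "O" |
    grepl(paste0("^(", paste(scheme_prefixes(scheme), collapse = "|"),
                 ")-\\S+$"), tags)
  if (!all(ok)) {
    stop(sprintf("invalid tag(s) for scheme %s: %s", scheme,
                 paste(unique(tags[!ok]), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Encode entity spans as a per-token tag sequence
#'
#' Converts character-offset spans into one tag per token under the chosen
#' scheme. Under IO every covered token receives `I-<TYPE>`; IOB marks the
#' first covered token `B-<TYPE>`; BILOU distinguishes unit-length spans
#' (`U-`) and span-final tokens (`L-`). Tokens outside every span get `O`.
#' Note that IO cannot represent the boundary between two adjacent
#' same-type spans: decoding merges them (documented information loss).
#'
#' @param tokens Token data frame from [tokenize()].
#' @param spans Span data frame (`start`, `end`, `label`), offsets on the
#'   same text as the tokens; spans must coincide with token boundaries.
#' @param scheme Encoding scheme, default `"IO"`.
#' @return Character vector of tags, one per token.
#' @examples
#' toks <- tokenize("I love mango vape")
#' encode_tags(toks, data.frame(start = 7, end = 12, label = "FLAVOR"))
#' @export
encode_tags <- function(tokens, spans, scheme = c("IO", "IOB", "BILOU")) {
  scheme <- match.arg(scheme)
  spans <- as_span_df(spans)
  check_no_overlap(spans)
  tags <- rep("O", nrow(tokens))
  if (nrow(spans) == 0L) return(tags)
  for (i in seq_len(nrow(spans))) {
    s <- spans$start[i]; e <- spans$end[i]
    touch <- which(tokens$end > s & tokens$start < e)
    inside <- touch[tokens$start[touch] >= s & tokens$end[touch] <= e]
    if (length(touch) == 0L || length(inside) != length(touch) ||
        tokens$start[inside[1L]] != s ||
        tokens$end[inside[length(inside)]] != e) {
      stop(sprintf(
        "span [%d,%d) %s does not align with token boundaries", s, e,
        spans$label[i]))
    }
    ty <- spans$label[i]
    k <- length(inside)
    tags[inside] <- switch(scheme,
      IO = paste0("I-", ty),
      IOB = c(paste0("B-", ty), rep(paste0("I-", ty), k - 1L)),
      BILOU = if (k == 1L) paste0("U-", ty) else
        c(paste0("B-", ty), rep(paste0("I-", ty), max(0L, k - 2L)),
          paste0("L-", ty))
    )
  }
  tags
}

#' Decode a tag sequence back into entity spans
#'
#' Inverse of [encode_tags()]. Under IO, maximal runs of the same inside
#' tag become a single span; under IOB/BILOU the boundary markers are
#' respected (a stray continuation tag starts a new span, so decoding is
#' total on any valid tag vocabulary). The round trip
#' `decode_tags(encode_tags(spans))` is the identity whenever the
#' annotation has no adjacent same-type entities (always true for IOB and
#' BILOU).
#'
#' @param tokens Token data frame from [tokenize()].
#' @param tags Character vector of tags, one per token.
#' @param scheme Encoding scheme used by `tags`.
#' @param text Optional text the tokens index into; used to recover exact
#'   span surfaces. When absent, surfaces are reconstructed from token
#'   surfaces and single-space gaps.
#' @return Span data frame (`start`, `end`, `label`, `text`).
#' @export
decode_tags <- function(tokens, tags, scheme = c("IO", "IOB", "BILOU"),
                        text = NULL) {
  scheme <- match.arg(scheme)
  if (length(tags) != nrow(tokens)) {
    stop("tag sequence length does not match token count")
  }
  validate_tags(tags, scheme)
  if (length(tags) == 0L) return(as_span_df(NULL))
  decode_runs(tokens, tags, scheme, text)
}

# Core run-collection used by decode_tags (kept separate for clarity).
decode_runs <- function(tokens, tags, scheme, text = NULL) {
  n <- length(tags)
  parts <- split_tag(tags)
  out_start <- integer(0); out_end <- integer(0); out_type <- character(0)
  open <- FALSE; run_first <- NA_integer_; run_type <- NA_character_
  emit <- function(first, last, type) {
    out_start <<- c(out_start, first); out_end <<- c(out_end, last)
    out_type <<- c(out_type, type)
  }
  for (i in seq_len(n)) {
    p <- parts$prefix[i]; ty <- parts$type[i]
    if (p == "O") {
      if (open) { emit(run_first, i - 1L, run_type); open <- FALSE }
      next
    }
    new_run <- switch(scheme,
      IO = !open || !identical(ty, run_type),
      IOB = p == "B" || !open || !identical(ty, run_type),
      BILOU = p %in% c("B", "U") || !open || !identical(ty, run_type)
    )
    if (new_run) {
      if (open) emit(run_first, i - 1L, run_type)
      run_first <- i; run_type <- ty; open <- TRUE
    }
    if (scheme == "BILOU" && p %in% c("L", "U")) {
      emit(run_first, i, run_type); open <- FALSE
    }
  }
  if (open) emit(run_first, n, run_type)
  if (length(out_start) == 0L) return(as_span_df(NULL))
  start <- tokens$start[out_start]
  end <- tokens$end[out_end]
  surf <- if (!is.null(text)) {
    substr0(text, start, end)
  } else {
    vapply(seq_along(out_start), function(j) {
      idx <- out_start[j]:out_end[j]
      reconstruct_surface(tokens[idx, , drop = FALSE])
    }, "")
  }
  data.frame(start = start, end = end, label = out_type, text = surf,
             stringsAsFactors = FALSE)
}

# join token surfaces, restoring gap widths from the offsets
reconstruct_surface <- function(tokens) {
  if (nrow(tokens) == 0L) return("")
  parts <- tokens$surface[1L]
  if (nrow(tokens) > 1L) {
    for (i in 2L:nrow(tokens)) {
      gap <- tokens$start[i] - tokens$end[i - 1L]
      parts <- paste0(parts, strrep(" ", gap), tokens$surface[i])
    }
  }
  parts
}
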