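#' @title Social-text normalization with offset tracking
#' @name normalize_post
NULL

# Load the pinned CLDR emoji short-name table as a named character vector
# keyed by the emoji character itself. Cached per session.
emoji_table <- function() {
  if (!is.null(.endsner_env$emoji)) return(.endsner_env$emoji)
  path <- system.file("extdata", "emoji_cldr.tsv", package = "endsner")
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  cp <- vapply(parts, `[`, "", 1L)
  nm <- vapply(parts, `[`, "", 2L)
  out <- stats::setNames(nm, vapply(strtoi(cp, 16L), intToUtf8, ""))
  .endsner_env$emoji <- out
  out
}

# Codepoints treated as emoji/pictographic plumbing even when not in the
# short-name table: such characters are removed during normalization.
is_emoji_codepoint <- function(cp) {
  (cp >= 0x1F000 & cp <= 0x1FAFF) |
    (cp >= 0x2600 & cp <= 0x27BF) |
    (cp >= 0x2B00 & cp <= 0x2BFF) |
    cp == 0xFE0F | cp == 0x200D | cp == 0x20E3
}

offset_map <- function(map, status) {
  structure(list(map = as.integer(map), status = status), class = "offset_map")
}

#' @export
print.offset_map <- function(x, ...) {
  cat("<offset_map> raw length", length(x$status),
      "-> normalized length", x$map[length(x$map)], "\n")
  invisible(x)
}

#' Normalize raw post text
#'
#' Applies the social-text cleaning used throughout the pipeline: whole
#' hashtag tokens (`#word`) are removed, emoji with a known CLDR short name
#' are replaced by that short name as plain words, other emoji/pictographic
#' codepoints (variation selectors, zero-width joiners, skin-tone modifiers,
#' unknown pictographs) are removed, and whitespace is collapsed to single
#' spaces with no leading/trailing space. An offset map relating raw to
#' normalized character positions is returned so that stand-off annotations
#' made on the raw text can be carried over with [project_spans()].
#'
#' All character offsets in this package are 0-based and half-open.
#' Normalization is idempotent: running it on already-normalized text
#' returns the text unchanged with an identity map.
#'
#' @param text A single character string (may be empty).
#' @return A list with elements `text` (the normalized string) and `map`
#'   (an `offset_map`: integer vector of length `nchar(text) + 1` giving,
#'   for every raw offset, the corresponding normalized offset; deleted
#'   regions map to the position of the gap they leave).
#' @examples
#' normalize_post("new juice drop #vape #ecigs")$text
#' normalize_post("so good \U0001F525")$text
#' @export
normalize_post <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- enc2utf8(text)
  n <- nchar(text, type = "chars")
  if (n == 0L) {
    return(list(text = "", map = offset_map(0L, character(0))))
  }
  chars <- strsplit(text, "")[[1]]
  cp <- utf8ToInt(text)

  status <- rep("kept", n)
  pieces <- chars
  ws <- grepl("^\\s$", chars, perl = TRUE)
  status[ws] <- "space"
  pieces[ws] <- " "

  # maximal #-initiated word tokens, removed whole
  m <- gregexpr("#[\\p{L}\\p{N}_]+", text, perl = TRUE)[[1]]
  if (m[1] != -1L) {
    for (j in seq_along(m)) {
      idx <- m[j]:(m[j] + attr(m, "match.length")[j] - 1L)
      status[idx] <- "deleted"
      pieces[idx] <- ""
    }
  }

  # emoji replacement / removal
  emo <- emoji_table()
  hit <- status == "kept" & chars %in% names(emo)
  if (any(hit)) {
    pieces[hit] <- paste0(" ", emo[chars[hit]], " ")
    status[hit] <- "replaced"
  }
  strip <- status == "kept" & is_emoji_codepoint(cp)
  if (any(strip)) {
    status[strip] <- "deleted"
    pieces[strip] <- ""
  }

  inter <- paste0(pieces, collapse = "")
  ic <- strsplit(inter, "")[[1]]
  ni <- length(ic)
  if (ni == 0L) {
    return(list(text = "", map = offset_map(rep(0L, n + 1L), status)))
  }
  isp <- ic == " "
  prev_nonsp <- c(FALSE, !isp[-ni])
  nonsp_after <- rev(cumsum(rev(!isp))) > 0  # non-space at or after position
  keep <- !isp | (prev_nonsp & nonsp_after)

  out <- paste0(ic[keep], collapse = "")
  cum0 <- c(0L, cumsum(keep))
  piece_n <- nchar(pieces, type = "chars")
  inter_start <- c(0L, cumsum(piece_n))        # 0-based start of each piece
  map <- cum0[inter_start + 1L]                 # length n + 1
  list(text = out, map = offset_map(map, status))
}

#' Tokenize normalized text
#'
#' Splits text into tokens delimited by whitespace and punctuation: maximal
#' runs of non-space, non-punctuation characters form word tokens, and every
#' punctuation or symbol character (Unicode categories P and S) is its own
#' single-character token. Offsets are 0-based, half-open, into the input
#' text; concatenating token surfaces with the original gaps reconstructs
#' the text exactly.
#'
#' @param text A single character string, assumed already normalized.
#' @return A data frame with columns `surface`, `start`, `end`, `index`
#'   (0-based token position); zero rows for empty input.
#' @examples
#' tokenize("Puff Bar, yes")
#' tokenize("e-liquid")$surface
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- enc2utf8(text)
  empty <- data.frame(surface = character(0), start = integer(0),
                      end = integer(0), index = integer(0),
                      stringsAsFactors = FALSE)
  if (!nzchar(text)) return(empty)
  m <- gregexpr("[^\\s\\p{P}\\p{S}]+|[\\p{P}\\p{S}]", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  surf <- regmatches(text, list(m))[[1]]
  data.frame(surface = surf, start = starts, end = starts + lens,
             index = seq_along(surf) - 1L, stringsAsFactors = FALSE)
}

# substring by 0-based half-open character offsets (vectorized)
substr0 <- function(text, start, end) substring(text, start + 1L, end)

#' Project entity spans through an offset map
#'
#' Remaps stand-off spans annotated on raw text onto the normalized text
#' produced by [normalize_post()]. A span lying entirely inside deleted
#' material (for example inside a removed hashtag) is dropped with a
#' warning; a span that is only partially deleted raises an error because
#' its boundaries can no longer be trusted.
#'
#' @param spans Data frame with columns `start`, `end`, `label` and
#'   optionally `text`, offsets on the raw text (0-based, half-open).
#' @param map An `offset_map` from [normalize_post()].
#' @param normalized_text Optional normalized text; when given, the `text`
#'   column of the result is refreshed from it.
#' @return A list with `spans` (projected data frame) and `dropped`
#'   (number of spans removed because they fell inside deleted regions).
#' @export
project_spans <- function(spans, map, normalized_text = NULL) {
  stopifnot(inherits(map, "offset_map"))
  spans <- as_span_df(spans)
  if (nrow(spans) == 0L) return(list(spans = spans, dropped = 0L))
  n_raw <- length(map$status)
  if (any(spans$start < 0L) || any(spans$end > n_raw) ||
      any(spans$start >= spans$end)) {
    stop("span offsets out of range for the raw text")
  }
  keep <- rep(TRUE, nrow(spans))
  out_start <- integer(nrow(spans))
  out_end <- integer(nrow(spans))
  dropped <- 0L
  for (i in seq_len(nrow(spans))) {
    st <- map$status[(spans$start[i] + 1L):spans$end[i]]
    alive <- st %in% c("kept", "replaced")
    dead <- st == "deleted"
    if (!any(alive)) {
      keep[i] <- FALSE
      dropped <- dropped + 1L
      next
    }
    if (any(dead)) {
      stop(sprintf("span [%d,%d) '%s' is partially deleted by normalization",
                   spans$start[i], spans$end[i],
                   if ("text" %in% names(spans)) spans$text[i] else ""))
    }
    out_start[i] <- map$map[spans$start[i] + 1L]
    out_end[i] <- map$map[spans$end[i] + 1L]
  }
  if (dropped > 0L) {
    warning(sprintf("%d span(s) dropped: fully inside removed text", dropped),
            call. = FALSE)
  }
  res <- spans[keep, , drop = FALSE]
  res$start <- out_start[keep]
  res$end <- out_end[keep]
  if (!is.null(normalized_text) && nrow(res) > 0L) {
    res$text <- substr0(normalized_text, res$start, res$end)
  }
  rownames(res) <- NULL
  list(spans = res, dropped = dropped)
}

# coerce user input to a canonical span data frame
as_span_df <- function(spans) {
  if (is.null(spans) || (is.data.frame(spans) && nrow(spans) == 0L) ||
      (is.list(spans) && length(spans) == 0L && !is.data.frame(spans))) {
    return(data.frame(start = integer(0), end = integer(0),
                      label = character(0), text = character(0),
                      stringsAsFactors = FALSE))
  }
  spans <- as.data.frame(spans, stringsAsFactors = FALSE)
  stopifnot(all(c("start", "end", "label") %in% names(spans)))
  spans$start <- as.integer(spans$start)
  spans$end <- as.integer(spans$end)
  spans$label <- as.character(spans$label)
  if (!"text" %in% names(spans)) spans$text <- NA_character_
  spans[, c("start", "end", "label", "text")]
}

# error if any two spans in one annotation set overlap
check_no_overlap <- function(spans, what = "spans") {
  if (nrow(spans) < 2L) return(invisible(TRUE))
  o <- order(spans$start, spans$end)
  s <- spans[o, ]
  if (any(s$end[-nrow(s)] > s$start[-1L])) {
    stop(sprintf("overlapping %s within one annotation set", what))
  }
  invisible(TRUE)
}
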