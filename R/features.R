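#' CRF feature templates
#'
#' The tagger uses a fixed set of binary orthographic indicator features
#' per token: the lower-cased surface, case-shape tests (lower / upper /
#' title cased), a digit test, a lower-cased prefix and suffix of
#' configurable length, the case-shape tests of the previous and next
#' token, and `BOS`/`EOS` pseudo-features at the sequence edges.
#'
#' @name features
NULL

# vectorized case-shape flags for a vector of token surfaces
token_shape <- function(s) {
  has_letter <- grepl("\\p{L}", s, perl = TRUE)
  low <- tolower(s)
  up <- toupper(s)
  list(
    lower = has_letter & s == low & s != up,
    upper = has_letter & s == up & s != low,
    title = grepl("^\\p{Lu}\\p{Ll}*$", s, perl = TRUE),
    digit = grepl("^\\p{Nd}+$", s, perl = TRUE),
    lowered = low
  )
}

#' Extract the feature vector for one token position
#'
#' @param tokens Token surfaces (character vector) or a token data frame.
#' @param position 1-based position in the sequence.
#' @param config A [crf_config()] (controls prefix/suffix length).
#' @return Character vector of active feature names.
#' @examples
#' extract_features(c("JUUL"), 1)
#' @export
extract_features <- function(tokens, position, config = crf_config()) {
  extract_feature_seq(tokens, config)[[position]]
}

# feature vectors for every position of one sequence
extract_feature_seq <- function(tokens, config = crf_config()) {
  if (is.data.frame(tokens)) tokens <- tokens$surface
  n <- length(tokens)
  if (n == 0L) return(list())
  sh <- token_shape(tokens)
  pl <- config$prefix_length
  sl <- config$suffix_length
  nc <- nchar(sh$lowered, type = "chars")
  pref <- paste0("prefix", pl, "=", substr(sh$lowered, 1L, pl))
  suff <- paste0("suffix", sl, "=",
                 substr(sh$lowered, pmax(1L, nc - sl + 1L), nc))
  curlow <- paste0("cur.lower=", sh$lowered)
  lapply(seq_len(n), function(i) {
    f <- c(curlow[i],
           if (sh$lower[i]) "cur.islower",
           if (sh$upper[i]) "cur.isupper",
           if (sh$title[i]) "cur.istitle",
           if (sh$digit[i]) "cur.isdigit",
           pref[i], suff[i])
    if (i == 1L) {
      f <- c(f, "BOS")
    } else {
      f <- c(f,
             if (sh$lower[i - 1L]) "prev.islower",
             if (sh$upper[i - 1L]) "prev.isupper",
             if (sh$title[i - 1L]) "prev.istitle")
    }
    if (i == n) {
      f <- c(f, "EOS")
    } else {
      f <- c(f,
             if (sh$lower[i + 1L]) "next.islower",
             if (sh$upper[i + 1L]) "next.isupper",
             if (sh$title[i + 1L]) "next.istitle")
    }
    f
  })
}
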