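#' Default synthetic brand vocabulary
#'
#' Deterministic list of invented vaping-brand surface forms, mixing fused
#' CamelCase names ("VaporKing") and spaced two-word names ("Cloud Labs"),
#' the two shapes dictionary look-up confuses most easily once posts vary
#' the spacing.
#'
#' @param n Number of brands (up to 100).
#' @return Character vector of canonical brand surfaces.
#' @export
default_brand_vocab <- function(n = 50L) {
  pre <- c("Vapor", "Cloud", "Drip", "Mist", "Nova", "Zen", "Aero",
           "Volt", "Ember", "Frost")
  suf <- c("King", "Labs", "Bar", "Craft", "Works", "Supply", "Society",
           "Mods", "City", "Co")
  combos <- as.vector(t(outer(pre, suf, paste)))
  stopifnot(n >= 1L, n <= length(combos))
  out <- combos[seq_len(n)]
  fuse <- seq_along(out) %% 2L == 1L
  out[fuse] <- gsub(" ", "", out[fuse], fixed = TRUE)
  out
}

#' Default synthetic flavor vocabulary
#'
#' @param n Number of flavors (up to 30).
#' @return Character vector of flavor surfaces (lower case, one or two
#'   words).
#' @export
default_flavor_vocab <- function(n = 30L) {
  fl <- c("mango", "blue razz", "strawberry", "watermelon", "mint",
          "menthol", "grape", "peach ice", "banana", "vanilla custard",
          "caramel", "cool mint", "lemon tart", "apple", "cherry cola",
          "pink lemonade", "blueberry", "raspberry", "tropical punch",
          "honeydew", "cucumber", "coffee", "tobacco", "butterscotch",
          "dragon fruit", "guava", "lychee", "melon ice", "mixed berries",
          "sour apple")
  stopifnot(n >= 1L, n <= length(fl))
  fl[seq_len(n)]
}

# generic words that double as (polluting) brand-lexicon entries
homograph_words <- function() {
  c("carbon", "square", "epic", "zoom", "pop", "pulse", "edge", "crisp")
}

filler_words <- function() {
  c("just", "got", "my", "new", "setup", "today", "loving", "this",
    "juice", "all", "day", "clouds", "for", "days", "check", "out",
    "the", "shop", "link", "in", "bio", "who", "else", "is", "vaping",
    "best", "ever", "so", "smooth", "hits", "different", "restock",
    "now", "available", "online", "store", "come", "through", "grab",
    "yours", "while", "supplies", "last", "big", "thanks", "to", "crew",
    "happy", "friday", "weekend", "vibes", "tank", "coil", "mod",
    "battery", "charged", "ready", "go")
}

hashtag_words <- function() {
  c("vape", "vapelife", "vapecommunity", "ecig", "ecigs", "vapenation",
    "vapedaily", "cloudchaser", "vapefam", "eliquid", "vapeshop")
}

generator_emoji <- function() {
  c("\U0001F525", "\U0001F4A8", "\U0001F60D", "\U0001F4AF",
    "\U0001F343", "\U0001F680", "\u2728")
}

#' Synthetic-corpus generator configuration
#'
#' Controls the shape of generated Instagram-like posts. Defaults emulate
#' the summary shape of a manually annotated vaping corpus: about 35
#' tokens per post, roughly 0.54 brand and 0.22 flavor mentions per post,
#' hashtags and emoji as non-entity noise, and occasional generic
#' homograph words that collide with brand-lexicon entries. Per-mention
#' surface realization draws a variant: canonical form, casing change,
#' spacing change (fuse/split/hyphenate), or a product-line suffix
#' ("XL", "Plus", ...), reproducing the casing/spacing noise that makes
#' learned taggers outperform dictionary look-up on social text.
#'
#' @param n_posts Number of posts to generate.
#' @param brand_vocab,flavor_vocab Canonical entity surface forms.
#' @param p_brand_mention,p_flavor_mention Expected mentions per post; the
#'   integer part is deterministic and the fractional part Bernoulli, so
#'   a rate of 1 forces exactly one mention.
#' @param tokens_per_post Target mean token count of the normalized text.
#' @param p_hashtag,p_emoji Per-post probability of a trailing hashtag
#'   block / of emoji insertions.
#' @param homograph_rate Per-post probability that a generic homograph
#'   word appears as plain (non-entity) text.
#' @param variant_probs Probabilities of the four per-mention surface
#'   variants, in order canonical/case/spacing/suffix; must sum to 1.
#' @param truncated_fraction Fraction of brands (by planted frequency)
#'   kept in the truncated companion lexicon.
#' @param seed Generator seed; the corpus is a pure function of the
#'   config.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_posts = 1000L,
                             brand_vocab = default_brand_vocab(50L),
                             flavor_vocab = default_flavor_vocab(30L),
                             p_brand_mention = 0.54,
                             p_flavor_mention = 0.22,
                             tokens_per_post = 35,
                             p_hashtag = 0.6,
                             p_emoji = 0.3,
                             homograph_rate = 0.1,
                             variant_probs = c(canonical = 0.5, case = 0.2,
                                               spacing = 0.2, suffix = 0.1),
                             truncated_fraction = 0.3,
                             seed = 1L) {
  stopifnot(n_posts >= 1L, length(brand_vocab) > 0L,
            length(flavor_vocab) > 0L,
            p_brand_mention >= 0, p_flavor_mention >= 0,
            p_hashtag >= 0, p_hashtag <= 1, p_emoji >= 0, p_emoji <= 1,
            homograph_rate >= 0, homograph_rate <= 1,
            length(variant_probs) == 4L,
            abs(sum(variant_probs) - 1) < 1e-8,
            truncated_fraction > 0, truncated_fraction <= 1)
  structure(list(n_posts = as.integer(n_posts),
                 brand_vocab = brand_vocab, flavor_vocab = flavor_vocab,
                 p_brand_mention = p_brand_mention,
                 p_flavor_mention = p_flavor_mention,
                 tokens_per_post = tokens_per_post,
                 p_hashtag = p_hashtag, p_emoji = p_emoji,
                 homograph_rate = homograph_rate,
                 variant_probs = variant_probs,
                 truncated_fraction = truncated_fraction,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# integer part deterministic, fractional part Bernoulli
int_rate <- function(p) {
  base <- floor(p)
  extra <- if (p - base > 0) rbinom(1L, 1L, p - base) else 0L
  as.integer(base + extra)
}

# realize one brand mention: returns surface string (space-separated raw
# tokens) for a sampled variant of the canonical form
realize_brand <- function(canonical, variant_probs) {
  v <- sample(c("canonical", "case", "spacing", "suffix"), 1L,
              prob = variant_probs)
  surf <- canonical
  if (v == "case") {
    surf <- if (runif(1) < 0.5) tolower(canonical) else toupper(canonical)
  } else if (v == "spacing") {
    if (grepl(" ", canonical, fixed = TRUE)) {
      surf <- if (runif(1) < 0.5) gsub(" ", "", canonical, fixed = TRUE)
              else gsub(" ", "-", canonical, fixed = TRUE)
    } else {
      split <- gsub("([\\p{Ll}])([\\p{Lu}])", "\\1 \\2", canonical,
                    perl = TRUE)
      surf <- if (runif(1) < 0.5) split
              else gsub(" ", "-", split, fixed = TRUE)
    }
  } else if (v == "suffix") {
    surf <- paste(canonical, sample(c("XL", "Plus", "Max", "Mini", "2"), 1L))
  }
  surf
}

realize_flavor <- function(canonical) {
  if (runif(1) < 0.2) {
    gsub("\\b(\\p{Ll})", "\\U\\1", canonical, perl = TRUE)
  } else {
    canonical
  }
}

#' Generate one synthetic annotated post
#'
#' Builds a raw Instagram-like post (filler words, entity mentions,
#' optional homograph distractors, emoji, trailing hashtags), then runs it
#' through [normalize_post()] and projects the gold spans onto the
#' normalized text, so every generated span is token-aligned by
#' construction. Consumes the current RNG state; deterministic given that
#' state.
#'
#' @param config A [generator_config()].
#' @param id Post identifier.
#' @return An `annotated_post`. The canonical surface of each planted
#'   brand is recorded in attribute `"brand_used"`.
#' @export
generate_post <- function(config, id = "post-1") {
  nb <- int_rate(config$p_brand_mention)
  nf <- int_rate(config$p_flavor_mention)
  brands_used <- character(0)

  mention_units <- list()
  if (nb > 0L) {
    nv <- length(config$brand_vocab)
    probs <- (1 / seq_len(nv))
    for (i in seq_len(nb)) {
      ci <- sample.int(nv, 1L, prob = probs)
      canonical <- config$brand_vocab[ci]
      brands_used <- c(brands_used, canonical)
      mention_units[[length(mention_units) + 1L]] <-
        list(tokens = strsplit(realize_brand(canonical,
                                             config$variant_probs),
                               " ", fixed = TRUE)[[1]],
             label = "BRAND")
    }
  }
  if (nf > 0L) {
    for (i in seq_len(nf)) {
      canonical <- sample(config$flavor_vocab, 1L)
      mention_units[[length(mention_units) + 1L]] <-
        list(tokens = strsplit(realize_flavor(canonical), " ",
                               fixed = TRUE)[[1]],
             label = "FLAVOR")
    }
  }

  ent_tokens <- sum(vapply(mention_units, function(u) length(u$tokens), 1L))
  target <- max(8L, round(rnorm(1L, config$tokens_per_post, 6)))
  n_fill <- max(length(mention_units) + 1L, target - ent_tokens)
  fills <- sample(filler_words(), n_fill, replace = TRUE)
  units <- lapply(fills, function(w) list(tokens = w, label = NA_character_))

  if (runif(1) < config$homograph_rate) {
    hslot <- sample.int(length(units) + 1L, 1L) - 1L
    units <- append(units, list(list(tokens = sample(homograph_words(), 1L),
                                     label = NA_character_)), after = hslot)
  }

  if (length(mention_units) > 0L) {
    # distinct insertion slots keep same-type mentions non-adjacent
    slots <- sort(sample.int(length(units) + 1L,
                             length(mention_units)) - 1L)
    for (i in rev(seq_along(mention_units))) {
      units <- append(units, mention_units[i], after = slots[i])
    }
  }

  if (runif(1) < config$p_emoji) {
    for (i in seq_len(1L + rbinom(1L, 1L, 0.5))) {
      eslot <- sample.int(length(units) + 1L, 1L) - 1L
      units <- append(units, list(list(tokens = sample(generator_emoji(), 1L),
                                       label = NA_character_)),
                      after = eslot)
    }
  }
  if (runif(1) < config$p_hashtag) {
    n_tags <- min(1L + rpois(1L, 1.5), length(hashtag_words()))
    tags <- paste0("#", sample(hashtag_words(), n_tags))
    for (tg in tags) {
      units <- append(units, list(list(tokens = tg, label = NA_character_)))
    }
  }

  # assemble raw text and raw-offset gold spans
  pieces <- character(0)
  spans <- list()
  pos <- 0L
  for (u in units) {
    surf <- paste(u$tokens, collapse = " ")
    if (length(pieces) > 0L) pos <- pos + 1L  # joining space
    if (!is.na(u$label)) {
      spans[[length(spans) + 1L]] <-
        data.frame(start = pos, end = pos + nchar(surf, type = "chars"),
                   label = u$label, text = surf, stringsAsFactors = FALSE)
    }
    pieces <- c(pieces, surf)
    pos <- pos + nchar(surf, type = "chars")
  }
  raw <- paste(pieces, collapse = " ")
  spans <- if (length(spans) > 0L) do.call(rbind, spans) else NULL
  post <- annotate_post(id, raw, spans)
  attr(post, "brand_used") <- brands_used
  post
}

#' Generate a synthetic corpus with companion lexicons
#'
#' Generates `n_posts` annotated posts (seeded by the config; the output
#' is a pure function of the config) together with three brand lexicons
#' mirroring the complete-vs-partial dictionary contrast used for
#' benchmarking: `brand_full` (every canonical brand surface in the
#' vocabulary), `brand_truncated` (the top `truncated_fraction` of brands
#' by planted mention frequency — a "top-sellers" style list), and
#' `brand_polluted` (`brand_full` plus generic homograph words, which adds
#' false positives but can never remove a gold surface, so its recall
#' equals the full lexicon's). A `flavor_full` lexicon is included as
#' well.
#'
#' @param config A [generator_config()].
#' @return List with `corpus` (a `ner_corpus`), `lexicons` (named list of
#'   `ner_lexicon`), and `brand_counts` (planted canonical-brand
#'   frequencies).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    posts <- vector("list", config$n_posts)
    usage <- integer(length(config$brand_vocab))
    names(usage) <- config$brand_vocab
    for (i in seq_len(config$n_posts)) {
      p <- generate_post(config, id = sprintf("post-%05d", i))
      used <- attr(p, "brand_used")
      for (b in used) usage[b] <- usage[b] + 1L
      attr(p, "brand_used") <- NULL
      posts[[i]] <- p
    }
    corpus <- ner_corpus(posts)
    n_keep <- max(1L, ceiling(config$truncated_fraction *
                              length(config$brand_vocab)))
    ord <- order(-usage, tolower(names(usage)))
    trunc_entries <- names(usage)[ord][seq_len(n_keep)]
    lexicons <- list(
      brand_full = lexicon(config$brand_vocab, "BRAND", "full"),
      brand_truncated = lexicon(trunc_entries, "BRAND", "nielsen-like"),
      brand_polluted = lexicon(c(config$brand_vocab, homograph_words()),
                               "BRAND", "polluted"),
      flavor_full = lexicon(config$flavor_vocab, "FLAVOR", "flavor-full")
    )
    list(corpus = corpus, lexicons = lexicons, brand_counts = usage)
  })
}

#' Summary statistics of an annotated corpus
#'
#' Post, token, unique-token (case-sensitive surfaces) and per-label
#' mention counts — the schema used to summarize an annotated data set.
#'
#' @param corpus A `ner_corpus`.
#' @return Named list with `posts`, `tokens`, `unique_tokens`,
#'   `brand_mentions`, `flavor_mentions`.
#' @export
corpus_statistics <- function(corpus) {
  stopifnot(inherits(corpus, "ner_corpus"))
  surfaces <- unlist(lapply(corpus, function(p) p$tokens$surface),
                     use.names = FALSE)
  spans <- corpus_spans(corpus)
  list(posts = length(corpus),
       tokens = length(surfaces),
       unique_tokens = length(unique(surfaces)),
       brand_mentions = sum(spans$label == "BRAND"),
       flavor_mentions = sum(spans$label == "FLAVOR"))
}
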