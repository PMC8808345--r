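# Brute-force enumeration oracles for linear-chain inference, independent
# of the package's forward-backward/Viterbi implementation.

enum_tag_grid <- function(T_, L) {
  as.matrix(expand.grid(rep(list(seq_len(L)), T_)))
}

enum_seq_scores <- function(emission, transition) {
  T_ <- nrow(emission)
  grid <- enum_tag_grid(T_, ncol(emission))
  scores <- apply(grid, 1L, function(y) {
    s <- sum(emission[cbind(seq_len(T_), y)])
    if (T_ > 1L) s <- s + sum(transition[cbind(y[-T_], y[-1L])])
    s
  })
  list(grid = grid, scores = scores)
}

enum_logZ <- function(emission, transition) {
  sc <- enum_seq_scores(emission, transition)$scores
  m <- max(sc)
  m + log(sum(exp(sc - m)))
}

enum_node_marginals <- function(emission, transition) {
  e <- enum_seq_scores(emission, transition)
  p <- exp(e$scores - enum_logZ(emission, transition))
  T_ <- nrow(emission); L <- ncol(emission)
  node <- matrix(0, T_, L)
  for (t in seq_len(T_)) {
    for (y in seq_len(L)) node[t, y] <- sum(p[e$grid[, t] == y])
  }
  node
}

enum_max_score <- function(emission, transition) {
  max(enum_seq_scores(emission, transition)$scores)
}

random_chain <- function(T_, L, scale = 1) {
  list(emission = matrix(stats::rnorm(T_ * L, sd = scale), T_, L),
       transition = matrix(stats::rnorm(L * L, sd = scale), L, L))
}

# score of a specific 1-based tag path under the chain
path_score <- function(path, emission, transition) {
  s <- sum(emission[cbind(seq_along(path), path)])
  if (length(path) > 1L) {
    s <- s + sum(transition[cbind(path[-length(path)], path[-1L])])
  }
  s
}

# build an annotated post from word vectors: spans given as
# list(c(first_word, last_word, label)) in 1-based word indices
post_from_words <- function(id, words, spans = list()) {
  text <- paste(words, collapse = " ")
  ends <- cumsum(nchar(words, type = "chars") + 1L) - 1L
  starts <- c(0L, utils::head(ends, -1L) + 1L)
  sp <- NULL
  if (length(spans) > 0L) {
    sp <- do.call(rbind, lapply(spans, function(s) {
      data.frame(start = starts[as.integer(s[1L])],
                 end = ends[as.integer(s[2L])],
                 label = s[3L], stringsAsFactors = FALSE)
    }))
  }
  annotated_post(id, text, sp)
}

# tiny separable training corpus: brand tokens are title-cased vocabulary
# words in an otherwise lower-case context
toy_brand_corpus <- function(n = 50L, seed = 42L) {
  brands <- c("Zephyr", "Quartz", "Onyx", "Argon", "Krypton")
  ctx_a <- c("i", "like", "my")
  ctx_b <- c("pod", "a", "lot")
  posts <- lapply(seq_len(n), function(i) {
    b <- brands[(i %% length(brands)) + 1L]
    words <- c(ctx_a, b, ctx_b)
    post_from_words(sprintf("toy-%03d", i), words,
                    list(c(4, 4, "BRAND")))
  })
  ner_corpus(posts)
}

# access to internal constructors used when building hand-set models
new_params_for_test <- function(W, Tr, tags, cfg) {
  endsner:::new_crf_params(W, Tr, tags, cfg)
}

crf_viterbi_for_test <- function(emission, transition) {
  endsner:::crf_viterbi_cpp(emission, transition)
}

# node marginals stripped of names and the pairwise attribute
node_only <- function(m) {
  attr(m, "pairwise") <- NULL
  unname(m)
}
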