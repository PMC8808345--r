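#' CRF training configuration
#'
#' Hyperparameters of the linear-chain CRF tagger. The model is trained by
#' penalized maximum likelihood with an elastic-net penalty
#' `l1 * sum(|w|) + l2 * sum(w^2)` added to the negative log-likelihood,
#' optimized by limited-memory quasi-Newton iterations (orthant-wise when
#' `l1 > 0`; see [owlqn]).
#'
#' @param l1,l2 Non-negative elastic-net penalty weights (defaults 0.1).
#' @param max_iterations Optimizer iteration cap (default 100).
#' @param gradient_tolerance Convergence tolerance on the max-norm of the
#'   (pseudo-)gradient (default 1e-5).
#' @param prefix_length,suffix_length Character lengths of the prefix and
#'   suffix features (default 3).
#' @param scheme Tag encoding scheme used for training and decoding.
#' @param types Entity types in tag-set order.
#' @param seed Stored for provenance; training itself is deterministic.
#' @return An object of class `crf_config`.
#' @export
crf_config <- function(l1 = 0.1, l2 = 0.1, max_iterations = 100L,
                       gradient_tolerance = 1e-5, prefix_length = 3L,
                       suffix_length = 3L, scheme = "IO",
                       types = c("BRAND", "FLAVOR"), seed = 1L) {
  stopifnot(l1 >= 0, l2 >= 0, max_iterations >= 1,
            gradient_tolerance > 0, prefix_length >= 1, suffix_length >= 1)
  scheme <- match.arg(scheme, c("IO", "IOB", "BILOU"))
  structure(list(l1 = l1, l2 = l2,
                 max_iterations = as.integer(max_iterations),
                 gradient_tolerance = gradient_tolerance,
                 prefix_length = as.integer(prefix_length),
                 suffix_length = as.integer(suffix_length),
                 scheme = scheme, types = types, seed = as.integer(seed)),
            class = "crf_config")
}

# parameters container -------------------------------------------------------

new_crf_params <- function(state_weights, trans_weights, tags, config) {
  dimnames(state_weights) <- list(rownames(state_weights), tags)
  dimnames(trans_weights) <- list(tags, tags)
  structure(list(state_weights = state_weights,
                 trans_weights = trans_weights,
                 tag_set = tags, config = config),
            class = "crf_params")
}

#' @export
print.crf_params <- function(x, ...) {
  cat(sprintf("<crf_params> %d features x %d tags (%s scheme)\n",
              nrow(x$state_weights), length(x$tag_set), x$config$scheme))
  invisible(x)
}

#' Emission and transition score tables
#'
#' Computes the linear-chain factor tables for one feature sequence:
#' `emission[t, y]` is the sum of state weights of the features active at
#' position `t` for tag `y`; the transition table is the learned tag-to-tag
#' weight matrix. Feature names unseen at training time contribute zero.
#'
#' @param params A `crf_params`.
#' @param features List (one element per position) of active feature-name
#'   vectors, from [extract_features()].
#' @return List with `emission` (T x L matrix) and `transition` (L x L).
#' @export
log_potentials <- function(params, features) {
  L <- length(params$tag_set)
  T_ <- length(features)
  em <- matrix(0, T_, L, dimnames = list(NULL, params$tag_set))
  if (T_ > 0L) {
    idx <- match(unlist(features, use.names = FALSE),
                 rownames(params$state_weights))
    pos <- rep.int(seq_len(T_), lengths(features))
    ok <- !is.na(idx)
    if (any(ok)) {
      acc <- rowsum(params$state_weights[idx[ok], , drop = FALSE],
                    group = pos[ok])
      em[as.integer(rownames(acc)), ] <- acc
    }
  }
  list(emission = em, transition = params$trans_weights)
}

#' Log-partition function of a linear-chain CRF
#'
#' Forward recursion with log-sum-exp stabilization; equals the log of the
#' sum of `exp(score)` over all `L^T` tag sequences.
#'
#' @param emission T x L emission score matrix.
#' @param transition L x L transition score matrix.
#' @return The scalar log-partition value.
#' @export
forward_log_partition <- function(emission, transition) {
  emission <- as.matrix(emission)
  if (nrow(emission) == 0L) stop("empty sequence: log-partition undefined")
  crf_logZ_cpp(emission, as.matrix(transition))
}

#' Posterior tag marginals
#'
#' Forward-backward recursion returning, for every position, the posterior
#' probability of each tag; rows sum to one. The summed adjacent-pair
#' marginals (the expected transition counts) are attached as attribute
#' `"pairwise"`.
#'
#' @inheritParams forward_log_partition
#' @return T x L matrix of per-position tag probabilities.
#' @export
posterior_marginals <- function(emission, transition) {
  emission <- as.matrix(emission)
  if (nrow(emission) == 0L) stop("empty sequence: marginals undefined")
  r <- crf_marginals_cpp(emission, as.matrix(transition))
  node <- r$node
  colnames(node) <- colnames(emission)
  attr(node, "pairwise") <- r$pair
  node
}

# map a dataset (features + tags) onto integer ids for the compiled core
build_seqs <- function(feature_seqs, tag_seqs, feature_names, tags) {
  mapply(function(fs, ts) {
    idx <- match(unlist(fs, use.names = FALSE), feature_names)
    pos <- rep.int(seq_along(fs), lengths(fs))
    keep <- !is.na(idx)
    gold <- match(ts, tags)
    if (anyNA(gold)) {
      stop("gold tag not in tag set: ",
           paste(unique(ts[is.na(gold)]), collapse = ", "))
    }
    offs <- c(0L, cumsum(tabulate(pos[keep], nbins = length(fs))))
    # feats must be grouped by position in order; pos is already sorted
    list(feats = as.integer(idx[keep] - 1L), offs = as.integer(offs),
         gold = as.integer(gold - 1L))
  }, feature_seqs, tag_seqs, SIMPLIFY = FALSE)
}

#' Penalized negative log-likelihood and gradient
#'
#' Computes `sum(log Z - gold score)` over the dataset plus the elastic-net
#' penalty `l2 * sum(w^2) + l1 * sum(|w|)`. The returned gradient is that
#' of the smooth part (expected minus empirical feature counts plus
#' `2 * l2 * w`); the non-smooth L1 term is handled inside the orthant-wise
#' optimizer, not here.
#'
#' @param params A `crf_params`.
#' @param dataset List of sequences, each a list with `features` (list of
#'   feature-name vectors) and `tags` (gold tag vector).
#' @param config A [crf_config()] providing `l1` and `l2`.
#' @return List with `nll` (penalized value) and `gradient` (list with
#'   `state_weights` and `trans_weights` matrices).
#' @export
nll_and_gradient <- function(params, dataset, config = params$config) {
  fn <- rownames(params$state_weights)
  seqs <- build_seqs(lapply(dataset, `[[`, "features"),
                     lapply(dataset, `[[`, "tags"), fn, params$tag_set)
  r <- crf_obj_cpp(seqs, params$state_weights, params$trans_weights, TRUE)
  wvec <- c(params$state_weights, params$trans_weights)
  nll <- r$nll + config$l2 * sum(wvec^2) + config$l1 * sum(abs(wvec))
  gW <- r$gW + 2 * config$l2 * params$state_weights
  gT <- r$gT + 2 * config$l2 * params$trans_weights
  dimnames(gW) <- dimnames(params$state_weights)
  dimnames(gT) <- dimnames(params$trans_weights)
  list(nll = nll, gradient = list(state_weights = gW, trans_weights = gT))
}

#' Train a linear-chain CRF on an annotated corpus
#'
#' Encodes gold spans under the configured scheme, extracts the feature
#' templates from every training post (the feature space is built from the
#' training data only), and minimizes the elastic-net-penalized negative
#' log-likelihood with the quasi-Newton optimizer. Training is
#' deterministic: the same corpus and config always give the same weights.
#'
#' @param corpus A non-empty `ner_corpus` with gold spans.
#' @param config A [crf_config()].
#' @return A `crf_params` object; optimizer diagnostics (`converged`,
#'   `iterations`, objective `trace`) are attached as attribute `"optim"`.
#' @export
train_crf <- function(corpus, config = crf_config()) {
  if (!inherits(corpus, "ner_corpus") || length(corpus) == 0L) {
    stop("training requires a non-empty annotated corpus")
  }
  keep <- vapply(corpus, function(p) nrow(p$tokens) > 0L, TRUE)
  corpus <- corpus[keep]
  if (length(corpus) == 0L) stop("no non-empty posts to train on")
  tags <- tag_set(config$scheme, config$types)
  feature_seqs <- lapply(corpus, function(p)
    extract_feature_seq(p$tokens, config))
  tag_seqs <- lapply(corpus, function(p)
    encode_tags(p$tokens, p$spans, config$scheme))
  feature_names <- unique(unlist(feature_seqs, use.names = FALSE))
  seqs <- build_seqs(feature_seqs, tag_seqs, feature_names, tags)
  F_ <- length(feature_names)
  L <- length(tags)
  nW <- F_ * L
  fn_gr <- function(par) {
    W <- matrix(par[seq_len(nW)], F_, L)
    Tr <- matrix(par[nW + seq_len(L * L)], L, L)
    r <- crf_obj_cpp(seqs, W, Tr, TRUE)
    list(f = r$nll + config$l2 * sum(par^2),
         g = c(r$gW, r$gT) + 2 * config$l2 * par)
  }
  opt <- owlqn(numeric(nW + L * L), fn_gr, l1 = config$l1,
               max_iter = config$max_iterations,
               tol = config$gradient_tolerance)
  if (!opt$converged) {
    warning(sprintf(
      "CRF training stopped after %d iterations before reaching the %.1e gradient tolerance",
      opt$iterations, config$gradient_tolerance), call. = FALSE)
  }
  W <- matrix(opt$par[seq_len(nW)], F_, L,
              dimnames = list(feature_names, tags))
  Tr <- matrix(opt$par[nW + seq_len(L * L)], L, L)
  params <- new_crf_params(W, Tr, tags, config)
  attr(params, "optim") <- opt[c("converged", "iterations", "value",
                                 "trace")]
  params
}

#' Viterbi decoding
#'
#' Returns a maximum a-posteriori tag sequence for a token sequence under
#' a trained model. Ties are resolved toward earlier tags in the tag set
#' at each backtracking step, so an all-zero model yields all-`O`.
#'
#' @param params A `crf_params`.
#' @param tokens Token surfaces (character vector) or token data frame;
#'   an empty input returns an empty tag sequence.
#' @param config Feature configuration (defaults to the training config).
#' @return Character vector of predicted tags.
#' @export
viterbi_decode <- function(params, tokens, config = params$config) {
  if (is.data.frame(tokens)) tokens <- tokens$surface
  if (length(tokens) == 0L) return(character(0))
  feats <- extract_feature_seq(tokens, config)
  pot <- log_potentials(params, feats)
  path <- crf_viterbi_cpp(pot$emission, pot$transition)
  params$tag_set[path]
}

# tagger interface ------------------------------------------------------------

#' Linear-chain CRF as a tagger
#'
#' Wraps [train_crf()] / [viterbi_decode()] in the generic tagger
#' interface used by [cross_validate()].
#'
#' @param config A [crf_config()].
#' @return An object of class `crf_tagger`.
#' @export
crf_tagger <- function(config = crf_config()) {
  structure(list(config = config), class = c("crf_tagger", "ner_tagger"))
}

#' @rdname fit_tagger
#' @export
fit_tagger.crf_tagger <- function(tagger, corpus, ...) {
  params <- train_crf(corpus, tagger$config)
  structure(list(params = params, config = tagger$config),
            class = c("crf_fit", "ner_tagger"))
}

#' @rdname predict_spans
#' @export
predict_spans.crf_fit <- function(object, post, ...) {
  tags <- viterbi_decode(object$params, post$tokens, object$config)
  decode_tags(post$tokens, tags, object$config$scheme, text = post$text)
}

# serialization ---------------------------------------------------------------

#' Save / load a trained CRF model as JSON
#'
#' The JSON container stores the tag set, feature names, state and
#' transition weights, the training configuration, and a format version;
#' `load_crf(save_crf(m))` reproduces the model losslessly.
#'
#' @param params A `crf_params`.
#' @param path File path.
#' @return `save_crf` returns `path` invisibly; `load_crf` returns a
#'   `crf_params`.
#' @export
save_crf <- function(params, path) {
  obj <- list(
    format = "endsner-crf",
    format_version = 1L,
    tag_set = params$tag_set,
    features = rownames(params$state_weights),
    state_weights = unname(params$state_weights),
    trans_weights = unname(params$trans_weights),
    config = unclass(params$config)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_crf
#' @export
load_crf <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$format, "endsner-crf")) {
    stop("not an endsner CRF model file")
  }
  cfg <- do.call(crf_config, obj$config)
  W <- matrix(as.numeric(obj$state_weights), nrow = length(obj$features))
  rownames(W) <- obj$features
  Tr <- matrix(as.numeric(obj$trans_weights),
               nrow = length(obj$tag_set))
  new_crf_params(W, Tr, obj$tag_set, cfg)
}
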