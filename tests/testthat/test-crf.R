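test_that("feature templates emit the documented indicator families", {
  f <- extract_features("JUUL", 1)
  expect_true(all(c("cur.isupper", "cur.lower=juul", "prefix3=juu",
                    "suffix3=uul", "BOS", "EOS") %in% f))
  expect_false("cur.islower" %in% f)

  expect_true("cur.isdigit" %in% extract_features(c("7", "ml"), 1))
  expect_true("prev.istitle" %in% extract_features(c("Puff", "Bar"), 2))
  expect_true("next.istitle" %in% extract_features(c("Puff", "Bar"), 1))
  # edge markers only at the edges
  mid <- extract_features(c("a", "b", "c"), 2)
  expect_false(any(c("BOS", "EOS") %in% mid))
})

test_that("log potentials are additive in active features", {
  cfg <- crf_config()
  tags <- tag_set("IO")
  W <- matrix(0, 3, 3, dimnames = list(c("f1", "f2", "f3"), tags))
  Tr <- matrix(0, 3, 3)
  p <- new_params_for_test(W, Tr, tags, cfg)
  expect_equal(log_potentials(p, list(character(0)))$emission,
               matrix(0, 1, 3), ignore_attr = TRUE)
  p$state_weights["f1", ] <- c(1, 2, 3)
  p$state_weights["f2", ] <- c(10, 0, 0)
  pot <- log_potentials(p, list("f1", c("f1", "f2"), "unseen"))
  expect_equal(pot$emission[1, ], c(1, 2, 3), ignore_attr = TRUE)
  expect_equal(pot$emission[2, ], c(11, 2, 3), ignore_attr = TRUE)
  expect_equal(pot$emission[3, ], c(0, 0, 0), ignore_attr = TRUE)
})

test_that("inference matches enumeration and is stable", {
  # uniform model: logZ = T log L, marginals uniform
  expect_equal(forward_log_partition(matrix(0, 4, 3), matrix(0, 3, 3)),
               4 * log(3))
  expect_equal(posterior_marginals(matrix(0, 2, 2), matrix(0, 2, 2)),
               matrix(0.5, 2, 2), ignore_attr = TRUE)
  expect_error(forward_log_partition(matrix(0, 0, 3), matrix(0, 3, 3)),
               "empty")

  set.seed(101)
  for (i in 1:25) {
    T_ <- sample(1:4, 1); L <- sample(2:3, 1)
    ch <- random_chain(T_, L)
    expect_equal(forward_log_partition(ch$emission, ch$transition),
                 enum_logZ(ch$emission, ch$transition), tolerance = 1e-10)
    marg <- posterior_marginals(ch$emission, ch$transition)
    expect_equal(unname(rowSums(marg)), rep(1, T_), tolerance = 1e-12)
    expect_equal(node_only(marg),
                 enum_node_marginals(ch$emission, ch$transition),
                 tolerance = 1e-10)
  }
})

test_that("emission shift changes logZ by the constant, not the posterior", {
  set.seed(7)
  ch <- random_chain(4, 3)
  shift <- ch$emission
  shift[2, ] <- shift[2, ] + 5.5
  expect_equal(forward_log_partition(shift, ch$transition),
               forward_log_partition(ch$emission, ch$transition) + 5.5)
  expect_equal(posterior_marginals(shift, ch$transition),
               posterior_marginals(ch$emission, ch$transition),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Viterbi attains the enumerated maximum, ties give all-O", {
  tags <- tag_set("IO")
  cfg <- crf_config()
  W <- matrix(0, 1, 3, dimnames = list("f1", tags))
  p <- new_params_for_test(W, matrix(0, 3, 3), tags, cfg)
  expect_identical(viterbi_decode(p, c("a", "b", "c")), rep("O", 3))
  expect_identical(viterbi_decode(p, character(0)), character(0))

  set.seed(202)
  for (i in 1:25) {
    T_ <- sample(1:4, 1); L <- sample(2:3, 1)
    ch <- random_chain(T_, L)
    path <- crf_viterbi_for_test(ch$emission, ch$transition)
    best <- enum_max_score(ch$emission, ch$transition)
    expect_equal(path_score(path, ch$emission, ch$transition), best,
                 tolerance = 1e-10)
    # max over sequences never exceeds the log-sum-exp
    expect_lte(best,
               forward_log_partition(ch$emission, ch$transition) + 1e-12)
  }
})

test_that("uniform-model NLL is log L and the penalty enters as stated", {
  cfg <- crf_config(l1 = 0, l2 = 0)
  tags <- tag_set("IO")
  W <- matrix(0, 2, 3, dimnames = list(c("f1", "f2"), tags))
  p <- new_params_for_test(W, matrix(0, 3, 3), tags, cfg)
  ds <- list(list(features = list("f1"), tags = "O"))
  expect_equal(nll_and_gradient(p, ds, cfg)$nll, log(3))

  # elastic net: value adds l2*||w||^2 + l1*||w||1, smooth grad adds 2*l2*w
  p2 <- p
  p2$state_weights["f1", ] <- c(1, -2, 0.5)
  cfg2 <- crf_config(l1 = 0.3, l2 = 0.7)
  r0 <- nll_and_gradient(p2, ds, crf_config(l1 = 0, l2 = 0))
  r1 <- nll_and_gradient(p2, ds, cfg2)
  w <- c(p2$state_weights, p2$trans_weights)
  expect_equal(r1$nll, r0$nll + 0.7 * sum(w^2) + 0.3 * sum(abs(w)))
  expect_equal(r1$gradient$state_weights,
               r0$gradient$state_weights + 2 * 0.7 * p2$state_weights)

  expect_error(nll_and_gradient(p, list(list(features = list("f1"),
                                             tags = "I-JUICE")), cfg),
               "tag set")
})

test_that("analytic gradient matches central finite differences", {
  corpus <- toy_brand_corpus(2)
  cfg <- crf_config(l1 = 0, l2 = 0.1, max_iterations = 3)
  params <- suppressWarnings(train_crf(corpus, cfg))
  ds <- lapply(corpus, function(p) {
    list(features = lapply(seq_len(nrow(p$tokens)), function(i)
      extract_features(p$tokens, i, cfg)),
         tags = encode_tags(p$tokens, p$spans, cfg$scheme))
  })
  base <- nll_and_gradient(params, ds, cfg)
  set.seed(5)
  h <- 1e-5
  F_ <- nrow(params$state_weights)
  coords <- cbind(sample(F_, 20, replace = TRUE),
                  sample(length(params$tag_set), 20, replace = TRUE))
  for (r in seq_len(20)) {
    i <- coords[r, 1]; j <- coords[r, 2]
    up <- params; up$state_weights[i, j] <- up$state_weights[i, j] + h
    dn <- params; dn$state_weights[i, j] <- dn$state_weights[i, j] - h
    fd <- (nll_and_gradient(up, ds, cfg)$nll -
             nll_and_gradient(dn, ds, cfg)$nll) / (2 * h)
    an <- base$gradient$state_weights[i, j]
    expect_lt(abs(fd - an) / max(1e-8, abs(fd)), 1e-4)
  }
})

test_that("training is deterministic, separable data is learned, and the
           objective decreases monotonically", {
  corpus <- toy_brand_corpus(50)
  cfg <- crf_config(l1 = 0, l2 = 0.01, max_iterations = 60)
  m1 <- suppressWarnings(train_crf(corpus, cfg))
  m2 <- suppressWarnings(train_crf(corpus, cfg))
  expect_identical(m1$state_weights, m2$state_weights)
  expect_identical(m1$trans_weights, m2$trans_weights)

  tr <- attr(m1, "optim")$trace
  expect_true(all(diff(tr) < 0))

  held <- c("i", "like", "my", "Quartz", "pod", "a", "lot")
  expect_identical(viterbi_decode(m1, held),
                   c("O", "O", "O", "I-BRAND", "O", "O", "O"))

  # elastic net with l1 > 0 also trains and predicts the toy problem
  men <- suppressWarnings(train_crf(corpus, crf_config(max_iterations = 60)))
  expect_identical(viterbi_decode(men, held)[4], "I-BRAND")

  # overwhelming l2 shrinks weights to ~0 and predictions to all-O
  big <- suppressWarnings(train_crf(corpus, crf_config(l1 = 0, l2 = 1e6,
                                                       max_iterations = 30)))
  expect_lt(max(abs(big$state_weights)), 1e-3)
  expect_identical(viterbi_decode(big, held), rep("O", 7))

  expect_error(train_crf(ner_corpus(list()), cfg), "non-empty")
})

test_that("model serialization round-trips losslessly", {
  m <- suppressWarnings(train_crf(toy_brand_corpus(10),
                                  crf_config(max_iterations = 15)))
  f <- withr::local_tempfile(fileext = ".json")
  save_crf(m, f)
  back <- load_crf(f)
  expect_equal(back$state_weights, m$state_weights)
  expect_equal(back$trans_weights, m$trans_weights, ignore_attr = TRUE)
  expect_identical(back$tag_set, m$tag_set)
  expect_identical(viterbi_decode(back, c("my", "Onyx", "pod")),
                   viterbi_decode(m, c("my", "Onyx", "pod")))
})
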