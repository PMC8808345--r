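test_that("entity matching counts exact and partial matches as defined", {
  g <- data.frame(start = c(0, 10), end = c(5, 15),
                  label = c("BRAND", "FLAVOR"))
  m <- match_entities(g, g)
  expect_identical(m$tp, c(1L, 1L))
  expect_identical(m$fp + m$fn, c(0L, 0L))

  # truncated prediction: exact misses, partial pairs it up
  gold <- data.frame(start = 0, end = 12, label = "BRAND")  # "BANG Bars XL"
  pred <- data.frame(start = 0, end = 9, label = "BRAND")   # "BANG Bars"
  ex <- match_entities(gold, pred, "exact")
  expect_identical(ex[, c("tp", "fp", "fn")],
                   data.frame(tp = 0L, fp = 1L, fn = 1L))
  pa <- match_entities(gold, pred, "partial")
  expect_identical(pa[, c("tp", "fp", "fn")],
                   data.frame(tp = 1L, fp = 0L, fn = 0L))

  # right offsets, wrong label
  wl <- match_entities(data.frame(start = 0, end = 5, label = "BRAND"),
                       data.frame(start = 0, end = 5, label = "FLAVOR"))
  expect_identical(wl$fn[wl$label == "BRAND"], 1L)
  expect_identical(wl$fp[wl$label == "FLAVOR"], 1L)

  expect_error(
    match_entities(data.frame(start = c(0, 3), end = c(5, 8),
                              label = "BRAND"), g[0, ]),
    "overlap")
})

test_that("partial matching is one-to-one and never below exact", {
  set.seed(31)
  for (i in 1:30) {
    mk <- function() {
      k <- sample(0:4, 1)
      if (k == 0) return(data.frame(start = integer(0), end = integer(0),
                                    label = character(0)))
      start <- sort(sample(seq(0, 40, by = 4), k))
      data.frame(start = start, end = start + sample(1:3, k, TRUE),
                 label = sample(c("BRAND", "FLAVOR"), k, TRUE))
    }
    gold <- mk(); pred <- mk()
    ex <- match_entities(gold, pred, "exact")
    pa <- match_entities(gold, pred, "partial")
    expect_true(all(pa$tp >= ex$tp))
    # paired counts are consistent with set sizes
    expect_true(all(pa$tp + pa$fn == ex$tp + ex$fn))
    expect_true(all(pa$tp + pa$fp == ex$tp + ex$fp))
  }
})

test_that("precision, recall and F1 follow the defining formulas", {
  c1 <- list(tp = 4, fp = 1, fn = 4)
  expect_equal(precision(c1), 0.8)
  expect_equal(recall(c1), 0.5)
  expect_equal(f1(c1), 2 / (1 / 0.5 + 1 / 0.8))

  expect_true(is.na(precision(list(tp = 0, fp = 0, fn = 3))))
  expect_true(is.na(recall(list(tp = 0, fp = 2, fn = 0))))
  expect_true(is.na(f1(list(tp = 0, fp = 0, fn = 3))))
  expect_equal(f1(list(tp = 0, fp = 2, fn = 3)), 0)

  set.seed(17)
  for (i in 1:50) {
    ct <- list(tp = sample(0:20, 1), fp = sample(0:20, 1),
               fn = sample(0:20, 1))
    p <- precision(ct); r <- recall(ct); fv <- f1(ct)
    if (!is.na(p) && !is.na(r)) {
      # harmonic mean identity and bounds
      if (p + r > 0) expect_equal(fv, 2 * p * r / (p + r))
      expect_lte(fv, max(p, r) + 1e-12)
      expect_gte(fv, min(p, r) - 1e-12)
      if (p == r) expect_equal(fv, p)
    }
  }
})

test_that("micro-aggregated counts equal concatenated-corpus counts", {
  set.seed(19)
  posts <- lapply(1:10, function(i) {
    k <- sample(0:3, 1)
    if (k == 0) {
      g <- data.frame(start = integer(0), end = integer(0),
                      label = character(0))
    } else {
      s <- sort(sample(seq(0, 30, 5), k))
      g <- data.frame(start = s, end = s + 3,
                      label = sample(c("BRAND", "FLAVOR"), k, TRUE))
    }
    p <- g[sample(nrow(g), sample(0:nrow(g), 1)), , drop = FALSE]
    list(gold = g, pred = p)
  })
  summed <- NULL
  for (pp in posts) {
    m <- match_entities(pp$gold, pp$pred, types = c("BRAND", "FLAVOR"))
    summed <- if (is.null(summed)) m else {
      j <- merge(summed, m, by = "label")
      data.frame(label = j$label, tp = j$tp.x + j$tp.y,
                 fp = j$fp.x + j$fp.y, fn = j$fn.x + j$fn.y)
    }
  }
  # concatenate with per-post offset shifts so spans stay distinct
  shift <- function(df, k) transform(df, start = start + k * 1000,
                                     end = end + k * 1000)
  allg <- do.call(rbind, lapply(seq_along(posts), function(i)
    shift(posts[[i]]$gold, i)))
  allp <- do.call(rbind, lapply(seq_along(posts), function(i)
    shift(posts[[i]]$pred, i)))
  whole <- match_entities(allg, allp, types = c("BRAND", "FLAVOR"))
  expect_identical(summed[order(summed$label), ],
                   whole[order(whole$label), ])
})

test_that("fold assignment is a seeded partition with near-equal sizes", {
  f1_ <- endsner:::fold_assignment(103, 5, 42)
  f2_ <- endsner:::fold_assignment(103, 5, 42)
  expect_identical(f1_, f2_)
  expect_identical(sort(unique(f1_)), 1:5)
  expect_true(max(table(f1_)) - min(table(f1_)) <= 1)
  expect_false(identical(f1_, endsner:::fold_assignment(103, 5, 43)))
  expect_error(endsner:::fold_assignment(3, 5, 1), "smaller")
  expect_error(endsner:::fold_assignment(10, 1, 1), "at least 2")
})

test_that("cross-validation is deterministic and reports sample SD", {
  g <- generate_corpus(generator_config(n_posts = 60, seed = 12))
  tg <- gazetteer_tagger(g$lexicons$brand_full)
  cv1 <- cross_validate(g$corpus, tg, k = 4, seed = 99)
  cv2 <- cross_validate(g$corpus, tg, k = 4, seed = 99)
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(cv1$per_fold, cv2$per_fold)
  # summary statistics recompute from per-fold values (n-1 SD)
  s <- cv1$summary
  d <- cv1$per_fold
  for (r in seq_len(nrow(s))) {
    v <- d[[s$metric[r]]][d$label == s$label[r]]
    v <- v[!is.na(v)]
    if (length(v) > 1) {
      expect_equal(s$mean[r], mean(v))
      expect_equal(s$sd[r], sd(v))
    }
  }
  # constant metric across folds gives SD 0
  if (any(!is.na(s$sd))) expect_true(all(s$sd[!is.na(s$sd)] >= 0))
})

test_that("Cohen's kappa matches hand computations", {
  a <- c(rep("O", 25), rep("I", 25))
  expect_equal(cohen_kappa(a, a), 1)

  # confusion [[20, 5], [10, 15]] on n = 50: po = .7, pe = .5, kappa = .4
  x <- c(rep("A", 25), rep("B", 25))
  y <- c(rep("A", 20), rep("B", 5), rep("A", 10), rep("B", 15))
  expect_equal(cohen_kappa(x, y), 0.4)

  # complete disagreement with symmetric marginals
  expect_equal(cohen_kappa(c("A", "B"), c("B", "A")), -1)
  # degenerate all-same-category agreement
  expect_equal(cohen_kappa(rep("O", 5), rep("O", 5)), 1)
  expect_error(cohen_kappa("A", c("A", "B")), "length")
})

test_that("mention shares reproduce printed-table arithmetic", {
  mk_spans <- function(counts) {
    do.call(rbind, lapply(names(counts), function(nm) {
      k <- counts[[nm]]
      data.frame(start = seq_len(k) * 100, end = seq_len(k) * 100 + 5,
                 label = "BRAND", text = nm, stringsAsFactors = FALSE)
    }))
  }
  filler <- stats::setNames(rep(6, 59), sprintf("brand%02d", 1:59))
  tab <- mention_share(mk_spans(c(list("Puff Bar" = 16,
                                       "Adore eLiquid" = 13,
                                       "Chief of Vapes" = 9),
                                  as.list(filler))))
  expect_identical(attr(tab, "total"), 392L)
  expect_equal(tab$share[tab$name == "Puff Bar"], 4.1)
  expect_equal(tab$share[tab$name == "Adore eLiquid"], 3.3)
  expect_equal(tab$share[tab$name == "Chief of Vapes"], 2.3)
  # sorted by count desc; case-folded grouping; half-up rounding
  expect_true(all(diff(tab$count) <= 0))
  one <- mention_share(mk_spans(list(JUUL = 3)))
  expect_equal(one$share, 100.0)
  folded <- mention_share(data.frame(start = c(0, 100), end = c(4, 104),
                                     label = "BRAND",
                                     text = c("JUUL", "juul")))
  expect_identical(nrow(folded), 1L)
  expect_identical(folded$count, 2L)
  empty <- mention_share(data.frame(start = 1, end = 2, label = "BRAND",
                                    text = "x")[0, ], label = "FLAVOR")
  expect_identical(attr(empty, "total"), 0L)
  expect_identical(nrow(empty), 0L)
})

test_that("ranking comparison is a case-folded set operation", {
  a <- c("Smok", "GeekVape", "Puff Bar")
  expect_identical(compare_rankings(a, a)$both, a)
  dis <- compare_rankings(c("Smok"), c("JUUL"))
  expect_length(dis$both, 0)
  one <- compare_rankings(c("Puff Bar", "Smok"), c("puff bar", "Vuse"),
                          top_n = 2)
  expect_identical(one$both, "Puff Bar")
  expect_identical(one$only_a, "Smok")
  expect_identical(one$only_b, "Vuse")
})
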