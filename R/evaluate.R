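#' Entity-level confusion counts
#'
#' Compares predicted spans against gold spans for one post (or any pair
#' of span sets on the same text) and returns true/false positive and
#' false negative counts per entity type. Under `"exact"` matching a
#' prediction is correct only if start, end and label all agree — the
#' standard character-exact NER criterion. Under `"partial"` matching a
#' prediction with the right label counts as correct if it overlaps a gold
#' span by at least one character; overlapping candidates are paired
#' one-to-one greedily by descending overlap. A correct-offset,
#' wrong-label prediction is a false positive for its own type and a false
#' negative for the gold type.
#'
#' @param gold,pred Span data frames (`start`, `end`, `label`); spans
#'   within each set must not overlap.
#' @param mode `"exact"` (default) or `"partial"`.
#' @param types Optional entity types to always include in the output.
#' @return Data frame with columns `label`, `tp`, `fp`, `fn`.
#' @examples
#' g <- data.frame(start = 0, end = 12, label = "BRAND")
#' p <- data.frame(start = 0, end = 9, label = "BRAND")
#' match_entities(g, p, "exact")    # fp = 1, fn = 1
#' match_entities(g, p, "partial")  # tp = 1
#' @export
match_entities <- function(gold, pred, mode = c("exact", "partial"),
                           types = NULL) {
  mode <- match.arg(mode)
  gold <- as_span_df(gold)
  pred <- as_span_df(pred)
  check_no_overlap(gold, "gold spans")
  check_no_overlap(pred, "predicted spans")
  labels <- sort(unique(c(gold$label, pred$label, types)))
  res <- lapply(labels, function(l) {
    g <- gold[gold$label == l, , drop = FALSE]
    p <- pred[pred$label == l, , drop = FALSE]
    if (mode == "exact") {
      gk <- paste(g$start, g$end)
      pk <- paste(p$start, p$end)
      tp <- sum(pk %in% gk)
    } else {
      tp <- 0L
      if (nrow(g) > 0L && nrow(p) > 0L) {
        ov <- outer(seq_len(nrow(g)), seq_len(nrow(p)),
                    Vectorize(function(i, j) {
                      max(0L, min(g$end[i], p$end[j]) -
                              max(g$start[i], p$start[j]))
                    }))
        cand <- which(ov > 0, arr.ind = TRUE)
        if (nrow(cand) > 0L) {
          o <- order(-ov[cand], g$start[cand[, 1L]], p$start[cand[, 2L]])
          cand <- cand[o, , drop = FALSE]
          gused <- logical(nrow(g)); pused <- logical(nrow(p))
          for (r in seq_len(nrow(cand))) {
            i <- cand[r, 1L]; j <- cand[r, 2L]
            if (!gused[i] && !pused[j]) {
              gused[i] <- TRUE; pused[j] <- TRUE
              tp <- tp + 1L
            }
          }
        }
      }
    }
    data.frame(label = l, tp = tp, fp = nrow(p) - tp, fn = nrow(g) - tp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(label = character(0), tp = integer(0),
                      fp = integer(0), fn = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`, and
#' `f1 = 2 / (1/recall + 1/precision)` (the harmonic mean). A metric whose
#' denominator is zero is undefined and returned as `NA`; when exactly one
#' of precision/recall is zero the harmonic mean is taken as 0.
#'
#' @param counts A list or one-row data frame with elements `tp`, `fp`,
#'   `fn` (vectors are handled elementwise).
#' @return Numeric value(s) in `[0, 1]`, or `NA` where undefined.
#' @examples
#' precision(list(tp = 4, fp = 1, fn = 4))  # 0.8
#' recall(list(tp = 4, fp = 1, fn = 4))     # 0.5
#' f1(list(tp = 4, fp = 1, fn = 4))         # 0.6154
#' @export
precision <- function(counts) {
  denom <- counts$tp + counts$fp
  ifelse(denom > 0, counts$tp / denom, NA_real_)
}

#' @rdname precision
#' @export
recall <- function(counts) {
  denom <- counts$tp + counts$fn
  ifelse(denom > 0, counts$tp / denom, NA_real_)
}

#' @rdname precision
#' @export
f1 <- function(counts) {
  p <- precision(counts)
  r <- recall(counts)
  ifelse(is.na(p) | is.na(r), NA_real_,
         ifelse(p + r == 0, 0, 2 * p * r / (p + r)))
}

# deterministic near-equal fold assignment
fold_assignment <- function(n, k, seed) {
  if (k < 2L) stop("need at least 2 folds")
  if (n < k) stop("corpus smaller than the number of folds")
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

# run code under a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' k-fold cross-validated entity-level evaluation
#'
#' Randomly partitions the corpus into `k` near-equal folds (seeded,
#' post-level), trains the tagger on the complement of each fold, scores
#' its span predictions on the held-out fold with micro-averaged
#' entity-level counts per type, and reports per-fold
#' precision/recall/F1 with mean and sample SD (n-1 denominator) across
#' folds. Undefined (zero-denominator) fold metrics are excluded from the
#' mean/SD with a note.
#'
#' @param corpus A `ner_corpus` with gold spans; must have at least `k`
#'   posts.
#' @param tagger A tagger specification (see [crf_tagger()],
#'   [gazetteer_tagger()]).
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @param mode Span matching mode, `"exact"` or `"partial"`.
#' @param types Entity types to report.
#' @return An object of class `cv_report`: list with `k`, `seed`, `mode`,
#'   `folds` (assignment vector), `per_fold` (data frame of per-fold
#'   counts and metrics per type) and `summary` (mean/SD per type and
#'   metric).
#' @export
cross_validate <- function(corpus, tagger, k = 5L, seed = 1L,
                           mode = "exact", types = c("BRAND", "FLAVOR")) {
  stopifnot(inherits(corpus, "ner_corpus"))
  n <- length(corpus)
  folds <- fold_assignment(n, k, seed)
  per_fold <- list()
  for (f in seq_len(k)) {
    fitted <- fit_tagger(tagger, corpus[folds != f])
    test <- corpus[folds == f]
    counts <- NULL
    for (p in test) {
      c1 <- match_entities(p$spans, predict_spans(fitted, p), mode = mode,
                           types = types)
      counts <- if (is.null(counts)) c1 else {
        m <- merge(counts, c1, by = "label", all = TRUE)
        m[is.na(m)] <- 0L
        data.frame(label = m$label, tp = m$tp.x + m$tp.y,
                   fp = m$fp.x + m$fp.y, fn = m$fn.x + m$fn.y)
      }
    }
    counts <- counts[counts$label %in% types, , drop = FALSE]
    counts$precision <- precision(counts)
    counts$recall <- recall(counts)
    counts$f1 <- f1(counts)
    per_fold[[f]] <- cbind(fold = f, counts)
  }
  per_fold <- do.call(rbind, per_fold)
  rownames(per_fold) <- NULL
  summ <- do.call(rbind, lapply(split(per_fold, per_fold$label),
    function(d) {
      do.call(rbind, lapply(c("precision", "recall", "f1"), function(mname) {
        v <- d[[mname]]
        nd <- sum(!is.na(v))
        if (nd < length(v)) {
          message(sprintf(
            "%s %s: %d of %d folds undefined; excluded from mean/SD",
            d$label[1], mname, length(v) - nd, length(v)))
        }
        data.frame(label = d$label[1], metric = mname,
                   mean = if (nd > 0) mean(v, na.rm = TRUE) else NA_real_,
                   sd = if (nd > 1) stats::sd(v, na.rm = TRUE) else NA_real_,
                   n_folds_defined = nd, stringsAsFactors = FALSE)
      }))
    }))
  rownames(summ) <- NULL
  structure(list(k = as.integer(k), seed = as.integer(seed), mode = mode,
                 folds = folds, per_fold = per_fold, summary = summ),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, digits = 3, ...) {
  cat(sprintf("<cv_report> %d-fold, %s matching, seed %d\n",
              x$k, x$mode, x$seed))
  s <- x$summary
  wide <- do.call(rbind, lapply(split(s, s$label), function(d) {
    data.frame(label = d$label[1],
               precision = sprintf("%.*f (%.*f)", digits,
                                   d$mean[d$metric == "precision"], digits,
                                   d$sd[d$metric == "precision"]),
               recall = sprintf("%.*f (%.*f)", digits,
                                d$mean[d$metric == "recall"], digits,
                                d$sd[d$metric == "recall"]),
               f1 = sprintf("%.*f (%.*f)", digits,
                            d$mean[d$metric == "f1"], digits,
                            d$sd[d$metric == "f1"]))
  }))
  rownames(wide) <- NULL
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Serialize a CV report to JSON
#'
#' @param report A `cv_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  jsonlite::write_json(
    list(k = report$k, seed = report$seed, mode = report$mode,
         per_fold = report$per_fold, summary = report$summary),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Cohen's kappa for inter-annotator agreement
#'
#' Chance-corrected agreement between two equal-length categorical
#' labelings (here, token-level tag sequences from two annotators):
#' `kappa = (p_o - p_e) / (1 - p_e)` with expected agreement `p_e` from
#' the marginal products. Complete agreement with degenerate marginals
#' (`p_o = p_e = 1`) returns 1.
#'
#' @param labels_a,labels_b Equal-length character vectors.
#' @return Kappa in `[-1, 1]`.
#' @examples
#' cohen_kappa(c("O", "I-BRAND"), c("O", "I-BRAND"))  # 1
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("annotation sequences differ in length")
  }
  n <- length(labels_a)
  if (n == 0L) stop("empty annotation sequences")
  lev <- sort(unique(c(labels_a, labels_b)))
  tab <- table(factor(labels_a, levels = lev),
               factor(labels_b, levels = lev))
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) return(1)
  (po - pe) / (1 - pe)
}

# round half away from zero (the printed-table convention)
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Mention-share table
#'
#' Counts entity mentions of one label grouped by case-folded surface form
#' and reports each form's share of all mentions as a percentage, rounded
#' half-up to one decimal — the brand-mention-share statistic used to
#' compare social-media mentions against market-share rankings. Rows are
#' sorted by count descending, name ascending on ties; the displayed name
#' is the most frequent original casing.
#'
#' @param x A `ner_corpus` or a span data frame with a `text` column.
#' @param label Entity label to tabulate (default `"BRAND"`).
#' @return Data frame (`name`, `count`, `share`) of class
#'   `mention_share_table`, with attribute `total` (total mention count).
#' @export
mention_share <- function(x, label = "BRAND") {
  spans <- if (inherits(x, "ner_corpus")) corpus_spans(x) else
    as_span_df(x)
  spans <- spans[spans$label == label, , drop = FALSE]
  total <- nrow(spans)
  if (total == 0L) {
    out <- data.frame(name = character(0), count = integer(0),
                      share = numeric(0))
    return(structure(out, total = 0L, label = label,
                     class = c("mention_share_table", "data.frame")))
  }
  key <- tolower(spans$text)
  counts <- table(key)
  name <- vapply(names(counts), function(k) {
    forms <- sort(table(spans$text[key == k]), decreasing = TRUE)
    top <- names(forms)[forms == max(forms)]
    sort(top)[1L]
  }, "")
  out <- data.frame(name = unname(name), count = as.integer(counts),
                    share = round_half_up(100 * as.integer(counts) / total, 1L),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, tolower(out$name)), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, total = total, label = label,
            class = c("mention_share_table", "data.frame"))
}

#' @export
print.mention_share_table <- function(x, n = 10L, ...) {
  cat(sprintf("Mention share (%s; n=%d)\n", attr(x, "label"),
              attr(x, "total")))
  d <- utils::head(as.data.frame(x), n)
  if (nrow(d) > 0L) {
    d$share <- sprintf("(%.1f)", d$share)
    print(d, row.names = FALSE)
  }
  invisible(x)
}

#' Compare two mention/market rankings
#'
#' Set comparison of the top-n names of two share tables (or plain name
#' vectors), case-folded — used to ask how much the most-mentioned brands
#' on social media overlap with the top-selling brands.
#'
#' @param table_a,table_b `mention_share_table`s or character vectors.
#' @param top_n How many top rows to compare.
#' @return List with `both`, `only_a`, `only_b` (original names from each
#'   input).
#' @export
compare_rankings <- function(table_a, table_b, top_n = 10L) {
  take <- function(x) {
    nm <- if (is.character(x)) x else x$name
    utils::head(nm, top_n)
  }
  a <- take(table_a); b <- take(table_b)
  af <- tolower(a); bf <- tolower(b)
  list(both = a[af %in% bf],
       only_a = a[!af %in% bf],
       only_b = b[!bf %in% af])
}
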