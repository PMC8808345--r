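#' Tagger interface
#'
#' Every sequence tagger in the package (the CRF, the gazetteer baseline,
#' and any future model) implements two generics so that evaluation code
#' is model-agnostic: `fit_tagger(tagger, corpus)` returns a fitted tagger,
#' and `predict_spans(object, post)` returns predicted entity spans for one
#' annotated post.
#'
#' @param tagger,object A tagger specification / fitted tagger.
#' @param corpus A `ner_corpus` with gold spans.
#' @param post An `annotated_post`.
#' @param ... Passed to methods.
#' @return `fit_tagger` returns a fitted tagger; `predict_spans` returns a
#'   span data frame (`start`, `end`, `label`, `text`).
#' @name tagger-interface
NULL

#' @rdname tagger-interface
#' @export
fit_tagger <- function(tagger, corpus, ...) UseMethod("fit_tagger")

#' @rdname tagger-interface
#' @export
predict_spans <- function(object, post, ...) UseMethod("predict_spans")
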