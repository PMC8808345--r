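---
title: "Tagging vaping brand and flavor mentions: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tagging vaping brand and flavor mentions: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endsner)
```

## The task

Short promotional posts about electronic nicotine delivery systems (ENDS)
mention brands and flavors in noisy, informal language. The surveillance
question — *which brands are being talked about, and how often?* — needs
those mentions located and typed inside the post text, not just a
post-level yes/no. `endsner` treats this as named entity recognition with
two entity types, `BRAND` and `FLAVOR`, and packages the complete
pipeline: text normalization, tokenization, span/tag conversion, a
linear-chain CRF tagger, dictionary look-up baselines, entity-level
cross-validated evaluation, and a synthetic corpus generator that stands
in for annotated social-media data that cannot be redistributed.

This vignette records the model, its assumptions, the parameters that
matter, and the design decisions taken where more than one reasonable
choice existed.

## Text normalization

`normalize_post()` applies three transformations before anything else
sees the text:

* **Hashtags** are removed as whole `#word` tokens, not just the `#`
  sign. Hashtag blocks are overwhelmingly topical boilerplate
  (`#vape #vapelife`), and keeping their word parts would inject
  near-duplicate vocabulary into every post. A consequence: an annotation
  lying entirely inside a removed hashtag cannot survive; such spans are
  dropped with a warning (and counted), while a span only partially
  inside removed text raises an error rather than silently shifting.
* **Emoji** with a known short name are replaced by that name as plain
  words (so `🔥` contributes the token `fire`). The mapping ships as a
  pinned table of Unicode CLDR short names
  (`inst/extdata/emoji_cldr.tsv`, ~75 common emoji, CLDR v44 naming
  style) so results do not drift with any system emoji library. Emoji
  and pictographic codepoints *not* in the table — including variation
  selectors, zero-width joiners and skin-tone modifiers — are removed;
  a fully general CLDR table would be thousands of rows without changing
  the pipeline's behavior on the common cases.
* **Whitespace** collapses to single spaces with no leading/trailing
  space, which makes normalization idempotent.

All offsets in the package are 0-based and half-open. Normalization
returns an offset map (total and monotone over every raw offset) and
`project_spans()` carries stand-off annotations from raw onto normalized
text. Annotation offsets are *defined on the normalized text*
throughout the package: the corpus JSONL format stores normalized text,
and raw-text annotations are expected to pass through the offset map
exactly once, at ingestion (`annotate_post()`).

`tokenize()` splits on whitespace and makes every punctuation or symbol
character (Unicode categories P and S) its own single-character token,
so `e-liquid` becomes `e`, `-`, `liquid`. One canonical tokenizer is
used for every pipeline stage — models, gazetteers, lexicon compilation —
because mixing tokenizers is a classic source of silent evaluation skew.

## Tag encodings

The default encoding is IO (`O`, `I-BRAND`, `I-FLAVOR`): the simplest
scheme, adequate because entity mentions in this domain are rarely
adjacent. Its known information loss — two adjacent same-type spans
decode as one — is documented and tested rather than hidden; IOB and
BILOU are supported behind the same `encode_tags()`/`decode_tags()`
interface for corpora where boundaries matter. Decoding is total on any
valid tag vocabulary (a stray continuation tag opens a new span), so
model output never crashes the scorer.

## The CRF tagger

The tagger is a linear-chain conditional random field: per-position
emission scores (a linear function of binary features of the token and
its neighbors) plus a tag-transition matrix, globally normalized by the
partition function. The feature templates are deliberately compact and
orthographic: lower-cased surface, is-lower/is-upper/is-title/is-digit,
lower-cased prefix and suffix (default length 3), the three case-shape
tests of the previous and next token, and `BOS`/`EOS` pseudo-features at
the edges. Sequence edges are handled by those pseudo-features rather
than by extra boundary tags, keeping the tag set minimal. The feature
space is built from the training data only; features unseen at
prediction time contribute zero score (no hashing).

Training minimizes the negative log-likelihood plus an elastic-net
penalty `l1·‖w‖₁ + l2·‖w‖²` (that exact parameterization: the gradient
of the smooth part adds `2·l2·w`). Defaults: `l1 = 0.1`, `l2 = 0.1`,
`max_iterations = 100`, `gradient_tolerance = 1e-5`, prefix/suffix
length 3. These are stated as this package's defaults, chosen as
mild-regularization values conventional for CRF software, not as a
reconstruction of any particular study's settings.

The optimizer is a limited-memory quasi-Newton method written for the
package. With `l1 = 0` it is plain L-BFGS with Armijo backtracking; with
`l1 > 0` it uses the orthant-wise variant (OWL-QN): the descent
direction comes from the pseudo-gradient of the L1 term, is constrained
to the current orthant, and line-search iterates are projected so no
coordinate crosses zero within a step. One implementation serves both
cases — CRF toolkits conventionally pair elastic net with OWL-QN, and no
installed optimizer handles the non-smooth term — and the whole training
path is deterministic: the same corpus and config always produce
bit-identical weights. When the iteration cap is reached before the
gradient tolerance, training returns the current weights with a warning;
for tagging accuracy this is typically immaterial (the objective has
long flattened), which is why the cap rather than the tolerance usually
ends training at the defaults.

Inference (forward log-partition, forward-backward marginals, Viterbi)
runs in log space with log-sum-exp stabilization, implemented in C++
because these inner loops dominate training time. Viterbi ties are
broken toward earlier tags in the fixed tag order (`O` first), so an
all-zero model predicts all-`O`; an empty token sequence decodes to an
empty tag sequence, while the partition function of an empty sequence is
an error (there is no valid path to sum over). Correctness is
established in the test suite by brute-force enumeration on small chains
and by central finite differences against the analytic gradient.

## Dictionary look-up baselines

`gazetteer_tag()` is the recall-favoring baseline: every occurrence of a
lexicon entry in the post is flagged as a predicted mention. Two
decisions where conventions diverge:

* **Token-boundary anchoring** (default): entries are matched as
  case-insensitive token sequences, so `pop` does not fire inside
  `lollipop`. A raw-substring mode is available behind a flag for the
  fully naive variant.
* **Longest match, then leftmost** for overlap resolution — the standard
  gazetteer convention — so `puff bar plus` wins over `puff bar` at the
  same site, and output spans never overlap.

Lexicon entries pass through the same normalization and tokenizer as
post text, and `benchmark_lexicon()` scores the dictionary under exactly
the same fold partitions and entity-level scorer as the learned tagger.

## Evaluation

Scoring is entity-level. Exact mode requires identical (start, end,
label); partial mode credits same-label spans overlapping by at least
one character, paired one-to-one greedily by descending overlap —
useful because a tagger that finds `BANG Bars` where the annotation was
`BANG Bars XL` is wrong by the exact criterion but plainly useful.
Counts are micro-averaged within entity type (brand and flavor are
reported separately, never blended into a macro average).

`cross_validate()` partitions posts into k seeded near-equal folds,
trains on each complement, and reports per-fold metrics with mean and
sample SD (n−1). A zero-denominator metric (e.g. precision when a fold
has no predictions for a type) is *undefined*: it is reported as `NA`
and excluded from the mean/SD with a note, rather than silently treated
as 0 — folding 0/0 into the average would bias baselines with sparse
predictions.

`cohen_kappa()` computes chance-corrected agreement on token-level tag
sequences. Annotator agreement could also be defined at the mention or
post level; the token level is used here because it is the unit the
taggers are trained on, and the choice is documented rather than claimed
equivalent to any other.

`mention_share()` tabulates mentions by case-folded surface form with
shares rounded half-up to one decimal (the convention of printed share
tables; R's default banker's rounding would disagree on exact halves).

## The synthetic corpus generator

No annotated Instagram corpus can ship with the package, so
`generate_corpus()` produces one with the statistical silhouette of an
annotated vaping corpus: ~35 tokens per post, ~0.54 brand and ~0.22
flavor mentions per post (integer part deterministic, fractional part
Bernoulli, so a rate of 1 forces exactly one mention), trailing hashtag
blocks, emoji, and generic homograph words (`pop`, `epic`, …) planted as
plain text. Brands are drawn from a configurable vocabulary with a
Zipf-like frequency skew; each realized mention samples a surface
variant — canonical (0.5), casing change (0.2), spacing change:
fused/split/hyphenated (0.2), or a product-line suffix like `XL`/`Plus`
(0.1). Generation composes token units and then runs the real
normalization/projection pipeline, so every gold span is token-aligned
by construction and the generator doubles as an end-to-end exerciser of
the preprocessing code. The corpus is a pure function of its config,
including the seed.

Three companion brand lexicons mirror the complete-vs-partial dictionary
contrast used in benchmarking. `brand_full` contains every *canonical*
brand surface: the dictionary is allowed to know every brand, but not
every spelling — per-mention casing variants still match (look-up is
case-insensitive) while fused/split/hyphenated and suffix-extended
mentions do not, which is precisely the failure mode that separates
dictionaries from learned taggers on social text. `brand_truncated`
keeps only the top fraction (default 30%) of brands by planted
frequency, emulating a top-sellers list; `brand_polluted` adds the
homograph words to `brand_full`, which can only add false positives,
never remove a gold surface — so its recall provably equals the full
lexicon's, a relation the tests assert.

What the generator does *not* emulate: real lexical diversity (its
filler vocabulary is a few dozen words, so unique-token counts are far
below a real corpus), multilingual text, discourse structure, images,
and annotation disagreement. Passing tests on synthetic data therefore
demonstrate the pipeline's correctness and the qualitative
tagger-vs-dictionary ordering, not expected real-world F1 levels —
synthetic brand contexts are more regular than real posts, and measured
scores there are optimistic.

## Problem sizes and tolerances in the test suite

The unit suite checks inference against exhaustive enumeration (chains
up to length 4, up to 3 tags, tolerances 1e-8 to 1e-10), gradients
against central finite differences (h = 1e-5, relative error < 1e-4),
and runs the full cross-validated comparison on a 1000-post generated
corpus with 50 brands, 30 flavors and homograph rate 0.1 — large enough
for fold metrics to be stable, small enough to train 5 folds in about a
minute. The same computation is what `scripts/acceptance.R` re-runs and
reports.

## Known limitations

* IO encoding merges adjacent same-type mentions; use BILOU if that
  matters for a corpus.
* The emoji table is a pinned subset; rare emoji are dropped rather than
  named.
* Entity linking (mapping `puffbar`, `puff bar`, `Puff Bar XL` to one
  canonical brand) is out of scope; `mention_share()` groups by
  case-folded surface form only.
* The CRF's feature set is purely orthographic/contextual by design;
  gazetteer-membership features, word embeddings, or neural taggers can
  be added behind the same `fit_tagger()`/`predict_spans()` interface
  but are deliberately not part of this package.
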