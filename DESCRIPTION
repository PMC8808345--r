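Package: endsner
Title: Named Entity Recognition of Vaping Brands and Flavors in Social Media Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for identifying electronic nicotine delivery system (ENDS)
    brand and flavor mentions in short social-media posts. Provides social-text
    normalization (hashtag removal, emoji-to-CLDR-short-name replacement) with
    offset tracking, a Unicode-aware tokenizer, IO/IOB/BILOU span encodings, a
    linear-chain conditional random field tagger with hand-crafted orthographic
    feature templates trained by penalized maximum likelihood (elastic net,
    quasi-Newton optimization), dictionary look-up baselines over brand and
    flavor lexicons, entity-level precision/recall/F1 with k-fold
    cross-validation, Cohen's kappa for annotator agreement, mention-share
    tables, and a synthetic annotated-corpus generator for end-to-end testing
    when annotated social-media data cannot be shared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
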