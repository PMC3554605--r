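Package: taxresolve
Title: Batch Resolution and Standardization of Plant Scientific Names
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A self-contained engine for standardizing plant scientific
    names against one or more reference taxonomies. Messy name strings are
    cleaned (family prefixes, annotations such as "cf." and "aff.",
    morphospecies codes, all-caps input), atomized into genus, epithets,
    rank indicators and authorship, and fuzzy-matched against a local
    reference store using a modified Damerau-Levenshtein distance with
    multi-character block transpositions, phonetic normalization with
    epithet stemming, and n-gram author similarity. Candidate matches are
    scored with a four-step per-component scheme, ranked with and without
    higher-taxonomy constraints, flagged with warnings, and synonyms are
    converted to their accepted names. Includes a synthetic taxonomy and
    query generator for fully offline testing, and a batch command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
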