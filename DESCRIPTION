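Package: textfacet
Title: Key-Collision and Nearest-Neighbour Clustering for Cleaning
    Semistructured Text Columns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for cleaning columns of semistructured free-text values,
    such as parasite names extracted from clinical examination reports.
    Distinct values are tabulated into a text facet, clustered by
    complementary key-collision methods (fingerprint, character n-gram
    fingerprint, an English Metaphone-family phonetic coder, and Cologne
    phonetics) and by blocked nearest-neighbour clustering on normalized
    Levenshtein distance, then merged onto the most frequent value of each
    cluster.  Includes correction-rate evaluation against a gold standard,
    a seeded generator of synthetic typo corpora with matching gold
    standards, readers and writers for mapping and review files, and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
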