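---
title: "Cleaning semistructured text columns by complementary clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cleaning semistructured text columns by complementary clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(textfacet)
```

## The problem

Columns of typed findings — here, parasite names in stool-examination
reports accumulated over many years — contain one intended vocabulary of a
few dozen terms buried under typographical errors, case and punctuation
variants, abbreviations and near-duplicate spellings.  Manual review of
every distinct value does not scale; exact deduplication misses everything
that is not byte-identical.

textfacet implements a cleaning procedure built on two complementary
clustering families applied to the *text facet* (the table of distinct
values with occurrence counts):

1. **Key collision.**  Each value is mapped to a normalized key; values
   sharing a non-empty key form a cluster.  Four keyers run in sequence:
   *fingerprint* (lowercase, ASCII-fold, punctuation to spaces, sorted
   deduplicated tokens), *n-gram fingerprint* at n = 2 and n = 1 (sorted
   distinct character n-grams of the punctuation-free string; n = 1
   collides anagrams, which is what unites transposition typos like
   "Negaitve" with "Negative"), an English *Metaphone-family* consonant
   skeleton, and *Cologne phonetics* (both make vowel errors collide,
   since vowels carry no code).
2. **Nearest neighbour.**  Values whose normalized Levenshtein distance is
   at most a radius are joined; clusters are connected components (single
   linkage), so a typo of a typo still reaches the canonical spelling.

The families fail on different error classes.  Key collision cannot unite
a dropped or substituted consonant ("Eolimax" vs "Endolimax"); the distance
stage cannot unite typos whose *relative* edit distance is large ("Native"
vs "Negative" is 2 edits over 8 characters).  Run in sequence — keyers
first, distance last, re-faceting after every stage — they leave only the
pathological cases for manual review.

After each stage, every cluster is merged onto its **canonical value**: the
member with the highest occurrence count (ties break lexicographically,
then by first occurrence).  The frequency criterion encodes the empirical
fact that the correct spelling of a report term is typically orders of
magnitude more frequent than any one misspelling of it.

## Tunable parameters

* **Nearest-neighbour radius** (`distance_spec(threshold = )`, default
  0.23, dimensionless fraction of the longer string).  The radius is
  calibrated on the canonical typo-failure fixture
  (`table1_fixture()`): dropped-letter variants such as "Eolimax" sit at
  2/9 ≈ 0.222 and must fall inside, while "Negaitve" and "Native" sit at
  2/8 = 0.25 and must fall outside.  Any radius in (0.222, 0.25) reproduces
  that split; 0.23 sits at the conservative end.  Raw (unnormalized)
  Levenshtein distance with an integer radius cannot reproduce the split at
  all — "Eolimax" and "Negaitve" are both 2 edits away — which is why the
  normalized form is the default and the raw form is only provided as an
  option.
* **Normalization conventions.**  Clustering normalizes the edit distance
  by the *longer* string (needed for the separation above);
  `inconsistency_rate()` normalizes by the *shorter* string, expressing how
  much of the smaller word disagrees (2/6 = 33% for native/negative).  Both
  conventions are intentional and documented on their functions.
* **Blocking** (`block_chars`, default 6).  On large facets only value
  pairs sharing a substring of `block_chars` characters are compared;
  facets of at most 2000 values are compared exhaustively, and a property
  test asserts blocked and exhaustive clustering agree on small facets.
* **Stage order** (`pipeline_config()`).  Cheap, high-precision keyers
  first; the distance stage last, after obvious variants have been pooled
  into their canonicals.  Merges are applied and the facet rebuilt between
  stages, so later stages see the consolidated counts; the whole sequence
  runs once (a second run is a no-op on all fixtures — the pipeline is a
  fixed point, and a test asserts it).
* **Review workflow** (`auto_accept`).  With `auto_accept = TRUE` every
  proposed cluster is merged.  With `auto_accept = FALSE` the pipeline
  writes a CSV review file (one row per member, editable
  `decision`/`canonical_override` columns) and merges nothing until the
  edited file is supplied on a second run — a batch stand-in for an
  interactive merging UI.

## Phonetic coders

The English coder is a self-contained Metaphone-family rule set (initial
letter exceptions, soft/hard c and g, digraphs ph/th/sh/ch, vowels dropped
after the initial position, adjacent duplicate codes collapsed; the full
table is in the source of `phonetic_en_key`).  It is *not* a
bit-compatible reimplementation of any particular Metaphone release —
those rule sets are proprietary or version-bound — and no compatibility is
claimed; the binding contract is behavioural, pinned by the fixture tests
(for example, "negaitve" and "negative" must share a code, "etamoeba" and
"entamoeba" must not).  `ch` codes as K because the vocabulary this
package targets is Latin binomial nomenclature (Clonorchis, Trichuris),
where that is the pronunciation.  The Cologne coder follows the published
Kölner Phonetik table exactly (Meyer/Maier is the classic collision).

A compression-based distance (`compression_distance()`) is available for
the distance stage but off by default.  It follows the normalized
compression distance form d(a,b) = (C(ab)+C(ba))/(C(aa)+C(bb)) with a
pluggable compressor; the reference compressor is an order-2
adaptive-context model that returns the ideal code length (the sum of
−log2 of Laplace-smoothed conditional byte probabilities) rather than an
actual encoded bitstream — the same quantity an adaptive arithmetic coder
would realize, deterministic, and sufficient for a distance.  Its radius
has no fixture to calibrate against, which is why the stage is optional.

## The synthetic generator

Real report corpora of this kind cannot be redistributed, so
`generate_corpus()` emulates one: records are drawn from a 30-term
parasite-examination vocabulary and corrupted by a seeded typo model.
Design choices, fixed once:

* **Frequencies.**  "Negative" carries 90% of records — screening data are
  overwhelmingly negative — and the remaining 29 terms share 10% with
  Zipf(1) weights.  Only a handful of terms are attested report values;
  the rest are common stool-parasite species, clearly synthetic filler.
* **Error channels.**  Character substitution/deletion/insertion/adjacent
  transposition, plus token drop, punctuation/spacing variants, case
  variants and abbreviation ("Giardia lamblia" → "G.lamblia") — the error
  classes visible in real report facets.  Given that a record is corrupted
  (probability `typo_fraction`, default 0.02), the number of character
  edits is 1 with probability 0.9 and 2 with probability 0.1, following
  the classic spelling-error literature (Damerau 1964; Pollock & Zamora
  1984), in which the large majority of misspellings are single-error.
* **Gold unambiguity.**  Corruption is re-drawn whenever it would collide
  with a different vocabulary term or re-use a wrong form for a different
  source, so the emitted gold standard maps every corrupted string in the
  corpus to exactly one source term.  A companion constraint holds for the
  vocabulary itself: no two correct terms may collide under any pipeline
  stage (a fixed-point test asserts the clean vocabulary passes the
  pipeline unchanged).

What the generator does **not** emulate: multi-term records, Korean or
other non-Latin report text, OCR noise, field-structure errors, and real
keyboards' non-uniform substitution preferences.  Passing the synthetic
recovery benchmark therefore shows the pipeline recovers Zipf-weighted
single/double-edit typo corpora, not that it attains any particular rate
on other institutions' data.

## Evaluation vocabulary

A *word* is an individual wrong string; a *pattern* is a class of wrong
strings belonging to one correct term (by default each distinct wrong
string is its own pattern; an explicit `pattern_id` can group them — the
grouping is gold input, not something the evaluator infers).  A wrong
string counts as corrected only if the resolved merge plan maps it to its
exact gold term; joining some other cluster counts as uncorrected.
Accuracy is occurrence-weighted: the share of all occurrences that end as
their intended term.  Degenerate cases: rates over zero error words are
reported as 100 (nothing to correct), while the rate functions themselves
refuse a zero denominator.

## Numerical and degenerate-input choices

* Empty keys never collide: values reduced to nothing by normalization
  ("???" and "!!!") must not be merged with each other.
* Distances are computed case-insensitively on trimmed strings — case is
  the keyers' job, and the distance stage should not double-count it.
* `normalized_levenshtein("", "")` is an error (undefined ratio);
  `inconsistency_rate` requires a non-empty typo.
* Cluster output is invariant under permutation of the input records; all
  tie-breaks (canonical choice, component roots, cluster ordering) are by
  count then C-locale lexicographic order.
* ASCII folding uses a fixed transliteration table rather than
  locale-dependent `iconv`, for identical keys on every platform.

## Problem sizes in the test suite

The suite verifies the edit distance against a brute-force recursive
oracle exhaustively over the 3-letter alphabet up to length 3 and on
sampled pairs up to length 5; blocked-vs-exhaustive equivalence on a
~300-value synthetic facet; and the end-to-end recovery benchmark on a
10,000-record corpus at 2% typo incidence — sizes at which the full suite
runs in well under a minute while still exercising every code path the
desk-scale fixtures exercise.

## Known limitations

* Single-linkage components can chain two legitimate terms through a
  bridge typo if the vocabulary contains terms within twice the radius;
  the fixed-point vocabulary test guards the shipped vocabulary, but users
  supplying their own dictionaries should run the clean-facet check.
* The phonetic coders target English/Latin nomenclature; applying them to
  other orthographies will under- or over-collide.
* The review-file workflow is batch, not interactive: cluster membership
  is recomputed on the second run, so edits that change membership upstream
  of a stage can shift later stages' proposals.
* `resolve_mapping()` follows merge chains to a fixed point; a cyclic plan
  (impossible for plans the pipeline itself produces) would be truncated
  after one pass per row.
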