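# Key-collision key functions.  Each keyer maps a string to a collision key;
# values sharing a non-empty key are candidates for merging.

# Fixed Latin-1 / Latin-Extended-A folding table.  Characters outside the
# table pass through unchanged so keys are reproducible across locales.
.fold_from <- paste0(
  "àáâãäåāăą",
  "çćčðďđ",
  "èéêëēėęě",
  "ìíîïĩīį",
  "ñńň",
  "òóôõöøōő",
  "śšş",
  "ùúûüũūůű",
  "ýÿźżžťţł",
  "ÀÁÂÃÄÅĀ",
  "ÇĆČÈÉÊË",
  "ÌÍÎÏÑ",
  "ÒÓÔÕÖØ",
  "ÙÚÛÜÝŠŽŁ")
.fold_to <- paste0(
  "aaaaaaaaa",
  "cccddd",
  "eeeeeeee",
  "iiiiiii",
  "nnn",
  "oooooooo",
  "sss",
  "uuuuuuuu",
  "yyzzzttl",
  "AAAAAAA",
  "CCCEEEE",
  "IIIIN",
  "OOOOOO",
  "UUUUYSZL")

#' Fold accented Latin characters to ASCII
#'
#' Applies a fixed Latin-1/Latin-Extended-A transliteration table (plus the
#' ligatures \code{ss}, \code{ae}, \code{oe}, \code{th}).  Characters outside
#' the table pass through unchanged.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @export
ascii_fold <- function(x) {
  x <- enc2utf8(as.character(x))
  x <- gsub("ß", "ss", x, fixed = TRUE)
  x <- gsub("æ", "ae", x, fixed = TRUE)
  x <- gsub("œ", "oe", x, fixed = TRUE)
  x <- gsub("þ", "th", x, fixed = TRUE)
  x <- gsub("Æ", "AE", x, fixed = TRUE)
  x <- gsub("Œ", "OE", x, fixed = TRUE)
  chartr(.fold_from, .fold_to, x)
}

# trim, lowercase, fold; shared first step of all keyers
.norm_key_base <- function(x) {
  tolower(ascii_fold(trimws(as.character(x))))
}

# punctuation and control characters become spaces (so "G.lamblia" splits
# into two tokens); letters and digits survive
.strip_punct <- function(x) {
  gsub("[^a-z0-9]+", " ", x)
}

#' Fingerprint key
#'
#' The classic key-collision fingerprint: trim, lowercase, transliterate to
#' ASCII, replace punctuation and control characters with spaces, split on
#' whitespace, drop duplicate tokens, sort tokens, join with single spaces.
#' Invariant under token order, case, surrounding whitespace and punctuation
#' substitution, and idempotent.
#'
#' @param value character vector of raw values.
#' @return character vector of keys; empty input yields the empty key.
#' @examples
#' fingerprint_key("  Clonorchis sinensis ")   # "clonorchis sinensis"
#' fingerprint_key("Sinensis,  CLONORCHIS")    # "clonorchis sinensis"
#' @export
fingerprint_key <- function(value) {
  x <- .strip_punct(.norm_key_base(value))
  vapply(strsplit(trimws(x), "[ ]+"), function(tok) {
    tok <- tok[nzchar(tok)]
    if (!length(tok)) return("")
    paste(sort(unique(tok), method = "radix"), collapse = " ")
  }, character(1))
}

#' Character n-gram fingerprint key
#'
#' Lowercases, folds to ASCII, removes all punctuation and whitespace, then
#' keys the string by its sorted set of distinct character n-grams.  With
#' \code{n = 1} the key is the sorted set of distinct characters, so anagrams
#' (for example transposition typos) collide.
#'
#' @param value character vector of raw values.
#' @param n n-gram size, a positive integer (default 2).
#' @return character vector of keys; strings shorter than \code{n} (after
#'   stripping) yield the empty key.
#' @examples
#' ngram_fingerprint_key("Negaitve", 1) == ngram_fingerprint_key("Negative", 1)
#' @export
ngram_fingerprint_key <- function(value, n = 2L) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, !is.na(n), n >= 1L)
  x <- gsub("[^a-z0-9]+", "", .norm_key_base(value))
  vapply(x, function(s) {
    L <- nchar(s)
    if (L < n) return("")
    grams <- substring(s, 1:(L - n + 1L), n:L)
    paste(sort(unique(grams), method = "radix"), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# --- English Metaphone-family phonetic coder ------------------------------
#
# Self-contained consonant-skeleton coder in the Metaphone family.  Rules:
#   * initial gn-, kn-, pn-, wr-, ps- drop the first letter; initial x -> S
#   * an initial vowel (a e i o u y) is coded A; later vowels are dropped
#   * b -> P (silent in final -mb); c -> S before e/i/y else K; ch -> K
#     (Latin/Greek medical vocabulary: Clonorchis, Trichuris); ck -> K
#   * d -> T, but dge/dgi/dgy -> J; f -> F; g -> J before e/i/y else K,
#     silent before n; h is always silent in the skeleton; j -> J; k -> K;
#   * l m n r keep themselves; p -> P, ph -> F; q -> K; s -> S (sh -> S);
#     t -> T (th -> T); v -> F; w -> W; x -> KS; z -> S
#   * adjacent duplicate codes collapse
# The coder is deterministic and idempotent on its own output domain.
.metaphone_token <- function(s) {
  s <- gsub("[^a-z]", "", s)
  L <- nchar(s)
  if (L == 0L) return("")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  vow <- c("a", "e", "i", "o", "u", "y")
  soft <- c("e", "i", "y")
  out <- character(0)
  i <- 1L
  if (L >= 2L && substr(s, 1, 2) %in% c("gn", "kn", "pn", "wr", "ps")) {
    i <- 2L
  } else if (ch[1] == "x") {
    out <- "S"
    i <- 2L
  }
  if (i <= L && ch[i] %in% vow && (i == 1L || i == 2L)) {
    # initial vowel (possibly after a dropped initial letter)
    if (i == 1L) {
      out <- c(out, "A")
      i <- 2L
    }
  }
  while (i <= L) {
    c0 <- ch[i]
    nx <- if (i < L) ch[i + 1L] else ""
    n2 <- if (i + 1L < L) ch[i + 2L] else ""
    adv <- 1L
    code <- ""
    if (c0 %in% vow) {
      if (i == 1L) code <- "A"
    } else if (c0 == "b") {
      if (!(i == L && i > 1L && ch[i - 1L] == "m")) code <- "P"
    } else if (c0 == "c") {
      if (nx == "h") { code <- "K"; adv <- 2L }
      else if (nx %in% soft) code <- "S"
      else if (nx == "k") { code <- "K"; adv <- 2L }
      else code <- "K"
    } else if (c0 == "d") {
      if (nx == "g" && n2 %in% soft) { code <- "J"; adv <- 2L }
      else code <- "T"
    } else if (c0 == "f") { code <- "F"
    } else if (c0 == "g") {
      if (nx == "n") code <- ""           # gn: g silent
      else if (nx == "h") { code <- "K"; adv <- 2L }
      else if (nx %in% soft) code <- "J"
      else code <- "K"
    } else if (c0 == "h") { code <- ""
    } else if (c0 == "j") { code <- "J"
    } else if (c0 == "k") { code <- "K"
    } else if (c0 == "l") { code <- "L"
    } else if (c0 == "m") { code <- "M"
    } else if (c0 == "n") { code <- "N"
    } else if (c0 == "p") {
      if (nx == "h") { code <- "F"; adv <- 2L } else code <- "P"
    } else if (c0 == "q") { code <- "K"
    } else if (c0 == "r") { code <- "R"
    } else if (c0 == "s") {
      if (nx == "h") { code <- "S"; adv <- 2L } else code <- "S"
    } else if (c0 == "t") {
      if (nx == "h") { code <- "T"; adv <- 2L } else code <- "T"
    } else if (c0 == "v") { code <- "F"
    } else if (c0 == "w") { code <- "W"
    } else if (c0 == "x") { code <- "KS"
    } else if (c0 == "z") { code <- "S"
    }
    if (nzchar(code)) out <- c(out, strsplit(code, "", fixed = TRUE)[[1]])
    i <- i + adv
  }
  if (!length(out)) return("")
  keep <- c(TRUE, out[-1L] != out[-length(out)])
  paste(out[keep], collapse = "")
}

#' English phonetic key (Metaphone family)
#'
#' Deterministic consonant-skeleton code approximating English pronunciation,
#' so homophone-like typos (vowel-order errors such as "negaitve") collide
#' with their correct word.  Multi-token values are keyed token by token and
#' joined with single spaces.  The full rule set is documented in the source;
#' it is a self-contained Metaphone-family coder, not a byte-compatible
#' reimplementation of any particular Metaphone release.
#'
#' @param value character vector of raw values.
#' @return character vector of keys; empty input yields the empty key.
#' @examples
#' phonetic_en_key("negaitve") == phonetic_en_key("negative")   # TRUE
#' phonetic_en_key("etamoeba") == phonetic_en_key("entamoeba")  # FALSE
#' @export
phonetic_en_key <- function(value) {
  x <- .strip_punct(.norm_key_base(value))
  vapply(strsplit(trimws(x), "[ ]+"), function(tok) {
    tok <- tok[nzchar(tok)]
    if (!length(tok)) return("")
    codes <- vapply(tok, .metaphone_token, character(1))
    paste(codes[nzchar(codes)], collapse = " ")
  }, character(1))
}

# --- Cologne phonetics ----------------------------------------------------

# published Koelner Phonetik code table; context-sensitive rules for c, p,
# d/t and x, then adjacent duplicate codes collapse and 0 is removed except
# in leading position
.cologne_token <- function(s) {
  if (grepl("^[0-9]+$", s)) return(s)  # digit runs pass through unchanged
  s <- gsub("[^a-z]", "", s)
  L <- nchar(s)
  if (L == 0L) return("")
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  codes <- character(L)
  for (i in seq_len(L)) {
    c0 <- ch[i]
    pv <- if (i > 1L) ch[i - 1L] else ""
    nx <- if (i < L) ch[i + 1L] else ""
    codes[i] <- switch(c0,
      a = , e = , i = , j = , o = , u = , y = "0",
      h = "",
      b = "1",
      p = if (nx == "h") "3" else "1",
      d = , t = if (nx %in% c("c", "s", "z")) "8" else "2",
      f = , v = , w = "3",
      g = , k = , q = "4",
      c = {
        if (i == 1L) {
          if (nx %in% c("a", "h", "k", "l", "o", "q", "r", "u", "x")) "4" else "8"
        } else if (pv %in% c("s", "z")) {
          "8"
        } else if (nx %in% c("a", "h", "k", "o", "q", "u", "x")) {
          "4"
        } else "8"
      },
      x = if (pv %in% c("c", "k", "q")) "8" else "48",
      l = "5",
      m = , n = "6",
      r = "7",
      s = , z = "8",
      "")
  }
  digs <- strsplit(paste(codes, collapse = ""), "", fixed = TRUE)[[1]]
  if (!length(digs)) return("")
  digs <- digs[c(TRUE, digs[-1L] != digs[-length(digs)])]
  digs <- digs[c(TRUE, digs[-1L] != "0")]
  paste(digs, collapse = "")
}

#' Cologne phonetic key
#'
#' Digit code per the published Koelner Phonetik table (context-sensitive
#' letter-to-digit rules; adjacent duplicate codes collapse; code 0 is
#' deleted except when leading).  Designed for German-style pronunciation;
#' useful here because vowels all code 0, so vowel typos collide.
#' Multi-token values are keyed token by token and joined with spaces;
#' all-digit tokens pass through unchanged.
#'
#' @param value character vector of raw values.
#' @return character vector of keys; values with no codable letters yield
#'   the empty key.
#' @examples
#' phonetic_cologne_key("Meyer") == phonetic_cologne_key("Maier")  # TRUE
#' @export
phonetic_cologne_key <- function(value) {
  x <- .strip_punct(.norm_key_base(value))
  vapply(strsplit(trimws(x), "[ ]+"), function(tok) {
    tok <- tok[nzchar(tok)]
    if (!length(tok)) return("")
    codes <- vapply(tok, .cologne_token, character(1))
    paste(codes[nzchar(codes)], collapse = " ")
  }, character(1))
}

#' Key-collision method specification
#'
#' @param method one of \code{"fingerprint"}, \code{"ngram_fingerprint"},
#'   \code{"phonetic_en"}, \code{"phonetic_cologne"}.
#' @param ngram_size positive integer, used only by
#'   \code{"ngram_fingerprint"} (default 2; the default pipeline also runs
#'   size 1 to catch transpositions).
#' @return an object of class \code{"key_spec"}.
#' @export
key_spec <- function(method = c("fingerprint", "ngram_fingerprint",
                                "phonetic_en", "phonetic_cologne"),
                     ngram_size = 2L) {
  method <- match.arg(method)
  ngram_size <- as.integer(ngram_size)
  stopifnot(length(ngram_size) == 1L, !is.na(ngram_size), ngram_size >= 1L)
  structure(list(method = method, ngram_size = ngram_size),
            class = "key_spec")
}

#' Apply a key specification to values
#'
#' @param spec a \code{\link{key_spec}}.
#' @param values character vector.
#' @return character vector of collision keys.
#' @export
apply_key <- function(spec, values) {
  stopifnot(inherits(spec, "key_spec"))
  switch(spec$method,
    fingerprint      = fingerprint_key(values),
    ngram_fingerprint = ngram_fingerprint_key(values, spec$ngram_size),
    phonetic_en      = phonetic_en_key(values),
    phonetic_cologne = phonetic_cologne_key(values))
}

#' @export
print.key_spec <- function(x, ...) {
  lab <- x$method
  if (x$method == "ngram_fingerprint") lab <- paste0(lab, "(n=", x$ngram_size, ")")
  cat("<key_spec> ", lab, "\n", sep = "")
  invisible(x)
}

# stable label used in merge plans and review files
.stage_label <- function(spec) {
  if (inherits(spec, "key_spec")) {
    if (spec$method == "ngram_fingerprint")
      paste0("ngram_fingerprint_", spec$ngram_size)
    else spec$method
  } else {
    paste0(spec$method, "_", format(spec$threshold, trim = TRUE))
  }
}
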