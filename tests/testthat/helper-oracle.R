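# Independent edit-distance oracle: the textbook recursive definition,
# kept free of adist() so it can stand against the implementation.
oracle_lev <- function(a, b, memo = NULL) {
  key <- NULL
  if (!is.null(memo)) {
    key <- paste0(a, "\r", b)
    hit <- get0(key, envir = memo, ifnotfound = NULL)
    if (!is.null(hit)) return(hit)
  }
  res <- if (!nchar(a)) {
    nchar(b)
  } else if (!nchar(b)) {
    nchar(a)
  } else {
    ta <- substring(a, 2); tb <- substring(b, 2)
    cost <- if (substring(a, 1, 1) == substring(b, 1, 1)) 0L else 1L
    min(oracle_lev(ta, b, memo) + 1L,
        oracle_lev(a, tb, memo) + 1L,
        oracle_lev(ta, tb, memo) + cost)
  }
  if (!is.null(memo)) assign(key, res, envir = memo)
  res
}

# all strings over an alphabet up to a maximum length (including "")
all_strings <- function(alphabet, max_len) {
  out <- ""
  frontier <- ""
  for (l in seq_len(max_len)) {
    frontier <- as.vector(outer(frontier, alphabet, paste0))
    out <- c(out, frontier)
  }
  out
}

table1_typos <- function() {
  fx <- table1_fixture()
  list(wrong = fx$gold$wrong, correct = fx$gold$correct, facet = fx$facet,
       gold = fx$gold)
}

all_keyers <- function() {
  list(key_spec("fingerprint"),
       key_spec("ngram_fingerprint", 2L),
       key_spec("ngram_fingerprint", 1L),
       key_spec("phonetic_en"),
       key_spec("phonetic_cologne"))
}

# does any keyer give the pair a shared non-empty key?
collides_any <- function(a, b, keyers = all_keyers()) {
  any(vapply(keyers, function(k) {
    ka <- apply_key(k, a); kb <- apply_key(k, b)
    nzchar(ka) && identical(ka, kb)
  }, logical(1)))
}
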