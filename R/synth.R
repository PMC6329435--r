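# Seeded synthetic corpora: a parasite-examination vocabulary with
# Zipf-like frequencies, a typo model injecting realistic error channels,
# and the small fixtures used throughout the tests and examples.

#' Term vocabulary with relative frequencies
#'
#' @param terms character vector of distinct, non-empty correct terms.
#' @param weights positive relative frequencies, recycled/normalized; by
#'   default Zipf(1) over the term ranks.
#' @return an object of class \code{"vocabulary"}.
#' @export
vocabulary <- function(terms, weights = NULL) {
  terms <- as.character(terms)
  if (!length(terms) || any(!nzchar(terms)))
    stop("vocabulary terms must be non-empty")
  if (anyDuplicated(terms)) stop("vocabulary terms must be distinct")
  if (is.null(weights)) weights <- 1 / seq_along(terms)
  stopifnot(length(weights) == length(terms), all(weights > 0))
  structure(list(terms = terms, weights = weights / sum(weights)),
            class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat("<vocabulary> ", length(x$terms), " terms; most frequent: ",
      x$terms[which.max(x$weights)],
      sprintf(" (%.1f%%)", 100 * max(x$weights)), "\n", sep = "")
  invisible(x)
}

#' Default stool-parasite vocabulary
#'
#' Thirty terms emulating a parasite-examination report vocabulary: the
#' negative finding plus helminth and protozoa names.  Only a handful of
#' the terms are attested report values; the rest are common stool-parasite
#' species added as plausible, synthetic filler, so the list as a whole is
#' a synthetic stand-in, not an authoritative reference vocabulary.
#' "Negative" carries 90\% of the mass (screening data are overwhelmingly
#' negative) and the remaining terms share 10\% with Zipf(1) weights.
#'
#' @return a \code{\link{vocabulary}} of 30 terms.
#' @export
default_vocabulary <- function() {
  terms <- c(
    "Negative", "Endolimax", "Entamoeba", "Lamblia",
    "Clonorchis sinensis", "Dientamoeba fragilis", "Entamoeba coli",
    "Entamoeba histolytica", "Giardia lamblia", "Ascaris lumbricoides",
    "Trichuris trichiura", "Enterobius vermicularis",
    "Strongyloides stercoralis", "Taenia solium", "Taenia saginata",
    "Diphyllobothrium latum", "Hymenolepis nana", "Fasciola hepatica",
    "Fasciolopsis buski", "Paragonimus westermani", "Metagonimus yokogawai",
    "Gymnophalloides seoi", "Blastocystis hominis", "Iodamoeba butschlii",
    "Chilomastix mesnili", "Cryptosporidium parvum",
    "Cyclospora cayetanensis", "Isospora belli", "Balantidium coli",
    "Trichostrongylus orientalis")
  w <- c(0.9, 0.1 * (1 / seq_len(29)) / sum(1 / seq_len(29)))
  vocabulary(terms, w)
}

#' Typographical-error model
#'
#' Channels emulate the error classes seen in semistructured report text:
#' character substitutions, deletions (dropped letters), insertions,
#' adjacent transpositions, token drops, punctuation/spacing variants, case
#' variants and abbreviations.  When a record is corrupted, the number of
#' character edits is drawn from \code{edit_probs} (default 90\% one edit,
#' 10\% two, following the classic spelling-error literature in which the
#' large majority of misspellings are single-error), each edit's channel
#' from the normalized character-channel rates; the token-level channels
#' each fire independently with their own probability.
#'
#' @param typo_fraction probability that a record carries at least one
#'   error (default 0.02).
#' @param rates named per-channel probabilities; see Details above.
#' @param edit_probs probabilities of 1, 2, ... character edits given that
#'   corruption happens.
#' @param seed default integer seed used by \code{\link{generate_corpus}}.
#' @return an object of class \code{"typo_model"}.
#' @export
typo_model <- function(typo_fraction = 0.02,
                       rates = c(substitution = 0.30, deletion = 0.25,
                                 insertion = 0.20, transposition = 0.25,
                                 token_drop = 0.02, punct_space = 0.05,
                                 case_variant = 0.05, abbreviation = 0.02),
                       edit_probs = c(0.9, 0.1),
                       seed = 1L) {
  stopifnot(typo_fraction >= 0, typo_fraction <= 1,
            all(rates >= 0), all(rates <= 1),
            all(edit_probs >= 0), sum(edit_probs) > 0)
  defaults <- c(substitution = 0.30, deletion = 0.25, insertion = 0.20,
                transposition = 0.25, token_drop = 0.02, punct_space = 0.05,
                case_variant = 0.05, abbreviation = 0.02)
  defaults[names(rates)] <- rates
  structure(list(typo_fraction = typo_fraction, rates = defaults,
                 edit_probs = edit_probs / sum(edit_probs),
                 seed = as.integer(seed)),
            class = "typo_model")
}

#' @export
print.typo_model <- function(x, ...) {
  cat("<typo_model> typo_fraction ", x$typo_fraction, "; edit count probs ",
      paste(format(x$edit_probs), collapse = "/"), "\n", sep = "")
  invisible(x)
}

.rand_letter <- function(exclude = "") {
  letters_ok <- setdiff(letters, exclude)
  sample(letters_ok, 1L)
}

# one character-level edit; returns the edited string
.char_edit <- function(s, channel) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (channel == "substitution") {
    p <- sample.int(n, 1L)
    ch[p] <- .rand_letter(tolower(ch[p]))
  } else if (channel == "deletion") {
    if (n > 1L) ch <- ch[-sample.int(n, 1L)]
  } else if (channel == "insertion") {
    p <- sample.int(n + 1L, 1L)
    ch <- append(ch, .rand_letter(), after = p - 1L)
  } else if (channel == "transposition") {
    if (n > 1L) {
      # prefer a position with distinct neighbours so the string changes
      cand <- which(ch[-n] != ch[-1L])
      p <- if (length(cand)) cand[sample.int(length(cand), 1L)] else
        sample.int(n - 1L, 1L)
      ch[c(p, p + 1L)] <- ch[c(p + 1L, p)]
    }
  }
  paste(ch, collapse = "")
}

# token-level channels
.token_edit <- function(s, channel) {
  toks <- strsplit(s, " ", fixed = TRUE)[[1]]
  if (channel == "token_drop") {
    if (length(toks) > 1L) {
      toks <- toks[-sample.int(length(toks), 1L)]
      s <- paste(toks, collapse = " ")
    }
  } else if (channel == "punct_space") {
    if (length(toks) > 1L) {
      sep <- sample(c("  ", ". ", " - "), 1L)
      s <- paste0(toks[1L], sep, paste(toks[-1L], collapse = " "))
    } else {
      s <- paste0(s, sample(c(".", " ", ".."), 1L))
    }
  } else if (channel == "case_variant") {
    s <- switch(sample.int(3L, 1L), toupper(s), tolower(s),
                { substr(s, 1, 1) <- toupper(substr(s, 1, 1)); s })
  } else if (channel == "abbreviation") {
    if (length(toks) > 1L)
      s <- paste0(toupper(substr(toks[1L], 1L, 1L)), ".",
                  paste(toks[-1L], collapse = " "))
  }
  s
}

.char_channels <- c("substitution", "deletion", "insertion", "transposition")
.token_channels <- c("token_drop", "punct_space", "case_variant",
                     "abbreviation")

# corrupt one term; guaranteed != term (retries internally)
.corrupt_once <- function(term, model) {
  p_char <- model$rates[.char_channels]
  for (try in 1:25) {
    s <- term
    if (sum(p_char) > 0) {
      k <- sample.int(length(model$edit_probs), 1L, prob = model$edit_probs)
      for (e in seq_len(k))
        s <- .char_edit(s, sample(.char_channels, 1L, prob = p_char))
    }
    for (tc in .token_channels) {
      if (stats::runif(1) < model$rates[[tc]]) s <- .token_edit(s, tc)
    }
    if (s != term && nzchar(trimws(s))) return(s)
  }
  paste0(term, "x")  # unreachable in practice; keeps the contract total
}

#' Generate a synthetic report corpus with its gold standard
#'
#' Draws \code{n_records} terms from the vocabulary at its relative
#' frequencies; with probability \code{typo_fraction} a record's term is
#' corrupted by the typo model.  Corruption never yields a string identical
#' to any vocabulary term, and a corrupted form is never reused for a
#' different source term, so the emitted gold standard is closed and
#' unambiguous.  Deterministic given the seed.
#'
#' @param vocab a \code{\link{vocabulary}}.
#' @param model a \code{\link{typo_model}}.
#' @param n_records number of records to draw (at least 1).
#' @param seed integer seed; defaults to \code{model$seed}.
#' @return list with \code{records} (character vector), \code{gold} (a
#'   \code{\link{gold_standard}} mapping every corrupted form in the corpus
#'   to its source term) and \code{corrupted} (logical per record).
#' @examples
#' cp <- generate_corpus(default_vocabulary(), typo_model(0.1), 500, seed = 7)
#' head(cp$gold)
#' @export
generate_corpus <- function(vocab, model, n_records, seed = model$seed) {
  stopifnot(inherits(vocab, "vocabulary"), inherits(model, "typo_model"))
  n_records <- as.integer(n_records)
  if (is.na(n_records) || n_records < 1L) stop("n_records must be >= 1")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  terms <- sample(vocab$terms, n_records, replace = TRUE,
                  prob = vocab$weights)
  corrupt <- stats::runif(n_records) < model$typo_fraction
  records <- terms
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in which(corrupt)) {
    ok <- FALSE
    for (try in 1:50) {
      s <- .corrupt_once(terms[i], model)
      if (s %in% vocab$terms) next            # collided with a real term
      src <- get0(s, envir = seen, ifnotfound = NULL)
      if (!is.null(src) && src != terms[i]) next  # would make gold ambiguous
      seen[[s]] <- terms[i]
      records[i] <- s
      ok <- TRUE
      break
    }
    if (!ok) corrupt[i] <- FALSE  # leave verbatim rather than emit ambiguity
  }
  wrong <- ls(seen, sorted = TRUE)
  wrong <- wrong[wrong %in% records[corrupt]]
  gold <- gold_standard(wrong,
                        vapply(wrong, function(w) seen[[w]], character(1)))
  list(records = records, gold = gold, corrupted = corrupt)
}

#' Packaged typo-failure fixture
#'
#' The small facet exercising the seven canonical typo strings whose
#' clustering behaviour separates key collision from nearest neighbour:
#' four correct words at count 100 each, seven typos at count 1 each
#' (11 distinct values, 407 occurrences), with their gold mapping.
#'
#' @return list with elements \code{facet} and \code{gold}.
#' @examples
#' table1_fixture()$facet
#' @export
table1_fixture <- function() {
  correct <- c("Negative", "Endolimax", "Entamoeba", "Lamblia")
  typos <- c(Native = "Negative", Negaitve = "Negative",
             Eolimax = "Endolimax", Endolix = "Endolimax",
             Etamoeba = "Entamoeba",
             Lamdlia = "Lamblia", "G.lamblia" = "Lamblia")
  facet <- facet_table(c(correct, names(typos)),
                       c(rep(100L, length(correct)),
                         rep(1L, length(typos))))
  list(facet = facet, gold = gold_standard(names(typos), unname(typos)))
}

#' Packaged value-merging fixture
#'
#' A dominant "Clonorchis sinensis" with five low-frequency misspelled
#' variants, emulating the frequency-ordered value-merging situation: the
#' overwhelmingly more frequent spelling is the canonical.
#'
#' @return list with elements \code{facet} and \code{gold}.
#' @export
fig2_fixture <- function() {
  canon <- "Clonorchis sinensis"
  variants <- c("clonorchis sinesis", "clnorchis sinensis",
                "clonorchis cinensis", "clonrchis sinensis",
                "clornorchis sinensis")
  facet <- facet_table(c(canon, variants), c(900L, 4L, 2L, 2L, 1L, 1L))
  list(facet = facet, gold = gold_standard(variants, canon))
}
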