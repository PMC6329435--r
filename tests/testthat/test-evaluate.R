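test_that("correction rates are plain percentages to two decimals", {
  expect_identical(pattern_correction_rate(39, 45), 86.67)
  expect_identical(pattern_correction_rate(43, 45), 95.56)
  expect_identical(pattern_correction_rate(44, 45), 97.78)
  expect_identical(pattern_correction_rate(0, 45), 0)
  expect_error(pattern_correction_rate(0, 0), "undefined")
  expect_identical(word_correction_rate(71, 72), 98.61)
  expect_identical(word_correction_rate(66, 72), 91.67)
  expect_identical(word_correction_rate(70, 72), 97.22)
  expect_identical(word_correction_rate(50, 50), 100)
  expect_error(word_correction_rate(1, 0), "undefined")
})

test_that("72 is the only word total consistent with a 98.61% rate from one residual", {
  hits <- which(vapply(1:10000, function(n)
    round(100 * (n - 1) / n, 2) == 98.61, logical(1)))
  expect_identical(hits, 72L)
  # and the same total reproduces the companion rates
  expect_identical(word_correction_rate(72 - 6, 72), 91.67)
  expect_identical(word_correction_rate(72 - 2, 72), 97.22)
})

test_that("score marks a wrong string corrected only when it reaches its gold term", {
  tt <- table1_typos()
  res <- run_pipeline(tt$facet)
  rep <- score(res, tt$gold, tt$facet)
  expect_s3_class(rep, "cleaning_report")
  expect_identical(rep$residuals, "Native")
  expect_identical(rep$pattern_rate, round(100 * 6 / 7, 2))
  expect_identical(rep$word_rate, round(100 * 6 / 7, 2))
  expect_identical(rep$accuracy, round(100 * 406 / 407, 2))

  # mapping to the wrong canonical does not count as corrected
  bad <- structure(
    data.frame(wrong = "Eolimax", canonical = "Entamoeba", count = 1L,
               stage = 1L, method = "fingerprint", stringsAsFactors = FALSE),
    class = c("merge_plan", "data.frame"))
  rep_bad <- score(bad, tt$gold, tt$facet)
  expect_true("Eolimax" %in% rep_bad$residuals)
})

test_that("an empty plan on an all-correct facet scores 100% accuracy", {
  f <- facet_table(c("Negative", "Lamblia"), c(10L, 5L))
  gold <- gold_standard("Negaitve", "Negative")
  rep <- score(structure(data.frame(wrong = character(0),
                                    canonical = character(0),
                                    count = integer(0), stage = integer(0),
                                    method = character(0)),
                         class = c("merge_plan", "data.frame")),
               gold, f, correct_terms = c("Negative", "Lamblia"))
  expect_identical(rep$accuracy, 100)
  expect_identical(rep$word_rate, 100)
})

test_that("score names a facet value the gold standard does not cover", {
  tt <- table1_typos()
  f <- facet_table(c(tt$facet$value, "Mystery"), c(tt$facet$count, 1L))
  expect_error(score(run_pipeline(tt$facet), tt$gold, f), "Mystery")
})

test_that("correction rates never decrease as pipeline stages are appended", {
  tt <- table1_typos()
  keys <- default_key_stages()
  prev <- -1
  for (k in seq(0, length(keys))) {
    cfg <- pipeline_config(key_stages = keys[seq_len(k)], nn_stages = list())
    rep <- score(run_pipeline(tt$facet, cfg), tt$gold, tt$facet)
    expect_gte(rep$word_rate, prev)
    prev <- rep$word_rate
  }
  full <- score(run_pipeline(tt$facet), tt$gold, tt$facet)
  expect_gte(full$word_rate, prev)
})

test_that("score is invariant under reordering of plan rows within a stage", {
  tt <- table1_typos()
  res <- run_pipeline(tt$facet)
  plan <- res$plan
  set.seed(99)
  shuffled <- plan[unlist(lapply(split(seq_len(nrow(plan)), plan$stage),
                                 sample)), , drop = FALSE]
  class(shuffled) <- class(plan)
  r1 <- score(plan, tt$gold, tt$facet)
  r2 <- score(shuffled, tt$gold, tt$facet)
  r1$residuals <- sort(r1$residuals); r2$residuals <- sort(r2$residuals)
  expect_identical(r1[c("pattern_rate", "word_rate", "accuracy")],
                   r2[c("pattern_rate", "word_rate", "accuracy")])
  expect_identical(r1$residuals, r2$residuals)
})

test_that("patterns group wrong strings: one uncorrected word fails its whole pattern", {
  gold <- gold_standard(c("negaitve", "negatve", "lamdlia"),
                        c("Negative", "Negative", "Lamblia"),
                        pattern_id = c("p1", "p1", "p2"))
  f <- facet_table(c("Negative", "Lamblia", "negaitve", "negatve", "lamdlia"),
                   c(10L, 10L, 1L, 1L, 1L))
  plan <- structure(
    data.frame(wrong = c("negaitve", "lamdlia"),
               canonical = c("Negative", "Lamblia"),
               count = 1L, stage = 1L, method = "m",
               stringsAsFactors = FALSE),
    class = c("merge_plan", "data.frame"))
  rep <- score(plan, gold, f)
  expect_identical(rep$n_patterns, 2L)
  expect_identical(rep$pattern_rate, 50)      # p1 only half corrected
  expect_identical(rep$word_rate, round(100 * 2 / 3, 2))
})
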