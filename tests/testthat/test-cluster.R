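test_that("build_facet counts multiplicities and conserves the total", {
  f <- build_facet(c("negative", "negative", "native"))
  expect_s3_class(f, "facet_table")
  expect_identical(f$value, c("negative", "native"))
  expect_identical(f$count, c(2L, 1L))
  expect_identical(nrow(build_facet(character(0))), 0L)
  f2 <- build_facet(rep("x", 1000))
  expect_identical(f2$count, 1000L)
  expect_identical(facet_total(build_facet(letters)), 26L)
})

test_that("facet_table rejects duplicates and non-positive counts", {
  expect_error(facet_table(c("a", "a"), c(1, 2)), "distinct")
  expect_error(facet_table("a", 0L), "positive")
})

test_that("choose_canonical prefers frequency, then lexicographic order", {
  expect_identical(
    choose_canonical(c("Clonorchis sinensis", "clonorchis sinesis"),
                     c(900L, 4L)),
    "Clonorchis sinensis")
  expect_identical(choose_canonical("a", 1L), "a")
  expect_identical(choose_canonical(c("b", "a"), c(2L, 2L)), "a")
  expect_error(choose_canonical(character(0), integer(0)), "empty")
})

test_that("key collision clusters values sharing a non-empty key", {
  f <- facet_table(c("Negative", "Negaitve"), c(5000L, 3L))
  cl <- key_collision_cluster(f, key_spec("ngram_fingerprint", 1L))
  expect_length(cl, 1L)
  expect_identical(cl[[1]]$canonical, "Negative")
  expect_setequal(cl[[1]]$members$value, c("Negative", "Negaitve"))

  f2 <- facet_table(c("Negative", "Native"), c(5000L, 2L))
  for (spec in all_keyers()) {
    expect_length(key_collision_cluster(f2, spec), 0L)
  }
  expect_length(key_collision_cluster(facet_table("x", 1L),
                                      key_spec("fingerprint")), 0L)
  # empty keys are not collisions
  f3 <- facet_table(c("???", "!!!", "ok"), c(2L, 1L, 1L))
  expect_length(key_collision_cluster(f3, key_spec("fingerprint")), 0L)
})

test_that("nearest-neighbour clustering joins values within the radius as components", {
  spec <- distance_spec("normalized_levenshtein", 0.23)
  f <- facet_table(c("Endolimax", "Eolimax", "Endolix"), c(800L, 2L, 1L))
  cl <- nn_cluster(f, spec)
  expect_length(cl, 1L)
  expect_identical(cl[[1]]$canonical, "Endolimax")
  expect_setequal(cl[[1]]$members$value, c("Endolimax", "Eolimax", "Endolix"))

  expect_length(nn_cluster(facet_table(c("Negative", "Negaitve"),
                                       c(5000L, 3L)), spec), 0L)
  expect_length(nn_cluster(facet_table(c("abc", "xyz"), c(1L, 1L)), spec), 0L)
})

test_that("blocked candidate generation reproduces the exhaustive clustering", {
  set.seed(11)
  cp <- generate_corpus(default_vocabulary(), typo_model(0.25), 400, seed = 11)
  f <- build_facet(cp$records)
  expect_lte(nrow(f), 500L)
  spec <- distance_spec("normalized_levenshtein", 0.23, block_chars = 4L)
  exhaustive <- nn_cluster(f, spec, max_exhaustive = 1e6)
  blocked <- nn_cluster(f, spec, max_exhaustive = 0L)
  sig <- function(cls) lapply(cls, function(cl)
    list(cl$canonical, sort(cl$members$value)))
  expect_identical(sig(blocked), sig(exhaustive))
})

test_that("cluster output is invariant under permutation of the input sequence", {
  set.seed(5)
  vals <- c(rep("Negative", 50), rep("Negaitve", 2), rep("Endolimax", 30),
            "Eolimax", "Endolix", rep("Lamblia", 20), "Lamdlia")
  f1 <- build_facet(vals)
  f2 <- build_facet(sample(vals))
  expect_identical(f1, f2)
  r1 <- run_pipeline(f1)
  r2 <- run_pipeline(f2)
  expect_identical(r1$plan, r2$plan)
  expect_identical(r1$facet, r2$facet)
})

test_that("the sequential pipeline reproduces the canonical typo-failure split", {
  tt <- table1_typos()
  res <- run_pipeline(tt$facet)
  expect_identical(intersect(res$facet$value, tt$wrong), "Native")
  expect_identical(facet_total(res$facet), facet_total(tt$facet))
  # key-collision stages alone fail 6 of 7; nearest neighbour alone fails 2
  key_only <- run_pipeline(tt$facet, pipeline_config(nn_stages = list()))
  map_k <- resolve_mapping(key_only)
  fixed_k <- tt$wrong[map_k[tt$wrong] == tt$correct & !is.na(map_k[tt$wrong])]
  expect_identical(unname(fixed_k), "Negaitve")
  nn_only <- run_pipeline(tt$facet, pipeline_config(key_stages = list()))
  map_n <- resolve_mapping(nn_only)
  failed_n <- tt$wrong[is.na(map_n[tt$wrong]) | map_n[tt$wrong] != tt$correct]
  expect_setequal(unname(failed_n), c("Native", "Negaitve"))
})

test_that("the pipeline conserves occurrence totals and reaches a fixed point", {
  tt <- table1_typos()
  res <- run_pipeline(tt$facet)
  expect_identical(facet_total(res$facet), 407L)
  again <- run_pipeline(res$facet)
  expect_identical(nrow(again$plan), 0L)
  expect_identical(again$facet, res$facet)
  # conservation also holds on a messier synthetic facet
  cp <- generate_corpus(default_vocabulary(), typo_model(0.3), 2000, seed = 9)
  f <- build_facet(cp$records)
  expect_identical(facet_total(run_pipeline(f)$facet), 2000L)
})

test_that("an empty stage list is the identity pipeline", {
  tt <- table1_typos()
  res <- run_pipeline(tt$facet,
                      pipeline_config(key_stages = list(),
                                      nn_stages = list()))
  expect_identical(nrow(res$plan), 0L)
  expect_identical(res$facet, tt$facet)
})

test_that("merge chains resolve to the final canonical form", {
  plan <- structure(
    data.frame(wrong = c("a", "b"), canonical = c("b", "c"),
               count = c(1L, 1L), stage = c(1L, 2L),
               method = "fingerprint", stringsAsFactors = FALSE),
    class = c("merge_plan", "data.frame"))
  map <- resolve_mapping(plan)
  expect_identical(unname(map["a"]), "c")
  expect_identical(unname(map["b"]), "c")
})

test_that("review-file workflow defers merges until decisions are accepted", {
  tt <- table1_typos()
  review_path <- withr::local_tempfile(fileext = ".csv")
  cfg <- pipeline_config(auto_accept = FALSE, review_path = review_path)
  first <- run_pipeline(tt$facet, cfg)
  expect_identical(nrow(first$plan), 0L)
  expect_identical(first$facet, tt$facet)
  expect_true(file.exists(review_path))
  review <- read_review_file(review_path)
  expect_true(all(c("cluster_id", "stage", "method", "member", "count",
                    "proposed_canonical", "decision", "canonical_override")
                  %in% names(review)))
  # reject one cluster, accept the rest
  review$decision[review$proposed_canonical == "Negative"] <- "reject"
  write_review_file(review, review_path)
  second <- run_pipeline(tt$facet, cfg)
  expect_false("Negaitve" %in% second$plan$wrong)
  expect_true("Negaitve" %in% second$facet$value)
  expect_gt(nrow(second$plan), 0L)
})
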