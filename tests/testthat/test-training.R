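rand_aa_fixed <- function() {
  set.seed(97)
  rand_aa(20)
}

test_that("homology filtering collapses planted families", {
  base <- local({ set.seed(71); rand_aa(60) })
  mutate <- function(s, k) {
    cs <- strsplit(s, "")[[1]]
    idx <- sample(length(cs), k)
    cs[idx] <- sample(AA_ALPHABET20, k, replace = TRUE)
    paste(cs, collapse = "")
  }
  set.seed(73)
  fam <- lapply(1:5, function(i) {
    substrate_record(paste0("fam", i), mutate(base, 3))   # >= 90% identity
  })
  outlier <- substrate_record("out", rand_aa(55))
  subs <- c(fam, list(outlier))
  reps <- homology_filter(subs, 0.70)
  expect_identical(length(reps), 2L)
  expect_true("out" %in% vapply(reps, `[[`, character(1), "id"))

  # identical pair collapses; disjoint pair survives
  a <- substrate_record("a", "ACDEFGHIKLMNPQRSTVWY")
  expect_identical(length(homology_filter(list(a, a), 0.7)), 1L)
  b <- substrate_record("b", paste(rep("W", 20), collapse = ""))
  expect_identical(length(homology_filter(list(a, b), 0.7)), 2L)
  expect_identical(homology_filter(list()), list())
})

test_that("homology filtering agrees with brute-force greedy clustering", {
  set.seed(79)
  subs <- lapply(1:12, function(i) {
    substrate_record(paste0("s", i), rand_aa(sample(25:45, 1)))
  })
  # plant two family clones so some merges actually happen
  subs[[3]] <- substrate_record("s3", subs[[1]]$residues)
  subs[[7]] <- substrate_record("s7", paste0(subs[[2]]$residues, "AA"))
  reps <- homology_filter(subs, 0.70)
  want <- brute_homology_reps(subs, 0.70)
  expect_identical(vapply(reps, `[[`, character(1), "id"),
                   vapply(subs[want], `[[`, character(1), "id"))
})

test_that("substrate-level splits are disjoint and reproducible", {
  set.seed(83)
  subs <- lapply(1:10, function(i) {
    substrate_record(paste0("s", i), rand_aa(30), p1_sites = 10L)
  })
  sp <- split_substrates(subs, 0.9, seed = 5)
  expect_identical(length(sp$train), 9L)
  expect_identical(length(sp$test), 1L)
  ids <- function(x) vapply(x, `[[`, character(1), "id")
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0L)
  expect_setequal(c(ids(sp$train), ids(sp$test)), ids(subs))
  sp2 <- split_substrates(subs, 0.9, seed = 5)
  expect_identical(ids(sp2$test), ids(sp$test))
  expect_error(split_substrates(subs[1], seed = 1), "at least 2")
})

test_that("labelled sets respect window boundaries and the 3:1 ratio", {
  s <- substrate_record("w", rand_aa_fixed(), p1_sites = c(5L, 9L))
  set1 <- build_labelled_sets(list(s), mode = "set1")
  expect_identical(length(set1$positives$aa), 2L)
  expect_identical(length(set1$negatives$aa), 11L)    # 13 candidates - 2
  set2 <- build_labelled_sets(list(s), mode = "set2", seed = 9)
  expect_identical(length(set2$positives$aa), 2L)
  expect_identical(length(set2$negatives$aa), 6L)
  expect_true(all(set2$negatives$aa %in% set1$negatives$aa))
  # near-terminal site is dropped from positives with a warning
  s2 <- substrate_record("t", rand_aa_fixed(), p1_sites = c(2L, 9L))
  expect_warning(out <- build_labelled_sets(list(s2), mode = "set1"),
                 "without a full window")
  expect_identical(length(out$positives$aa), 1L)
  expect_error(
    suppressWarnings(build_labelled_sets(
      list(substrate_record("n", rand_aa_fixed(), p1_sites = 2L)))),
    "insufficient data")
})

test_that("metric identities and degenerate cases", {
  m <- classification_metrics(tp = 3, fp = 1, tn = 5, fn = 1)
  expect_equal(m$precision, 0.75)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 5 / 6, tolerance = 1e-4)
  expect_equal(m$f1, 0.75)
  # all-negative predictions: precision undefined, never silent zero
  m2 <- classification_metrics(tp = 0, fp = 0, tn = 6, fn = 4)
  expect_true(is.nan(m2$precision))
  expect_identical(m2$sensitivity, 0)
  expect_identical(m2$specificity, 1)
  expect_true(is.nan(m2$f1))
  m3 <- classification_metrics(tp = 4, fp = 0, tn = 6, fn = 0)
  expect_identical(c(m3$precision, m3$sensitivity, m3$specificity, m3$f1),
                   rep(1, 4))
})

test_that("evaluate_model tabulates every window exactly once", {
  set.seed(101)
  corpus <- generate_corpus(30, c(60, 90), seed = 14)
  sp <- split_substrates(corpus, 0.9, seed = 14)
  model <- train_scoring_model(sp$train, threshold_criterion = "f1",
                               seed = 14)
  test <- build_labelled_sets(sp$test, mode = "set1")
  m <- evaluate_model(model, test)
  expect_identical(m$tp + m$fn, length(test$positives$aa))
  expect_identical(m$fp + m$tn, length(test$negatives$aa))
  expect_error(evaluate_model(model, structure(
    list(positives = list(aa = character(0)),
         negatives = list(aa = character(0))),
    class = "labelled_window_set")), "empty test set")
})

test_that("under-sampled evaluation raises precision in expectation", {
  corpus <- generate_corpus(40, c(80, 120), seed = 21)
  sp <- split_substrates(corpus, 0.9, seed = 21)
  model <- train_scoring_model(sp$train, threshold_criterion = "f1",
                               seed = 21)
  m1 <- evaluate_model(model, build_labelled_sets(sp$test, mode = "set1"))
  prec2 <- vapply(1:5, function(s) {
    evaluate_model(model,
                   build_labelled_sets(sp$test, mode = "set2",
                                       seed = s))$precision
  }, numeric(1))
  expect_gt(mean(prec2), m1$precision)
  # sensitivity is untouched by negative down-sampling
  m2 <- evaluate_model(model, build_labelled_sets(sp$test, mode = "set2",
                                                  seed = 1))
  expect_identical(m2$sensitivity, m1$sensitivity)
})
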