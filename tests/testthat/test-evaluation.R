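test_that("ratings collapse to binary labels by the 3-5 / 1-2 rule", {
  expect_identical(rating_to_label(4L), "positive")
  expect_identical(rating_to_label(3L), "positive")
  expect_identical(rating_to_label(2L), "negative")
  expect_identical(rating_to_label(1:5),
                   c("negative", "negative", "positive", "positive", "positive"))
  expect_error(rating_to_label(6L), class = "persent_range_error")
  expect_error(rating_to_label(0L), class = "persent_range_error")
})

test_that("90:10 splits are disjoint, exhaustive and reproducible", {
  ids <- sprintf("c%03d", 1:100)
  sp <- split_corpus(ids, ratio = 0.9, seed = 3)
  expect_length(sp$train, 90L)
  expect_length(sp$test, 10L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(split_corpus(ids, ratio = 0.9, seed = 3), sp)
  expect_false(identical(split_corpus(ids, ratio = 0.9, seed = 4)$test, sp$test))
  expect_error(split_corpus("one", 0.9), class = "persent_length_error")
  expect_error(split_corpus(ids, 1.2), class = "persent_range_error")
})

test_that("stratified splits allocate test seats by largest remainder", {
  ids <- sprintf("c%02d", 1:10)
  labels <- rep(c("positive", "negative"), each = 5)
  sp <- split_corpus(ids, ratio = 0.9, seed = 1, labels = labels)
  expect_length(sp$test, 1L)
  expect_length(sp$train, 9L)
  # larger check: strata proportions carried into the test set
  ids2 <- sprintf("c%03d", 1:200)
  labels2 <- rep(c("positive", "negative"), c(150, 50))
  sp2 <- split_corpus(ids2, ratio = 0.9, seed = 1, labels = labels2)
  test_labels <- labels2[match(sp2$test, ids2)]
  expect_identical(sum(test_labels == "positive"), 15L)
  expect_identical(sum(test_labels == "negative"), 5L)
})

test_that("confusion matrices count the four cells correctly", {
  cm <- confusion(c("positive", "positive", "negative", "negative"),
                  c("positive", "negative", "negative", "positive"))
  expect_identical(unclass(cm)[c("tp", "fn", "tn", "fp")],
                   list(tp = 1L, fn = 1L, tn = 1L, fp = 1L))
  perfect <- confusion(rep(c("positive", "negative"), 5),
                       rep(c("positive", "negative"), 5))
  expect_identical(perfect$fp + perfect$fn, 0L)
  inverted <- confusion(rep(c("positive", "negative"), 5),
                        rep(c("negative", "positive"), 5))
  expect_identical(inverted$tp + inverted$tn, 0L)
  expect_error(confusion("positive", c("positive", "negative")),
               class = "persent_length_error")
  expect_error(confusion("positive", "maybe"), class = "persent_label_error")
})

test_that("metrics match their defining formulas, with NA at zero denominators", {
  m <- compute_metrics(list(tp = 9, fp = 1, fn = 1, tn = 9))
  expect_equal(unlist(m[c("precision", "recall", "specificity",
                          "accuracy", "f_measure")]),
               c(precision = 0.9, recall = 0.9, specificity = 0.9,
                 accuracy = 0.9, f_measure = 0.9))
  m <- compute_metrics(list(tp = 8, fp = 2, fn = 4, tn = 6))
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f_measure, 2 * 0.8 * (2 / 3) / (0.8 + 2 / 3))
  m <- compute_metrics(list(tp = 0, fp = 0, fn = 3, tn = 7))
  expect_true(is.na(m$precision))
  expect_false(is.na(m$accuracy))
  expect_error(compute_metrics(list(tp = 0, fp = 0, fn = 0, tn = 0)),
               class = "persent_length_error")
})

test_that("AUC matches the pair-counting oracle and its closed-form limits", {
  # perfect separation and all-ties limits
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1),
                         c("positive", "positive", "negative", "negative")), 1)
  expect_equal(auc_score(rep(0.5, 6), rep(c("positive", "negative"), 3)), 0.5)
  expect_equal(auc_score(c(0.9, 0.4, 0.6, 0.1),
                         c("positive", "negative", "positive", "negative")), 1)
  set.seed(13)
  for (rep in 1:100) {
    n <- sample(2:12, 1)
    truth <- sample(c("positive", "negative"), n, replace = TRUE)
    if (length(unique(truth)) < 2) truth[1:2] <- c("positive", "negative")
    scores <- sample(seq(-1, 1, by = 0.25), n, replace = TRUE)  # force ties
    expect_equal(auc_score(scores, truth), oracle_auc(scores, truth))
  }
  expect_error(auc_score(1:3, rep("positive", 3)),
               class = "persent_label_error")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(17)
  scores <- rnorm(40)
  truth <- sample(c("positive", "negative"), 40, replace = TRUE)
  truth[1:2] <- c("positive", "negative")
  base <- auc_score(scores, truth)
  expect_equal(auc_score(exp(scores), truth), base)
  expect_equal(auc_score(scores^3 + 5 * scores, truth), base)
  expect_equal(auc_score(rank(scores, ties.method = "average"), truth), base)
})

test_that("label-shuffled AUC concentrates near one half", {
  set.seed(19)
  n <- 10000
  scores <- runif(n)
  truth <- sample(rep(c("positive", "negative"), n / 2))
  expect_gt(auc_score(scores, truth), 0.45)
  expect_lt(auc_score(scores, truth), 0.55)
})

test_that("per-section evaluation produces the metrics-by-section layout", {
  lexi <- generate_lexicon(40, seed = 23)
  cfg <- generator_config(n_docs = 240, seed = 23)
  sim <- generate_corpus(cfg, lexi)
  docs <- normalize_corpus(sim$comments, default_rules(), lexicon = lexi)
  sc <- score_corpus(docs, lexi)
  sc$rating <- sim$truth$docs$rating[match(sc$comment_id, sim$truth$docs$id)]
  rep <- evaluate_sections(sc)
  expect_identical(rep$metric,
                   c("precision", "recall", "specificity", "accuracy",
                     "f_measure", "auc"))
  expect_setequal(setdiff(names(rep), "metric"),
                  c("healthcare_services", "general_services",
                    "life_expectancy"))
  vals <- unlist(rep[-1])
  expect_true(all(vals >= 0 & vals <= 1))
  # a noise-free generator corpus is perfectly recoverable
  expect_true(all(rep[rep$metric == "accuracy", -1] == 1))

  one_class <- sc[sc$rating >= 4, ]
  w <- capture_warnings(evaluate_sections(one_class))
  expect_true(all(grepl("lacks both classes", w)))
})
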