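lex <- demo_lexicon()

test_that("sentence scoring follows the max-positive / min-negative rule", {
  s <- score_sentence(data.frame(stem = c("خوب", "دیر"),
                                 negated = c(FALSE, FALSE)), lex)
  expect_identical(s$max_pos, 3L)   # خوب +3
  expect_identical(s$min_neg, -2L)  # دیر -2
  expect_identical(s$polarity, 3L)

  s <- score_sentence(c("پرستار", "غذا"), lex)  # no lexicon terms
  expect_identical(unlist(s), c(max_pos = 0L, min_neg = 0L, polarity = 0L))

  # exact tie in absolute value is neutral
  s <- score_sentence(c("خوب", "بد"), lex)       # +3 vs -3
  expect_identical(s$polarity, 0L)
})

test_that("sentence scorer matches the brute-force oracle on random token lists", {
  set.seed(42)
  terms <- names(lex$entries)
  filler <- c("غذا", "تخت", "پرستار", "راهرو")
  for (rep in seq_len(300)) {
    n <- sample(1:12, 1)
    stems <- sample(c(terms, filler), n, replace = TRUE)
    negated <- runif(n) < 0.3
    got <- score_sentence(data.frame(stem = stems, negated = negated), lex)
    want <- oracle_sentence(stems, negated, lex$entries)
    expect_identical(got$max_pos, as.integer(want$max_pos))
    expect_identical(got$min_neg, as.integer(want$min_neg))
    expect_identical(got$polarity, as.integer(want$polarity))
  }
})

test_that("negating a single-term sentence flips the polarity sign exactly", {
  for (term in names(lex$entries)) {
    plain <- score_sentence(data.frame(stem = term, negated = FALSE), lex)
    neg <- score_sentence(data.frame(stem = term, negated = TRUE), lex)
    expect_identical(neg$polarity, -plain$polarity)
  }
})

test_that("raising a positive term's strength never decreases sentence polarity", {
  set.seed(7)
  base <- sentiment_lexicon(setNames(c(2L, -4L, 1L), c("a", "b", "c")))
  for (up in 3:5) {
    upgraded <- sentiment_lexicon(setNames(c(up, -4L, 1L), c("a", "b", "c")))
    for (rep in 1:20) {
      stems <- sample(c("a", "b", "c", "d"), sample(1:6, 1), replace = TRUE)
      lo <- score_sentence(stems, base)$polarity
      hi <- score_sentence(stems, upgraded)$polarity
      expect_gte(hi, lo)
    }
  }
})

test_that("document scores are the mean of nonzero sentence polarities over 5", {
  rules <- default_rules()
  doc <- normalize_comment(
    list(id = "d1", text = "غذا خوب. نوبت دیر."), rules, lexicon = lex)
  ds <- score_document(doc, lex)
  expect_identical(ds$sentence_polarities, c(3L, -2L))
  expect_equal(ds$score, (3 - 2) / (2 * 5))
  expect_identical(ds$label, "positive")

  neutral <- normalize_comment(list(id = "d2", text = "غذا تخت."),
                               rules, lexicon = lex)
  ds <- score_document(neutral, lex)
  expect_identical(ds$score, 0)
  expect_identical(ds$label, "neutral")

  worst <- normalize_comment(list(id = "d3", text = "افتضاح بیمارستان."),
                             rules, lexicon = lex)
  ds <- score_document(worst, lex)
  expect_equal(ds$score, -1)   # single -5 sentence hits the scale endpoint
  expect_identical(ds$label, "negative")
})

test_that("document scores stay within [-1, 1] on random corpora", {
  gen_lex <- generate_lexicon(40, seed = 5)
  cfg <- generator_config(n_docs = 60, seed = 5, negation_rate = 0.3)
  sim <- generate_corpus(cfg, gen_lex)
  docs <- normalize_corpus(sim$comments, default_rules(), lexicon = gen_lex)
  sc <- score_corpus(docs, gen_lex)
  expect_true(all(sc$score >= -1 & sc$score <= 1))
})

test_that("weighted aggregation implements the usefulness-weighted average", {
  expect_equal(aggregate_scores(c(0.4, -0.2))$V, 0.1)
  expect_equal(aggregate_scores(0.37)$V, 0.37)
  expect_equal(aggregate_scores(c(0.5, -0.5, 0.1), c(2, 1, 1))$V, 0.15)
  # equal weights equal the arithmetic mean to machine precision
  set.seed(8)
  for (rep in 1:50) {
    x <- runif(sample(1:30, 1), -1, 1)
    expect_equal(aggregate_scores(x)$V, mean(x), tolerance = 1e-15)
    w <- runif(length(x))
    v <- aggregate_scores(x, w)$V
    expect_gte(v, min(x) - 1e-12)
    expect_lte(v, max(x) + 1e-12)
  }
  expect_error(aggregate_scores(c(1, 2), c(1, -1)),
               class = "persent_weight_error")
  expect_error(aggregate_scores(c(1, 2), c(0, 0)),
               class = "persent_weight_error")
  expect_error(aggregate_scores(c(1, 2), 1), class = "persent_length_error")
})

test_that("classification respects the neutral band", {
  expect_identical(classify_score(0.1), "positive")
  expect_identical(classify_score(-0.004, 0.01), "neutral")
  expect_identical(classify_score(0), "neutral")
  expect_identical(classify_score(-0.2), "negative")
})

test_that("per-topic sentiment aggregates by dominant topic with shares", {
  sc <- data.frame(comment_id = c("a", "b", "c"),
                   score = c(0.2, 0.4, -0.3))
  topics <- setNames(c(1L, 1L, 2L), c("a", "b", "c"))
  tab <- topic_sentiment(sc, topics, k = 3L)
  expect_equal(tab$score[1:2], c(0.3, -0.3))
  expect_equal(tab$share[1:2], c(2 / 3, 1 / 3))
  expect_identical(tab$n[3], 0L)
  expect_true(is.na(tab$score[3]))
})

test_that("term frequency report ranks stems with lexicographic tie-breaks", {
  rules <- default_rules()
  docs <- normalize_corpus(
    data.frame(id = c("1", "2"),
               text = c("خوب خوب خوب بد بد.", "خوب خوب تخت."),
               stringsAsFactors = FALSE),
    rules)
  tab <- term_frequency_report(docs, 10)
  expect_identical(tab$term[1], "خوب")
  expect_identical(tab$count[1], 5L)
  expect_identical(term_frequency_report(docs, 1)$term, "خوب")
  # ties broken lexicographically
  ties <- tab[tab$count == 1L, "term"]
  expect_identical(ties, sort(ties, method = "radix"))
  expect_identical(nrow(term_frequency_report(list(), 5)), 0L)
})
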