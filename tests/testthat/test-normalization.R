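rules <- default_rules()

test_that("character unification maps Arabic code points and restores initial alef", {
  expect_identical(normalize_characters("ي", rules), "ی")
  expect_identical(normalize_characters("ك", rules), "ک")
  expect_identical(normalize_characters("اب", rules), "آب")
  # word-list driven: other alef-initial words untouched
  expect_identical(normalize_characters("امید", rules), "امید")
  expect_identical(normalize_characters("سلام", rules), "سلام")
})

test_that("spacing normalization collapses whitespace and deletes kashida", {
  expect_identical(normalize_spacing("بــــــر", rules), "بر")
  expect_identical(normalize_spacing("سلام   دنیا", rules), "سلام دنیا")
  expect_identical(normalize_spacing("  a\t\tb  ", rules), "a b")
  expect_identical(normalize_spacing("", rules), "")
})

test_that("affix standardization attaches suffixes and half-space-joins prefixes", {
  expect_identical(normalize_affixes("مناسب تر", rules), "مناسبتر")
  expect_identical(normalize_affixes("می رود", rules),
                   paste0("می", "‌", "رود"))
  expect_identical(normalize_affixes("خوب", rules), "خوب")
  # longer prefix wins over its prefix-substring
  expect_identical(normalize_affixes("نمی رود", rules),
                   paste0("نمی", "‌", "رود"))
})

test_that("spelling variants and split compounds map to canonical forms", {
  expect_identical(normalize_spelling("اطاق", rules), "اتاق")
  expect_identical(normalize_spelling("پیر مرد", rules), "پیرمرد")
  expect_identical(normalize_spelling("پرستار", rules), "پرستار")
})

test_that("punctuation removal strips the configured characters", {
  expect_identical(remove_punctuation("خوب!", rules), "خوب")
  expect_identical(remove_punctuation("(تست)", rules), "تست")
  expect_identical(remove_punctuation("بدون علامت", rules), "بدون علامت")
})

test_that("sentence splitting partitions at terminators and keeps trailing fragments", {
  expect_length(split_sentences("الف. ب!"), 2L)
  expect_length(split_sentences("بدون نقطه"), 1L)
  expect_length(split_sentences(""), 0L)
  expect_length(split_sentences("الف؟ ب؛ ج"), 3L)
})

test_that("tokenization splits on spaces but never on half-space", {
  zw <- paste0("می", "‌", "رود")
  expect_identical(tokenize(paste(zw, "خوب")), c(zw, "خوب"))
  expect_identical(tokenize("a  b"), c("a", "b"))
  expect_identical(tokenize(""), character())
})

test_that("stopword removal is an order-preserving surface filter", {
  expect_identical(remove_stopwords(c("از", "خوب"), rules), "خوب")
  expect_identical(remove_stopwords(character(), rules), character())
  expect_identical(remove_stopwords(c("از", "به"), rules), character())
  expect_identical(remove_stopwords(c("غذا", "و", "تخت"), rules),
                   c("غذا", "تخت"))
})

test_that("stemming strips listed suffixes and never empties a token", {
  expect_identical(stem_tokens("مناسبتر", rules), "مناسب")
  expect_identical(stem_tokens("خوب", rules), "خوب")
  expect_identical(stem_tokens("تر", rules), "تر")
  expect_identical(stem_tokens("اتاقها", rules), "اتاق")
  # two passes: plural then comparative
  expect_identical(stem_tokens("اتاقهاتر", rules), "اتاق")
})

test_that("spell-check replaces only unique distance-1 misses", {
  vocab <- c("خوب", "بد", "کار", "بار")
  expect_identical(spell_check("خواب", vocab), "خوب")
  expect_identical(spell_check("خوب", vocab), "خوب")
  # two candidates at distance one -> ambiguity guard leaves it alone
  expect_identical(spell_check("تار", vocab), "تار")
  expect_error(spell_check("x", character()), class = "persent_format_error")
})

test_that("the pipeline composes the stages in order", {
  lex <- demo_lexicon()
  doc <- normalize_comment(list(id = "a", text = "اطاق خوب!"),
                           rules, lexicon = lex)
  expect_s3_class(doc, "normalized_doc")
  expect_identical(doc$n_sentences, 1L)
  expect_identical(doc$tokens$stem, c("اتاق", "خوب"))
  expect_error(normalize_comment(list(id = "b", text = "   "), rules),
               class = "persent_empty_document")
})

test_that("every normalization operation is idempotent and order-preserving", {
  lex <- generate_lexicon(40, seed = 3)
  cfg <- generator_config(n_docs = 40, words_per_doc_mean = 15,
                          sentences_per_doc_mean = 2, seed = 9,
                          negation_rate = 0.2,
                          surface_noise_rates = list(
                            arabic_chars = 0.4, extra_spaces = 0.4,
                            detached_suffix = 0.5, split_prefix = 0.5,
                            elongation = 0.3, spelling_variant = 0.8))
  sim <- generate_corpus(cfg, lex)
  for (txt in sim$comments$text) {
    for (op in list(normalize_characters, normalize_spacing,
                    normalize_affixes, normalize_spelling,
                    remove_punctuation)) {
      once <- op(txt, rules)
      expect_identical(op(once, rules), once)
    }
    toks <- tokenize(remove_punctuation(normalize_spacing(txt, rules), rules))
    expect_identical(stem_tokens(stem_tokens(toks, rules), rules),
                     stem_tokens(toks, rules))
    kept <- remove_stopwords(toks, rules)
    expect_identical(kept, toks[toks %in% kept])   # order preserved
  }
})

test_that("re-normalizing a normalized document's text changes nothing", {
  lex <- generate_lexicon(40, seed = 3)
  cfg <- generator_config(n_docs = 25, words_per_doc_mean = 20, seed = 4,
                          negation_rate = 0)   # negation strips particles
  sim <- generate_corpus(cfg, lex)
  for (i in seq_len(nrow(sim$comments))) {
    doc <- normalize_comment(list(id = i, text = sim$comments$text[i]),
                             rules, lexicon = lex)
    rebuilt <- paste(vapply(split(doc$tokens, doc$tokens$sentence),
                            function(s) paste(s$surface, collapse = " "),
                            character(1)), collapse = ". ")
    doc2 <- normalize_comment(list(id = i, text = rebuilt),
                              rules, lexicon = lex)
    expect_identical(doc2$tokens$surface, doc$tokens$surface)
  }
})
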