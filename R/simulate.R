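# Synthetic feedback-corpus generator.
#
# The real study corpus is private, so every other module is exercised on
# generated corpora whose ground truth is known by construction. A corpus
# emulates short Persian hospital-feedback comments: about 41 words and 4
# sentences per comment, a planted topic structure over a real Persian word
# list, sentiment terms of known strength injected consistently with a 1-5
# satisfaction rating, rule-based negation written as shifter-attached
# forms, and surface noise drawn from the modeled orthographic problem
# classes (Arabic character variants, stray spaces, detached suffixes,
# spaced prefixes, kashida elongation, spelling variants). All guarantees
# are lexicon-relative: the text is not fluent Persian, but its tokens
# behave under normalization and scoring exactly as real orthography does.

#' Generator configuration
#'
#' @param n_docs Number of comments.
#' @param sentences_per_doc_mean Mean sentences per comment (default 3.9).
#' @param words_per_doc_mean Mean words per comment (default 41.3).
#' @param k_true Number of planted topics (default 3).
#' @param topic_word_concentration Dirichlet concentration of each planted
#'   topic over its own vocabulary block (default 0.5; smaller = sparser,
#'   better separated topics).
#' @param sentiment_injection_rate Probability that a sentence carries an
#'   injected sentiment term (the first sentence of every comment always
#'   does, so no comment is entirely neutral).
#' @param negation_rate Probability that a comment is written in a negating
#'   style: all its sentiment terms appear as shifter-attached forms of
#'   opposite-strength terms (plus a weaker plain term of the opposite
#'   sign), so correct scoring requires negation handling.
#' @param out_of_lexicon_rate Probability that an injected sentiment term is
#'   replaced by a word unknown to the lexicon.
#' @param surface_noise_rates Named list of per-class corruption rates in
#'   [0,1]: `arabic_chars`, `extra_spaces`, `detached_suffix`,
#'   `split_prefix`, `elongation`, `spelling_variant`. All 0 by default
#'   (clean corpus).
#' @param section_mix Named probabilities over the three feedback sections.
#' @param rating_probs Probabilities of ratings 1..5; the default skews
#'   positive, echoing the satisfaction distribution typical of hospital
#'   feedback forms.
#' @param seed RNG seed; the whole corpus is a deterministic function of
#'   the config.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_docs = 500L,
                             sentences_per_doc_mean = 3.9,
                             words_per_doc_mean = 41.3,
                             k_true = 3L,
                             topic_word_concentration = 0.5,
                             sentiment_injection_rate = 0.7,
                             negation_rate = 0.1,
                             out_of_lexicon_rate = 0,
                             surface_noise_rates = list(),
                             section_mix = c(healthcare_services = 1/3,
                                             general_services = 1/3,
                                             life_expectancy = 1/3),
                             rating_probs = c(0.10, 0.12, 0.18, 0.30, 0.30),
                             seed = 1L) {
  noise <- list(arabic_chars = 0, extra_spaces = 0, detached_suffix = 0,
                split_prefix = 0, elongation = 0, spelling_variant = 0)
  for (nm in names(surface_noise_rates)) {
    if (!nm %in% names(noise))
      stop_config(paste0("unknown noise class: ", nm))
    noise[[nm]] <- surface_noise_rates[[nm]]
  }
  cfg <- list(n_docs = as.integer(n_docs),
              sentences_per_doc_mean = sentences_per_doc_mean,
              words_per_doc_mean = words_per_doc_mean,
              k_true = as.integer(k_true),
              topic_word_concentration = topic_word_concentration,
              sentiment_injection_rate = sentiment_injection_rate,
              negation_rate = negation_rate,
              out_of_lexicon_rate = out_of_lexicon_rate,
              surface_noise_rates = noise,
              section_mix = section_mix,
              rating_probs = rating_probs,
              seed = as.integer(seed))
  rates <- c(sentiment_injection_rate, negation_rate, out_of_lexicon_rate,
             unlist(noise))
  if (any(rates < 0 | rates > 1)) stop_config("rates must be in [0, 1]")
  if (n_docs < 1L || k_true < 1L || sentences_per_doc_mean <= 0 ||
      words_per_doc_mean <= 0)
    stop_config("sizes and means must be positive")
  if (abs(sum(section_mix) - 1) > 1e-8 || abs(sum(rating_probs) - 1) > 1e-8)
    stop_config("section_mix and rating_probs must sum to 1")
  class(cfg) <- "generator_config"
  cfg
}

# Persian syllable soup for synthetic lexicon terms and out-of-lexicon
# words. First letters exclude the shifter-initial letters so generated
# terms can never be misread as negations, and alef so that a shifter
# prefix never produces an ambiguous "نا" parse.
synth_word <- function(n_syllables = 2L) {
  onset <- c("ب", "پ", "ت", "ج", "چ", "خ", "د", "ر", "ز", "س",
             "ش", "ف", "ق", "ک", "گ", "ل", "م", "و", "ه", "ی")
  vowel <- c("ا", "و", "ی")
  paste0(paste0(sample(onset, n_syllables, replace = TRUE),
                sample(vowel, n_syllables, replace = TRUE),
                collapse = ""),
         sample(onset, 1L))
}

#' Generate a balanced synthetic sentiment lexicon
#'
#' Produces `n_terms` unique synthetic Persian-script terms, half positive
#' and half negative, with strengths cycling through 1..5 so every
#' magnitude is represented in both signs. The default shifters and a
#' protected-word list ship with the lexicon.
#'
#' @param n_terms Number of terms (>= 2; rounded up to even).
#' @param seed RNG seed.
#' @param exclude Words the terms must avoid colliding with.
#' @return A `sentiment_lexicon`.
#' @export
generate_lexicon <- function(n_terms = 60L, seed = 1L, exclude = character()) {
  if (n_terms < 2L) stop_config("n_terms must be >= 2")
  n_terms <- as.integer(ceiling(n_terms / 2) * 2)
  set.seed(seed)
  rules <- default_rules()
  terms <- character()
  while (length(terms) < n_terms) {
    w <- synth_word(sample(2:3, 1L))
    if (w %in% terms || w %in% exclude || w %in% rules$stopwords) next
    if (any(endsWith(w, rules$suffixes))) next
    terms <- c(terms, w)
  }
  half <- n_terms / 2L
  strengths <- c(rep_len(1:5, half), -rep_len(1:5, half))
  sentiment_lexicon(stats::setNames(as.integer(strengths), terms),
                    shifters = rules$shifters,
                    protected_words = rules$protected_words)
}

# Draw one Dirichlet vector via gamma normalization.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

# Content vocabulary: the bundled Persian word list, extended with
# half-space compounds of word pairs until `size` words are available.
build_content_vocab <- function(size, rules, lexicon) {
  path <- system.file("extdata", "persian_words.txt", package = "persent")
  words <- read_utf8_lines(path)
  bad <- words %in% rules$stopwords | words %in% names(lexicon$entries) |
    words %in% rules$prefixes | words %in% rules$shifters |
    vapply(words, function(w) any(endsWith(w, rules$suffixes)), logical(1))
  words <- words[!bad]
  vocab <- words
  nw <- length(words)
  d <- 1L
  while (length(vocab) < size && d < nw) {
    for (i in seq_len(nw)) {
      j <- ((i + d - 1L) %% nw) + 1L
      vocab <- c(vocab, paste0(words[i], "\u200c", words[j]))
      if (length(vocab) >= size) break
    }
    d <- d + 1L
  }
  if (length(vocab) < size)
    stop_config("content vocabulary too small for requested topic structure")
  vocab[seq_len(size)]
}

#' Generate a synthetic feedback corpus with ground truth
#'
#' Each comment gets a section, a 1..5 rating, a planted dominant topic and
#' a number of sentences/words drawn around the configured means. Content
#' words come from per-topic distributions over disjoint 120-word
#' vocabulary blocks (with 5% leakage mass spread over the whole
#' vocabulary); stopwords are interleaved for realism. Sentiment terms
#' whose strengths realize the rating's intended polarity are injected into
#' scoring sentences: ratings 4-5 inject strong positives, 3 a mild
#' positive, 1-2 negatives, so the §rating-to-label rule is recoverable by
#' construction. Comments written in a negating style express each intended
#' polarity as a shifter-attached opposite term plus a weaker plain
#' opposite-sign term, so scores are only correct when negation detection
#' is on. Surface noise is applied per the configured rates; normalization
#' provably inverts it.
#'
#' @param config A [generator_config()].
#' @param lexicon A `sentiment_lexicon` whose strengths cover both signs of
#'   magnitudes 1..5 (as produced by [generate_lexicon()]).
#' @param rules A `norm_rules` (defaults to [default_rules()]).
#' @return A list with `comments` (data.frame: `id`, `section`, `text`,
#'   `rating`, `age`) and `truth` (list: per-comment data.frame `docs` with
#'   rating/label/topic/negation-style/intended score, `clean_text`,
#'   planted `phi` and `vocab`, and per-comment injection tables).
#' @export
generate_corpus <- function(config, lexicon, rules = default_rules()) {
  stopifnot(inherits(config, "generator_config"),
            inherits(lexicon, "sentiment_lexicon"))
  set.seed(config$seed)
  k <- config$k_true
  block <- 120L
  vocab <- build_content_vocab(k * block, rules, lexicon)

  # planted topic-word distributions: 95% mass on the topic's own block
  phi_true <- matrix(0, nrow = k, ncol = length(vocab),
                     dimnames = list(NULL, vocab))
  for (t in seq_len(k)) {
    idx <- ((t - 1L) * block + 1L):(t * block)
    w <- rdirichlet1(rep(config$topic_word_concentration, block))
    phi_true[t, idx] <- 0.95 * w
    phi_true[t, ] <- phi_true[t, ] + 0.05 / length(vocab)
  }

  strengths <- lexicon$entries
  term_of <- function(strength) {
    cand <- names(strengths)[strengths == strength]
    if (!length(cand))
      stop_config(paste0("lexicon lacks a term of strength ", strength))
    if (length(cand) == 1L) cand else sample(cand, 1L)
  }
  intended_polarity <- function(rating) {
    switch(rating,
           sample(c(-3L, -4L, -5L), 1L),   # 1
           sample(c(-1L, -2L), 1L),        # 2
           1L,                             # 3
           sample(c(2L, 3L), 1L),          # 4
           sample(c(4L, 5L), 1L))          # 5
  }

  n <- config$n_docs
  ids <- sprintf("c%04d", seq_len(n))
  section <- sample(names(config$section_mix), n, replace = TRUE,
                    prob = config$section_mix)
  rating <- sample(1:5, n, replace = TRUE, prob = config$rating_probs)
  age_bin <- sample(1:3, n, replace = TRUE, prob = c(0.089, 0.636, 0.275))
  age <- ifelse(age_bin == 1L, sample(18:29, n, replace = TRUE),
                ifelse(age_bin == 2L, sample(30:60, n, replace = TRUE),
                       sample(61:85, n, replace = TRUE)))
  neg_style <- stats::runif(n) < config$negation_rate

  clean_text <- character(n)
  dominant <- integer(n)
  intended_score <- numeric(n)
  injections <- vector("list", n)

  for (d in seq_len(n)) {
    theta_alpha <- rep(0.5, k)
    theta_alpha[sample.int(k, 1L)] <- 12
    theta <- rdirichlet1(theta_alpha)
    dominant[d] <- which.max(theta)

    n_sent <- 1L + stats::rpois(1L, config$sentences_per_doc_mean - 1)
    n_words <- max(3L * n_sent,
                   round(stats::rnorm(1L, config$words_per_doc_mean,
                                      0.12 * config$words_per_doc_mean)))
    scoring <- stats::runif(n_sent) < config$sentiment_injection_rate
    scoring[1L] <- TRUE
    # intended per-sentence polarities are fixed up front so the injected
    # token count can be budgeted against the target document length
    p_sent <- ifelse(scoring,
                     vapply(seq_len(n_sent), function(s)
                       intended_polarity(rating[d]), integer(1)),
                     0L)
    inj_tokens <- sum(scoring * (1L + (neg_style[d] & abs(p_sent) >= 2L)))
    n_content <- max(2L * n_sent, n_words - inj_tokens)
    per_sent <- diff(round(seq(0, n_content, length.out = n_sent + 1L)))

    sent_texts <- character(n_sent)
    pols <- integer()
    inj <- list()
    for (s in seq_len(n_sent)) {
      m <- max(per_sent[s], 2L)
      z <- sample.int(k, m, replace = TRUE, prob = theta)
      toks <- vapply(z, function(t)
        sample(vocab, 1L, prob = phi_true[t, ]), character(1))
      # sprinkle stopwords and an occasional prefixed form for realism
      sw <- stats::runif(m) < 0.15
      if (any(sw) && length(rules$stopwords))
        toks[sw] <- sample(rules$stopwords, sum(sw), replace = TRUE)
      pre <- !sw & stats::runif(m) < 0.05
      toks[pre] <- paste0("می", "\u200c", toks[pre])
      plural <- !sw & !pre & stats::runif(m) < 0.10
      toks[plural] <- paste0(toks[plural], "ها")

      if (scoring[s]) {
        p <- p_sent[s]
        oov <- stats::runif(1L) < config$out_of_lexicon_rate
        if (neg_style[d]) {
          main <- paste0("ن", term_of(-p))
          extra <- if (abs(p) >= 2L)
            term_of(as.integer(-sign(p) * (abs(p) - 1L))) else NULL
        } else {
          main <- term_of(p)
          extra <- NULL
        }
        if (oov) main <- synth_word(3L)
        ins <- c(main, extra)
        pos <- sort(sample.int(length(toks) + 1L, length(ins))) - 1L
        out <- character()
        last <- 0L
        for (q in seq_along(ins)) {
          out <- c(out, toks[seq_len(pos[q] - last) + last], ins[q])
          last <- pos[q]
        }
        toks <- c(out, if (last < length(toks)) toks[(last + 1L):length(toks)])
        pols <- c(pols, if (oov && !neg_style[d]) 0L
                  else if (oov && neg_style[d])
                    as.integer(-sign(p) * (abs(p) - 1L))
                  else p)
        inj[[length(inj) + 1L]] <- data.frame(
          sentence = s, term = main, intended = p,
          negated = neg_style[d] && !oov, oov = oov)
      }
      sent_texts[s] <- paste0(paste(toks, collapse = " "), ".")
    }
    nz <- pols[pols != 0L]
    intended_score[d] <- if (length(nz)) mean(nz) / 5 else 0
    injections[[d]] <- do.call(rbind, inj)
    clean_text[d] <- paste(sent_texts, collapse = " ")
  }

  noisy <- corrupt_surface(clean_text, config$surface_noise_rates, rules)
  comments <- data.frame(id = ids, section = section, text = noisy,
                         rating = rating, age = as.integer(age),
                         stringsAsFactors = FALSE)
  truth <- list(
    docs = data.frame(id = ids, section = section, rating = rating,
                      label = rating_to_label(rating),
                      dominant_topic = dominant,
                      negation_style = neg_style,
                      intended_score = intended_score,
                      stringsAsFactors = FALSE),
    clean_text = stats::setNames(clean_text, ids),
    phi = phi_true, vocab = vocab,
    injections = stats::setNames(injections, ids)
  )
  list(comments = comments, truth = truth)
}

#' Apply surface orthographic noise
#'
#' Corrupts clean normalized text with the modeled noise classes, each at
#' its configured rate: canonical spellings replaced by variant spellings
#' (including dropped initial "آ"), attached suffixes detached by a space,
#' half-space prefixes split by a space, Persian ی/ک re-encoded as their
#' Arabic code points, kashida elongation inserted, and extra spaces/tabs
#' added between words. By construction the normalization pipeline maps
#' the corrupted text back to the same normalized form as the clean text.
#'
#' @param text Character vector of clean text.
#' @param noise_rates Named list of per-class rates (see
#'   [generator_config()]).
#' @param rules A `norm_rules` supplying the inverse maps.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return Character vector of corrupted text, same length.
#' @export
corrupt_surface <- function(text, noise_rates = list(), rules = default_rules(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  noise <- list(arabic_chars = 0, extra_spaces = 0, detached_suffix = 0,
                split_prefix = 0, elongation = 0, spelling_variant = 0)
  for (nm in names(noise_rates)) noise[[nm]] <- noise_rates[[nm]]
  if (all(unlist(noise) == 0)) return(unname(text))

  # inverse spelling map: canonical -> variant (spelling variants plus the
  # dropped-alef word list from the character map)
  words_cm <- rules$char_map[nchar(names(rules$char_map)) > 1L]
  inv <- c(stats::setNames(names(rules$spelling_variants),
                           unname(rules$spelling_variants)),
           stats::setNames(names(words_cm), unname(words_cm)))
  sufs <- rules$suffixes[order(-nchar(rules$suffixes))]
  pres <- rules$prefixes

  vapply(text, function(txt) {
    toks <- strsplit(txt, " ", fixed = TRUE)[[1]]
    for (i in seq_along(toks)) {
      tok <- toks[[i]]
      term <- ""
      # keep a trailing sentence terminator out of word-level edits
      if (grepl("[.!?؟؛]$", tok, perl = TRUE)) {
        term <- substring(tok, nchar(tok))
        tok <- substring(tok, 1L, nchar(tok) - 1L)
      }
      if (!nzchar(tok)) next
      # one word-level corruption at most, so classes never interact
      if (tok %in% names(inv) && stats::runif(1) < noise$spelling_variant) {
        tok <- inv[[tok]]
      } else if (stats::runif(1) < noise$detached_suffix) {
        for (sfx in sufs) {
          if (endsWith(tok, sfx) && nchar(tok) > nchar(sfx) + 1L &&
              !grepl("\u200c", substring(tok, nchar(tok) - nchar(sfx),
                                     nchar(tok) - nchar(sfx)))) {
            tok <- paste0(substring(tok, 1L, nchar(tok) - nchar(sfx)),
                          " ", sfx)
            break
          }
        }
      } else if (stats::runif(1) < noise$split_prefix) {
        for (pre in pres) {
          zp <- paste0(pre, "\u200c")
          if (startsWith(tok, zp) && nchar(tok) > nchar(zp)) {
            tok <- paste0(pre, " ", substring(tok, nchar(zp) + 1L))
            break
          }
        }
      }
      # character-level corruptions stack freely
      if (noise$arabic_chars > 0) {
        ch <- strsplit(tok, "")[[1]]
        swap <- stats::runif(length(ch)) < noise$arabic_chars
        ch[swap & ch == "ی"] <- "ي"
        ch[swap & ch == "ک"] <- "ك"
        tok <- paste(ch, collapse = "")
      }
      if (stats::runif(1) < noise$elongation && nchar(tok) >= 2L &&
          !grepl(" ", tok, fixed = TRUE)) {
        at <- sample.int(nchar(tok) - 1L, 1L)
        tok <- paste0(substring(tok, 1L, at),
                      strrep("\u0640", sample.int(4L, 1L)),
                      substring(tok, at + 1L))
      }
      toks[[i]] <- paste0(tok, term)
    }
    seps <- ifelse(stats::runif(length(toks) - 1L) < noise$extra_spaces,
                   sample(c("  ", "   ", "\t", " \t "),
                          max(length(toks) - 1L, 1L), replace = TRUE),
                   " ")
    paste0(toks[1L],
           if (length(toks) > 1L)
             paste0(seps, toks[-1L], collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}
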