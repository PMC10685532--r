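# Text normalization pipeline for Persian feedback comments.
#
# Raw comments arrive with mixed Arabic/Persian code points, stray spaces
# and tabs, kashida elongation, detached suffixes, spaced prefixes, variant
# spellings and attached negation particles. Each operation below fixes one
# class of problem; `normalize_comment()` composes them in a fixed order:
# characters -> spacing -> affixes -> spelling -> sentence split ->
# punctuation removal -> tokenization -> optional spell-check -> negation
# detection -> stopword removal -> stemming. Every operation is idempotent
# and order-preserving.

# word-boundary lookarounds: a "word" here is a maximal run of letters and
# half-spaces, so ZWNJ never acts as a boundary.
.wb_left <- "(?<![\\p{L}\u200c])"
.wb_right <- "(?![\\p{L}\u200c])"

replace_words <- function(text, map) {
  for (key in names(map)) {
    text <- gsub(paste0(.wb_left, key, .wb_right), map[[key]],
                 text, perl = TRUE)
  }
  text
}

#' Unify character encodings
#'
#' Replaces Arabic code points that shadow Persian letters (e.g. U+064A
#' ARABIC YEH for U+06CC FARSI YEH, U+0643 KAF for U+06A9 KEHEH) with their
#' canonical Persian forms, strips Arabic diacritics, and restores the
#' initial long alef for the whole words enumerated in the rule set (e.g.
#' "اب" -> "آب"). Unknown characters pass through
#' unchanged; the operation is idempotent.
#'
#' @param text Character vector.
#' @param rules A `norm_rules` object.
#' @return Character vector of the same length.
#' @export
normalize_characters <- function(text, rules = default_rules()) {
  cm <- rules$char_map
  # elongation must go before the whole-word entries are matched, or a
  # kashida inside a mapped word ("اــب") would hide it
  for (ch in rules$elongation_chars) {
    text <- gsub(ch, "", text, fixed = TRUE)
  }
  singles <- cm[nchar(names(cm)) == 1L]
  words <- cm[nchar(names(cm)) > 1L]
  if (length(singles)) {
    text <- chartr(paste(names(singles), collapse = ""),
                   paste(unname(singles), collapse = ""), text)
  }
  # Arabic diacritics (fathatan..sukun) carry no meaning in this corpus
  text <- gsub("[\u064b-\u0652\u0670]", "", text, perl = TRUE)
  if (length(words)) text <- replace_words(text, words)
  text
}

#' Normalize spacing and remove elongation
#'
#' Collapses runs of spaces and tabs to a single space, trims leading and
#' trailing whitespace, deletes kashida elongation characters
#' ("بــــــر" -> "بر"), collapses repeated
#' half-spaces, and drops half-spaces stranded next to a space. Half-spaces
#' inside words are preserved.
#'
#' @inheritParams normalize_characters
#' @return Character vector of the same length.
#' @export
normalize_spacing <- function(text, rules = default_rules()) {
  for (ch in rules$elongation_chars) {
    text <- gsub(ch, "", text, fixed = TRUE)
  }
  text <- gsub(" ", " ", text, fixed = TRUE)   # no-break space
  text <- gsub("[ \t]+", " ", text, perl = TRUE)
  text <- gsub("\u200c+", "\u200c", text, perl = TRUE)
  # a half-space adjacent to a real space is typographic debris
  text <- gsub("\u200c | \u200c|^\u200c|\u200c$", " ", text, perl = TRUE)
  text <- gsub("[ \t]+", " ", text, perl = TRUE)
  trimws(text)
}

#' Standardize suffix and prefix attachment
#'
#' A listed suffix written as its own token ("مناسب تر")
#' or joined by a half-space is attached directly to the preceding word
#' ("مناسبتر"). A listed verbal/adjectival prefix written as
#' its own token ("می رود") is joined to the following word
#' with a half-space ("می‌رود"), the APLL-preferred form.
#' Words carrying no listed affix are untouched.
#'
#' @inheritParams normalize_characters
#' @return Character vector of the same length.
#' @export
normalize_affixes <- function(text, rules = default_rules()) {
  if (length(rules$prefixes)) {
    pre <- paste(rules$prefixes[order(-nchar(rules$prefixes))], collapse = "|")
    text <- gsub(paste0(.wb_left, "(", pre, ") (?=\\p{L})"), "\\1\u200c",
                 text, perl = TRUE)
  }
  if (length(rules$suffixes)) {
    suf <- paste(rules$suffixes[order(-nchar(rules$suffixes))], collapse = "|")
    text <- gsub(paste0("(\\p{L})[ \u200c](", suf, ")", .wb_right), "\\1\\2",
                 text, perl = TRUE)
  }
  text
}

#' Map variant spellings to their canonical form
#'
#' Whole-word occurrences of spelling-variant keys (homophone spellings
#' such as "اطاق" for "اتاق", and compound words
#' written apart such as "پیر مرد") are replaced by their
#' canonical values. Words absent from the map are unchanged.
#'
#' @inheritParams normalize_characters
#' @return Character vector of the same length.
#' @export
normalize_spelling <- function(text, rules = default_rules()) {
  if (length(rules$spelling_variants))
    text <- replace_words(text, rules$spelling_variants)
  text
}

#' Remove punctuation characters
#'
#' Deletes every character in the rule set's punctuation inventory. Callers
#' that need sentence boundaries must split first and strip after:
#' [split_sentences()] consumes the terminators that this operation deletes.
#'
#' @inheritParams normalize_characters
#' @return Character vector of the same length.
#' @export
remove_punctuation <- function(text, rules = default_rules()) {
  if (!length(rules$punctuation)) return(text)
  cls <- paste0("[", paste0("\\Q", rules$punctuation, "\\E", collapse = ""), "]")
  text <- gsub(cls, " ", text, perl = TRUE)
  normalize_spacing(text, rules)
}

#' Split text into sentences
#'
#' Partitions text at sentence terminators (Latin and Arabic full stop,
#' "؟", "?", "!", "؛" and newline). A trailing
#' fragment without a terminator forms its own sentence; empty fragments
#' are dropped.
#'
#' @param text A single character string.
#' @return Character vector of sentence texts (possibly empty).
#' @export
split_sentences <- function(text) {
  if (is.na(text) || !nzchar(trimws(text))) return(character())
  parts <- strsplit(text, "(?<=[.!?؟؛\n])", perl = TRUE)[[1]]
  parts <- trimws(gsub("^[.!?؟؛\n ]+", "", parts, perl = TRUE))
  parts[nzchar(parts)]
}

#' Tokenize a sentence
#'
#' Splits on spaces only; the half-space is a word-internal character and
#' never separates a token. Empty tokens are dropped.
#'
#' @param text A single character string (already space-normalized).
#' @return Character vector of surface tokens.
#' @export
tokenize <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character())
  toks <- strsplit(trimws(text), " +", perl = TRUE)[[1]]
  toks[nzchar(toks)]
}

#' Remove stopwords
#'
#' Order-preserving filter: a token is removed iff its surface form is in
#' the rule set's stopword list.
#'
#' @param tokens Character vector of tokens.
#' @inheritParams normalize_characters
#' @return Filtered character vector.
#' @export
remove_stopwords <- function(tokens, rules = default_rules()) {
  tokens[!(tokens %in% rules$stopwords)]
}

#' Stem tokens by suffix stripping
#'
#' The default stemmer strips the longest listed suffix (optionally joined
#' by a half-space), iterating at most twice so stacked suffixes like
#' "ها" + "یی" come off. If stripping would empty the
#' token it is returned unchanged, so stems are always non-empty. The
#' stemmer is deliberately a list-driven interface: a heavier morphological
#' stemmer can be swapped in by supplying a different suffix inventory.
#'
#' @param tokens Character vector of normalized tokens.
#' @inheritParams normalize_characters
#' @return Character vector of stems, same length and order.
#' @export
stem_tokens <- function(tokens, rules = default_rules()) {
  if (!length(tokens)) return(character())
  sufs <- rules$suffixes[order(-nchar(rules$suffixes))]
  strip_one <- function(tok) {
    for (s in sufs) {
      for (pat in c(paste0("\u200c", s), s)) {
        if (endsWith(tok, pat) && nchar(tok) > nchar(pat)) {
          return(substr(tok, 1L, nchar(tok) - nchar(pat)))
        }
      }
    }
    tok
  }
  vapply(tokens, function(tok) {
    out <- strip_one(tok)
    out <- strip_one(out)
    if (!nzchar(out)) tok else out
  }, character(1), USE.NAMES = FALSE)
}

#' Conservative dictionary spell-check
#'
#' A token absent from the vocabulary is replaced by the unique vocabulary
#' word at edit (Levenshtein) distance 1, if exactly one such word exists;
#' otherwise it passes through unchanged. In-vocabulary tokens are never
#' altered. This conservative rule trades recall for precision: it never
#' guesses between competing corrections.
#'
#' @param tokens Character vector of tokens.
#' @param vocabulary Non-empty character vector of known words.
#' @return Character vector, same length and order.
#' @export
spell_check <- function(tokens, vocabulary) {
  if (!length(vocabulary)) stop_format("spell_check requires a non-empty vocabulary")
  if (!length(tokens)) return(character())
  vocabulary <- unique(vocabulary)
  vapply(tokens, function(tok) {
    if (tok %in% vocabulary) return(tok)
    d <- utils::adist(tok, vocabulary)
    hits <- vocabulary[d == 1L]
    if (length(hits) == 1L) hits else tok
  }, character(1), USE.NAMES = FALSE)
}

#' Normalize one comment into a sentence-split, tokenized document
#'
#' Applies the full normalization pipeline in a fixed order: character
#' unification, spacing, affix standardization, spelling variants, sentence
#' splitting, punctuation removal, tokenization, optional spell-check,
#' negation detection (when a lexicon is supplied), stopword removal and
#' stemming. The order is chosen so that each stage sees the surface form
#' the next stage's rules expect: character and spacing fixes first so the
#' affix and spelling maps match, sentence splitting before punctuation
#' removal so terminators are still present.
#'
#' @param comment A character string, or a list/row with `id` and `text`
#'   fields (and optionally `section`, `rating`).
#' @param rules A `norm_rules` object.
#' @param lexicon Optional [sentiment_lexicon()]; enables negation
#'   detection. When `NULL`, all tokens are marked non-negated.
#' @param vocabulary Optional extra vocabulary for negation detection and
#'   spell-checking.
#' @param spell Logical; run the conservative spell-check (default `FALSE`).
#' @param stopword_removal Logical; remove stopwords (default `TRUE`).
#' @return An object of class `normalized_doc`: a list with `comment_id`,
#'   `n_sentences`, and `tokens`, a data.frame with columns `sentence`
#'   (1-based), `surface` (normalized, shifter-stripped), `stem`, `negated`.
#' @export
normalize_comment <- function(comment, rules = default_rules(),
                              lexicon = NULL, vocabulary = NULL,
                              spell = FALSE, stopword_removal = TRUE) {
  if (is.character(comment)) {
    comment <- list(id = NA_character_, text = comment)
  }
  text <- comment$text
  if (is.null(text) || is.na(text) || !nzchar(trimws(text)))
    stop_empty_document("comment text is empty")

  text <- normalize_characters(text, rules)
  text <- normalize_spacing(text, rules)
  text <- normalize_affixes(text, rules)
  text <- normalize_spelling(text, rules)

  sents <- split_sentences(text)
  rows <- list()
  si <- 0L
  for (s in sents) {
    s <- remove_punctuation(s, rules)
    toks <- tokenize(s)
    if (spell && length(toks)) {
      vocab <- unique(c(vocabulary, if (!is.null(lexicon)) names(lexicon$entries)))
      if (length(vocab)) toks <- spell_check(toks, vocab)
    }
    if (!is.null(lexicon) && length(toks)) {
      neg <- detect_negation(toks, lexicon, vocabulary = vocabulary)
      toks <- neg$base
      negated <- neg$negated
    } else {
      negated <- rep(FALSE, length(toks))
    }
    if (stopword_removal && length(toks)) {
      keep <- !(toks %in% rules$stopwords)
      toks <- toks[keep]
      negated <- negated[keep]
    }
    if (!length(toks)) next
    si <- si + 1L
    rows[[si]] <- data.frame(
      sentence = si, surface = toks,
      stem = stem_tokens(toks, rules), negated = negated,
      stringsAsFactors = FALSE
    )
  }
  if (!si) stop_empty_document("no sentence survived normalization")
  doc <- list(
    comment_id = as.character(comment$id %||% NA_character_),
    section = comment$section %||% NA_character_,
    n_sentences = si,
    tokens = do.call(rbind, rows)
  )
  class(doc) <- "normalized_doc"
  doc
}

#' Normalize a corpus of comments
#'
#' Applies [normalize_comment()] to every row of a comment data.frame.
#' Comments that normalize to nothing (whitespace-only, all stopwords) are
#' dropped with a warning by default.
#'
#' @param comments A data.frame with columns `id`, `text` and optionally
#'   `section`, `rating` (as produced by [read_comments()] or
#'   [generate_corpus()]).
#' @param on_empty Either `"drop"` (default; skip empty comments with one
#'   summary warning) or `"error"`.
#' @inheritParams normalize_comment
#' @return A list of `normalized_doc` objects, named by comment id.
#' @export
normalize_corpus <- function(comments, rules = default_rules(),
                             lexicon = NULL, vocabulary = NULL,
                             spell = FALSE, stopword_removal = TRUE,
                             on_empty = c("drop", "error")) {
  on_empty <- match.arg(on_empty)
  docs <- vector("list", nrow(comments))
  empty <- character()
  for (i in seq_len(nrow(comments))) {
    row <- as.list(comments[i, , drop = FALSE])
    doc <- tryCatch(
      normalize_comment(row, rules, lexicon = lexicon,
                        vocabulary = vocabulary, spell = spell,
                        stopword_removal = stopword_removal),
      persent_empty_document = function(e) e
    )
    if (inherits(doc, "condition")) {
      if (on_empty == "error")
        stop_empty_document(paste0("comment ", row$id, ": ", conditionMessage(doc)))
      empty <- c(empty, as.character(row$id))
      next
    }
    docs[[i]] <- doc
  }
  docs <- docs[!vapply(docs, is.null, logical(1))]
  if (length(empty))
    warning(length(empty), " comment(s) normalized to nothing and were dropped",
            call. = FALSE)
  names(docs) <- vapply(docs, function(d) d$comment_id, character(1))
  docs
}

#' @export
print.normalized_doc <- function(x, ...) {
  cat("<normalized_doc ", x$comment_id, "> ", x$n_sentences, " sentence(s), ",
      nrow(x$tokens), " token(s)\n", sep = "")
  invisible(x)
}
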