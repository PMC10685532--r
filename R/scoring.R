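# Sentence and document sentiment scoring.
#
# Sentence polarity follows the SentiStrength strategy: every token is
# looked up in the strength lexicon (with negation-aware sign inversion),
# the maximum positive and minimum negative strengths are recorded, and the
# one with the larger absolute value is the sentence polarity (an exact tie
# is neutral). Document scores are the mean of the nonzero sentence
# polarities rescaled to [-1, +1] by dividing by 5, so a document whose
# every scored sentence is maximally negative prints -1 ("most pessimistic")
# and maximally positive prints +1 ("most optimistic").

#' Score one sentence
#'
#' @param tokens A data.frame with columns `stem` and `negated` (one row per
#'   token, as produced by [normalize_comment()]), or a character vector of
#'   stems (taken as non-negated).
#' @param lexicon A `sentiment_lexicon`.
#' @return A list of class `sentence_score` with integer fields `max_pos`
#'   (0..5), `min_neg` (-5..0) and `polarity` (-5..+5).
#' @export
score_sentence <- function(tokens, lexicon) {
  if (is.character(tokens)) {
    tokens <- data.frame(stem = tokens, negated = rep(FALSE, length(tokens)),
                         stringsAsFactors = FALSE)
  }
  s <- lookup_strength(lexicon, tokens$stem, tokens$negated)
  s <- s[!is.na(s)]
  max_pos <- if (any(s > 0)) max(s) else 0L
  min_neg <- if (any(s < 0)) min(s) else 0L
  polarity <- if (max_pos > -min_neg) max_pos
              else if (-min_neg > max_pos) min_neg
              else 0L   # tie (including the all-neutral case) -> neutral
  structure(list(max_pos = as.integer(max_pos),
                 min_neg = as.integer(min_neg),
                 polarity = as.integer(polarity)),
            class = "sentence_score")
}

#' Score one normalized document
#'
#' Scores each sentence, then maps the sentence polarities onto the
#' [-1, +1] reporting scale: the document score is the arithmetic mean of
#' the nonzero sentence polarities divided by 5 (0 if every sentence is
#' neutral). The label is the sign of the score with `neutral` at zero (or
#' within the optional neutral band).
#'
#' @param doc A `normalized_doc`.
#' @param lexicon A `sentiment_lexicon`.
#' @param neutral_band Non-negative half-width of the neutral zone passed
#'   to [classify_score()] (default 0).
#' @return A list of class `document_score` with fields `comment_id`,
#'   `section`, `sentence_polarities` (integer vector), `score` in
#'   [-1, +1], and `label` in `{"positive","negative","neutral"}`.
#' @export
score_document <- function(doc, lexicon, neutral_band = 0) {
  stopifnot(inherits(doc, "normalized_doc"))
  if (!nrow(doc$tokens)) stop_empty_document("document has no tokens")
  pol <- vapply(split(doc$tokens, doc$tokens$sentence),
                function(tt) score_sentence(tt, lexicon)$polarity,
                integer(1))
  nz <- pol[pol != 0L]
  score <- if (length(nz)) mean(nz) / 5 else 0
  structure(list(comment_id = doc$comment_id,
                 section = doc$section,
                 sentence_polarities = unname(pol),
                 score = score,
                 label = classify_score(score, neutral_band)),
            class = "document_score")
}

#' Score a corpus of normalized documents
#'
#' @param docs A list of `normalized_doc` objects.
#' @param lexicon A `sentiment_lexicon`.
#' @param neutral_band Passed to [score_document()].
#' @return A data.frame with one row per document: `comment_id`, `section`,
#'   `score`, `label`, `n_sentences`.
#' @export
score_corpus <- function(docs, lexicon, neutral_band = 0) {
  rows <- lapply(docs, function(d) {
    ds <- score_document(d, lexicon, neutral_band)
    data.frame(comment_id = ds$comment_id,
               section = as.character(ds$section),
               score = ds$score, label = ds$label,
               n_sentences = length(ds$sentence_polarities),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a score into positive / negative / neutral
#'
#' @param score Numeric vector with values in [-1, 1].
#' @param neutral_band Non-negative half-width of the neutral zone: scores
#'   strictly above it are positive, strictly below its negative are
#'   negative, everything else neutral. Default 0.
#' @return Character vector of labels.
#' @export
classify_score <- function(score, neutral_band = 0) {
  stopifnot(neutral_band >= 0)
  ifelse(score > neutral_band, "positive",
         ifelse(score < -neutral_band, "negative", "neutral"))
}

#' Usefulness-weighted aggregation of review scores
#'
#' Computes the overall valuation of a group of reviews as the weighted
#' average of individual review polarities,
#' \deqn{V = \frac{\sum_i u_i \, s_i}{\sum_i u_i},}
#' where the weights \eqn{u_i} encode each review's relative usefulness.
#' With all weights equal this reduces to the arithmetic mean. Reviews of
#' hospital feedback carry no usefulness votes, so the weights default to 1.
#'
#' @param scores Numeric vector of document scores.
#' @param weights Non-negative numeric vector of the same length with
#'   positive sum (default all 1).
#' @param group_key Optional label carried through to the result.
#' @return A list of class `aggregate_score` with fields `group_key`, `V`,
#'   `n` and `weights`.
#' @export
aggregate_scores <- function(scores, weights = rep(1, length(scores)),
                             group_key = NA_character_) {
  if (length(scores) != length(weights))
    stop_length("scores and weights must have the same length")
  if (any(weights < 0)) stop_weight("weights must be non-negative")
  if (sum(weights) <= 0) stop_weight("weights must not sum to zero")
  structure(list(group_key = group_key,
                 V = sum(weights * scores) / sum(weights),
                 n = length(scores),
                 weights = weights),
            class = "aggregate_score")
}

#' Per-topic sentiment table
#'
#' Groups scored documents by their dominant topic and reports, for each
#' topic, the number of documents, the share of all scored documents, and
#' the equal-weight aggregate sentiment score. Topics with no documents are
#' reported with `n = 0` and an `NA` score.
#'
#' @param scores A data.frame with columns `comment_id` and `score` (as
#'   from [score_corpus()]).
#' @param dominant_topics Named integer vector mapping comment id to a
#'   dominant topic in `1..k`.
#' @param k Number of topics.
#' @return A data.frame with columns `topic`, `n`, `share`, `score`.
#' @export
topic_sentiment <- function(scores, dominant_topics, k) {
  topic <- unname(dominant_topics[scores$comment_id])
  if (any(is.na(topic)))
    stop_format("every scored comment needs a dominant topic")
  if (any(topic < 1L | topic > k))
    stop_range("dominant topic outside 1..k")
  n_total <- nrow(scores)
  rows <- lapply(seq_len(k), function(t) {
    idx <- which(topic == t)
    data.frame(topic = t, n = length(idx),
               share = length(idx) / n_total,
               score = if (length(idx))
                 aggregate_scores(scores$score[idx])$V else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ranked term-frequency report
#'
#' Counts stem occurrences over a normalized corpus (stopwords have already
#' been removed upstream) and returns the `top_n` most frequent terms,
#' descending, ties broken lexicographically. This is the tabular analogue
#' of a word cloud.
#'
#' @param docs A list of `normalized_doc` objects.
#' @param top_n Maximum number of terms to return.
#' @return A data.frame with columns `term` and `count`.
#' @export
term_frequency_report <- function(docs, top_n = 20L) {
  stems <- unlist(lapply(docs, function(d) d$tokens$stem), use.names = FALSE)
  if (!length(stems))
    return(data.frame(term = character(), count = integer()))
  tab <- table(stems)
  out <- data.frame(term = enc2utf8(names(tab)), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$term, method = "radix"), , drop = FALSE]
  out <- utils::head(out, top_n)
  rownames(out) <- NULL
  out
}

#' @export
print.sentence_score <- function(x, ...) {
  cat("<sentence_score> max_pos=", x$max_pos, " min_neg=", x$min_neg,
      " polarity=", x$polarity, "\n", sep = "")
  invisible(x)
}

#' @export
print.document_score <- function(x, ...) {
  cat("<document_score ", x$comment_id, "> score=", format(x$score),
      " label=", x$label, " [", paste(x$sentence_polarities, collapse = " "),
      "]\n", sep = "")
  invisible(x)
}
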